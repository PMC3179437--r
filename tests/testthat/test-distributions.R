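test_that("pdf matches canonical values and family nesting", {
  expect_equal(dist_pdf("lognormal", 0, 1, 1), 1 / sqrt(2 * pi))
  xs <- seq(0.05, 0.95, by = 0.1)
  expect_equal(dist_pdf("beta", 1, 1, xs), rep(1, length(xs)))
  grid <- seq(0.01, 5, length.out = 200)
  expect_equal(dist_pdf("gamma", 1, 0.5, grid),
               dist_pdf("exponential", NA, 2, grid), tolerance = 1e-12)
  # outside support the density is 0, not an error
  expect_equal(dist_pdf("beta", 2, 3, c(-0.5, 1.5)), c(0, 0))
  expect_equal(dist_pdf("lognormal", 0, 1, -1), 0)
  # invalid parameters raise
  expect_error(dist_pdf("gamma", -1, 1, 1), "positive")
  expect_error(dist_pdf("nope", 1, 1, 1), "unknown family")
})

test_that("fitted pdfs integrate to 1 over their support", {
  fits <- list(
    fit_mle("lognormal", exp(rnorm(200, -1, 0.5))),
    fit_mle("gamma", rgamma(200, 2, scale = 0.1)),
    fit_mle("beta", rbeta(200, 5, 2)),
    fit_mle("exponential", rexp(200, 3)))
  for (f in fits) {
    up <- if (f$family == "beta") 1 else Inf
    val <- stats::integrate(function(x)
      dist_pdf(f$family, f$alpha, f$beta_param, x), 0, up,
      rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
})

test_that("interval probability is a cdf difference", {
  f <- fit_mle("lognormal", exp(rnorm(100)))
  f$alpha <- 0; f$beta_param <- 1
  expect_equal(interval_probability(f, 2, 2), 0)
  expect_equal(interval_probability(f, 0, Inf), 1)
  expect_equal(interval_probability(f, exp(-1.96), exp(1.96)),
               2 * pnorm(1.96) - 1, tolerance = 1e-12)
  expect_error(interval_probability(f, 2, 1), "must not exceed")
})

test_that("closed-form estimators are exact", {
  f <- fit_mle("lognormal", c(exp(1), exp(3)))
  expect_identical(f$alpha, 2)
  expect_identical(f$beta_param, 1)

  x <- c(0.2, 0.5, 1.4, 2.2)
  fe <- fit_mle("exponential", x)
  expect_identical(fe$beta_param, 1 / mean(x))

  # degenerate sample: all equal
  fd <- fit_mle("lognormal", rep(3, 10))
  expect_true(fd$degenerate)
  expect_equal(fd$alpha, log(3))
  expect_identical(fd$beta_param, 0)

  expect_error(fit_mle("lognormal", 5), "at least 2")
  expect_error(fit_mle("gamma", c(-1, 2)), "positive")
})

test_that("numerical MLE recovers gamma parameters and matches fitdistrplus", {
  set.seed(77)
  x <- rgamma(10000, shape = 2, scale = 0.1)
  f <- fit_mle("gamma", x)
  expect_gt(f$alpha, 1.9); expect_lt(f$alpha, 2.1)
  expect_gt(f$beta_param, 0.095); expect_lt(f$beta_param, 0.105)

  ref <- fitdistrplus::fitdist(x, "gamma")   # shape/rate parameterization
  expect_equal(f$alpha, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$beta_param, 1 / unname(ref$estimate["rate"]),
               tolerance = 1e-3)
})

test_that("numerical MLE recovers beta parameters and matches fitdistrplus", {
  set.seed(78)
  x <- rbeta(10000, 8, 1.5)
  f <- fit_mle("beta", x)
  expect_lt(abs(f$alpha - 8) / 8, 0.05)
  expect_lt(abs(f$beta_param - 1.5) / 1.5, 0.05)
  ref <- fitdistrplus::fitdist(x, "beta")
  expect_equal(f$alpha, unname(ref$estimate["shape1"]), tolerance = 1e-3)
  expect_equal(f$beta_param, unname(ref$estimate["shape2"]),
               tolerance = 1e-3)
})

test_that("histograms are density-normalized with the requested binning", {
  set.seed(5)
  x <- rgamma(2000, 2, scale = 0.1)
  h <- make_histogram(x, bin_spec("linear", 25, c(0, 1)))
  expect_equal(sum(h$density * h$widths), length(x[x <= 1]) / length(x),
               tolerance = 1e-9)
  hl <- make_histogram(x, bin_spec("log", 30))
  expect_equal(sum(hl$density * hl$widths), 1, tolerance = 1e-9)
  expect_true(all(diff(hl$edges) > 0))
  expect_error(make_histogram(c(-1, x), bin_spec("log", 10)), "positive")
})

test_that("an exact-density histogram is a fixed point of the lsq fitter", {
  spec <- bin_spec("linear", 25, c(0, 1))
  h <- make_histogram(seq(0.01, 0.99, length.out = 100), spec)
  h$density <- dist_pdf("gamma", 2, 0.1, h$centers)
  h$counts <- rep(10L, length(h$centers))   # non-empty bins
  f <- fit_lsq("gamma", histogram = h)
  expect_equal(f$alpha, 2, tolerance = 1e-6)
  expect_equal(f$beta_param, 0.1, tolerance = 1e-6)
  expect_lt(f$goodness, 1e-12)
})

test_that("lsq recovers beta parameters from 10,000 draws", {
  set.seed(91)
  x <- rbeta(10000, 8, 1.5)
  f <- fit_lsq("beta", x, spec = bin_spec("linear", 30, c(0, 1)))
  expect_gt(f$alpha, 7.2); expect_lt(f$alpha, 8.8)
  expect_gt(f$beta_param, 1.35); expect_lt(f$beta_param, 1.65)
  expect_identical(f$method, "lsq")
  expect_true(f$ci95_alpha[1] < f$alpha & f$alpha < f$ci95_alpha[2])
})

test_that("mle and lsq agree with truth on lognormal samples", {
  set.seed(92)
  x <- rlnorm(5000, -2, 1)
  fm <- fit_mle("lognormal", x)
  fl <- fit_lsq("lognormal", x, spec = bin_spec("log", 30))
  expect_lt(abs(fm$alpha - (-2)) / 2, 0.05)
  expect_lt(abs(fl$alpha - (-2)) / 2, 0.05)
})

test_that("lsq is invariant to duplicating every observation", {
  set.seed(93)
  x <- rgamma(500, 2, scale = 0.12)
  x <- x[x < 1]
  spec <- bin_spec("linear", 25, c(0, 1))
  f1 <- fit_lsq("gamma", x, spec = spec)
  f2 <- fit_lsq("gamma", rep(x, 2), spec = spec)
  # the histograms are identical; optimizer paths may differ only through
  # the method-of-moments start (n-1 variance denominator), so the optima
  # agree to optimizer precision
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-7)
  expect_equal(f1$beta_param, f2$beta_param, tolerance = 1e-7)
})

test_that("lsq input validation", {
  expect_error(fit_lsq("gamma", rgamma(10, 2)), "at least 50")
  h <- make_histogram(rep(0.5, 100), bin_spec("linear", 25, c(0, 1)))
  expect_error(fit_lsq("gamma", histogram = h), "non-empty")
})

test_that("expected values and medians follow the closed forms", {
  g <- fit_mle("gamma", rgamma(100, 2, scale = 0.1))
  g$alpha <- 2; g$beta_param <- 0.1
  expect_equal(expected_value(g), 0.2)
  expect_lt(median_value(g), expected_value(g))   # right-skewed

  b <- fit_mle("beta", rbeta(100, 3, 3))
  b$alpha <- 4; b$beta_param <- 4
  expect_equal(expected_value(b), 0.5)
  b$alpha <- 1; b$beta_param <- 1
  expect_equal(median_value(b), 0.5)

  ln <- fit_mle("lognormal", exp(rnorm(100)))
  ln$alpha <- -2; ln$beta_param <- 1
  expect_equal(median_value(ln), exp(-2))
  expect_equal(expected_value(ln), exp(-2 + 0.5))
  ln$beta_param <- 0
  expect_equal(expected_value(ln), exp(-2))
})

test_that("model comparison picks the generating family", {
  set.seed(99)
  xl <- rlnorm(5000, -2, 1)
  cl <- compare_models(xl)
  expect_identical(cl$best, "lognormal")
  expect_lt(cl$sse["lognormal"], cl$sse["exponential"])

  xe <- rexp(5000, rate = 5)
  ce <- compare_models(xe)
  expect_identical(ce$best, "exponential")
})

test_that("fit JSON round trip preserves full precision", {
  set.seed(7)
  f <- fit_lsq("gamma", rgamma(500, 2, scale = 0.1),
               spec = bin_spec("linear", 25, c(0, 1)))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  g <- read_fit_json(path)
  expect_equal(g$alpha, f$alpha, tolerance = 1e-14)
  expect_equal(g$beta_param, f$beta_param, tolerance = 1e-14)
  expect_equal(g$ci95_alpha, f$ci95_alpha, tolerance = 1e-14)
  expect_identical(g$method, f$method)
  expect_identical(g$bin_spec$type, f$bin_spec$type)
})
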