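FIT_FAMILIES <- c("lognormal", "gamma", "beta", "exponential")

.check_family <- function(family) {
  if (!family %in% FIT_FAMILIES)
    stop("unknown family '", family, "'; must be one of ",
         paste(FIT_FAMILIES, collapse = ", "))
  family
}

.check_params <- function(family, alpha, beta_param) {
  if (!is.numeric(beta_param) || !is.finite(beta_param) || beta_param <= 0)
    stop(family, ": 'beta_param' must be a positive number")
  if (family %in% c("gamma", "beta") &&
      (!is.numeric(alpha) || !is.finite(alpha) || alpha <= 0))
    stop(family, ": 'alpha' must be a positive number")
  if (family == "lognormal" && (!is.numeric(alpha) || !is.finite(alpha)))
    stop("lognormal: 'alpha' must be a finite number")
  invisible(TRUE)
}

#' Two-parameter population density
#'
#' Density of the population models used for cluster properties, under one
#' shared (alpha, beta) parameter convention:
#' \describe{
#'   \item{lognormal}{`ln x ~ Normal(alpha, beta^2)`; alpha is the scale
#'     (log-location, `exp(alpha)` is the median), beta the shape.}
#'   \item{gamma}{shape `alpha`, scale `beta`; mean `alpha * beta`.}
#'   \item{beta}{standard two-shape density on \[0, 1\].}
#'   \item{exponential}{rate `beta_param` (alpha unused).}
#' }
#' Evaluation outside the support returns 0.
#'
#' @param family One of `"lognormal"`, `"gamma"`, `"beta"`,
#'   `"exponential"`.
#' @param alpha,beta_param Parameters as above.
#' @param x Evaluation points.
#' @return Density values.
#' @export
dist_pdf <- function(family, alpha, beta_param, x) {
  .check_family(family)
  .check_params(family, alpha, beta_param)
  out <- switch(family,
    lognormal = dlnorm(x, meanlog = alpha, sdlog = beta_param),
    gamma = dgamma(x, shape = alpha, scale = beta_param),
    beta = ifelse(x < 0 | x > 1, 0, dbeta(x, alpha, beta_param)),
    exponential = dexp(x, rate = beta_param))
  out[!is.finite(out)] <- 0
  out
}

#' Cumulative distribution of a population model
#' @inheritParams dist_pdf
#' @return CDF values.
#' @export
dist_cdf <- function(family, alpha, beta_param, x) {
  .check_family(family)
  .check_params(family, alpha, beta_param)
  switch(family,
    lognormal = plnorm(x, meanlog = alpha, sdlog = beta_param),
    gamma = pgamma(x, shape = alpha, scale = beta_param),
    beta = pbeta(pmin(pmax(x, 0), 1), alpha, beta_param),
    exponential = pexp(x, rate = beta_param))
}

#' Probability of an interval under a fitted model
#'
#' `P(a <= X <= b) = F(b) - F(a)` for the fitted population model: the
#' probability that a cluster property (size, eccentricity, or location)
#' lies between `a` and `b`.
#'
#' @param fit A `dist_fit` object.
#' @param a,b Interval endpoints, `a <= b`.
#' @return Probability in \[0, 1\].
#' @export
interval_probability <- function(fit, a, b) {
  stopifnot(inherits(fit, "dist_fit"))
  if (a > b) stop("'a' must not exceed 'b'")
  dist_cdf(fit$family, fit$alpha, fit$beta_param, b) -
    dist_cdf(fit$family, fit$alpha, fit$beta_param, a)
}

.new_fit <- function(family, alpha, beta_param, se_alpha, se_beta,
                     method, n, goodness, bin_spec = NULL,
                     degenerate = FALSE) {
  ci <- function(est, se) {
    if (is.na(se)) c(NA_real_, NA_real_) else est + c(-1.96, 1.96) * se
  }
  # positive parameters get log-scale (Wald-on-log) intervals so the lower
  # bound stays positive; the lognormal location is real-valued and gets a
  # plain Wald interval
  ci_pos <- function(est, se) {
    if (is.na(se) || est <= 0) return(ci(est, se))
    est * exp(c(-1.96, 1.96) * se / est)
  }
  ci_alpha <- if (family == "lognormal") ci(alpha, se_alpha)
              else if (family == "exponential") c(NA_real_, NA_real_)
              else ci_pos(alpha, se_alpha)
  ci_beta <- if (degenerate) c(0, 0) else ci_pos(beta_param, se_beta)
  structure(
    list(family = family, alpha = alpha, beta_param = beta_param,
         se_alpha = se_alpha, se_beta = se_beta,
         ci95_alpha = ci_alpha, ci95_beta = ci_beta,
         method = method, n = n, goodness = goodness,
         bin_spec = bin_spec, degenerate = degenerate),
    class = "dist_fit")
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, n = %d)\n", x$family, x$method, x$n))
  if (x$family != "exponential")
    cat(sprintf("  alpha = %.6g  [%.6g, %.6g]\n", x$alpha,
                x$ci95_alpha[1], x$ci95_alpha[2]))
  cat(sprintf("  beta  = %.6g  [%.6g, %.6g]\n", x$beta_param,
              x$ci95_beta[1], x$ci95_beta[2]))
  cat(sprintf("  %s = %.6g\n",
              if (x$method == "mle") "log-likelihood" else "SSE",
              x$goodness))
  if (x$degenerate) cat("  (degenerate sample: all values equal)\n")
  invisible(x)
}

#' Maximum likelihood fit of a population model
#'
#' Lognormal and exponential use their closed-form estimators (lognormal:
#' `alpha = mean(ln x)`, `beta = sqrt(mean((ln x - alpha)^2))` with the n
#' denominator; exponential: rate `= 1/mean(x)`). Gamma and beta maximize
#' the log-likelihood numerically in log-parameter space from
#' method-of-moments starts. Standard errors come from the observed Fisher
#' information at the optimum; 95% intervals are Wald intervals (on the log
#' scale for positivity-constrained parameters).
#'
#' @param family One of the four families.
#' @param x Sample (positive; in \[0, 1\] for beta -- exact 0/1 values are
#'   nudged inward by 1e-9 where the density is unbounded or zero).
#' @return A `dist_fit` (method `"mle"`, goodness = maximized
#'   log-likelihood). An all-equal lognormal/exponential sample yields a
#'   degenerate fit flagged with `degenerate = TRUE`.
#' @export
fit_mle <- function(family, x) {
  .check_family(family)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  if (family %in% c("lognormal", "gamma", "exponential") && any(x <= 0))
    stop(family, ": all observations must be positive")
  if (family == "beta") {
    if (any(x < 0 | x > 1)) stop("beta: observations must lie in [0, 1]")
    x <- pmin(pmax(x, 1e-9), 1 - 1e-9)
  }

  if (family == "lognormal") {
    lx <- log(x)
    alpha <- mean(lx)
    beta <- sqrt(mean((lx - alpha)^2))
    if (beta < .Machine$double.eps^0.5) {
      return(.new_fit("lognormal", alpha, 0, NA_real_, NA_real_, "mle", n,
                      goodness = NA_real_, degenerate = TRUE))
    }
    ll <- sum(dlnorm(x, alpha, beta, log = TRUE))
    return(.new_fit("lognormal", alpha, beta,
                    se_alpha = beta / sqrt(n), se_beta = beta / sqrt(2 * n),
                    method = "mle", n = n, goodness = ll))
  }
  if (family == "exponential") {
    rate <- 1 / mean(x)
    ll <- sum(dexp(x, rate, log = TRUE))
    return(.new_fit("exponential", NA_real_, rate, NA_real_,
                    se_beta = rate / sqrt(n), method = "mle", n = n,
                    goodness = ll))
  }

  start <- .mom_start(family, x)
  negll <- function(lp) {
    d <- dist_pdf(family, exp(lp[1]), exp(lp[2]), x)
    if (any(d <= 0)) return(1e10)
    -sum(log(d))
  }
  opt <- optim(log(start), negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop(sprintf("MLE optimization failed for %s (n = %d, code %d)",
                 family, n, opt$convergence))
  est <- exp(opt$par)
  se_log <- sqrt(diag(solve(opt$hessian)))
  # delta method back to the natural scale
  .new_fit(family, est[1], est[2],
           se_alpha = est[1] * se_log[1], se_beta = est[2] * se_log[2],
           method = "mle", n = n, goodness = -opt$value)
}

.mom_start <- function(family, x) {
  m <- mean(x); v <- var(x)
  v <- max(v, 1e-12)
  switch(family,
    gamma = c(max(m^2 / v, 1e-6), max(v / m, 1e-12)),
    beta = {
      k <- m * (1 - m) / v - 1
      c(max(m * k, 1e-3), max((1 - m) * k, 1e-3))
    },
    lognormal = {
      lx <- log(x); c(mean(lx), max(sd(lx), 1e-6))
    },
    exponential = c(NA_real_, 1 / m))
}

#' Histogram bin specification
#'
#' @param type `"linear"` or `"log"` (log-spaced edges for size data
#'   plotted on logarithmic axes).
#' @param n Number of bins.
#' @param range Optional c(lo, hi); defaults to the data range at build
#'   time (\[0, 1\] is the conventional choice for eccentricity and
#'   normalized location).
#' @return A `bin_spec` list.
#' @export
bin_spec <- function(type = c("linear", "log"), n = 25L, range = NULL) {
  type <- match.arg(type)
  n <- as.integer(n)
  if (n < 2L) stop("need at least 2 bins")
  if (!is.null(range)) {
    stopifnot(length(range) == 2L, range[1] < range[2])
    if (type == "log" && range[1] <= 0)
      stop("log-spaced bins require a positive lower range")
  }
  structure(list(type = type, n = n, range = range), class = "bin_spec")
}

#' Density-normalized histogram
#'
#' Builds the empirical frequency distribution used by the least-squares
#' fitters: counts per bin divided by (total n x bin width), so the
#' histogram integrates to 1 regardless of sample size.
#'
#' @param x Sample.
#' @param spec A [bin_spec].
#' @return A `cluster_histogram`: list with `edges`, `centers` (arithmetic
#'   midpoints; geometric midpoints for log bins), `counts`, `density`,
#'   `n`.
#' @export
make_histogram <- function(x, spec = bin_spec("linear", 25L)) {
  stopifnot(inherits(spec, "bin_spec"))
  rng <- spec$range
  if (is.null(rng)) rng <- range(x)
  if (spec$type == "log") {
    if (any(x <= 0)) stop("log-spaced bins require positive data")
    if (rng[1] <= 0) rng[1] <- min(x)
    edges <- exp(seq(log(rng[1]), log(rng[2]), length.out = spec$n + 1L))
    centers <- sqrt(edges[-1] * edges[-length(edges)])
  } else {
    edges <- seq(rng[1], rng[2], length.out = spec$n + 1L)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
  }
  xin <- x[x >= rng[1] & x <= rng[2]]
  counts <- .bincount(xin, edges)
  widths <- diff(edges)
  structure(
    list(edges = edges, centers = centers, counts = counts,
         density = counts / (length(x) * widths), widths = widths,
         n = length(x), spec = spec),
    class = "cluster_histogram")
}

.bincount <- function(x, edges) {
  k <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  k[k < 1L | k > length(edges) - 1L] <- NA_integer_
  tabulate(k, nbins = length(edges) - 1L)
}

#' Least-squares fit of a population model to a histogram
#'
#' Builds (or accepts) a density-normalized histogram and finds the
#' parameters minimizing the sum of squared differences between bin
#' densities and the model density at bin centers, by Levenberg-Marquardt
#' in log-parameter space from a method-of-moments start. Confidence
#' intervals come from the linearized (Jacobian-based) covariance at the
#' optimum with residual variance `SSE / (m - p)`.
#'
#' Because the histogram is density-normalized, the fit is invariant to
#' duplicating every observation.
#'
#' @param family One of the four families.
#' @param x Sample (>= 50 observations), or NULL when `histogram` is given.
#' @param spec A [bin_spec]; ignored when `histogram` is supplied.
#' @param histogram Optional pre-built `cluster_histogram` to fit directly.
#' @return A `dist_fit` (method `"lsq"`, goodness = SSE).
#' @export
fit_lsq <- function(family, x = NULL, spec = NULL, histogram = NULL) {
  .check_family(family)
  if (is.null(histogram)) {
    if (length(x) < 50L)
      stop("least-squares fitting needs at least 50 observations")
    if (is.null(spec))
      spec <- if (family == "lognormal")
        bin_spec("log", 30L) else bin_spec("linear", 25L,
          range = if (family == "beta") c(0, 1) else NULL)
    histogram <- make_histogram(x, spec)
  }
  if (sum(histogram$counts > 0) < 5L)
    stop("fewer than 5 non-empty histogram bins; cannot fit")
  if (is.null(x)) {
    # method-of-moments start from the binned data themselves
    xs <- rep(histogram$centers, histogram$counts)
    if (length(xs) < 2L) xs <- histogram$centers
    start <- .mom_start(family, xs)
  } else {
    start <- .mom_start(family, if (family == "beta")
      pmin(pmax(x, 1e-9), 1 - 1e-9) else x)
  }

  centers <- histogram$centers
  dens <- histogram$density
  # positivity-constrained parameters are optimized on the log scale; the
  # lognormal location is real-valued and enters untransformed
  if (family == "exponential") {
    resid_fn <- function(lp) dens - dist_pdf(family, NA, exp(lp), centers)
    p0 <- log(start[2])
  } else if (family == "lognormal") {
    resid_fn <- function(lp) dens - dist_pdf(family, lp[1], exp(lp[2]),
                                             centers)
    p0 <- c(start[1], log(start[2]))
  } else {
    resid_fn <- function(lp) dens - dist_pdf(family, exp(lp[1]), exp(lp[2]),
                                             centers)
    p0 <- log(start)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!fit$info %in% 1:4)
    stop(sprintf("least-squares fit did not converge for %s: %s",
                 family, fit$message))
  lp <- fit$par
  sse <- sum(fit$fvec^2)

  # linearized covariance: sigma^2 (J'J)^-1 with a central-difference J
  m_bins <- length(centers)
  p <- length(lp)
  J <- matrix(0, m_bins, p)
  h <- 1e-6
  for (j in seq_len(p)) {
    up <- lp; up[j] <- up[j] + h
    dn <- lp; dn[j] <- dn[j] - h
    J[, j] <- (resid_fn(up) - resid_fn(dn)) / (2 * h)
  }
  sigma2 <- sse / max(m_bins - p, 1L)
  cov_log <- tryCatch(sigma2 * solve(crossprod(J)),
                      error = function(e) matrix(NA_real_, p, p))
  se_log <- sqrt(pmax(diag(cov_log), 0))

  if (family == "exponential") {
    rate <- exp(lp)
    .new_fit("exponential", NA_real_, rate, NA_real_,
             se_beta = rate * se_log, method = "lsq",
             n = histogram$n, goodness = sse, bin_spec = histogram$spec)
  } else if (family == "lognormal") {
    est <- c(lp[1], exp(lp[2]))
    .new_fit(family, est[1], est[2],
             se_alpha = se_log[1], se_beta = est[2] * se_log[2],
             method = "lsq", n = histogram$n, goodness = sse,
             bin_spec = histogram$spec)
  } else {
    est <- exp(lp)
    .new_fit(family, est[1], est[2],
             se_alpha = est[1] * se_log[1], se_beta = est[2] * se_log[2],
             method = "lsq", n = histogram$n, goodness = sse,
             bin_spec = histogram$spec)
  }
}

#' Expected value of a fitted population model
#'
#' Lognormal `exp(alpha + beta^2/2)`, gamma `alpha * beta`, beta
#' `alpha / (alpha + beta)`, exponential `1 / rate`.
#'
#' @param fit A `dist_fit`.
#' @return The population mean.
#' @export
expected_value <- function(fit) {
  stopifnot(inherits(fit, "dist_fit"))
  switch(fit$family,
    lognormal = exp(fit$alpha + fit$beta_param^2 / 2),
    gamma = fit$alpha * fit$beta_param,
    beta = fit$alpha / (fit$alpha + fit$beta_param),
    exponential = 1 / fit$beta_param)
}

#' Median of a fitted population model
#'
#' For lognormal data the median `exp(alpha)` locates the center of the
#' population better than the mean, which is inflated by the long right
#' tail. Other families invert their cdf at 0.5.
#'
#' @param fit A `dist_fit`.
#' @return The population median.
#' @export
median_value <- function(fit) {
  stopifnot(inherits(fit, "dist_fit"))
  switch(fit$family,
    lognormal = exp(fit$alpha),
    gamma = qgamma(0.5, shape = fit$alpha, scale = fit$beta_param),
    beta = qbeta(0.5, fit$alpha, fit$beta_param),
    exponential = qexp(0.5, rate = fit$beta_param))
}

#' Compare lognormal and exponential size models
#'
#' Fits both candidate size models with their preferred estimators
#' (lognormal by maximum likelihood, exponential by histogram least
#' squares) and scores each by its sum of squared residuals against the
#' same log-binned empirical frequency distribution. Nucleation-and-growth
#' size populations favor the lognormal; purely anisotropic growth would
#' favor the exponential.
#'
#' @param x Positive sample (>= 50 observations).
#' @param spec Shared [bin_spec] (default 30 log-spaced bins).
#' @return List with `fits` (named list of `dist_fit`), `sse` (named
#'   numeric), `best` (family name, or `"indistinguishable"` when the SSE
#'   difference is below 1e-12).
#' @export
compare_models <- function(x, spec = bin_spec("log", 30L)) {
  if (length(x) < 50L) stop("need at least 50 observations")
  hist <- make_histogram(x, spec)
  ln_fit <- fit_mle("lognormal", x)
  ex_fit <- fit_lsq("exponential", x, histogram = hist)
  sse_of <- function(f) {
    pred <- dist_pdf(f$family, f$alpha, f$beta_param, hist$centers)
    sum((hist$density - pred)^2)
  }
  sse <- c(lognormal = sse_of(ln_fit), exponential = sse_of(ex_fit))
  best <- if (abs(diff(sse)) < 1e-12) "indistinguishable"
          else names(sse)[which.min(sse)]
  list(fits = list(lognormal = ln_fit, exponential = ex_fit),
       sse = sse, best = best, histogram = hist)
}
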