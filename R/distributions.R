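#' Fit a beta distribution to a mean and 95% interval
#'
#' Finds the beta distribution whose mean equals `mean` exactly and whose
#' central 95% interval matches `(lo, hi)` as closely as possible, by a
#' one-dimensional search over the first shape parameter with
#' `shape2 = shape1 * (1 - mean) / mean` (which pins the mean). Used for
#' probabilistic sensitivity analysis of event rates, the progression
#' probability, and health-state utilities, whose printed uncertainty is
#' a 95% interval.
#'
#' @param mean Target mean in `(0, 1)`.
#' @param lo,hi Target 2.5% and 97.5% quantiles, `0 <= lo < mean < hi <= 1`.
#'   A degenerate interval (`lo == hi == mean`) yields a point mass.
#' @return A `dist_spec` list: `family` (`"beta"` or `"point"`) and shape
#'   parameters.
#' @examples
#' fit_beta_from_interval(0.90, 0.79, 0.95) # hypertension utility
#' @export
fit_beta_from_interval <- function(mean, lo, hi) {
  stopifnot(length(mean) == 1, length(lo) == 1, length(hi) == 1)
  if (lo == hi) {
    if (lo != mean) abort("Degenerate interval must equal the mean.")
    return(dist_spec("point", value = mean))
  }
  if (!(mean > 0 && mean < 1)) abort("`mean` must lie in (0, 1).")
  if (!(lo >= 0 && lo < mean && mean < hi && hi <= 1)) {
    abort("Need 0 <= lo < mean < hi <= 1; the interval must bracket the mean.")
  }
  objective <- function(log_a) {
    a <- exp(log_a)
    b <- a * (1 - mean) / mean
    (qbeta(0.025, a, b) - lo)^2 + (qbeta(0.975, a, b) - hi)^2
  }
  opt <- optimize(objective, interval = c(-7, 16), tol = 1e-10)
  a <- exp(opt$minimum)
  dist_spec("beta", shape1 = a, shape2 = a * (1 - mean) / mean)
}

#' Fit a gamma distribution from a mean and coefficient of variation
#'
#' Method of moments: `shape = 1 / cv^2`, `scale = mean * cv^2`, so the
#' fitted mean and CV are exact. Used for cost parameters, whose standard
#' error is taken as a fixed fraction (default 25%) of the mean.
#'
#' @param mean Positive mean (dollars).
#' @param cv Coefficient of variation in `(0, 1)` (default 0.25).
#' @return A `dist_spec` with `family = "gamma"`, `shape`, `scale`.
#' @examples
#' fit_gamma_from_mean_cv(88.92, 0.25) # annual drug cost
#' @export
fit_gamma_from_mean_cv <- function(mean, cv = 0.25) {
  stopifnot(length(mean) == 1, length(cv) == 1)
  if (mean <= 0) abort("`mean` must be positive.")
  if (cv <= 0 || cv >= 1) abort("`cv` must lie in (0, 1).")
  dist_spec("gamma", shape = 1 / cv^2, scale = mean * cv^2)
}

#' Fit a lognormal distribution to a ratio estimate and its 95% CI
#'
#' Standard treatment of ratio measures (relative risks): the log of the
#' ratio is normal with median at the point estimate and
#' `sdlog = log(hi / lo) / (2 * 1.96)`.
#'
#' @param mean Point estimate of the ratio (becomes the median).
#' @param lo,hi 95% CI bounds, `0 < lo <= mean <= hi`.
#' @return A `dist_spec` with `family = "lognormal"`, `meanlog`, `sdlog`.
#' @examples
#' fit_lognormal_from_ci(0.85, 0.68, 1.06) # stroke relative risk
#' @export
fit_lognormal_from_ci <- function(mean, lo, hi) {
  stopifnot(length(mean) == 1, length(lo) == 1, length(hi) == 1)
  if (!(lo > 0 && lo <= mean && mean <= hi)) {
    abort("Need 0 < lo <= mean <= hi.")
  }
  if (lo == hi) return(dist_spec("point", value = mean))
  dist_spec("lognormal", meanlog = log(mean),
            sdlog = log(hi / lo) / (2 * qnorm(0.975)))
}

dist_spec <- function(family, ...) {
  structure(c(list(family = family), list(...)), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("<dist_spec> %s(%s)\n", x$family,
              paste(names(pars), signif(unlist(pars), 6),
                    sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Draw random samples from a fitted distribution specification
#'
#' @param spec A `dist_spec` from one of the `fit_*` functions.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n) {
  switch(spec$family,
    beta = rbeta(n, spec$shape1, spec$shape2),
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    point = rep(spec$value, n),
    abort(paste0("Unknown distribution family: ", spec$family))
  )
}

#' Quantiles of a fitted distribution specification
#'
#' @param spec A `dist_spec`.
#' @param p Probabilities.
#' @return Quantiles at `p`.
#' @export
quantile_dist <- function(spec, p) {
  switch(spec$family,
    beta = qbeta(p, spec$shape1, spec$shape2),
    gamma = qgamma(p, shape = spec$shape, scale = spec$scale),
    lognormal = qlnorm(p, spec$meanlog, spec$sdlog),
    point = rep(spec$value, length(p)),
    abort(paste0("Unknown distribution family: ", spec$family))
  )
}

mean_dist <- function(spec) {
  switch(spec$family,
    beta = spec$shape1 / (spec$shape1 + spec$shape2),
    gamma = spec$shape * spec$scale,
    lognormal = exp(spec$meanlog + spec$sdlog^2 / 2),
    point = spec$value
  )
}

#' @importFrom stats qnorm
NULL
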