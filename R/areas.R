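#' Scale patch areas before fitting
#'
#' Multiplies areas by a common factor. Area values are conventionally
#' scaled down (factor 0.01, or 0.1 for small quilts) to bring them into a
#' numerically comfortable range before maximum-likelihood fitting; AIC
#' *differences* between families are invariant to the common factor, so
#' the scaling does not affect model selection.
#'
#' @param areas Positive numeric vector (cm^2).
#' @param factor Positive scale factor.
#' @return `areas * factor`.
#' @export
scale_areas <- function(areas, factor) {
  if (!is.numeric(areas) || any(!is.finite(areas)) || any(areas <= 0)) {
    stop("areas must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("scale factor must be a positive number", call. = FALSE)
  }
  areas * factor
}

#' Maximum-likelihood fit of one distribution family
#'
#' Fits one of four two-parameter families to (scaled) patch areas by
#' maximum likelihood: `gamma` (shape, rate), `weibull` (shape, scale),
#' `lognormal` (meanlog, sdlog) and `normal` (mean, sd). The normal and
#' lognormal MLEs are closed-form (MLE variance, 1/n denominator); the
#' gamma and Weibull fits maximise the log-likelihood numerically over
#' log-parameters from method-of-moments starting values.
#'
#' @param areas Numeric vector, n >= 3; strictly positive for the gamma,
#'   Weibull and lognormal families.
#' @param family One of `"gamma"`, `"weibull"`, `"lognormal"`, `"normal"`.
#' @param scale_factor Scale factor already applied to `areas`, recorded in
#'   the result for bookkeeping (the fit itself uses `areas` as given).
#' @return A `"family_fit"` object: list with `family`, `params` (named
#'   numeric), `log_likelihood`, `aic` (`2k - 2 logLik`, `k = 2`), `n`,
#'   `scale_factor`.
#' @examples
#' fit_family(rgamma(500, 3, 2), "gamma")
#' @export
fit_family <- function(areas, family = c("gamma", "weibull", "lognormal", "normal"),
                       scale_factor = 1) {
  family <- match.arg(family)
  x <- as.numeric(areas)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x))) stop("areas must be finite", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate data: zero variance", call. = FALSE)
  if (family != "normal" && any(x <= 0)) {
    stop("areas must be positive for the ", family, " family", call. = FALSE)
  }
  res <- switch(family,
    normal = {
      mu <- mean(x); sd_mle <- sqrt(mean((x - mu) ^ 2))
      list(params = c(mean = mu, sd = sd_mle),
           loglik = sum(stats::dnorm(x, mu, sd_mle, log = TRUE)))
    },
    lognormal = {
      lx <- log(x)
      mu <- mean(lx); sd_mle <- sqrt(mean((lx - mu) ^ 2))
      list(params = c(meanlog = mu, sdlog = sd_mle),
           loglik = sum(stats::dlnorm(x, mu, sd_mle, log = TRUE)))
    },
    gamma = fit_positive_mle(x, stats::dgamma,
                             start = gamma_moment_start(x),
                             par_names = c("shape", "rate")),
    weibull = fit_positive_mle(x, stats::dweibull,
                               start = weibull_moment_start(x),
                               par_names = c("shape", "scale"))
  )
  structure(list(family = family, params = res$params,
                 log_likelihood = res$loglik,
                 aic = 2 * 2 - 2 * res$loglik, n = n,
                 scale_factor = scale_factor),
            class = "family_fit")
}

# Numerical MLE on log-parameters: BFGS, Nelder-Mead polish, BFGS again.
# Convergence is certified by a local-maximum probe: no +/-0.5% parameter
# perturbation may improve the log-likelihood.
fit_positive_mle <- function(x, dfun, start, par_names) {
  nll <- function(lp) {
    # extreme line-search steps can overflow the density; a large finite
    # penalty keeps the optimiser on track without NaN warnings
    v <- suppressWarnings(-sum(dfun(x, exp(lp[1]), exp(lp[2]), log = TRUE)))
    if (is.finite(v)) v else 1e300
  }
  opt <- stats::optim(log(start), nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  opt2 <- stats::optim(opt$par, nll, control = list(maxit = 2000, reltol = 1e-14))
  if (opt2$value < opt$value) opt <- opt2
  opt3 <- stats::optim(opt$par, nll, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
  if (opt3$value < opt$value) opt <- opt3
  if (!is.finite(opt$value)) {
    stop("maximum-likelihood fit failed to converge", call. = FALSE)
  }
  probes <- expand.grid(d1 = c(-1, 0, 1), d2 = c(-1, 0, 1)) * log(1.005)
  vals <- apply(probes, 1, function(d) nll(opt$par + as.numeric(d)))
  if (any(vals < opt$value - 1e-9 * max(1, abs(opt$value)))) {
    stop("maximum-likelihood fit did not reach a local maximum", call. = FALSE)
  }
  list(params = stats::setNames(exp(opt$par), par_names), loglik = -opt$value)
}

gamma_moment_start <- function(x) {
  m <- mean(x); v <- stats::var(x)
  shape <- max(m ^ 2 / v, 1e-3)
  c(shape, shape / m)
}

weibull_moment_start <- function(x) {
  # Menon-style start from the log-moments; adequate as an optimiser seed.
  slx <- stats::sd(log(x))
  shape <- max(1.2 / max(slx, 1e-6), 1e-3)
  c(shape, mean(x) / gamma(1 + 1 / shape))
}

#' Akaike weights
#'
#' Converts AIC values into normalised Akaike weights
#' `w_i = exp(-d_i / 2) / sum_j exp(-d_j / 2)` with `d_i = aic_i - min(aic)`;
#' the minimum is subtracted first for numerical stability. The weights are
#' interpreted as relative likelihoods of the candidate models given the
#' data, and are invariant to adding a constant to every AIC.
#'
#' @param aics Numeric vector of at least two finite AIC (or delta-AIC)
#'   values.
#' @return Numeric weights summing to one.
#' @examples
#' akaike_weights(c(1.72, 0, 53.41, 125.34))  # ~0.30, 0.70, <0.01, <0.01
#' @export
akaike_weights <- function(aics) {
  a <- as.numeric(aics)
  if (length(a) < 2 || any(!is.finite(a))) {
    stop("need at least two finite AIC values", call. = FALSE)
  }
  rel <- exp(-(a - min(a)) / 2)
  rel / sum(rel)
}

#' Rank fitted families by AIC
#'
#' Orders a set of [fit_family()] results fitted to the same data by AIC,
#' computes delta-AIC and Akaike weights, and flags as *candidates* all
#' families within delta-AIC < 2 of the best one (the conventional rule for
#' treating models as indistinguishable). AIC ties keep both families;
#' ordering is made deterministic by breaking ties in the fixed family
#' order gamma < weibull < lognormal < normal.
#'
#' @param fits List of `"family_fit"` objects on identical data.
#' @return A `"family_ranking"` object: data frame `table` (family, params,
#'   log_likelihood, aic, delta_aic, weight, candidate) sorted by AIC, plus
#'   `candidates`, the character vector of candidate families.
#' @export
rank_families <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "family_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1) {
    stop("fits were not computed on the same data (different n)", call. = FALSE)
  }
  fam_order <- c("gamma", "weibull", "lognormal", "normal")
  fam <- vapply(fits, `[[`, character(1), "family")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  ord <- order(aic, match(fam, fam_order))
  fits <- fits[ord]; fam <- fam[ord]; aic <- aic[ord]
  delta <- aic - min(aic)
  w <- akaike_weights(aic)
  tab <- data.frame(family = fam, log_likelihood =
                      vapply(fits, `[[`, numeric(1), "log_likelihood"),
                    aic = aic, delta_aic = delta, weight = w,
                    candidate = delta < 2, stringsAsFactors = FALSE)
  structure(list(table = tab, fits = fits,
                 candidates = fam[delta < 2]),
            class = "family_ranking")
}

#' @export
print.family_ranking <- function(x, ...) {
  cat("Family ranking by AIC (candidates: delta AIC < 2)\n")
  print(transform(x$table, weight = round(weight, 3),
                  delta_aic = round(delta_aic, 2)), row.names = FALSE)
  invisible(x)
}

#' Moment coefficient of skewness
#'
#' The plain (biased) moment estimator `g1 = m3 / m2^(3/2)` with central
#' moments using `1/n` denominators; positive values indicate a right tail.
#'
#' @param values Numeric vector, n >= 3, non-zero variance.
#' @return Skewness `g1`.
#' @examples
#' sample_skewness(c(-1, 0, 1))  # 0
#' @export
sample_skewness <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 3 || any(!is.finite(x))) {
    stop("need at least 3 finite values", call. = FALSE)
  }
  m <- mean(x)
  m2 <- mean((x - m) ^ 2)
  if (m2 == 0) stop("degenerate data: zero variance", call. = FALSE)
  mean((x - m) ^ 3) / m2 ^ 1.5
}
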