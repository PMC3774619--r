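#' Construct a univariate Gaussian mixture model
#'
#' @param weights Component weights (must sum to 1).
#' @param means Component means.
#' @param sds Component standard deviations (> 0).
#' @return A `"mixture_model"` object.
#' @export
mixture_model <- function(weights, means, sds) {
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  if (abs(sum(weights) - 1) > 1e-12 || any(weights < 0)) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(sds <= 0)) stop("component sds must be positive", call. = FALSE)
  structure(list(weights = as.numeric(weights), means = as.numeric(means),
                 sds = as.numeric(sds), n_components = length(weights)),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> %d component(s)\n", x$n_components))
  print(data.frame(weight = round(x$weights, 4), mean = round(x$means, 4),
                   sd = round(x$sds, 4)), row.names = FALSE)
  invisible(x)
}

mixture_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w),
                 function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                 numeric(length(x)))
  sum(log(rowSums(matrix(dens, nrow = length(x)))))
}

#' Fit a seeded Gaussian mixture by EM
#'
#' Fits a univariate Gaussian mixture to patch areas by
#' expectation-maximisation started from externally supplied seeds. For a
#' regular quilt the seeds are the per-motif-category area means, standard
#' deviations and relative frequencies; seeding with the known categories
#' avoids the misclassification that unseeded information-criterion fitting
#' produces when distinct shapes have similar areas. For a crazy quilt a
#' single seed (the overall mean and standard deviation) yields a single
#' Gaussian, returned in closed form (sample mean, MLE standard deviation)
#' without running EM.
#'
#' @param areas Numeric data vector.
#' @param seeds Data frame (or list) with columns/elements `mean`, `sd`,
#'   `frequency` — one row per component; frequencies are normalised to
#'   weights.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 1000).
#' @param min_sd Optional variance floor: component standard deviations are
#'   clamped at this value in every M step, which regularises the unbounded
#'   Gaussian-mixture likelihood (a component shrinking onto a few
#'   near-identical areas). With the default `NULL`, no floor is applied
#'   and a component whose sd falls below `1e-12` of the data range raises
#'   a collapse error naming the component.
#' @return A `"mixture_model"` with attributes `log_likelihood` and
#'   `loglik_trace` (per-iteration log-likelihood, non-decreasing).
#' @export
fit_seeded_mixture <- function(areas, seeds, tol = 1e-8, max_iter = 1000L,
                               min_sd = NULL) {
  x <- as.numeric(areas)
  seeds <- as.data.frame(seeds)
  stopifnot(all(c("mean", "sd", "frequency") %in% names(seeds)))
  k <- nrow(seeds)
  if (length(x) < k) stop("fewer observations than components", call. = FALSE)
  if (any(seeds$sd <= 0)) stop("seed sds must be positive", call. = FALSE)
  if (k == 1L) {
    mu <- mean(x); sd_mle <- sqrt(mean((x - mu) ^ 2))
    model <- mixture_model(1, mu, sd_mle)
    ll <- sum(stats::dnorm(x, mu, sd_mle, log = TRUE))
    attr(model, "log_likelihood") <- ll
    attr(model, "loglik_trace") <- ll
    return(model)
  }
  w <- seeds$frequency / sum(seeds$frequency)
  mu <- seeds$mean
  sd <- seeds$sd
  collapse_tol <- 1e-12 * diff(range(x))
  trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(length(x)))
    dens <- matrix(dens, nrow = length(x))
    tot <- rowSums(dens)
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / length(x)
    mu <- colSums(resp * x) / nk
    sd <- sqrt(vapply(seq_len(k), function(j)
      sum(resp[, j] * (x - mu[j]) ^ 2) / nk[j], numeric(1)))
    if (!is.null(min_sd)) {
      sd[!is.finite(sd)] <- min_sd
      sd <- pmax(sd, min_sd)
    } else if (any(!is.finite(sd)) || any(sd < collapse_tol)) {
      bad <- which(!is.finite(sd) | sd < collapse_tol)[1]
      stop(sprintf("mixture component %d collapsed (sd below 1e-12 of the data range)",
                   bad), call. = FALSE)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    ll_old <- ll
  }
  model <- mixture_model(w, mu, sd)
  attr(model, "log_likelihood") <- trace[length(trace)]
  attr(model, "loglik_trace") <- trace
  model
}

#' Simulate areas from a Gaussian mixture
#'
#' Draws `n` independent values: a component is chosen by its weight, then
#' a Gaussian value from that component. A single Gaussian fitted to
#' positively-skewed areas can place probability mass below zero; such
#' negative draws are deliberately *not* truncated, since the violation of
#' the minimum-size constraint is itself diagnostic of model misfit.
#'
#' @param model A [mixture_model()].
#' @param n Number of draws.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return Numeric vector of length `n`.
#' @export
simulate_from_mixture <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "mixture_model"), n >= 1)
  draw <- function() {
    comp <- sample.int(model$n_components, n, replace = TRUE,
                       prob = model$weights)
    stats::rnorm(n, model$means[comp], model$sds[comp])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Kernel density estimate with its bandwidth
#'
#' Gaussian-kernel density estimate of (area) values using the
#' rule-of-thumb bandwidth `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, i.e. the
#' standard deviation of the smoothing kernel. The bandwidth is the
#' quantity compared between quilt classes: multimodal regular-quilt areas
#' need little smoothing, while forcing a smooth unimodal estimate onto
#' crazy-quilt areas requires a much larger bandwidth.
#'
#' @param values Numeric vector, n >= 2, non-zero spread.
#' @return List with `density` (a [stats::density] object) and `bandwidth`.
#' @export
kde_with_bandwidth <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2 || any(!is.finite(x))) {
    stop("need at least 2 finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("degenerate data: zero spread", call. = FALSE)
  bw <- stats::bw.nrd0(x)
  list(density = stats::density(x, bw = bw), bandwidth = bw)
}

#' Sorted-area simulation envelope test
#'
#' Monte-Carlo goodness-of-fit test of a (mixture) model for patch areas.
#' `n_sim` simulations of `length(areas)` values are drawn from the model;
#' each simulated series and the data are sorted ascending, and for every
#' rank the envelope is the minimum and maximum over the simulations. Data
#' values strictly below the rank-wise minimum or strictly above the
#' rank-wise maximum count as deviations; with the default 39 simulations
#' the pointwise two-sided level is `2/(39 + 1) = 0.05`.
#'
#' @param areas Observed areas.
#' @param model A [mixture_model()].
#' @param n_sim Number of simulations (default 39).
#' @param seed Optional integer seed.
#' @return An `"area_envelope"` object: list with `n_sim`, `rank_min`,
#'   `rank_max`, `data_sorted`, `n_deviations`, `pct_deviations`, `alpha`.
#' @export
area_envelope_test <- function(areas, model, n_sim = 39L, seed = NULL) {
  x <- sort(as.numeric(areas))
  n <- length(x)
  if (n_sim < 1) stop("n_sim must be at least 1", call. = FALSE)
  stopifnot(inherits(model, "mixture_model"))
  run <- function() {
    sims <- matrix(0, nrow = n, ncol = n_sim)
    for (s in seq_len(n_sim)) sims[, s] <- sort(simulate_from_mixture(model, n))
    rank_min <- apply(sims, 1, min)
    rank_max <- apply(sims, 1, max)
    dev <- x < rank_min | x > rank_max
    structure(list(n_sim = as.integer(n_sim), rank_min = rank_min,
                   rank_max = rank_max, data_sorted = x,
                   n_deviations = sum(dev),
                   pct_deviations = 100 * sum(dev) / n,
                   alpha = 2 / (n_sim + 1)),
              class = "area_envelope")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.area_envelope <- function(x, ...) {
  cat(sprintf(
    "<area_envelope> %d simulations, %d/%d deviations (%.2f%%), pointwise alpha %.3g\n",
    x$n_sim, x$n_deviations, length(x$data_sorted), x$pct_deviations, x$alpha))
  invisible(x)
}

#' Seeds for a quilt's mixture model
#'
#' Builds the seeding table for [fit_seeded_mixture()] from a quilt: one
#' component per motif category (mean, sd and relative frequency of that
#' category's areas) when category labels are present, otherwise a single
#' component with the overall mean and standard deviation.
#'
#' Categories whose mean areas are indistinguishable are merged before
#' seeding: patches of different shapes but (near-)identical areas cannot
#' be separated on areas alone, and seeding two components at the same
#' location only invites degenerate EM solutions. Two categories are
#' merged when their means differ by less than half the larger
#' within-category standard deviation (single-linkage, applied
#' transitively); merged components pool their members. Zero-variance
#' categories (e.g. noise-free synthetic quilts) receive a negligible
#' positive seed sd so the seeds remain valid.
#'
#' @param x A [quilt()].
#' @return Data frame with columns `category` (merged labels joined by
#'   `+`), `mean`, `sd`, `frequency`.
#' @export
mixture_seeds <- function(x) {
  stopifnot(inherits(x, "quilt"))
  areas <- patch_areas(x)
  cats <- patch_categories(x)
  if (all(is.na(cats))) {
    return(data.frame(category = NA_character_, mean = mean(areas),
                      sd = stats::sd(areas), frequency = 1))
  }
  split_areas <- split(areas, cats)
  mu <- vapply(split_areas, mean, numeric(1))
  sdv <- vapply(split_areas, stats::sd, numeric(1))
  sdv[is.na(sdv)] <- 0
  # transitive merge of categories with indistinguishable mean areas
  grp <- seq_along(mu)
  for (i in seq_along(mu)) {
    for (j in seq_len(i - 1L)) {
      if (abs(mu[i] - mu[j]) <= 0.5 * max(sdv[i], sdv[j], 0)) {
        grp[grp == grp[i]] <- grp[j]
      }
    }
  }
  merged <- lapply(unique(grp), function(g) {
    members <- which(grp == g)
    vals <- unlist(split_areas[members])
    s <- if (length(vals) > 1) stats::sd(vals) else 0
    list(category = paste(names(split_areas)[members], collapse = "+"),
         mean = mean(vals),
         sd = max(s, 1e-9 * max(abs(mean(vals)), 1)),
         frequency = length(vals) / length(areas))
  })
  data.frame(category = vapply(merged, `[[`, character(1), "category"),
             mean = vapply(merged, `[[`, numeric(1), "mean"),
             sd = vapply(merged, `[[`, numeric(1), "sd"),
             frequency = vapply(merged, `[[`, numeric(1), "frequency"),
             row.names = NULL)
}
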