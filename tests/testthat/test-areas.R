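test_that("area scaling is elementwise and guards its domain", {
  expect_equal(scale_areas(c(2, 3), 1), c(2, 3))
  expect_equal(scale_areas(c(100, 400), 0.01), c(1, 4))
  expect_error(scale_areas(c(1, -1), 0.01), "positive")
  expect_error(scale_areas(c(1, 2), 0), "positive")
})

test_that("AIC differences are invariant to the common area scale", {
  set.seed(10)
  x <- rgamma(400, 2.5, 0.03)
  d_raw <- fit_family(x, "gamma")$aic - fit_family(x, "weibull")$aic
  xs <- scale_areas(x, 0.01)
  d_scaled <- fit_family(xs, "gamma", 0.01)$aic - fit_family(xs, "weibull", 0.01)$aic
  expect_equal(d_raw, d_scaled, tolerance = 1e-6)
})

test_that("normal and lognormal MLEs are the closed forms", {
  f <- fit_family(c(1, 2, 3), "normal")
  expect_equal(unname(f$params), c(2, sqrt(2 / 3)))
  expect_equal(f$log_likelihood, sum(dnorm(c(1, 2, 3), 2, sqrt(2 / 3), log = TRUE)))
  expect_equal(f$aic, 4 - 2 * f$log_likelihood)
  g <- fit_family(exp(1:3), "lognormal")
  expect_equal(unname(g$params), c(2, sqrt(2 / 3)))
})

test_that("gamma and Weibull MLEs recover simulated parameters", {
  set.seed(123)
  fg <- fit_family(rgamma(20000, shape = 3, rate = 2), "gamma")
  expect_equal(unname(fg$params["shape"]), 3, tolerance = 0.05)
  expect_equal(unname(fg$params["rate"]), 2, tolerance = 0.05)
  fw <- fit_family(rweibull(20000, shape = 1.5, scale = 2), "weibull")
  expect_equal(unname(fw$params["shape"]), 1.5, tolerance = 0.05)
  expect_equal(unname(fw$params["scale"]), 2, tolerance = 0.05)
})

test_that("numerical MLEs agree with fitdistrplus", {
  set.seed(99)
  x <- rgamma(800, 2, 0.4)
  ours <- fit_family(x, "gamma")
  ref <- fitdistrplus::fitdist(x, "gamma")
  expect_equal(unname(ours$params), unname(ref$estimate), tolerance = 1e-3)
  expect_gte(ours$log_likelihood, ref$loglik - 1e-6)
  y <- rweibull(800, 1.3, 5)
  ours_w <- fit_family(y, "weibull")
  ref_w <- fitdistrplus::fitdist(y, "weibull")
  expect_equal(unname(ours_w$params), unname(ref_w$estimate), tolerance = 1e-3)
  expect_gte(ours_w$log_likelihood, ref_w$loglik - 1e-6)
})

test_that("log-likelihood at the MLE dominates nearby parameters", {
  set.seed(8)
  x <- rweibull(500, 2, 3)
  for (fam in c("gamma", "weibull", "lognormal", "normal")) {
    f <- fit_family(x, fam)
    dfun <- switch(fam, gamma = dgamma, weibull = dweibull,
                   lognormal = dlnorm, normal = dnorm)
    for (eps in c(0.99, 1.01)) {
      ll <- sum(dfun(x, f$params[1] * eps, f$params[2], log = TRUE))
      expect_lte(ll, f$log_likelihood + 1e-8)
      ll2 <- sum(dfun(x, f$params[1], f$params[2] * eps, log = TRUE))
      expect_lte(ll2, f$log_likelihood + 1e-8)
    }
  }
})

test_that("fit_family rejects degenerate inputs", {
  expect_error(fit_family(c(1, 2), "gamma"), "at least 3")
  expect_error(fit_family(c(2, 2, 2), "normal"), "zero variance")
  expect_error(fit_family(c(-1, 1, 2), "lognormal"), "positive")
})

test_that("Akaike weights follow the closed form and its invariances", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)))
  # published delta-AIC row for one crazy quilt
  w_c1 <- akaike_weights(c(1.72, 0, 53.41, 125.34))
  expect_equal(round(w_c1[1], 2), 0.30)
  expect_equal(round(w_c1[2], 2), 0.70)
  expect_lt(w_c1[3], 0.01)
  expect_lt(w_c1[4], 0.01)
  # invariance to adding a constant
  expect_equal(akaike_weights(c(1.72, 0, 53.41, 125.34) + 500), w_c1)
  expect_equal(sum(w_c1), 1, tolerance = 1e-12)
  expect_error(akaike_weights(c(1, Inf)), "finite")
  expect_error(akaike_weights(3), "at least two")
})

test_that("family ranking applies the delta-AIC < 2 candidate rule", {
  set.seed(4)
  x <- rgamma(300, 2, 1)
  fits <- lapply(c("gamma", "weibull", "lognormal", "normal"),
                 function(f) fit_family(x, f))
  rk <- rank_families(fits)
  expect_equal(rk$table$delta_aic[1], 0)
  expect_true(all(diff(rk$table$aic) >= 0))
  expect_equal(sum(rk$table$weight), 1, tolerance = 1e-12)
  expect_identical(rk$candidates, rk$table$family[rk$table$delta_aic < 2])
  expect_gte(length(rk$candidates), 1)
  # identical AICs keep all four as candidates, in the fixed family order
  tied <- lapply(fits, function(f) {
    f$aic <- 100; f$log_likelihood <- (4 - 100) / 2; f
  })
  rk_tied <- rank_families(tied)
  expect_equal(rk_tied$candidates, c("gamma", "weibull", "lognormal", "normal"))
  # fits on different data are refused
  short <- fit_family(rgamma(50, 2, 1), "gamma")
  expect_error(rank_families(list(fits[[1]], short)), "same data")
  # a gap larger than 2 leaves a single candidate
  lone <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    f$aic <- 100 + c(0, 9.42, 30, 60)[i]
    f$log_likelihood <- (4 - f$aic) / 2
    f
  })
  expect_equal(length(rank_families(lone)$candidates), 1L)
})

test_that("skewness is the plain moment coefficient g1", {
  expect_equal(sample_skewness(c(-1, 0, 1)), 0)
  expect_equal(sample_skewness(c(0, 0, 0, 1)), 0.09375 / 0.1875 ^ 1.5)
  set.seed(5)
  expect_equal(sample_skewness(rexp(1e5)), 2, tolerance = 0.1)
  expect_error(sample_skewness(c(3, 3, 3)), "zero variance")
  z <- rlnorm(500)
  expect_equal(sample_skewness(z), e1071::skewness(z, type = 1),
               tolerance = 1e-12)
})

test_that("the true family is a candidate in at least 90% of replicates", {
  set.seed(1)
  gens <- list(gamma = function() rgamma(1000, 2, 0.5),
               weibull = function() rweibull(1000, 1.5, 2),
               lognormal = function() rlnorm(1000, 1, 0.6))
  for (fam in names(gens)) {
    hits <- vapply(1:50, function(i) {
      x <- gens[[fam]]()
      rk <- rank_families(lapply(c("gamma", "weibull", "lognormal", "normal"),
                                 function(f) fit_family(x, f)))
      fam %in% rk$candidates
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  }
})

test_that("the normal family ranks last on strongly right-skewed areas", {
  set.seed(6)
  tries <- 0
  for (i in 1:5) {
    x <- rlnorm(400, 3, 0.9)
    if (sample_skewness(x) <= 1.5) next
    tries <- tries + 1
    rk <- rank_families(lapply(c("gamma", "weibull", "lognormal", "normal"),
                               function(f) fit_family(x, f)))
    expect_equal(rk$table$family[4], "normal")
  }
  expect_gte(tries, 3)
})
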