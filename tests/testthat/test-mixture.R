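test_that("single-seed fit is the closed-form Gaussian", {
  m <- fit_seeded_mixture(c(1, 2, 3), data.frame(mean = 0, sd = 1, frequency = 1))
  expect_equal(m$means, 2)
  expect_equal(m$sds, sqrt(2 / 3))
  expect_equal(m$weights, 1)
  expect_equal(attr(m, "log_likelihood"),
               sum(dnorm(c(1, 2, 3), 2, sqrt(2 / 3), log = TRUE)))
})

test_that("seeded EM recovers well-separated components", {
  set.seed(2)
  x <- c(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  m <- fit_seeded_mixture(x, data.frame(mean = c(1, 9), sd = c(2, 2),
                                        frequency = c(0.5, 0.5)))
  expect_equal(sort(m$means), c(0, 10), tolerance = 0.2)
  expect_equal(m$weights, c(0.5, 0.5), tolerance = 0.05)
  trace <- attr(m, "loglik_trace")
  expect_true(all(diff(trace) >= -1e-8 * abs(trace[-length(trace)])))
})

test_that("component collapse raises an informative error", {
  x <- c(0, 0.01, -0.01, 0, 10)
  expect_error(
    fit_seeded_mixture(x, data.frame(mean = c(0, 10), sd = c(1, 1),
                                     frequency = c(0.8, 0.2))),
    "collapsed")
  # the same fit succeeds under a variance floor
  m <- fit_seeded_mixture(x, data.frame(mean = c(0, 10), sd = c(1, 1),
                                        frequency = c(0.8, 0.2)),
                          min_sd = 1e-6 * diff(range(x)))
  expect_equal(m$n_components, 2L)
})

test_that("mixture simulation is seeded and respects component weights", {
  m <- mixture_model(c(0.3, 0.7), c(0, 100), c(1, 1))
  x1 <- simulate_from_mixture(m, 1000, seed = 4)
  x2 <- simulate_from_mixture(m, 1000, seed = 4)
  expect_identical(x1, x2)
  big <- simulate_from_mixture(m, 1e5, seed = 5)
  expect_equal(mean(big < 50), 0.3, tolerance = 0.01)
  narrow <- mixture_model(1, 5, 1e-12)
  expect_equal(simulate_from_mixture(narrow, 10, seed = 1), rep(5, 10),
               tolerance = 1e-9)
})

test_that("kde bandwidth follows the rule-of-thumb formula", {
  # constructed sample: n = 32, sd exactly 1, IQR/1.34 > 1, so the rule
  # gives 0.9 * 32^(-1/5) = 0.45
  set.seed(3)
  repeat {
    z <- rnorm(32)
    z <- (z - mean(z)) / sd(z)
    if (IQR(z) / 1.34 > 1) break
  }
  res <- kde_with_bandwidth(z)
  expect_equal(res$bandwidth, 0.45)
  # homogeneity: scaling the data scales the bandwidth
  expect_equal(kde_with_bandwidth(7 * z)$bandwidth, 7 * res$bandwidth)
  # density integrates to one on its grid
  d <- res$density
  expect_equal(sum(d$y) * diff(d$x)[1], 1, tolerance = 1e-3)
  expect_error(kde_with_bandwidth(rep(2, 5)), "zero spread")
})

test_that("kde is close to the true density for large samples", {
  set.seed(11)
  x <- rnorm(1e4)
  d <- kde_with_bandwidth(x)$density
  expect_lt(max(abs(d$y - dnorm(d$x))), 0.05)
})

test_that("a series drawn inside the envelope set shows zero deviations", {
  m <- mixture_model(c(0.4, 0.6), c(20, 60), c(5, 8))
  n <- 150
  # reproduce the 5th simulated series the envelope test will draw
  sim5 <- patchstat:::with_seed(7, {
    x <- NULL
    for (i in 1:5) x <- simulate_from_mixture(m, n)
    x
  })
  env <- area_envelope_test(sim5, m, n_sim = 39, seed = 7)
  expect_equal(env$n_deviations, 0L)
  expect_equal(env$alpha, 0.05)
  expect_true(all(env$rank_min <= env$rank_max))
})

test_that("planted outliers are counted as deviations", {
  set.seed(13)
  m <- mixture_model(1, 50, 5)
  x <- simulate_from_mixture(m, 200, seed = 21)
  x[1:5] <- 50 + 10 * 5 + (1:5)  # far above mean + 10 sd
  env <- area_envelope_test(x, m, n_sim = 39, seed = 22)
  expect_gte(env$n_deviations, 5)
})

test_that("the envelope result ignores input order", {
  m <- mixture_model(1, 10, 2)
  x <- simulate_from_mixture(m, 100, seed = 31)
  e1 <- area_envelope_test(x, m, seed = 8)
  e2 <- area_envelope_test(rev(x), m, seed = 8)
  expect_equal(e1$n_deviations, e2$n_deviations)
  expect_equal(e1$rank_min, e2$rank_min)
})

test_that("envelope deviations are calibrated under the true model", {
  set.seed(17)
  m <- mixture_model(1, 50, 10)
  pct <- replicate(200, {
    x <- simulate_from_mixture(m, 100)
    area_envelope_test(x, m, 39)$pct_deviations
  })
  expect_lte(mean(pct), 10)
  expect_lte(median(pct), 5)
})

test_that("single Gaussians fitted to skewed areas leak below zero", {
  set.seed(19)
  q <- generate_crazy_quilt(c(100, 80), generator_config(seed = 23,
                                                         target_n = 150))
  a <- patch_areas(q)
  m <- fit_seeded_mixture(a, mixture_seeds(q))
  expect_equal(m$n_components, 1L)
  expect_gt(pnorm(0, m$means, m$sds), 0)
  sims <- simulate_from_mixture(m, 5000, seed = 3)
  expect_gt(sum(sims < 0), 0)  # the model violates the minimum-size constraint
})

test_that("mixture seeds merge categories with indistinguishable areas", {
  tmpl <- motif_template("four_patch", block_size = 20)  # equal-area categories
  q <- generate_regular_quilt(tmpl, 3, 3, generator_config(seed = 2,
                                                           jitter_sd = 0.1))
  seeds <- mixture_seeds(q)
  expect_equal(nrow(seeds), 1L)
  tmpl2 <- two_rect_template()  # distinct areas stay separate
  q2 <- generate_regular_quilt(tmpl2, 3, 3, generator_config(seed = 2,
                                                             jitter_sd = 0.1))
  expect_equal(nrow(mixture_seeds(q2)), 2L)
  expect_equal(sum(mixture_seeds(q2)$frequency), 1)
})
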