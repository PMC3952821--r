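test_that("stimulus generators are seeded and match their moments", {
  a <- white_noise_stimulus(3L, 100L, seed = 5L)
  b <- white_noise_stimulus(3L, 100L, seed = 5L)
  expect_identical(a, b)
  big <- white_noise_stimulus(4L, 10000L, seed = 1L)
  expect_lt(max(abs(rowMeans(big))), 3 / sqrt(10000))
  C <- tcrossprod(big) / ncol(big)
  expect_lt(max(abs(C - diag(4))), 0.1)

  cs <- correlated_stimulus(3L, 20000L, rho_time = 0.9, seed = 2L)
  expect_identical(cs, correlated_stimulus(3L, 20000L, rho_time = 0.9,
                                           seed = 2L))
  ac <- cor(cs[1, -1], cs[1, -20000])
  expect_equal(ac, 0.9, tolerance = 0.05)
  # zero temporal and channel correlation reduces to white noise moments
  w <- correlated_stimulus(3L, 20000L, rho_time = 0, channel_scale = 0,
                           seed = 3L)
  expect_lt(max(abs(tcrossprod(w) / ncol(w) - diag(3))), 0.1)
  expect_error(correlated_stimulus(2L, 10L, channel_cov = -diag(2)),
               "positive definite")
})

test_that("LNP simulation hits its calibrated target rate", {
  set.seed(4)
  d <- 8L
  X <- white_noise_stimulus(d, 100000L, seed = 9L)
  w <- rnorm(d)
  sim <- lnp_simulate(lnp_spec(w, slope = 4, target_rate = 0.015), X,
                      seed = 10L)
  expect_equal(mean(sim$rate), 0.015, tolerance = 1e-6)
  expect_lt(abs(mean(sim$spikes) - 0.015), 0.0015)
  # f ~ 0 -> no spikes; f ~ 1 -> all spikes
  expect_identical(sum(lnp_simulate(lnp_spec(w, offset = 100,
                                             target_rate = NULL),
                                    X)$spikes), 0L)
  all1 <- lnp_simulate(lnp_spec(w, offset = -100, target_rate = NULL), X)
  expect_true(all(all1$spikes == 1L))
  expect_error(lnp_simulate(lnp_spec(w), X, nonlinearity = function(z) z),
               "outside")
})

test_that("discretized log-normal kernel has zero mean, unit mass, growing
           right skew", {
  expect_identical(discretized_lognormal_kernel(0)$probs,
                   as.numeric(-8:8 == 0))
  skews <- vapply(c(0.5, 2, 5), function(s2) {
    k <- discretized_lognormal_kernel(s2, support = -15:25)
    expect_equal(sum(k$probs), 1, tolerance = 1e-12)
    mu <- sum(k$lags * k$probs)
    expect_lt(abs(mu), 0.5)  # zero mean up to the integer discretization
    v <- sum((k$lags - mu)^2 * k$probs)
    sum((k$lags - mu)^3 * k$probs) / v^1.5
  }, 0)
  expect_true(all(skews > 0))
  expect_true(all(diff(skews) > 0))
})

test_that("jitter application preserves spikes and reproduces the kernel in
           the cross-correlogram", {
  spikes <- integer(3000)
  spikes[seq(10, 2990, by = 15)] <- 1L  # spaced beyond the jitter range
  delta <- discretized_lognormal_kernel(0)
  expect_identical(apply_jitter(spikes, delta, seed = 1L), spikes)
  pmf <- discretized_lognormal_kernel(2, support = -6:6)
  # empirical shift distribution over many independent jitters
  set.seed(3)
  counts <- setNames(rep(0, 13), -6:6)
  for (k in 1:60) {
    j <- apply_jitter(spikes, pmf)
    for (s in -6:6)
      counts[as.character(s)] <- counts[as.character(s)] +
        sum(j[pmin(pmax(which(spikes == 1L) + s, 1), 3000)])
  }
  emp <- counts / sum(counts)
  expect_lt(sum(abs(emp - pmf$probs)) / 2, 0.05)
  # spike count preserved up to edge clipping
  expect_lte(sum(apply_jitter(spikes, pmf, seed = 2L)), sum(spikes))
  expect_gte(sum(apply_jitter(spikes, pmf, seed = 2L)), sum(spikes) - 5L)
})

test_that("switching simulator follows its Markov chain", {
  d <- 6L
  X <- white_noise_stimulus(d, 20000L, seed = 7L)
  w <- rnorm(d)
  same <- switching_lnp_simulate(list(lnp_spec(w, target_rate = 0.05),
                                      lnp_spec(w, target_rate = 0.05)),
                                 X, seed = 8L)
  expect_equal(mean(same$spikes), 0.05, tolerance = 0.01)
  expect_equal(mean(same$states == 1L), 0.5, tolerance = 0.05)
  stay <- switching_lnp_simulate(list(lnp_spec(w, target_rate = 0.05),
                                      lnp_spec(-w, target_rate = 0.05)),
                                 X, switch_matrix = diag(2), seed = 9L)
  expect_identical(length(unique(stay$states)), 1L)
})

test_that("STA equals RC on identity covariance and RC recovers linear
           generative filters", {
  set.seed(20)
  d <- 6L
  X <- white_noise_stimulus(d, 30000L, seed = 21L)
  w <- rnorm(d)
  sim <- lnp_simulate(lnp_spec(w, slope = 3, target_rate = 0.05), X,
                      seed = 22L)
  pair <- mph_pair(X, sim$spikes)
  sta <- sta_fit(pair)
  # rc with the true identity covariance equals sta up to sampling error in
  # the empirical covariance; with an exact identity they coincide
  rc_ident <- drop(solve(diag(d), sta))
  expect_identical(rc_ident, sta)
  expect_gt(cosine_similarity(sta, w), 0.95)

  # correlated Gaussian stimulus: RC recovers the filter direction, STA is
  # biased toward the stimulus correlation
  cs <- correlated_stimulus(d, 40000L, rho_time = 0, channel_scale = 1.5,
                            seed = 23L)
  sim2 <- lnp_simulate(lnp_spec(w, slope = 3, target_rate = 0.05), cs,
                       seed = 24L)
  pair2 <- mph_pair(cs, sim2$spikes)
  rc <- rc_fit(pair2, lam = 0.05)
  expect_gt(cosine_similarity(rc, w), cosine_similarity(sta_fit(pair2), w))
  expect_gt(cosine_similarity(rc, w), 0.9)
  expect_error(sta_fit(mph_pair(X, integer(30000L))), "no spikes")
})

test_that("STC returns orthonormal filters and solves the symmetric
           two-pool model where STA fails", {
  set.seed(25)
  d <- 8L
  X <- white_noise_stimulus(d, 60000L, seed = 26L)
  w <- rnorm(d)
  w <- w / sqrt(sum(w^2)) * 2
  # pooling over w and -w: spike when |projection| is large
  z <- drop(crossprod(X, w))
  p <- plogis(4 * (abs(z) - 4))
  spikes <- rbinom(length(p), 1L, p)
  pair <- mph_pair(X, spikes)
  sta <- sta_fit(pair)
  stc <- stc_fit(pair, 2L)
  expect_equal(crossprod(stc), diag(2), tolerance = 1e-10)
  expect_lt(sqrt(sum(sta^2)), 0.2)                    # STA near zero
  expect_gt(abs(cosine_similarity(stc[, 1], w)), 0.9) # STC finds the axis
  expect_warning(stc_fit(mph_pair(X[, 1:20], c(1L, rep(0L, 19)))),
                 "fewer spikes")
})

test_that("rate correlation metric behaves and the jitter upper bound
           decreases with variance", {
  x <- rnorm(500)
  expect_equal(evaluate_cc(x, x), 1, tolerance = 1e-12)
  set.seed(27)
  expect_lt(abs(evaluate_cc(rnorm(2000), rnorm(2000))), 0.15)
  expect_warning(cc0 <- evaluate_cc(rep(1, 100), rnorm(100)),
                 "zero-variance")
  expect_true(is.nan(cc0))

  spikes <- integer(4000)
  set.seed(28)
  spikes[sample(4000, 120)] <- 1L
  ubs <- vapply(c(0.5, 2, 6), function(s2)
    cc_upper_bound(spikes, discretized_lognormal_kernel(s2),
                   n_samples = 6L, seed = 29L), 0)
  expect_true(all(diff(ubs) < 0))
})

test_that("cosine similarity handles shifts and rejects zero vectors", {
  a <- c(1, 2, 3, 4)
  expect_equal(cosine_similarity(a, 2 * a), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(a, rep(0, 4)), "zero")
  # a filter against its 2-bin temporal shift: shift-invariant mode
  # recovers similarity 1
  w <- c(0, 0, 1, 2, 1, 0, 0, 0)
  ws <- c(0, 0, 0, 0, 1, 2, 1, 0)
  expect_lt(cosine_similarity(w, ws), 0.75)
  expect_equal(cosine_similarity(w, ws, shift_invariant = TRUE), 1,
               tolerance = 1e-12)
})

test_that("tv distance aligns lag supports", {
  a <- list(lags = -1:1, probs = c(0.2, 0.5, 0.3))
  b <- list(lags = 0:2, probs = c(0.5, 0.3, 0.2))
  expect_equal(tv_distance(a, a), 0)
  # union support -1..2: |pa - pb| = (.2, 0, 0, .2), halved
  expect_equal(tv_distance(a, b), 0.2, tolerance = 1e-12)
})
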