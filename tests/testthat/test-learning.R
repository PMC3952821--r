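test_that("expected transition counts conserve posterior flow", {
  for (seed in c(2, 8, 13, 25)) {
    m <- rand_model(seed, d = 2L, n_extra = 2L, W = 3L)
    pair <- rand_pair(seed, d = 2L, Tx = 3L, Tr = 3L)
    en <- enumerate_paths(m, pair)
    if (en$total == 0) next
    es <- mph_estep(m, pair)[[1]]
    # total occupancy of each state from the enumeration oracle
    occ <- vapply(seq_along(m$states), function(s)
      sum(vapply(seq_along(en$probs), function(p)
        sum(en$states[[p]] == s) * en$probs[p], 0)) / en$total, 0)
    # inflow: initial occupancy plus transitions into s
    expect_equal(es$init_occ + colSums(es$xi), occ, tolerance = 1e-9)
    # outflow: transitions out of s plus terminal occupancy
    expect_equal(rowSums(es$xi) + es$final_occ, occ, tolerance = 1e-9)
    # per-pair log-likelihood matches the forward total
    expect_equal(es$loglik, log(en$total), tolerance = 1e-9)
  }
})

test_that("single-path model puts unit expected counts on its transitions", {
  set.seed(5)
  emb <- stimulus_embedding(2L, 1L)
  m <- mph_mn(1L, emb, spike_prob = 0.3)
  pair <- mph_pair(matrix(rnorm(8), 2, 4), c(0L, 1L, 1L, 0L))
  es <- mph_estep(m, pair)[[1]]
  expect_equal(es$xi[1, 1], 3, tolerance = 1e-10)  # 4 steps, 3 transitions
  expect_equal(es$init_occ, 1, tolerance = 1e-12)
  expect_equal(es$final_occ, 1, tolerance = 1e-12)
})

test_that("one M-step on the M-MPH sets the RF to the spike-triggered mean", {
  set.seed(10)
  d <- 6L
  emb <- stimulus_embedding(d, 1L)
  Tn <- 400L
  X <- matrix(rnorm(d * Tn), d, Tn)
  r <- rbinom(Tn, 1L, 0.2)
  pair <- mph_pair(X, r)
  m <- mph_mn(1L, emb, spike_prob = 0.5)
  es <- mph_estep(m, pair)
  m2 <- mph_mstep(m, es, pair)
  # independent computation of the spike-triggered ensemble mean
  sta <- rowMeans(X[, r == 1L, drop = FALSE])
  expect_equal(m2$states[[1]]$emission$conditional[[2]]$means[, 1], sta,
               tolerance = 1e-10)
  # marginal becomes the empirical spike rate; no-spike mean stays fixed at 0
  expect_equal(m2$states[[1]]$emission$marginal$probs[2], mean(r),
               tolerance = 1e-10)
  expect_identical(m2$states[[1]]$emission$conditional[[1]]$means[, 1],
                   rep(0, d))
})

test_that("a fully frozen model is returned unchanged by the M-step", {
  set.seed(3)
  emb <- stimulus_embedding(2L, 1L)
  m <- mph_mn(1L, emb, spike_prob = 0.3)
  # freeze everything that is free in the template
  m$states[[1]]$emission$marginal$mode <- "fixed"
  m$states[[1]]$emission$conditional[[2]]$mean_mode <- "fixed_value"
  pair <- mph_pair(matrix(rnorm(20), 2, 10), rbinom(10, 1, 0.4))
  es <- mph_estep(m, pair)
  m2 <- mph_mstep(m, es, pair)
  expect_identical(m2$states, m$states)
  # single-state chain transitions are forced: xi/(xi + final)
  expect_equal(m2$transitions[1, 1] + m2$final[1], 1, tolerance = 1e-12)
})

test_that("free K=1 Gaussian update equals weighted sample moments on a
           single-path model", {
  set.seed(6)
  d <- 3L
  emb <- stimulus_embedding(d, 1L)
  Tn <- 60L
  X <- matrix(rnorm(d * Tn), d, Tn)
  r <- rbinom(Tn, 1L, 0.5)
  m <- mph_mn(1L, emb, spike_prob = 0.5)
  for (v in 1:2) {
    m$states[[1]]$emission$conditional[[v]] <-
      gm_emission(matrix(0, d, 1), diag(d), 1,
                  cov_mode = "free", mean_mode = "free")
  }
  pair <- mph_pair(X, r)
  m2 <- mph_mstep(m, mph_estep(m, pair), pair,
                  mph_control(cov_floor = 0))
  for (v in 1:2) {
    Xv <- X[, r == (v - 1L), drop = FALSE]
    mu <- rowMeans(Xv)
    S <- tcrossprod(Xv - mu) / ncol(Xv)
    expect_equal(m2$states[[1]]$emission$conditional[[v]]$means[, 1], mu,
                 tolerance = 1e-10)
    expect_equal(m2$states[[1]]$emission$conditional[[v]]$covs[, , 1], S,
                 tolerance = 1e-10)
  }
})

test_that("EM keeps all distributions normalized and constraints intact", {
  set.seed(9)
  emb <- stimulus_embedding(2L, 2L)
  m <- mph_mxr(emb, band_width = 3L)
  stim <- white_noise_stimulus(2L, 300L)
  X <- embed_stimulus(stim, emb)
  r <- rbinom(300L, 1L, 0.1)
  fit <- mph_fit(m, mph_pair(X, r), mph_control(max_iters = 8L, seed = 2L))
  mm <- fit$model
  expect_equal(rowSums(mm$transitions) + mm$final, rep(1, 3),
               tolerance = 1e-12)
  expect_equal(sum(mm$initial), 1, tolerance = 1e-12)
  rs <- which(state_kinds(mm) == "R")
  expect_identical(mm$states[[rs]]$emission$probs, c(1, 0))
  ms <- which(state_kinds(mm) == "M")
  em <- mm$states[[ms]]$emission
  expect_equal(sum(em$marginal$probs), 1, tolerance = 1e-12)
  # identity covariances and fixed no-spike mean preserved bit-exactly
  expect_identical(em$conditional[[1]]$covs[, , 1], diag(4))
  expect_identical(em$conditional[[2]]$covs[, , 1], diag(4))
  expect_identical(em$conditional[[1]]$means[, 1], rep(0, 4))
  xs <- which(state_kinds(mm) == "X")
  expect_identical(mm$states[[xs]]$emission$means[, 1], rep(0, 4))
})

test_that("EM log-likelihood is monotone across architectures and seeds", {
  worst <- 0
  n_fits <- 0L
  for (seed in 1:18) {
    set.seed(seed)
    arch <- seed %% 3L
    if (arch == 0L) {
      emb <- stimulus_embedding(3L, 1L)
      m <- mph_mn(1L, emb)
      X <- matrix(rnorm(3 * 80), 3, 80)
      r <- rbinom(80, 1, 0.2)
    } else if (arch == 1L) {
      emb <- stimulus_embedding(2L, 2L)
      m <- mph_mxr(emb, band_width = 2L)
      X <- embed_stimulus(white_noise_stimulus(2L, 80L), emb)
      r <- rbinom(80, 1, 0.15)
    } else {
      emb <- stimulus_embedding(4L, 1L)
      m <- mph_mn(2L, emb)
      X <- matrix(rnorm(4 * 80), 4, 80)
      r <- rbinom(80, 1, 0.3)
    }
    fit <- mph_fit(m, mph_pair(X, r),
                   mph_control(max_iters = 12L, seed = seed))
    n_fits <- n_fits + 1L
    if (length(fit$trace) > 1L)
      worst <- min(worst, min(diff(fit$trace)))
  }
  expect_identical(n_fits, 18L)
  expect_gte(worst, -1e-8)
})

test_that("M-MPH with fixed shared covariance converges in one iteration", {
  set.seed(12)
  emb <- stimulus_embedding(3L, 1L)
  m <- mph_mn(1L, emb)
  X <- matrix(rnorm(3 * 500), 3, 500)
  r <- rbinom(500, 1, 0.1)
  fit <- mph_fit(m, mph_pair(X, r), mph_control(seed = 4L))
  # iteration 1 jumps to the optimum; iteration 2 confirms convergence
  expect_lte(fit$n_iter, 3L)
  expect_true(fit$converged)
  # refitting from the fitted model changes nothing
  fit2 <- mph_fit(fit$model, fit$pairs,
                  mph_control(seed = 4L, init_from_data = FALSE))
  expect_lte(fit2$n_iter, 2L)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("max_iters = 0 returns the input model unchanged", {
  emb <- stimulus_embedding(2L, 1L)
  m <- mph_mn(1L, emb)
  fit <- mph_fit(m, rand_pair(1, 2L, 4L, 4L), mph_control(max_iters = 0L))
  expect_identical(fit$model, m)
  expect_identical(fit$n_iter, 0L)
})

test_that("multiple restarts return the highest-likelihood fit", {
  set.seed(30)
  emb <- stimulus_embedding(4L, 1L)
  m <- mph_mn(2L, emb)
  X <- matrix(rnorm(4 * 300), 4, 300)
  r <- rbinom(300, 1, 0.2)
  fit <- mph_fit(m, mph_pair(X, r),
                 mph_control(max_iters = 10L, n_restarts = 3L, seed = 7L))
  expect_identical(nrow(fit$restarts), 3L)
  expect_equal(fit$loglik, max(fit$restarts$loglik), tolerance = 1e-12)
})
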