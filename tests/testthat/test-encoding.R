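test_that("rewriting reproduces original log-likelihoods on random pairs", {
  for (seed in c(1, 5, 12, 20, 31)) {
    m <- rand_model(seed, d = 2L, n_extra = 2L, W = 3L)
    rw <- rewrite_for_inference(m)
    expect_false(any(state_kinds(rw) == "M"))
    for (k in 1:4) {
      pair <- rand_pair(seed * 100 + k, d = 2L, Tx = 3L, Tr = 3L)
      ll1 <- try(mph_forward(m, pair)$loglik, silent = TRUE)
      if (inherits(ll1, "try-error")) next
      ll2 <- mph_forward(rw, pair)$loglik
      expect_equal(ll2, ll1, tolerance = 1e-9)
    }
  }
})

test_that("rewriting leaves M-free deterministic models unchanged and prunes
           zero branches", {
  emb <- stimulus_embedding(2L, 1L)
  # X + deterministic R only: no rewriting needed
  xst <- mph_state("X", gm_emission(matrix(0, 2, 1)))
  rst <- mph_state("R", discrete_emission(c(1, 0), "fixed"))
  m <- mph_model(list(xst, rst), matrix(c(0.4, 0.5, 0.5, 0.4), 2),
                 c(0.5, 0.5), c(0.1, 0.1), band_width = 2L, embedding = emb)
  expect_identical(rewrite_for_inference(m), m)

  # MXR with a never-spiking R-state: its split keeps only the r0 branch
  m2 <- mph_mxr(emb, band_width = 2L)
  rw <- rewrite_for_inference(m2)
  labs <- vapply(rw$states, `[[`, "", "label")
  expect_false(any(grepl("^R\\.r1$", labs)))
  # M-state expands into four states; R stays single
  expect_identical(length(rw$states), 3L + 3L)  # X, R, M.x0, M.x1, M.r0, M.r1
})

test_that("response probabilities agree with brute-force response
           marginalization", {
  for (seed in c(4, 9, 16)) {
    m <- rand_model(seed, d = 2L, n_extra = 2L, W = 3L)
    set.seed(seed + 5)
    Tn <- 3L
    X <- matrix(rnorm(2 * Tn), 2, Tn)
    probs <- response_probabilities(m, X, Tn)
    # oracle: sum P(X, R) over all 2^Tn response sequences
    tot <- 0
    num <- numeric(Tn)
    for (bits in 0:(2^Tn - 1)) {
      r <- as.integer(intToBits(bits)[1:Tn])
      en <- enumerate_paths(m, mph_pair(X, r))
      tot <- tot + en$total
      num <- num + (r >= 1L) * en$total
    }
    expect_equal(probs$spike_prob, num / tot, tolerance = 1e-9)
    expect_equal(rowSums(probs$probs), rep(1, Tn), tolerance = 1e-10)
  }
})

test_that("M-MPH spike probabilities equal the closed-form sigmoid", {
  set.seed(8)
  d <- 5L
  emb <- stimulus_embedding(d, 1L)
  S <- rand_spd(d)
  m <- mph_mn(1L, emb, spike_prob = 0.23)
  for (v in 1:2) {
    m$states[[1]]$emission$conditional[[v]] <-
      gm_emission(matrix(rnorm(d), d, 1), S, 1,
                  cov_mode = "fixed_shared", mean_mode = "free")
  }
  X <- matrix(rnorm(d * 50), d, 50)
  pr <- response_probabilities(m, X)$spike_prob
  bridge <- mph_as_lnp(m)
  expect_equal(pr, predict(bridge, X), tolerance = 1e-12)
  # Eq-6 filter: covariance-corrected mean difference
  mu0 <- m$states[[1]]$emission$conditional[[1]]$means[, 1]
  mu1 <- m$states[[1]]$emission$conditional[[2]]$means[, 1]
  expect_equal(bridge$w, drop(solve(S, mu1 - mu0)), tolerance = 1e-12)
})

test_that("extreme spike marginals force all-zero / all-one responses", {
  set.seed(2)
  emb <- stimulus_embedding(2L, 1L)
  X <- matrix(rnorm(10), 2, 5)
  m0 <- mph_mn(1L, emb, spike_prob = 1e-9)
  # identical conditional Gaussians: emission argmax driven by the marginal
  m0$states[[1]]$emission$conditional[[2]]$mean_mode <- "fixed_zero"
  enc0 <- encode_map(m0, X)
  expect_identical(enc0$response, rep(0L, 5))
  m1 <- mph_mn(1L, emb, spike_prob = 1 - 1e-9)
  m1$states[[1]]$emission$conditional[[2]]$mean_mode <- "fixed_zero"
  m1$states[[1]]$emission$conditional[[2]]$means[, 1] <- 0
  enc1 <- encode_map(m1, X)
  expect_identical(enc1$response, rep(1L, 5))
  # spike marginal 0 gives flat zero predicted spike probability
  expect_equal(response_probabilities(m0, X)$spike_prob, rep(0, 5),
               tolerance = 1e-8)
})

test_that("encode_map attains the joint (path, response) optimum", {
  for (seed in c(3, 7, 14, 22)) {
    m <- rand_model(seed, d = 2L, n_extra = 2L, W = 3L)
    set.seed(seed + 50)
    Tn <- 3L
    X <- matrix(rnorm(2 * Tn), 2, Tn)
    enc <- try(encode_map(m, X, Tn), silent = TRUE)
    if (inherits(enc, "try-error")) next
    # oracle: max over response sequences of the best path probability
    best <- -Inf
    for (bits in 0:(2^Tn - 1)) {
      r <- as.integer(intToBits(bits)[1:Tn])
      en <- enumerate_paths(m, mph_pair(X, r))
      if (length(en$probs)) best <- max(best, max(en$probs))
    }
    expect_equal(enc$logp, log(best), tolerance = 1e-9)
    # the returned response must achieve that maximum
    en_r <- enumerate_paths(m, mph_pair(X, enc$response))
    expect_equal(log(max(en_r$probs)), log(best), tolerance = 1e-9)
  }
})

test_that("cascade estimation is calibrated on model-generated data and
           reproduces forced shapes", {
  set.seed(11)
  emb <- stimulus_embedding(3L, 1L)
  m <- mph_mn(1L, emb, spike_prob = 0.2)
  m$states[[1]]$emission$conditional[[2]]$means[, 1] <- c(1.5, -1, 0.5)
  pair <- mph_sample(m, 20000L)
  map <- fit_cascade(m, pair, n_bins = 10L)
  wts <- map$den / sum(map$den)
  expect_lt(sum(wts * abs(map$g - map$centers)), 0.08)

  # identity mapping leaves a series unchanged
  ident <- structure(list(edges = seq(0, 1, 0.1),
                          centers = seq(0.05, 0.95, 0.1),
                          g = seq(0.05, 0.95, 0.1),
                          num = rep(1, 10), den = rep(1, 10)),
                     class = "mph_cascade")
  p <- seq(0.05, 0.95, 0.05)
  expect_equal(apply_cascade(ident, p), p, tolerance = 1e-12)
  # constant mapping flattens everything
  const <- ident
  const$g <- rep(0.5, 10)
  expect_equal(apply_cascade(const, p), rep(0.5, length(p)))
  # step mapping thresholds a ramp
  step <- ident
  step$g <- as.numeric(ident$centers > 0.5)
  out <- apply_cascade(step, c(0.1, 0.9))
  expect_equal(out, c(0, 1))
  expect_error(fit_cascade(m, mph_pair(pair$stimulus, rep(0L, 20000L))),
               "no spikes")
})

test_that("predict and coef methods expose rates and receptive fields", {
  set.seed(15)
  emb <- stimulus_embedding(3L, 1L)
  X <- matrix(rnorm(3 * 200), 3, 200)
  r <- rbinom(200, 1, 0.2)
  fit <- mph_fit(mph_mn(1L, emb), mph_pair(X, r),
                 mph_control(max_iters = 4L, seed = 1L))
  rf <- coef(fit)
  expect_identical(dim(rf), c(3L, 1L))
  pr <- predict(fit, X[, 1:20])
  expect_s3_class(pr, "mph_rate")
  expect_length(pr$spike_prob, 20L)
  expect_true(all(pr$spike_prob >= 0 & pr$spike_prob <= 1))
  enc <- predict(fit, X[, 1:10], type = "map")
  expect_length(enc$response, 10L)
})
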