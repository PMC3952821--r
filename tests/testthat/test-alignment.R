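test_that("single M-state, single bin: forward equals the unique path", {
  set.seed(42)
  emb <- stimulus_embedding(2L, 1L)
  m <- mph_mn(1L, emb)
  m$states[[1]]$emission$conditional[[2]]$means[, 1] <- c(1, -1)
  pair <- mph_pair(matrix(rnorm(2), 2, 1), 1L)
  fw <- mph_forward(m, pair)
  em <- m$states[[1]]$emission
  dens <- em$marginal$probs[2] *
    exp(mphmm:::mvn_logdens(pair$stimulus,
                            em$conditional[[2]]$means[, 1], diag(2)))
  expect_equal(fw$loglik, log(m$initial[1] * dens * m$final[1]),
               tolerance = 1e-12)
  # backward initialization and the alpha-beta identity at (1,1)
  bw <- mph_backward(m, pair)
  expect_equal(at_band(bw$beta, 1, 1, m$band_width)[1], log(m$final[1]))
  vt <- mph_viterbi(m, pair)
  expect_identical(vt$path$kind, "M")
  expect_equal(vt$logp, fw$loglik, tolerance = 1e-12)
})

test_that("forward, Viterbi, posteriors and kernel match brute-force
           enumeration on random instances", {
  n_checked <- 0L
  for (seed in 1:60) {
    m <- rand_model(seed, d = 2L, n_extra = sample(1:3, 1), W = 3L)
    Tx <- sample(2:4, 1)
    Tr <- sample(max(1, Tx - 2):min(4, Tx + 2), 1)
    pair <- rand_pair(seed, d = 2L, Tx = Tx, Tr = Tr)
    en <- enumerate_paths(m, pair)
    if (en$total == 0) next
    n_checked <- n_checked + 1L

    fw <- mph_forward(m, pair)
    expect_equal(fw$loglik, log(en$total), tolerance = 1e-8)

    vt <- mph_viterbi(m, pair)
    expect_equal(vt$logp, log(max(en$probs)), tolerance = 1e-8)
    # the returned path must be one of the maximizing paths (ties allowed)
    argmax <- which(log(en$probs) > log(max(en$probs)) - 1e-9)
    expect_true(any(vapply(argmax, function(p)
      identical(en$states[[p]], vt$path$state), TRUE)))

    po <- mph_posteriors(m, pair)
    gb <- bruteforce_gamma(en, m, Tx, Tr)
    for (i in 0:Tx) for (j in max(0, i - 3):min(Tr, i + 3)) {
      expect_equal(at_band(po$gamma, i, j, 3), gb[i + 1, j + 1, ],
                   tolerance = 1e-9)
    }

    if (any(pair$response >= 1L)) {
      kern <- alignment_kernel(m, pair)
      # oracle: expected number of M-matches at each lag over paths
      kinds <- state_kinds(m)
      acc <- setNames(rep(0, length(kern$lags)), kern$lags)
      for (p in seq_along(en$probs)) {
        st <- en$states[[p]]
        for (q in seq_along(st)) {
          if (kinds[st[q]] != "M") next
          j <- en$j[[p]][q]
          if (pair$response[j] < 1L) next
          lag <- as.character(j - en$i[[p]][q])
          acc[lag] <- acc[lag] + en$probs[p]
        }
      }
      if (sum(acc) > 0)
        expect_equal(kern$probs, unname(acc / sum(acc)), tolerance = 1e-9)
    }
  }
  expect_gte(n_checked, 40L)
})

test_that("forward and backward totals agree and posteriors partition each
           response position", {
  for (seed in c(3, 11, 17)) {
    m <- rand_model(seed, d = 2L, n_extra = 2L, W = 4L)
    pair <- rand_pair(seed, d = 2L, Tx = 3L, Tr = 3L)
    fw <- mph_forward(m, pair)
    bw <- mph_backward(m, pair)
    expect_equal(fw$loglik, bw$loglik, tolerance = 1e-9)
    # every path consumes each response position exactly once, via an R- or
    # M-state, so those posteriors sum to one per column j
    po <- mph_posteriors(m, pair)
    consuming <- which(state_kinds(m) %in% c("R", "M"))
    for (j in 1:3) {
      tot <- 0
      for (i in max(0, j - 4):min(3, j + 4))
        tot <- tot + sum(at_band(po$gamma, i, j, 4)[consuming])
      expect_equal(tot, 1, tolerance = 1e-9)
    }
  }
})

test_that("banding beyond max(Tx, Tr) never changes results", {
  for (seed in c(5, 9)) {
    m <- rand_model(seed, d = 2L, n_extra = 2L, W = 10L)
    pair <- rand_pair(seed, d = 2L, Tx = 4L, Tr = 4L)
    ll <- vapply(c(4L, 6L, 10L), function(W)
      mph_forward(m, pair, band_width = W)$loglik, 0)
    expect_equal(ll[1], ll[2], tolerance = 1e-10)
    expect_equal(ll[2], ll[3], tolerance = 1e-10)
    v <- vapply(c(4L, 6L, 10L), function(W)
      mph_viterbi(m, pair, band_width = W)$logp, 0)
    expect_equal(max(v) - min(v), 0, tolerance = 1e-10)
  }
})

test_that("M-only models give a delta alignment kernel at lag 0", {
  set.seed(7)
  emb <- stimulus_embedding(2L, 1L)
  m <- mph_mn(1L, emb, spike_prob = 0.4)
  pair <- mph_pair(matrix(rnorm(12), 2, 6), c(0L, 1L, 0L, 1L, 1L, 0L))
  kern <- alignment_kernel(m, pair, band_width = 2L)
  expect_equal(kern$probs[kern$lags == 0], 1, tolerance = 1e-12)
  expect_error(alignment_kernel(m, mph_pair(pair$stimulus, rep(0L, 6))),
               "no spikes")
})

test_that("delayed spikes put the kernel mode at a positive lag", {
  # spikes delayed by +1 bin relative to their matched stimulus: the model
  # must match response position j to stimulus position i = j - 1, lag +1
  set.seed(21)
  d <- 4L
  emb <- stimulus_embedding(d, 1L)
  w <- c(2, -2, 2, -2)
  Tn <- 200L
  X <- matrix(rnorm(d * Tn), d, Tn)
  z <- drop(crossprod(X, w))
  ideal <- as.integer(z > quantile(z, 0.93))
  delayed <- c(0L, ideal[-Tn])
  m <- mph_mxr(emb, band_width = 3L, spike_prob = mean(delayed))
  m$states[[3]]$emission$conditional[[2]]$means[, 1] <- w * 0.8
  kern <- alignment_kernel(m, mph_pair(X, delayed))
  expect_identical(kern$lags[which.max(kern$probs)], 1L)
})

test_that("path enumeration matches the lattice-path count inside the band", {
  m <- rand_model(2, d = 2L, n_extra = 2L, W = 2L)
  kinds <- state_kinds(m)
  # force nonzero transition everywhere so all geometric paths are counted
  pair <- rand_pair(2, d = 2L, Tx = 2L, Tr = 2L)
  en <- enumerate_paths(m, pair)
  # independent combinatorial count: monotone lattice paths (0,0)->(2,2)
  # with steps E/N/D and |i-j| <= 2, each step decorated by a state of the
  # matching kind
  nX <- sum(kinds == "X")
  nR <- sum(kinds == "R")
  nM <- sum(kinds == "M")
  count_paths <- function(i, j) {
    if (i == 2 && j == 2) return(1)
    tot <- 0
    if (i < 2 && abs(i + 1 - j) <= 2) tot <- tot + nX * count_paths(i + 1, j)
    if (j < 2 && abs(i - j - 1) <= 2) tot <- tot + nR * count_paths(i, j + 1)
    if (i < 2 && j < 2) tot <- tot + nM * count_paths(i + 1, j + 1)
    tot
  }
  expect_identical(length(en$probs), as.integer(count_paths(0, 0)))
})

test_that("log-domain DP survives long sequences without underflow", {
  set.seed(4)
  d <- 40L
  emb <- stimulus_embedding(d, 1L)
  m <- mph_mn(1L, emb, spike_prob = 0.05)
  Tn <- 10000L
  X <- matrix(rnorm(d * Tn), d, Tn)
  r <- rbinom(Tn, 1L, 0.05)
  fw <- mph_forward(m, mph_pair(X, r))
  expect_true(is.finite(fw$loglik))
  expect_lt(fw$loglik, 0)
})

test_that("band too narrow to connect the corners raises an error", {
  m <- rand_model(1, d = 2L)
  pair <- rand_pair(1, d = 2L, Tx = 6L, Tr = 2L)
  expect_error(mph_forward(m, pair, band_width = 1L), "band width")
})
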