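# Shared fixtures: random small models and pairs for oracle comparisons.

rand_spd <- function(d) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + diag(d) * 0.5
}

rand_gm <- function(d, K = 1L) {
  w <- runif(K) + 0.2
  gm_emission(matrix(rnorm(d * K), d, K),
              array(vapply(seq_len(K), function(k) rand_spd(d),
                           matrix(0, d, d)), dim = c(d, d, K)),
              w / sum(w))
}

rand_discrete <- function(V = 2L) {
  p <- runif(V) + 0.1
  discrete_emission(p / sum(p))
}

rand_mixed <- function(d, V = 2L, K = 1L) {
  mixed_emission(rand_discrete(V), lapply(seq_len(V), function(v)
    rand_gm(d, K)))
}

# random valid model; always contains an M-state so any (Tx, Tr) pair with
# |Tx - Tr| <= W is reachable
rand_model <- function(seed, d = 2L, n_extra = 2L, W = 3L, K = 1L) {
  set.seed(seed)
  emb <- stimulus_embedding(d, 1L)  # d-dim embedding, raw vectors
  kinds <- c("M", sample(c("X", "R", "M"), n_extra, replace = TRUE))
  states <- lapply(kinds, function(k) {
    switch(k,
           X = mph_state("X", rand_gm(d, K)),
           R = mph_state("R", rand_discrete()),
           M = mph_state("M", rand_mixed(d, K = K)))
  })
  N <- length(states)
  A <- matrix(runif(N * N) + 0.1, N)
  tau <- runif(N, 0.05, 0.3)
  A <- A / rowSums(A) * (1 - tau)
  rho <- runif(N) + 0.1
  mph_model(states, A, rho / sum(rho), tau, band_width = W, embedding = emb)
}

rand_pair <- function(seed, d = 2L, Tx = 3L, Tr = 3L) {
  set.seed(seed + 777L)
  mph_pair(matrix(rnorm(d * Tx), d, Tx),
           sample(0:1, Tr, replace = TRUE))
}

# posterior mass per (i, j, s) from enumerated paths (independent oracle)
bruteforce_gamma <- function(en, model, Tx, Tr) {
  N <- length(model$states)
  g <- array(0, dim = c(Tx + 1L, Tr + 1L, N))
  for (p in seq_along(en$probs)) {
    st <- en$states[[p]]
    for (q in seq_along(st))
      g[en$i[[p]][q] + 1L, en$j[[p]][q] + 1L, st[q]] <-
        g[en$i[[p]][q] + 1L, en$j[[p]][q] + 1L, st[q]] + en$probs[p]
  }
  g / en$total
}

# banded array value at (i, j, s) (log or prob domain)
at_band <- function(arr, i, j, W) {
  k <- j - i + W + 1L
  if (k < 1L || k > dim(arr)[2]) return(rep(-Inf, dim(arr)[3]))
  arr[i + 1L, k, ]
}
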