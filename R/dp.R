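# Banded dynamic programming over the alignment tensor: R wrappers around
# the compiled recursions, plus the brute-force path-enumeration oracle.
#
# Banded storage convention: value[i + 1, k, s] holds the quantity at cell
# (i, j, s) with j = i - W + (k - 1); cells outside the band or outside
# 0..Tr are -Inf.

kind_codes <- function(model)
  match(state_kinds(model), c("X", "R", "M")) - 1L

# Precompute per-position log emissions for the compiled DP.
# response_free = TRUE treats the response as unobserved: R-state emissions
# contribute log 1 = 0 (only valid for models without M-states).
prep_dp <- function(model, pair, response_free = FALSE) {
  X <- pair$stimulus
  r <- pair$response
  Tx <- ncol(X)
  Tr <- length(r)
  N <- length(model$states)
  V <- model$V
  kinds <- state_kinds(model)
  if (nrow(X) != model$embedding$d)
    stop("stimulus dimension ", nrow(X), " does not match model embedding d = ",
         model$embedding$d)
  if (max(r) >= V) stop("response symbols outside model alphabet")
  EX <- matrix(0, max(Tx, 1L), N)
  ER <- matrix(0, max(Tr, 1L), N)
  EM <- array(0, dim = c(max(Tx, 1L), V, N))
  for (s in seq_len(N)) {
    st <- model$states[[s]]
    if (kinds[s] == "X") {
      EX[, s] <- gm_logdens(st$emission, X)
    } else if (kinds[s] == "R") {
      if (!response_free)
        ER[, s] <- log(st$emission$probs)[r + 1L]
    } else {
      if (response_free)
        stop("response-free inference requires a model without M-states; ",
             "use rewrite_for_inference() first")
      lp <- log(st$emission$marginal$probs)
      for (v in seq_len(V))
        EM[, v, s] <- lp[v] + gm_logdens(st$emission$conditional[[v]], X)
    }
  }
  list(kinds = kind_codes(model), logA = log(model$transitions),
       logrho = log(model$initial), logtau = log(model$final),
       Tx = Tx, Tr = Tr, EX = EX, ER = ER, EM = EM, r = as.integer(r))
}

# per-state allowed lag range (lag = j - i); models carry custom bounds only
# when produced by rewrite_for_inference
lag_bounds_of <- function(model, W) {
  N <- length(model$states)
  if (!is.null(model$lag_bounds)) {
    lb <- model$lag_bounds
  } else {
    lb <- cbind(rep(-W, N), rep(W, N))
  }
  list(lo = as.integer(pmax(lb[, 1], -W)), hi = as.integer(pmin(lb[, 2], W)))
}

check_band <- function(Tx, Tr, W) {
  if (abs(Tx - Tr) > W)
    stop("band width W = ", W, " too narrow to connect (0,0) to (",
         Tx, ",", Tr, ")")
}

#' Generalized forward algorithm
#'
#' Fills the banded forward tensor alpha(i, j, s): the probability of the
#' stimulus up to position i, the response up to position j, ending in state
#' s.  All arithmetic is in the log domain.  The total data log-likelihood
#' is \code{log sum_s alpha(Tx, Tr, s) tau(s)}.
#'
#' @param model an \code{\link{mph_model}}.
#' @param pair an \code{\link{mph_pair}}.
#' @param band_width band width override (defaults to the model's).
#' @return List with \code{alpha} (banded array), \code{loglik}, and the
#'   band geometry (\code{Tx}, \code{Tr}, \code{W}).
#' @export
mph_forward <- function(model, pair, band_width = model$band_width) {
  W <- as.integer(band_width)
  p <- prep_dp(model, pair)
  check_band(p$Tx, p$Tr, W)
  lb <- lag_bounds_of(model, W)
  out <- dp_forward_cpp(p$kinds, p$logA, p$logrho, p$logtau,
                        p$Tx, p$Tr, W, p$EX, p$ER, p$EM, p$r, lb$lo, lb$hi)
  if (!is.finite(out$loglik))
    stop("pair impossible under model (zero probability; band width and ",
         "state kinds may not admit any path)")
  list(alpha = out$alpha, loglik = out$loglik, Tx = p$Tx, Tr = p$Tr, W = W)
}

#' Generalized backward algorithm
#'
#' Mirror recursion of \code{\link{mph_forward}} starting from the final
#' probabilities tau at cell (Tx, Tr): beta(i, j, s) is the probability of
#' emitting the remaining symbols given the path currently sits in state s
#' at cell (i, j).
#'
#' @inheritParams mph_forward
#' @return List with \code{beta} (banded array), \code{loglik} (recomputed
#'   from the start distribution), and the band geometry.
#' @export
mph_backward <- function(model, pair, band_width = model$band_width) {
  W <- as.integer(band_width)
  p <- prep_dp(model, pair)
  check_band(p$Tx, p$Tr, W)
  lb <- lag_bounds_of(model, W)
  out <- dp_backward_cpp(p$kinds, p$logA, p$logrho, p$logtau,
                         p$Tx, p$Tr, W, p$EX, p$ER, p$EM, p$r, lb$lo, lb$hi)
  list(beta = out$beta, loglik = out$loglik, Tx = p$Tx, Tr = p$Tr, W = W)
}

#' Generalized Viterbi algorithm
#'
#' Computes the most likely hidden path through the alignment tensor for a
#' stimulus-response pair, by the banded max-product recursion with
#' backtracking.  Ties are broken deterministically (lowest precursor state
#' index; at termination M- over X- over R-states, then lowest index).
#'
#' @inheritParams mph_forward
#' @return List with \code{path} (data frame: step, state index, kind,
#'   label, i, j) and \code{logp}, the log joint probability of the path and
#'   the data.
#' @export
mph_viterbi <- function(model, pair, band_width = model$band_width) {
  W <- as.integer(band_width)
  p <- prep_dp(model, pair)
  check_band(p$Tx, p$Tr, W)
  lb <- lag_bounds_of(model, W)
  out <- dp_viterbi_cpp(p$kinds, p$logA, p$logrho, p$logtau,
                        p$Tx, p$Tr, W, p$EX, p$ER, p$EM, p$r, lb$lo, lb$hi)
  if (!is.finite(out$logp))
    stop("pair impossible under model (zero probability; band width and ",
         "state kinds may not admit any path)")
  kinds <- state_kinds(model)
  s <- out$final_state
  i <- p$Tx
  j <- p$Tr
  states <- integer(0)
  ii <- integer(0)
  jj <- integer(0)
  repeat {
    states <- c(s, states)
    ii <- c(i, ii)
    jj <- c(j, jj)
    prev <- out$ptr[i + 1L, j - i + W + 1L, s]
    ni <- if (kinds[s] == "R") i else i - 1L
    nj <- if (kinds[s] == "X") j else j - 1L
    if (prev == -1L) break
    s <- prev + 1L
    i <- ni
    j <- nj
  }
  path <- data.frame(step = seq_along(states), state = states,
                     kind = kinds[states],
                     label = vapply(model$states[states], `[[`, "", "label"),
                     i = ii, j = jj)
  list(path = path, logp = out$logp)
}

#' State posteriors over the alignment tensor
#'
#' gamma(i, j, s) = alpha(i, j, s) beta(i, j, s) / P(X, R): the posterior
#' probability that a hidden path passes through cell (i, j) in state s.
#'
#' @inheritParams mph_forward
#' @return List with \code{gamma} (banded array of probabilities),
#'   \code{loglik}, and the band geometry.
#' @export
mph_posteriors <- function(model, pair, band_width = model$band_width) {
  fw <- mph_forward(model, pair, band_width)
  bw <- mph_backward(model, pair, band_width)
  g <- exp(fw$alpha + bw$beta - fw$loglik)
  g[!is.finite(g)] <- 0
  list(gamma = g, loglik = fw$loglik, Tx = fw$Tx, Tr = fw$Tr, W = fw$W)
}

# extract value at cell (i, j, s) from a banded array (i in 0..Tx)
band_get <- function(arr, i, j, W) {
  k <- j - i + W + 1L
  if (k < 1L || k > dim(arr)[2]) return(-Inf)
  arr[i + 1L, k, ]
}

#' Alignment kernel: posterior distribution of spike-stimulus lags
#'
#' The posterior-weighted histogram of lags d = j - i over matched
#' (stimulus i, response j) cells at spike positions: the model's estimate
#' of the jitter / latency distribution.  Negative lags mean spikes precede
#' their matched stimulus; positive lags mean they follow it.
#'
#' @inheritParams mph_forward
#' @param include_r also count R-state posteriors at spike positions
#'   (variant summand; irrelevant when R-states cannot emit spikes).
#' @return Object of class \code{"mph_kernel"}: list with integer
#'   \code{lags} (-W..W), \code{probs} (normalized), and \code{bin_width}.
#' @export
alignment_kernel <- function(model, pair, band_width = model$band_width,
                             include_r = FALSE) {
  if (!any(pair$response >= 1L))
    stop("kernel undefined: pair contains no spikes")
  po <- mph_posteriors(model, pair, band_width)
  W <- po$W
  kinds <- state_kinds(model)
  use <- kinds == "M" | (include_r & kinds == "R")
  Tx <- po$Tx
  Tr <- po$Tr
  # mask[i + 1, k] = 1 iff cell (i, j = i + k - 1 - W) has a spike at j
  iidx <- rep(0:Tx, times = 2 * W + 1)
  kidx <- rep(seq_len(2 * W + 1), each = Tx + 1)
  jidx <- iidx + kidx - 1L - W
  ok <- jidx >= 1L & jidx <= Tr
  mask <- matrix(0, Tx + 1, 2 * W + 1)
  mask[cbind(iidx + 1L, kidx)[ok, , drop = FALSE]] <-
    as.numeric(pair$response[jidx[ok]] >= 1L)
  tot <- numeric(2 * W + 1)
  for (s in which(use))
    tot <- tot + colSums(po$gamma[, , s] * mask)
  if (sum(tot) <= 0)
    stop("kernel undefined: no posterior mass on spike-matching states")
  structure(list(lags = (-W):W, probs = tot / sum(tot),
                 bin_width = pair$bin_width),
            class = "mph_kernel")
}

#' Pool alignment kernels over several pairs
#'
#' Kernels are averaged with weights proportional to each pair's spike
#' count, giving the spike-level lag distribution of the collection.
#'
#' @param model an \code{\link{mph_model}}.
#' @param pairs list of \code{\link{mph_pair}} objects.
#' @param ... passed to \code{\link{alignment_kernel}}.
#' @return An \code{"mph_kernel"}.
#' @export
pooled_alignment_kernel <- function(model, pairs, ...) {
  pairs <- as_pair_list(pairs)
  acc <- NULL
  wtot <- 0
  for (p in pairs) {
    ns <- sum(p$response >= 1L)
    if (ns == 0) next
    k <- alignment_kernel(model, p, ...)
    if (is.null(acc)) acc <- 0 * k$probs
    acc <- acc + ns * k$probs
    wtot <- wtot + ns
    lags <- k$lags
    bw <- k$bin_width
  }
  if (wtot == 0) stop("kernel undefined: no spikes in any pair")
  structure(list(lags = lags, probs = acc / wtot, bin_width = bw),
            class = "mph_kernel")
}

#' Brute-force enumeration of hidden paths (test oracle)
#'
#' Exhaustively enumerates every hidden path consuming the full pair within
#' the band and returns exact path probabilities.  Exponential cost; only
#' for small instances.
#'
#' @inheritParams mph_forward
#' @param max_paths guard on the number of enumerated paths.
#' @return List with \code{states} (list of state-index vectors), \code{i},
#'   \code{j} (lists of the cell trajectories, excluding the origin),
#'   \code{probs}, and \code{total} = P(X, R).
#' @export
enumerate_paths <- function(model, pair, band_width = model$band_width,
                            max_paths = 50000L) {
  W <- as.integer(band_width)
  p <- prep_dp(model, pair)
  kinds <- state_kinds(model)
  N <- length(model$states)
  lb <- lag_bounds_of(model, W)
  A <- model$transitions
  rho <- model$initial
  tau <- model$final
  emit <- function(s, i, j) {
    if (kinds[s] == "X") exp(p$EX[i, s])
    else if (kinds[s] == "R") exp(p$ER[j, s])
    else exp(p$EM[i, p$r[j] + 1L, s])
  }
  env <- new.env()
  env$states <- list()
  env$ii <- list()
  env$jj <- list()
  env$probs <- numeric(0)
  env$n <- 0L
  recurse <- function(i, j, s, prob, seq_s, seq_i, seq_j) {
    if (i == p$Tx && j == p$Tr) {
      pr <- prob * tau[s]
      if (pr > 0 || TRUE) {
        env$n <- env$n + 1L
        if (env$n > max_paths) stop("path cap exceeded")
        env$states[[env$n]] <- seq_s
        env$ii[[env$n]] <- seq_i
        env$jj[[env$n]] <- seq_j
        env$probs[env$n] <- pr
      }
    }
    for (t in seq_len(N)) {
      ni <- if (kinds[t] == "R") i else i + 1L
      nj <- if (kinds[t] == "X") j else j + 1L
      if (ni > p$Tx || nj > p$Tr || abs(ni - nj) > W) next
      if (nj - ni < lb$lo[t] || nj - ni > lb$hi[t]) next
      step <- A[s, t] * emit(t, ni, nj)
      if (step == 0) next
      recurse(ni, nj, t, prob * step,
              c(seq_s, t), c(seq_i, ni), c(seq_j, nj))
    }
  }
  for (s in seq_len(N)) {
    ni <- if (kinds[s] == "R") 0L else 1L
    nj <- if (kinds[s] == "X") 0L else 1L
    if (ni > p$Tx || nj > p$Tr || abs(ni - nj) > W) next
    if (nj - ni < lb$lo[s] || nj - ni > lb$hi[s]) next
    start <- rho[s] * emit(s, max(ni, 1L), max(nj, 1L))
    if (start == 0) next
    recurse(ni, nj, s, start, s, ni, nj)
  }
  list(states = env$states, i = env$ii, j = env$jj, probs = env$probs,
       total = sum(env$probs))
}
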