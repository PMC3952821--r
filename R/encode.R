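# Response prediction: inference-equivalent model rewriting, per-bin spike
# probabilities, extended (encoding) Viterbi, cascaded output nonlinearity,
# and the closed-form LNP bridge.

#' Rewrite an MPH for response-probability inference
#'
#' Replaces each M-state by two X-states and two deterministic R-states
#' (no-spike and spike branches chained with probability one), and each
#' stochastic R-state by a never-spike / always-spike pair, moving response
#' probabilities onto the transitions.  The rewritten model assigns every
#' stimulus-response pair the same probability as the original, but all
#' response emissions are deterministic, which makes per-bin spike
#' probabilities readable off state posteriors.  Zero-probability branches
#' are pruned.  Binary response alphabet only.
#'
#' @param model an \code{\link{mph_model}} with V = 2.
#' @return An \code{\link{mph_model}} without M-states, whose band width is
#'   the original plus one (an M diagonal step becomes X then R, which
#'   visits one off-diagonal cell in between).
#' @export
rewrite_for_inference <- function(model) {
  if (model$V != 2L)
    stop("rewriting is defined for binary responses (V = 2)")
  kinds <- state_kinds(model)
  stochastic_r <- vapply(model$states, function(st)
    st$kind == "R" && !(st$emission$probs[1] %in% c(0, 1)), TRUE)
  if (!any(kinds == "M") && !any(stochastic_r))
    return(model)  # nothing to rewrite
  N <- length(model$states)

  # per original state: entry states (with split weights), exit states,
  # and the new states themselves (plus internal deterministic edges)
  new_states <- list()
  internal <- list()  # list of c(from, to) index pairs with probability 1
  m_halves <- integer(0)  # stimulus-halves of split M-states
  entries <- vector("list", N)
  exits <- vector("list", N)
  add_state <- function(st) {
    new_states[[length(new_states) + 1L]] <<- st
    length(new_states)
  }
  r_never <- function(lab) mph_state("R", discrete_emission(c(1, 0), "fixed"), lab)
  r_always <- function(lab) mph_state("R", discrete_emission(c(0, 1), "fixed"), lab)

  for (s in seq_len(N)) {
    st <- model$states[[s]]
    if (kinds[s] == "X") {
      id <- add_state(st)
      entries[[s]] <- list(idx = id, w = 1)
      exits[[s]] <- id
    } else if (kinds[s] == "R") {
      pr <- st$emission$probs
      if (pr[1] %in% c(0, 1)) {  # already deterministic
        id <- add_state(st)
        entries[[s]] <- list(idx = id, w = 1)
        exits[[s]] <- id
      } else {
        i0 <- add_state(r_never(paste0(st$label, ".r0")))
        i1 <- add_state(r_always(paste0(st$label, ".r1")))
        entries[[s]] <- list(idx = c(i0, i1), w = c(pr[1], pr[2]))
        exits[[s]] <- c(i0, i1)
      }
    } else {  # M-state
      pr <- st$emission$marginal$probs
      x0 <- add_state(mph_state("X", st$emission$conditional[[1]],
                                paste0(st$label, ".x0")))
      x1 <- add_state(mph_state("X", st$emission$conditional[[2]],
                                paste0(st$label, ".x1")))
      m_halves <- c(m_halves, x0, x1)
      i0 <- add_state(r_never(paste0(st$label, ".r0")))
      i1 <- add_state(r_always(paste0(st$label, ".r1")))
      internal[[length(internal) + 1L]] <- c(x0, i0)
      internal[[length(internal) + 1L]] <- c(x1, i1)
      entries[[s]] <- list(idx = c(x0, x1), w = c(pr[1], pr[2]))
      exits[[s]] <- c(i0, i1)
    }
  }

  M <- length(new_states)
  A <- matrix(0, M, M)
  rho <- numeric(M)
  tau <- numeric(M)
  for (e in internal) A[e[1], e[2]] <- 1
  for (s in seq_len(N)) {
    rho[entries[[s]]$idx] <- rho[entries[[s]]$idx] +
      model$initial[s] * entries[[s]]$w
    for (ex in exits[[s]]) {
      tau[ex] <- model$final[s]
      for (t in seq_len(N))
        A[ex, entries[[t]]$idx] <- A[ex, entries[[t]]$idx] +
          model$transitions[s, t] * entries[[t]]$w
    }
  }

  # prune zero-probability branches (iterate: dropping a state can cut the
  # only inflow of its successor)
  keep <- rep(TRUE, M)
  repeat {
    inflow <- colSums(A[keep, , drop = FALSE]) + rho
    newkeep <- inflow > 0
    if (identical(newkeep, keep)) break
    keep <- newkeep
  }
  keep <- which(keep)
  A <- A[keep, keep, drop = FALSE]
  rho <- rho[keep]
  tau <- tau[keep]
  new_states <- new_states[keep]
  out <- mph_model(states = new_states, transitions = A,
                   initial = rho / sum(rho), final = tau,
                   band_width = model$band_width + 1L,
                   embedding = model$embedding, V = 2L)
  # per-state lag bounds: every state stays within the original band, but
  # the stimulus-half of a split M-state may transiently sit one lag below
  # it (x consumed, r not yet) -- exactly the cells an original M diagonal
  # step passes through, and no others
  W <- model$band_width
  lb <- cbind(rep(-W, length(keep)), rep(W, length(keep)))
  lb[match(intersect(m_halves, keep), keep), 1] <- -(W + 1L)
  out$lag_bounds <- lb
  out
}

#' Per-bin spike probabilities given a stimulus
#'
#' Runs forward-backward on the inference rewriting of the model with the
#' response treated as unobserved, and reads P(spike at bin j | stimulus)
#' off the posterior mass of spike-branch R-states at response position j,
#' normalized by the mass of all response-consuming states at j.
#'
#' @param model an \code{\link{mph_model}} (V = 2).
#' @param stimulus d x Tx matrix of embedded stimulus vectors.
#' @param Tr response length (defaults to the stimulus length).
#' @param bin_width bin width in seconds (metadata on the result).
#' @return Object of class \code{"mph_rate"}: list with \code{probs}
#'   (Tr x 2 matrix of per-bin response distributions), \code{spike_prob}
#'   (= \code{probs[, 2]}), and \code{bin_width}.
#' @export
response_probabilities <- function(model, stimulus, Tr = ncol(stimulus),
                                   bin_width = 1) {
  rw <- if (any(state_kinds(model) == "M")) rewrite_for_inference(model)
        else model
  kinds <- state_kinds(rw)
  det <- vapply(rw$states, function(st)
    st$kind != "R" || st$emission$probs[1] %in% c(0, 1), TRUE)
  if (!all(det))
    stop("model has stochastic R-states; apply rewrite_for_inference first")
  pair <- mph_pair(stimulus, integer(Tr), bin_width = bin_width, V = rw$V)
  W <- rw$band_width
  p <- prep_dp(rw, pair, response_free = TRUE)
  check_band(p$Tx, p$Tr, W)
  lb <- lag_bounds_of(rw, W)
  fw <- dp_forward_cpp(p$kinds, p$logA, p$logrho, p$logtau,
                       p$Tx, p$Tr, W, p$EX, p$ER, p$EM, p$r, lb$lo, lb$hi)
  if (!is.finite(fw$loglik)) stop("stimulus impossible under model")
  bw <- dp_backward_cpp(p$kinds, p$logA, p$logrho, p$logtau,
                        p$Tx, p$Tr, W, p$EX, p$ER, p$EM, p$r, lb$lo, lb$hi)
  g <- exp(fw$alpha + bw$beta - fw$loglik)
  g[!is.finite(g)] <- 0
  spiking <- kinds == "R" &
    vapply(rw$states, function(st)
      st$kind == "R" && st$emission$probs[2] == 1, TRUE)
  rstates <- which(kinds == "R")
  num <- numeric(Tr)
  den <- numeric(Tr)
  for (s in rstates) {
    uj <- occupancy_by_j(g[, , s], p$Tx, p$Tr, W)
    den <- den + uj
    if (spiking[s]) num <- num + uj
  }
  p1 <- ifelse(den > 0, num / den, 0)
  structure(list(probs = cbind(`0` = 1 - p1, `1` = p1), spike_prob = p1,
                 bin_width = bin_width),
            class = "mph_rate")
}

#' Most likely joint (response, hidden path) for a stimulus
#'
#' Extended Viterbi recursion: at every response-consuming step the response
#' symbol maximizing the emission probability is chosen, jointly maximizing
#' P(path, response | stimulus) for a known response length.
#'
#' @param model an \code{\link{mph_model}}.
#' @param stimulus d x Tx matrix of embedded stimulus vectors.
#' @param Tr response length (defaults to the stimulus length).
#' @return List with \code{response} (integer vector of length Tr),
#'   \code{path} (data frame as in \code{\link{mph_viterbi}}), and
#'   \code{logp}.
#' @export
encode_map <- function(model, stimulus, Tr = ncol(stimulus)) {
  stimulus <- as.matrix(stimulus)
  Tx <- ncol(stimulus)
  W <- model$band_width
  check_band(Tx, Tr, W)
  N <- length(model$states)
  V <- model$V
  kinds <- state_kinds(model)
  # best response symbol and emission per state/position
  bestE <- array(-Inf, dim = c(max(Tx, 1L), N))  # X and M states (by i)
  bestV <- array(NA_integer_, dim = c(max(Tx, 1L), N))
  bestER <- numeric(N)                           # R states (const over j)
  bestVR <- integer(N)
  for (s in seq_len(N)) {
    st <- model$states[[s]]
    if (kinds[s] == "X") {
      bestE[, s] <- gm_logdens(st$emission, stimulus)
    } else if (kinds[s] == "R") {
      v <- which.max(st$emission$probs)
      bestER[s] <- log(st$emission$probs[v])
      bestVR[s] <- v - 1L
    } else {
      lp <- log(st$emission$marginal$probs)
      evs <- vapply(seq_len(V), function(v)
        lp[v] + gm_logdens(st$emission$conditional[[v]], stimulus),
        numeric(Tx))
      evs <- matrix(evs, nrow = Tx)
      bestV[, s] <- max.col(evs, ties.method = "first") - 1L
      bestE[, s] <- evs[cbind(seq_len(Tx), bestV[, s] + 1L)]
    }
  }
  NEG <- -Inf
  delta <- array(NEG, dim = c(Tx + 1L, 2L * W + 1L, N))
  ptr <- array(-2L, dim = dim(delta))
  col_of <- function(i, j) j - i + W + 1L
  for (i in 0:Tx) {
    for (j in max(0L, i - W):min(Tr, i + W)) {
      if (i == 0L && j == 0L) next
      for (s in seq_len(N)) {
        pi_ <- if (kinds[s] == "R") i else i - 1L
        pj_ <- if (kinds[s] == "X") j else j - 1L
        if (pi_ < 0L || pj_ < 0L || abs(pi_ - pj_) > W) next
        e <- if (kinds[s] == "R") bestER[s] else bestE[i, s]
        if (pi_ == 0L && pj_ == 0L) {
          val <- log(model$initial[s])
          arg <- -1L
        } else {
          cand <- delta[pi_ + 1L, col_of(pi_, pj_), ] +
            log(model$transitions[, s])
          arg <- which.max(cand)
          val <- cand[arg]
          if (!is.finite(val)) next
        }
        if (!is.finite(val)) next
        delta[i + 1L, col_of(i, j), s] <- e + val
        ptr[i + 1L, col_of(i, j), s] <- arg
      }
    }
  }
  fin <- delta[Tx + 1L, col_of(Tx, Tr), ] + log(model$final)
  pref <- order(match(kinds, c("M", "X", "R")))
  s <- pref[which.max(fin[pref])]
  logp <- fin[s]
  if (!is.finite(logp))
    stop("no feasible (path, response) within the band")
  i <- Tx
  j <- Tr
  states <- integer(0)
  ii <- integer(0)
  jj <- integer(0)
  response <- integer(Tr)
  repeat {
    states <- c(s, states)
    ii <- c(i, ii)
    jj <- c(j, jj)
    if (kinds[s] == "R") response[j] <- bestVR[s]
    if (kinds[s] == "M") response[j] <- bestV[i, s]
    prev <- ptr[i + 1L, col_of(i, j), s]
    ni <- if (kinds[s] == "R") i else i - 1L
    nj <- if (kinds[s] == "X") j else j - 1L
    if (prev == -1L) break
    s <- prev
    i <- ni
    j <- nj
  }
  path <- data.frame(step = seq_along(states), state = states,
                     kind = kinds[states],
                     label = vapply(model$states[states], `[[`, "", "label"),
                     i = ii, j = jj)
  list(response = response, path = path, logp = logp)
}

#' Estimate the cascade output nonlinearity
#'
#' Histogram-division estimate of the mapping g from posterior spike
#' probability to observed spike probability: per probability bin, the
#' number of bins with an actual spike divided by the number of bins whose
#' posterior falls in that bin.  Empty bins are filled by linear
#' interpolation from their neighbors.
#'
#' @param model a fitted \code{\link{mph_model}}.
#' @param pairs training pairs (must contain spikes).
#' @param n_bins number of equal-width probability bins on [0, 1].
#' @return Object of class \code{"mph_cascade"}: list with \code{edges},
#'   \code{centers}, \code{g}, and the underlying \code{num} / \code{den}
#'   histogram counts.
#' @export
fit_cascade <- function(model, pairs, n_bins = 25L) {
  pairs <- as_pair_list(pairs)
  if (!any(unlist(lapply(pairs, function(p) p$response >= 1L))))
    stop("no spikes in pairs; cascade undefined")
  edges <- seq(0, 1, length.out = n_bins + 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  num <- numeric(n_bins)
  den <- numeric(n_bins)
  for (p in pairs) {
    pr <- response_probabilities(model, p$stimulus, length(p$response),
                                 p$bin_width)$spike_prob
    b <- pmin(pmax(findInterval(pr, edges, rightmost.closed = TRUE), 1L),
              n_bins)
    den <- den + tabulate(b, n_bins)
    num <- num + tabulate(b[p$response >= 1L], n_bins)
  }
  g <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  if (anyNA(g)) {
    ok <- which(!is.na(g))
    g <- stats::approx(centers[ok], g[ok], xout = centers, rule = 2)$y
  }
  structure(list(edges = edges, centers = centers, g = pmin(pmax(g, 0), 1),
                 num = num, den = den),
            class = "mph_cascade")
}

#' Apply a cascade mapping to spike probabilities
#'
#' Pointwise lookup with linear interpolation between bin centers; output
#' clipped to [0, 1].
#'
#' @param mapping an \code{\link{fit_cascade}} result.
#' @param p numeric vector of spike probabilities, or an \code{"mph_rate"}.
#' @return Remapped object of the same shape as \code{p}.
#' @export
apply_cascade <- function(mapping, p) {
  if (inherits(p, "mph_rate")) {
    p$spike_prob <- apply_cascade(mapping, p$spike_prob)
    p$probs <- cbind(`0` = 1 - p$spike_prob, `1` = p$spike_prob)
    return(p)
  }
  out <- stats::approx(mapping$centers, mapping$g, xout = p, rule = 2)$y
  pmin(pmax(out, 0), 1)
}

#' Closed-form LNP equivalent of a single-M-state MPH
#'
#' For an MPH with one M-state, single-Gaussian stimulus models and a shared
#' covariance, the posterior spike probability is the sigmoid of an affine
#' function of the stimulus: P(spike | x) = sigmoid(w x + c) with filter
#' w = Sigma^{-1} (mu1 - mu0) (reverse correlation / covariance-corrected
#' STA; the STA itself for white stimuli) and constant
#' c = log(P1 / P0) + (mu0' Sigma^{-1} mu0 - mu1' Sigma^{-1} mu1) / 2.
#'
#' @param model an \code{\link{mph_model}} whose first M-state has K = 1
#'   Gaussians with equal covariances.
#' @return Object of class \code{"lnp_bridge"}: list with \code{w} and
#'   \code{c}.
#' @export
mph_as_lnp <- function(model) {
  s <- which(state_kinds(model) == "M")[1]
  if (is.na(s)) stop("model has no M-state")
  em <- model$states[[s]]$emission
  g0 <- em$conditional[[1]]
  g1 <- em$conditional[[2]]
  if (length(g0$weights) != 1L || length(g1$weights) != 1L)
    stop("LNP bridge requires single-Gaussian stimulus models")
  S <- g0$covs[, , 1]
  if (max(abs(S - g1$covs[, , 1])) > 1e-10)
    stop("LNP bridge requires equal covariances")
  mu0 <- g0$means[, 1]
  mu1 <- g1$means[, 1]
  P <- em$marginal$probs
  w <- drop(solve(S, mu1 - mu0))
  cc <- log(P[2] / P[1]) +
    0.5 * (drop(mu0 %*% solve(S, mu0)) - drop(mu1 %*% solve(S, mu1)))
  structure(list(w = w, c = cc), class = "lnp_bridge")
}

#' @rdname mph_as_lnp
#' @param object an \code{"lnp_bridge"}.
#' @param newdata d x T matrix of embedded stimulus vectors.
#' @param ... unused.
#' @return \code{predict} returns the length-T vector sigmoid(w x + c).
#' @export
predict.lnp_bridge <- function(object, newdata, ...) {
  drop(plogis(crossprod(newdata, object$w) + object$c))
}
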