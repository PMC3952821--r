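# MPH parameter objects, validation, canonical templates, covariance
# regularizer.

#' Stimulus embedding specification
#'
#' Maps a channels x T stimulus matrix to the sequence of embedded vectors
#' x_t used by the model: x_t is the concatenation of all channels over the
#' window \code{[t - window_length + 1 + offset, t + offset]}, zero-padded at
#' the sequence edges.  The embedded dimension is
#' \code{d = channels * window_length}.
#'
#' @param window_length window length in bins (>= 1).
#' @param channels number of stimulus channels.
#' @param offset signed window offset in bins relative to the current bin;
#'   0 gives a causal window ending at t.
#' @return An object of class \code{"mph_embedding"}.
#' @export
stimulus_embedding <- function(window_length, channels = 1L, offset = 0L) {
  stopifnot(window_length >= 1, channels >= 1)
  structure(list(window_length = as.integer(window_length),
                 channels = as.integer(channels),
                 offset = as.integer(offset),
                 d = as.integer(window_length * channels)),
            class = "mph_embedding")
}

#' Embed a stimulus matrix
#'
#' @param stim channels x T numeric matrix.
#' @param embedding a \code{\link{stimulus_embedding}}.
#' @return d x T matrix of embedded stimulus vectors.
#' @export
embed_stimulus <- function(stim, embedding) {
  stim <- as.matrix(stim)
  if (nrow(stim) != embedding$channels)
    stop("stimulus has ", nrow(stim), " channels; embedding expects ",
         embedding$channels)
  Tn <- ncol(stim)
  wl <- embedding$window_length
  off <- embedding$offset
  out <- matrix(0, embedding$d, Tn)
  for (u in seq_len(wl)) {
    # source column for window slot u at target t: t - wl + u + off
    src <- seq_len(Tn) - wl + u + off
    ok <- src >= 1 & src <= Tn
    rows <- (u - 1L) * embedding$channels + seq_len(embedding$channels)
    out[rows, ok] <- stim[, src[ok], drop = FALSE]
  }
  out
}

#' Hidden-state specification
#'
#' @param kind one of \code{"X"} (stimulus-only), \code{"R"} (response-only),
#'   \code{"M"} (matching: joint stimulus-response).
#' @param emission a \code{\link{gm_emission}} (X), a
#'   \code{\link{discrete_emission}} (R), or a \code{\link{mixed_emission}}
#'   (M).
#' @param label free-text state label.
#' @return An object of class \code{"mph_state"}.
#' @export
mph_state <- function(kind, emission, label = kind) {
  kind <- match.arg(kind, c("X", "R", "M"))
  ok <- switch(kind,
               X = inherits(emission, "mph_gm"),
               R = inherits(emission, "mph_discrete"),
               M = inherits(emission, "mph_mixed"))
  if (!ok) stop("emission type does not match state kind ", kind)
  structure(list(kind = kind, emission = emission, label = label),
            class = "mph_state")
}

#' Construct a mixed pair hidden Markov model
#'
#' An MPH jointly generates a continuous stimulus sequence and a discrete
#' response sequence.  Hidden paths advance through the alignment tensor: an
#' M-state consumes one symbol of each sequence (diagonal step), an X-state
#' only a stimulus symbol (horizontal), an R-state only a response symbol
#' (vertical).  Per state, the transition row plus the final probability sum
#' to one, so the model is a proper distribution over finite paths.
#'
#' @param states list of \code{\link{mph_state}} objects.
#' @param transitions N x N transition matrix A, entry \code{A[s, t]} the
#'   probability of moving from state s to state t.
#' @param initial length-N initial state probabilities.
#' @param final length-N final (termination) probabilities.
#' @param band_width nonnegative integer W: maximum allowed |i - j| lag
#'   between consumed stimulus and response positions.
#' @param embedding the \code{\link{stimulus_embedding}} the model assumes.
#' @param V response alphabet size (default 2: spike / no spike).
#' @return An object of class \code{"mph_model"}.
#' @export
mph_model <- function(states, transitions, initial, final, band_width,
                      embedding, V = 2L) {
  m <- structure(list(states = states,
                      transitions = as.matrix(transitions),
                      initial = as.numeric(initial),
                      final = as.numeric(final),
                      band_width = as.integer(band_width),
                      embedding = embedding,
                      V = as.integer(V)),
                 class = "mph_model")
  bad <- mph_validate(m)
  if (length(bad))
    stop("invalid MPH model:\n  ", paste(bad, collapse = "\n  "))
  m
}

#' State kinds of an MPH model
#'
#' @param model an \code{\link{mph_model}}.
#' @return Character vector of state kinds ("X", "R", "M") in state order.
#' @export
state_kinds <- function(model) vapply(model$states, `[[`, "", "kind")

#' Validate an MPH model
#'
#' Checks all structural invariants (probability normalizations, symmetric
#' positive-definite covariances, matching dimensions, consumability of both
#' sequences) and reports violations without raising an error.
#'
#' @param model an object shaped like an \code{\link{mph_model}}.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
mph_validate <- function(model) {
  bad <- character(0)
  N <- length(model$states)
  A <- model$transitions
  if (!all(dim(A) == c(N, N)))
    bad <- c(bad, "transition matrix dimension does not match state count")
  if (length(model$initial) != N || length(model$final) != N)
    bad <- c(bad, "initial/final probability length does not match states")
  if (any(A < 0) || any(A > 1))
    bad <- c(bad, "transition probabilities outside [0, 1]")
  if (any(model$final < 0) || any(model$final > 1))
    bad <- c(bad, "final probabilities outside [0, 1]")
  if (any(model$initial < 0) || abs(sum(model$initial) - 1) > 1e-12)
    bad <- c(bad, "initial probabilities do not form a distribution")
  if (all(dim(A) == c(N, N))) {
    rs <- rowSums(A) + model$final
    off <- which(abs(rs - 1) > 1e-12)
    for (s in off)
      bad <- c(bad, sprintf(
        "transition row %d plus final probability sums to %.6g, not 1", s, rs[s]))
  }
  if (model$band_width < 0) bad <- c(bad, "band width negative")
  kinds <- state_kinds(model)
  if (!any(kinds == "M") && !(any(kinds == "X") && any(kinds == "R")))
    bad <- c(bad, paste("response sequence cannot be consumed: need an",
                        "M-state or both an X-state and an R-state"))
  d <- model$embedding$d
  for (s in seq_len(N)) {
    st <- model$states[[s]]
    where <- sprintf("state %d (%s)", s, st$label)
    if (st$kind == "X") {
      bad <- c(bad, validate_gm(st$emission, where, d))
    } else if (st$kind == "R") {
      bad <- c(bad, validate_discrete(st$emission, where))
      if (length(st$emission$probs) != model$V)
        bad <- c(bad, paste0(where, ": response alphabet size mismatch"))
    } else {
      bad <- c(bad, validate_discrete(st$emission$marginal, where))
      if (length(st$emission$marginal$probs) != model$V)
        bad <- c(bad, paste0(where, ": response alphabet size mismatch"))
      for (v in seq_along(st$emission$conditional))
        bad <- c(bad, validate_gm(st$emission$conditional[[v]],
                                  paste0(where, " | r=", v - 1L), d))
    }
  }
  bad
}

#' Shrinkage regularization of a covariance matrix
#'
#' Returns \code{(1 - lam) * C + lam * (tr(C)/d) * I}: shrinkage toward the
#' identity scaled by the normalized trace.  The trace is preserved for every
#' \code{lam}, and for positive semi-definite C the smallest eigenvalue of
#' the result is at least \code{lam * tr(C)/d}.
#'
#' @param C symmetric d x d matrix.
#' @param lam mixing weight in [0, 1].
#' @return Regularized d x d matrix.
#' @export
regularize_covariance <- function(C, lam) {
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("C must be symmetric")
  stopifnot(lam >= 0, lam <= 1)
  d <- nrow(C)
  (1 - lam) * C + lam * (sum(diag(C)) / d) * diag(d)
}

#' Three-state MXR template for jittered responses
#'
#' One M-state (matches spikes to stimuli), one X-state and one R-state
#' (absorb lag changes).  Covariances are fixed to the identity or to a
#' supplied shared matrix; the X-state mean and the M-state's no-spike mean
#' are fixed to the stimulus ensemble mean; the R-state never emits a spike.
#' Free parameters: the M-state spike-conditioned mean (the receptive field),
#' the response marginal, and the transition/initial/final probabilities.
#'
#' @param embedding a \code{\link{stimulus_embedding}}.
#' @param data_mean length-d stimulus ensemble mean (default zero).
#' @param data_cov shared d x d covariance for \code{cov_mode =
#'   "fixed_shared"} (must be symmetric positive definite).
#' @param cov_mode \code{"identity"} or \code{"fixed_shared"}.
#' @param band_width band width W in bins.
#' @param spike_prob initial M-state spike marginal.
#' @return An \code{\link{mph_model}}.
#' @export
mph_mxr <- function(embedding, data_mean = NULL, data_cov = NULL,
                    cov_mode = c("identity", "fixed_shared"),
                    band_width = 8L, spike_prob = 0.1) {
  cov_mode <- match.arg(cov_mode)
  d <- embedding$d
  if (is.null(data_mean)) data_mean <- rep(0, d)
  if (cov_mode == "fixed_shared") {
    if (is.null(data_cov)) stop("data_cov required for fixed_shared mode")
    ev <- eigen((data_cov + t(data_cov)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 0) stop("data_cov is not positive definite")
    C <- data_cov
  } else {
    C <- diag(d)
  }
  gm_fixed <- gm_emission(matrix(data_mean, d, 1), C, 1,
                          cov_mode = cov_mode, mean_mode = "fixed_value")
  gm_free <- gm_emission(matrix(data_mean, d, 1), C, 1,
                         cov_mode = cov_mode, mean_mode = "free")
  mst <- mph_state("M", mixed_emission(
    discrete_emission(c(1 - spike_prob, spike_prob), mode = "free"),
    list(gm_fixed, gm_free)), label = "M")
  xst <- mph_state("X", gm_fixed, label = "X")
  rst <- mph_state("R", discrete_emission(c(1, 0), mode = "fixed"),
                   label = "R")
  A <- rbind(c(0.10, 0.05, 0.83),   # from X
             c(0.05, 0.10, 0.83),   # from R
             c(0.05, 0.05, 0.88))   # from M
  tau <- 1 - rowSums(A)
  mph_model(states = list(xst, rst, mst), transitions = A,
            initial = c(0.05, 0.05, 0.9), final = tau,
            band_width = band_width, embedding = embedding)
}

#' M^n template for switching receptive fields
#'
#' n M-states and no X/R states: hidden paths run along the diagonal of the
#' alignment matrix, so the model is a Markov-switching response model.
#' Covariances are fixed to the identity, no-spike means are fixed to zero;
#' free parameters are the spike-conditioned means (the receptive fields),
#' the response marginals, and the transition probabilities.
#'
#' @param n number of M-states (>= 1); n = 1 gives the basic M-MPH, which is
#'   equivalent to a sigmoid LNP model.
#' @param embedding a \code{\link{stimulus_embedding}}.
#' @param spike_prob initial spike marginal (recycled to n).
#' @param band_width band width (0 suffices; kept as a parameter so mixed
#'   architectures can extend the template).
#' @return An \code{\link{mph_model}}.
#' @export
mph_mn <- function(n, embedding, spike_prob = 0.1, band_width = 0L) {
  if (n < 1) stop("n must be >= 1")
  d <- embedding$d
  spike_prob <- rep_len(spike_prob, n)
  states <- lapply(seq_len(n), function(s) {
    gm0 <- gm_emission(matrix(0, d, 1), diag(d), 1,
                       cov_mode = "identity", mean_mode = "fixed_zero")
    gm1 <- gm_emission(matrix(0, d, 1), diag(d), 1,
                       cov_mode = "identity", mean_mode = "free")
    mph_state("M", mixed_emission(
      discrete_emission(c(1 - spike_prob[s], spike_prob[s]), mode = "free"),
      list(gm0, gm1)), label = paste0("M", s))
  })
  tau <- rep(0.01, n)
  A <- matrix((1 - tau) / n, n, n)
  mph_model(states = states, transitions = A,
            initial = rep(1 / n, n), final = tau,
            band_width = band_width, embedding = embedding)
}
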