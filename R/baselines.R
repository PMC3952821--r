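# Reference estimators and evaluation metrics: STA, reverse correlation,
# STC, moment-based sigmoid LNP predictors, rate correlation, similarity.

#' Spike-triggered average and reverse correlation
#'
#' \code{sta_fit} returns the mean of the spike-triggered embedded stimuli
#' minus the ensemble mean.  \code{rc_fit} premultiplies by the (optionally
#' regularized) inverse stimulus covariance — reverse correlation /
#' covariance-corrected STA; for white stimuli with identity covariance the
#' two coincide.
#'
#' @param pairs an \code{\link{mph_pair}} or list thereof (embedded
#'   stimuli).
#' @param center subtract the ensemble mean (default TRUE).
#' @param lam covariance regularization weight passed to
#'   \code{\link{regularize_covariance}}.
#' @return Length-d filter vector.
#' @export
sta_fit <- function(pairs, center = TRUE) {
  pairs <- as_pair_list(pairs)
  st <- spike_triggered_mean(pairs)
  if (center) st <- st - pooled_mean(pairs)
  st
}

#' @rdname sta_fit
#' @export
rc_fit <- function(pairs, lam = 0) {
  pairs <- as_pair_list(pairs)
  C <- regularize_covariance(pooled_cov(pairs), lam)
  drop(solve(C, sta_fit(pairs, center = TRUE)))
}

pooled_mean <- function(pairs) {
  num <- 0
  den <- 0
  for (p in pairs) {
    num <- num + rowSums(p$stimulus)
    den <- den + ncol(p$stimulus)
  }
  num / den
}

pooled_cov <- function(pairs) {
  mu <- pooled_mean(pairs)
  num <- 0
  den <- 0
  for (p in pairs) {
    Xc <- p$stimulus - mu
    num <- num + tcrossprod(Xc)
    den <- den + ncol(p$stimulus)
  }
  num / den
}

#' Spike-triggered covariance filters
#'
#' Eigenvectors of the difference between the spike-triggered stimulus
#' covariance and the raw stimulus covariance (both about the ensemble
#' mean), ranked by absolute eigenvalue.  Returned filters are orthonormal.
#'
#' @param pairs pairs with embedded stimuli.
#' @param n_filters number of filters to return.
#' @return d x n_filters matrix; attribute \code{"values"} holds the ranked
#'   eigenvalues.
#' @export
stc_fit <- function(pairs, n_filters = 2L) {
  pairs <- as_pair_list(pairs)
  mu <- pooled_mean(pairs)
  num <- 0
  nspk <- 0
  for (p in pairs) {
    idx <- which(p$response >= 1L)
    if (!length(idx)) next
    Xc <- p$stimulus[, idx, drop = FALSE] - mu
    num <- num + tcrossprod(Xc)
    nspk <- nspk + length(idx)
  }
  if (nspk == 0) stop("no spikes in pairs")
  d <- length(mu)
  if (nspk < d)
    warning("fewer spikes (", nspk, ") than stimulus dimensions (", d, ")")
  delta <- num / nspk - pooled_cov(pairs)
  e <- eigen((delta + t(delta)) / 2, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(n_filters)]
  structure(e$vectors[, ord, drop = FALSE], values = e$values[ord])
}

#' Moment-based sigmoid LNP predictor (STA / RC baseline)
#'
#' Builds the closed-form sigmoid spike-probability model from class
#' moments of the training pairs: with spike rate P1, spike-triggered mean
#' mu1, non-spike mean mu0, and covariance Sigma (identity for white
#' stimuli, or the pooled stimulus covariance), predicts
#' sigmoid(w x + c) with w = Sigma^{-1}(mu1 - mu0).  This is the
#' single-M-state MPH at its likelihood optimum, i.e. the STA (white) or
#' reverse-correlation (non-white) predictor with its matched nonlinearity.
#'
#' @param pairs training pairs.
#' @param cov_mode \code{"identity"} or \code{"shared"} (pooled empirical
#'   covariance).
#' @param lam covariance regularization weight (shared mode).
#' @return An \code{"lnp_bridge"} (see \code{\link{mph_as_lnp}}).
#' @export
lnp_from_moments <- function(pairs, cov_mode = c("identity", "shared"),
                             lam = 0) {
  cov_mode <- match.arg(cov_mode)
  pairs <- as_pair_list(pairs)
  mu1 <- spike_triggered_mean(pairs)
  n1 <- sum(unlist(lapply(pairs, function(p) sum(p$response >= 1L))))
  ntot <- sum(unlist(lapply(pairs, function(p) length(p$response))))
  P1 <- n1 / ntot
  # non-spike mean from ensemble and spike moments
  mu <- pooled_mean(pairs)
  mu0 <- (mu * ntot - mu1 * n1) / (ntot - n1)
  S <- if (cov_mode == "identity") diag(length(mu))
       else regularize_covariance(pooled_cov(pairs), lam)
  w <- drop(solve(S, mu1 - mu0))
  cc <- log(P1 / (1 - P1)) +
    0.5 * (drop(mu0 %*% solve(S, mu0)) - drop(mu1 %*% solve(S, mu1)))
  structure(list(w = w, c = cc), class = "lnp_bridge")
}

#' Quadratic (two-filter Gaussian) predictor on STC projections
#'
#' Projects stimuli onto the STC filters and applies Bayes' rule with
#' Gaussian class-conditional models of the projections (spike-triggered
#' versus non-spike), giving a spike probability that is quadratic in the
#' projections.  Used as the STC response-prediction baseline.
#'
#' @param pairs training pairs.
#' @param filters d x m filter matrix from \code{\link{stc_fit}}.
#' @return Function mapping a d x T stimulus matrix to spike probabilities.
#' @export
stc_predict <- function(pairs, filters) {
  pairs <- as_pair_list(pairs)
  Z1 <- NULL
  Z0 <- NULL
  for (p in pairs) {
    z <- crossprod(filters, p$stimulus)
    spk <- p$response >= 1L
    Z1 <- cbind(Z1, z[, spk, drop = FALSE])
    Z0 <- cbind(Z0, z[, !spk, drop = FALSE])
  }
  P1 <- ncol(Z1) / (ncol(Z1) + ncol(Z0))
  m1 <- rowMeans(Z1)
  m0 <- rowMeans(Z0)
  S1 <- tcrossprod(Z1 - m1) / ncol(Z1)
  S0 <- tcrossprod(Z0 - m0) / ncol(Z0)
  function(stimulus) {
    z <- crossprod(filters, stimulus)
    l1 <- mvn_logdens(as.matrix(z), m1, S1) + log(P1)
    l0 <- mvn_logdens(as.matrix(z), m0, S0) + log(1 - P1)
    1 / (1 + exp(l0 - l1))
  }
}

#' Gaussian smoothing of a rate or spike series
#'
#' @param x numeric vector.
#' @param width Gaussian kernel standard deviation in bins; 0 disables
#'   smoothing.
#' @return Smoothed vector of the same length (edge-renormalized).
#' @export
gaussian_smooth <- function(x, width = 2) {
  if (width <= 0) return(x)
  half <- ceiling(4 * width)
  kern <- dnorm(-half:half, sd = width)
  num <- stats::filter(x, kern, sides = 2)
  den <- stats::filter(rep(1, length(x)), kern, sides = 2)
  out <- as.numeric(num / den)
  # edge bins where the kernel is truncated: renormalize by partial mass
  nas <- is.na(out)
  if (any(nas)) {
    xp <- c(rep(0, half), x, rep(0, half))
    op <- c(rep(0, half), rep(1, length(x)), rep(0, half))
    for (t in which(nas)) {
      idx <- t:(t + 2 * half)
      out[t] <- sum(xp[idx] * kern) / sum(op[idx] * kern)
    }
  }
  out
}

#' Correlation between predicted and reference firing rates
#'
#' Both series are smoothed with a Gaussian kernel before computing the
#' Pearson correlation coefficient, following the common practice of
#' comparing smoothed rate estimates.
#'
#' @param predicted,reference numeric vectors of equal length.
#' @param width smoothing kernel standard deviation in bins.
#' @return Correlation coefficient; \code{NaN} with a warning if either
#'   series has zero variance.
#' @export
evaluate_cc <- function(predicted, reference, width = 2) {
  a <- gaussian_smooth(predicted, width)
  b <- gaussian_smooth(reference, width)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance series; correlation undefined")
    return(NaN)
  }
  cor(a, b)
}

#' Sampling upper bound on the achievable rate correlation
#'
#' Mean pairwise correlation among independently re-jittered copies of the
#' ideal spike train: no rate predictor can be expected to correlate better
#' with one jittered realization than other realizations do with each
#' other.
#'
#' @param ideal_spikes 0/1 vector of unjittered spikes.
#' @param pmf jitter kernel (\code{\link{discretized_lognormal_kernel}}).
#' @param n_samples number of re-jittered copies.
#' @param width smoothing width for \code{\link{evaluate_cc}}.
#' @param seed optional integer seed.
#' @return Mean pairwise correlation coefficient.
#' @export
cc_upper_bound <- function(ideal_spikes, pmf, n_samples = 10L, width = 2,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(n_samples), function(k)
    gaussian_smooth(apply_jitter(ideal_spikes, pmf), width))
  ccs <- c()
  for (a in seq_len(n_samples - 1L))
    for (b in (a + 1L):n_samples)
      ccs <- c(ccs, cor(reps[[a]], reps[[b]]))
  mean(ccs)
}

#' Cosine similarity between two filters
#'
#' Normalized scalar product (cosine of the angle).  In shift-invariant
#' mode the second filter is shifted in time (columns of its
#' channels x window reshaping) over all offsets and the maximum cosine is
#' returned, discounting pure latency shifts.
#'
#' @param a,b length-d filter vectors.
#' @param shift_invariant maximize over integer temporal shifts.
#' @param channels number of channels in the embedding (needed to reshape
#'   for shift-invariant mode).
#' @return Cosine similarity in [-1, 1].
#' @export
cosine_similarity <- function(a, b, shift_invariant = FALSE, channels = 1L) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm filter")
  if (!shift_invariant) return(sum(a * b) / (na * nb))
  wl <- length(a) / channels
  if (wl != round(wl)) stop("filter length not divisible by channels")
  B <- matrix(b, channels, wl)
  best <- -1
  for (s in -(wl - 1L):(wl - 1L)) {
    Bs <- matrix(0, channels, wl)
    src <- seq_len(wl) - s
    ok <- src >= 1 & src <= wl
    Bs[, ok] <- B[, src[ok], drop = FALSE]
    nbs <- sqrt(sum(Bs^2))
    if (nbs == 0) next
    best <- max(best, sum(a * Bs) / (na * nbs))
  }
  best
}

#' Total-variation distance between two lag distributions
#'
#' @param a,b objects with \code{lags} and \code{probs} (e.g.
#'   \code{"mph_kernel"}, \code{"jitter_pmf"}); lags are aligned by value
#'   and missing lags count as probability zero.
#' @return TV distance in [0, 1].
#' @export
tv_distance <- function(a, b) {
  lags <- sort(union(a$lags, b$lags))
  pa <- setNames(rep(0, length(lags)), lags)
  pb <- pa
  pa[as.character(a$lags)] <- a$probs
  pb[as.character(b$lags)] <- b$probs
  sum(abs(pa - pb)) / 2
}
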