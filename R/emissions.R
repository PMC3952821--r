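# Emission families: Gaussian mixtures (stimulus), discrete distributions
# (response), and the mixed pair emission used by M-states.

#' Gaussian-mixture stimulus emission
#'
#' Emission density over embedded stimulus vectors, used by X-states and (per
#' response symbol) by M-states.  Component constraint flags control which
#' parameters EM may update: covariances with mode \code{"identity"} or
#' \code{"fixed_shared"} and means with mode \code{"fixed_zero"} or
#' \code{"fixed_value"} are held fixed; \code{"free"} parameters are
#' re-estimated.
#'
#' @param means d x K matrix of component means (one column per component).
#' @param covs d x d x K array of component covariance matrices; a single
#'   d x d matrix is recycled to all components.
#' @param weights length-K mixture weights (nonnegative, summing to one).
#' @param cov_mode,mean_mode constraint flags, recycled to length K.
#' @return An object of class \code{"mph_gm"}.
#' @export
gm_emission <- function(means, covs = NULL, weights = NULL,
                        cov_mode = "free", mean_mode = "free") {
  means <- as.matrix(means)
  d <- nrow(means)
  K <- ncol(means)
  if (is.null(covs)) covs <- diag(d)
  if (is.matrix(covs)) covs <- array(covs, dim = c(d, d, K))
  if (is.null(weights)) weights <- rep(1 / K, K)
  cov_mode <- rep_len(cov_mode, K)
  mean_mode <- rep_len(mean_mode, K)
  stopifnot(all(cov_mode %in% c("free", "identity", "fixed_shared")),
            all(mean_mode %in% c("free", "fixed_zero", "fixed_value")))
  structure(list(weights = as.numeric(weights), means = means, covs = covs,
                 cov_mode = cov_mode, mean_mode = mean_mode),
            class = "mph_gm")
}

#' Discrete response emission
#'
#' @param probs probability vector over the response alphabet \code{0..V-1}.
#' @param mode \code{"free"} (re-estimated by EM) or \code{"fixed"}.
#' @return An object of class \code{"mph_discrete"}.
#' @export
discrete_emission <- function(probs, mode = "free") {
  structure(list(probs = as.numeric(probs),
                 mode = match.arg(mode, c("free", "fixed"))),
            class = "mph_discrete")
}

#' Mixed stimulus-response emission for M-states
#'
#' Factorizes the pair emission as e(x, r) = P(r) p(x | r): a discrete
#' response marginal times one Gaussian-mixture stimulus model per response
#' symbol.
#'
#' @param marginal a \code{\link{discrete_emission}} over response symbols.
#' @param conditional list of length V of \code{\link{gm_emission}} objects,
#'   element v + 1 conditioning on response symbol v.
#' @return An object of class \code{"mph_mixed"}.
#' @export
mixed_emission <- function(marginal, conditional) {
  structure(list(marginal = marginal, conditional = conditional),
            class = "mph_mixed")
}

emission_dim <- function(em) {
  if (inherits(em, "mph_gm")) return(nrow(em$means))
  if (inherits(em, "mph_mixed")) return(nrow(em$conditional[[1]]$means))
  NA_integer_
}

# log N(x; mu, Sigma) for all columns of X, via Cholesky
mvn_logdens <- function(X, mu, Sigma) {
  d <- nrow(X)
  L <- tryCatch(chol(Sigma), error = function(e)
    stop("covariance matrix is not positive definite", call. = FALSE))
  z <- backsolve(L, X - mu, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + colSums(z^2))
}

# K x T matrix of log(c_k) + log N_k(x); weight-zero components give -Inf
gm_component_logdens <- function(em, X) {
  K <- length(em$weights)
  out <- matrix(-Inf, K, ncol(X))
  for (k in seq_len(K)) {
    if (em$weights[k] <= 0) next
    out[k, ] <- log(em$weights[k]) +
      mvn_logdens(X, em$means[, k], em$covs[, , k])
  }
  out
}

# length-T vector of log mixture densities
gm_logdens <- function(em, X) {
  lc <- gm_component_logdens(em, X)
  if (nrow(lc) == 1L) return(drop(lc))
  m <- apply(lc, 2, max)
  bad <- !is.finite(m)
  out <- m + log(colSums(exp(sweep(lc, 2, ifelse(bad, 0, m)))))
  out[bad] <- -Inf
  out
}

validate_gm <- function(em, where, d_expect = NULL) {
  bad <- character(0)
  w <- em$weights
  if (any(w < 0)) bad <- c(bad, paste0(where, ": mixture weights negative"))
  if (abs(sum(w) - 1) > 1e-12)
    bad <- c(bad, paste0(where, ": mixture weights do not sum to 1"))
  d <- nrow(em$means)
  if (!is.null(d_expect) && d != d_expect)
    bad <- c(bad, paste0(where, ": dimension ", d, " != expected ", d_expect))
  for (k in seq_along(w)) {
    C <- em$covs[, , k]
    if (max(abs(C - t(C))) > 1e-8)
      bad <- c(bad, paste0(where, ": covariance ", k, " not symmetric"))
    else if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      bad <- c(bad, paste0(where, ": covariance ", k,
                           " not positive definite"))
  }
  bad
}

validate_discrete <- function(em, where) {
  bad <- character(0)
  if (any(em$probs < 0))
    bad <- c(bad, paste0(where, ": probabilities negative"))
  if (abs(sum(em$probs) - 1) > 1e-12)
    bad <- c(bad, paste0(where, ": probabilities do not sum to 1"))
  bad
}
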