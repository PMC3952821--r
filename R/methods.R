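# S3 methods for the model, fit, kernel, rate, and cascade classes.

#' @export
print.mph_model <- function(x, ...) {
  kinds <- state_kinds(x)
  cat("Mixed pair hidden Markov model\n")
  cat(sprintf("  states: %d (%s)\n", length(kinds),
              paste(sprintf("%s:%s", kinds,
                            vapply(x$states, `[[`, "", "label")),
                    collapse = ", ")))
  cat(sprintf("  stimulus embedding: %d channel(s) x %d bin window (d = %d)\n",
              x$embedding$channels, x$embedding$window_length,
              x$embedding$d))
  cat(sprintf("  band width W = %d bins; response alphabet V = %d\n",
              x$band_width, x$V))
  invisible(x)
}

#' @export
print.mph_fit <- function(x, ...) {
  cat("MPH fit by EM\n")
  print(x$model)
  cat(sprintf("  log-likelihood: %.4f after %d iteration(s)%s\n",
              x$loglik, x$n_iter,
              if (isTRUE(x$converged)) " (converged)" else ""))
  if (nrow(x$restarts) > 1L)
    cat(sprintf("  best of %d restarts\n", nrow(x$restarts)))
  invisible(x)
}

#' @export
summary.mph_fit <- function(object, ...) {
  x <- object
  cat("MPH fit summary\n")
  print(x$model)
  cat(sprintf("  training pairs: %d (%d bins total)\n", length(x$pairs),
              sum(vapply(x$pairs, function(p) length(p$response), 0L))))
  cat(sprintf("  log-likelihood: %.4f, iterations: %d, converged: %s\n",
              x$loglik, x$n_iter, x$converged))
  cat("  transition matrix:\n")
  print(round(x$model$transitions, 4))
  cat("  initial:", round(x$model$initial, 4),
      " final:", round(x$model$final, 4), "\n")
  kinds <- state_kinds(x$model)
  for (s in which(kinds == "M")) {
    em <- x$model$states[[s]]$emission
    cat(sprintf("  state %d (%s): spike marginal %.4f, RF norm %.4f\n",
                s, x$model$states[[s]]$label, em$marginal$probs[2],
                sqrt(sum(mph_rf(x$model, s)^2))))
  }
  invisible(x)
}

#' Receptive fields of a fitted MPH
#'
#' Returns the covariance-corrected spike-conditioned mean differences (the
#' receptive fields) of all M-states, one column per M-state.
#'
#' @param object an \code{"mph_fit"}.
#' @param ... unused.
#' @return d x (number of M-states) matrix.
#' @export
coef.mph_fit <- function(object, ...) {
  ms <- which(state_kinds(object$model) == "M")
  out <- vapply(ms, function(s) mph_rf(object$model, s),
                numeric(object$model$embedding$d))
  out <- matrix(out, ncol = length(ms))
  colnames(out) <- vapply(object$model$states[ms], `[[`, "", "label")
  out
}

#' @export
logLik.mph_fit <- function(object, ...) {
  npar <- length(object$model$transitions) + 2L * length(object$model$initial)
  structure(object$loglik, df = npar, class = "logLik")
}

#' Predict spike probabilities from a fitted MPH
#'
#' @param object an \code{"mph_fit"}.
#' @param newdata d x T matrix of embedded stimulus vectors (or an
#'   \code{\link{mph_pair}}, whose stimulus is used).
#' @param type \code{"response"} for per-bin spike probabilities (via the
#'   inference rewriting), \code{"map"} for the most likely joint response
#'   and hidden path (extended Viterbi).
#' @param cascade optional \code{\link{fit_cascade}} mapping applied to the
#'   probabilities.
#' @param ... unused.
#' @return An \code{"mph_rate"} (type \code{"response"}) or the
#'   \code{\link{encode_map}} list (type \code{"map"}).
#' @export
predict.mph_fit <- function(object, newdata, type = c("response", "map"),
                            cascade = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "mph_pair")) newdata <- newdata$stimulus
  if (type == "map") return(encode_map(object$model, newdata))
  out <- response_probabilities(object$model, newdata)
  if (!is.null(cascade)) out <- apply_cascade(cascade, out)
  out
}

#' @export
residuals.mph_fit <- function(object, ...) {
  unlist(lapply(object$pairs, function(p)
    as.numeric(p$response >= 1L) -
      response_probabilities(object$model, p$stimulus,
                             length(p$response))$spike_prob))
}

#' Simulate stimulus-response pairs from a fitted MPH
#'
#' @param object an \code{"mph_fit"}.
#' @param nsim number of pairs to draw.
#' @param seed optional integer seed.
#' @param T_bins length of each simulated pair.
#' @param ... unused.
#' @return List of \code{\link{mph_pair}} objects (length \code{nsim}).
#' @export
simulate.mph_fit <- function(object, nsim = 1, seed = NULL, T_bins = 500L,
                             ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(k) mph_sample(object$model, T_bins))
}

#' @export
plot.mph_fit <- function(x, ...) {
  rf <- coef(x)
  emb <- x$model$embedding
  op <- par(mfrow = c(1, ncol(rf) + 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (k in seq_len(ncol(rf))) {
    img <- matrix(rf[, k], emb$channels, emb$window_length)
    image(t(img), xlab = "window bin", ylab = "channel",
          main = paste("RF", colnames(rf)[k]), ...)
  }
  plot(seq_along(x$trace), x$trace, type = "b", xlab = "EM iteration",
       ylab = "log-likelihood", main = "training trace")
  invisible(x)
}

#' @export
print.mph_kernel <- function(x, ...) {
  cat("Alignment kernel over", length(x$lags), "lags\n")
  mu <- sum(x$lags * x$probs)
  cat(sprintf("  mean lag %.3f bins (%.4f s), mode at %d bins\n",
              mu, mu * x$bin_width, x$lags[which.max(x$probs)]))
  invisible(x)
}

#' @export
plot.mph_kernel <- function(x, ...) {
  plot(x$lags, x$probs, type = "h", lwd = 3, xlab = "lag (bins)",
       ylab = "probability", main = "alignment kernel", ...)
  invisible(x)
}

#' @export
print.mph_rate <- function(x, ...) {
  cat("Per-bin spike probabilities for", length(x$spike_prob), "bins\n")
  cat(sprintf("  mean %.4f spikes/bin (%.3f spikes/s at bin width %.3g s)\n",
              mean(x$spike_prob), mean(x$spike_prob) / x$bin_width,
              x$bin_width))
  invisible(x)
}

#' @export
print.mph_cascade <- function(x, ...) {
  cat("Cascade mapping on", length(x$centers), "probability bins;",
      "occupied:", sum(x$den > 0), "\n")
  invisible(x)
}

#' @export
plot.mph_cascade <- function(x, ...) {
  plot(x$centers, x$g, type = "b", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "posterior spike probability", ylab = "g(p)",
       main = "cascade nonlinearity", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
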