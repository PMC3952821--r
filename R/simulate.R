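# Synthetic-data generators: white-noise and correlated Gaussian stimuli,
# LNP spiking, discretized log-normal spike-time jitter, Markov-switching
# LNP responses.

#' White-noise stimulus
#'
#' @param channels number of stimulus channels.
#' @param T_bins number of time bins.
#' @param seed optional integer seed for reproducibility.
#' @return channels x T_bins matrix of iid standard normal values.
#' @export
white_noise_stimulus <- function(channels, T_bins, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(channels * T_bins), channels, T_bins)
}

#' Correlated Gaussian stimulus
#'
#' Stationary Gaussian process standing in for natural stimuli (e.g., song
#' log-spectrograms): AR(1) dynamics in time with lag-one correlation
#' \code{rho_time}, and a squared-exponential cross-channel correlation with
#' length scale \code{channel_scale} (or an explicit channel covariance).
#' Each channel is marginally standard normal.
#'
#' @param channels number of channels.
#' @param T_bins number of time bins.
#' @param rho_time AR(1) coefficient in [0, 1).
#' @param channel_scale length scale (in channels) of the cross-channel
#'   correlation; 0 gives independent channels.
#' @param channel_cov optional explicit channels x channels covariance
#'   (must be positive definite).
#' @param seed optional integer seed.
#' @return channels x T_bins matrix.
#' @export
correlated_stimulus <- function(channels, T_bins, rho_time = 0.9,
                                channel_scale = 1, channel_cov = NULL,
                                seed = NULL) {
  stopifnot(rho_time >= 0, rho_time < 1)
  if (is.null(channel_cov)) {
    if (channel_scale <= 0) {
      channel_cov <- diag(channels)
    } else {
      idx <- seq_len(channels)
      channel_cov <- exp(-outer(idx, idx, `-`)^2 / (2 * channel_scale^2))
    }
  }
  ev <- eigen((channel_cov + t(channel_cov)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) stop("channel covariance is not positive definite")
  if (!is.null(seed)) set.seed(seed)
  L <- chol(channel_cov)
  z <- matrix(rnorm(channels * T_bins), channels, T_bins)
  x <- matrix(0, channels, T_bins)
  x[, 1] <- z[, 1]
  s_inn <- sqrt(1 - rho_time^2)
  for (t in seq_len(T_bins)[-1])
    x[, t] <- rho_time * x[, t - 1] + s_inn * z[, t]
  crossprod(L, x)
}

#' Linear-nonlinear-Poisson model specification
#'
#' Spiking probability per bin is \code{f(w . x_t)} with sigmoid
#' nonlinearity \code{f(z) = 1 / (1 + exp(-slope (z - offset)))}; spikes are
#' Bernoulli draws (at most one spike per bin).  When \code{offset} is
#' \code{NULL} it is calibrated at simulation time by bisection so the mean
#' rate over the supplied stimulus matches \code{target_rate}.
#'
#' @param filter length-d linear filter over embedded stimulus vectors.
#' @param slope sigmoid steepness.
#' @param offset sigmoid midpoint; \code{NULL} to calibrate.
#' @param target_rate target mean rate in spikes/bin.
#' @return Object of class \code{"lnp_spec"}.
#' @export
lnp_spec <- function(filter, slope = 4, offset = NULL, target_rate = 0.015) {
  stopifnot(all(is.finite(filter)), is.null(target_rate) ||
              (target_rate > 0 && target_rate < 1))
  structure(list(filter = as.numeric(filter), slope = slope,
                 offset = offset, target_rate = target_rate),
            class = "lnp_spec")
}

# solve the sigmoid offset so that mean_t f(z_t) = target (bisection)
calibrate_lnp <- function(spec, z) {
  target <- spec$target_rate
  f <- function(th) mean(plogis(spec$slope * (z - th))) - target
  lo <- min(z) - 10
  hi <- max(z) + 10
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  spec$offset <- (lo + hi) / 2
  spec
}

#' Simulate LNP spikes for a stimulus
#'
#' @param spec an \code{\link{lnp_spec}}.
#' @param stimulus d x T matrix of embedded stimulus vectors.
#' @param seed optional integer seed.
#' @param nonlinearity optional function overriding the sigmoid; must map
#'   filter outputs to probabilities in [0, 1].
#' @return List with \code{spikes} (0/1 integer vector), \code{rate}
#'   (per-bin spike probability), and \code{spec} with the calibrated
#'   offset filled in.
#' @export
lnp_simulate <- function(spec, stimulus, seed = NULL, nonlinearity = NULL) {
  z <- drop(crossprod(stimulus, spec$filter))
  if (is.null(nonlinearity)) {
    if (is.null(spec$offset)) spec <- calibrate_lnp(spec, z)
    p <- plogis(spec$slope * (z - spec$offset))
  } else {
    p <- nonlinearity(z)
    if (any(p < 0 | p > 1))
      stop("nonlinearity produced probabilities outside [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  list(spikes = rbinom(length(p), 1L, p), rate = p, spec = spec)
}

#' Discretized log-normal jitter kernel
#'
#' Log-normal density (meanlog 0, variance chosen to match \code{sigma2})
#' discretized on integer lags, shifted so the distribution has
#' approximately zero mean (the shift is an integer number of bins, so the
#' residual mean is below half a bin), and renormalized.  As the variance
#' grows the kernel becomes more asymmetric with a heavy right tail.
#'
#' @param sigma2 jitter variance in bins^2; values <= 0 give a delta at
#'   lag 0.
#' @param support integer lag grid on which the kernel lives.
#' @return Object of class \code{"jitter_pmf"}: list with \code{lags} and
#'   \code{probs}.
#' @export
discretized_lognormal_kernel <- function(sigma2, support = -8:8) {
  support <- sort(unique(as.integer(support)))
  if (sigma2 <= 0) {
    probs <- as.numeric(support == 0L)
    return(structure(list(lags = support, probs = probs),
                     class = "jitter_pmf"))
  }
  # meanlog 0; solve sdlog from var = (e^{s2} - 1) e^{s2}
  u <- (1 + sqrt(1 + 4 * sigma2)) / 2
  sdlog <- sqrt(log(u))
  m <- exp(sdlog^2 / 2)
  kmax <- max(support) - min(support) + ceiling(m) + 4L
  k <- 0:kmax
  pk <- plnorm(k + 0.5, 0, sdlog) - plnorm(pmax(k - 0.5, 0), 0, sdlog)
  shift <- round(sum(k * pk) / sum(pk))
  lag_k <- k - shift
  probs <- vapply(support, function(l) sum(pk[lag_k == l]), 0)
  probs <- probs / sum(probs)
  structure(list(lags = support, probs = probs), class = "jitter_pmf")
}

#' Jitter spike times
#'
#' Each spike is displaced by an independent draw from the jitter kernel.
#' Spikes displaced outside the sequence are dropped; multiple spikes
#' landing in one bin are kept as a single spike (binary response).
#'
#' @param spikes 0/1 integer vector.
#' @param pmf a \code{\link{discretized_lognormal_kernel}} (or any list with
#'   \code{lags} and \code{probs}).
#' @param seed optional integer seed.
#' @return 0/1 integer vector of the same length.
#' @export
apply_jitter <- function(spikes, pmf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Tn <- length(spikes)
  pos <- which(spikes >= 1L)
  out <- integer(Tn)
  if (!length(pos)) return(out)
  shifts <- sample(pmf$lags, length(pos), replace = TRUE, prob = pmf$probs)
  np <- pos + shifts
  np <- np[np >= 1L & np <= Tn]
  out[np] <- 1L
  out
}

#' Simulate a Markov-switching LNP response
#'
#' A first-order Markov chain over model identities selects which LNP model
#' is active in each bin; spikes are drawn from the active model.
#'
#' @param specs list of \code{\link{lnp_spec}} objects.
#' @param stimulus d x T matrix of embedded stimulus vectors.
#' @param switch_matrix row-stochastic switching matrix (default: equal
#'   stay/switch probabilities).
#' @param seed optional integer seed.
#' @return List with \code{spikes}, \code{states} (active model index per
#'   bin), \code{rate}, and the calibrated \code{specs}.
#' @export
switching_lnp_simulate <- function(specs, stimulus, switch_matrix = NULL,
                                   seed = NULL) {
  n <- length(specs)
  if (is.null(switch_matrix)) switch_matrix <- matrix(1 / n, n, n)
  if (any(abs(rowSums(switch_matrix) - 1) > 1e-12))
    stop("switching matrix must be row-stochastic")
  if (!is.null(seed)) set.seed(seed)
  Tn <- ncol(stimulus)
  rates <- matrix(0, n, Tn)
  for (i in seq_len(n)) {
    z <- drop(crossprod(stimulus, specs[[i]]$filter))
    if (is.null(specs[[i]]$offset)) specs[[i]] <- calibrate_lnp(specs[[i]], z)
    rates[i, ] <- plogis(specs[[i]]$slope * (z - specs[[i]]$offset))
  }
  states <- integer(Tn)
  states[1] <- sample.int(n, 1L)
  for (t in seq_len(Tn)[-1])
    states[t] <- sample.int(n, 1L, prob = switch_matrix[states[t - 1], ])
  p <- rates[cbind(states, seq_len(Tn))]
  list(spikes = rbinom(Tn, 1L, p), states = states, rate = p, specs = specs)
}

#' Sample a stimulus-response pair from an MPH
#'
#' Generative sampling: states follow the Markov chain (initial
#' probabilities, transitions), each state emits per its kind, and the run
#' stops once both sequences reach \code{T_bins} (final probabilities are
#' ignored so a fixed length can be requested; both sequences are truncated
#' to the shorter one if X/R states leave them unequal).
#'
#' @param model an \code{\link{mph_model}}.
#' @param T_bins requested sequence length.
#' @param seed optional integer seed.
#' @return An \code{\link{mph_pair}}.
#' @export
mph_sample <- function(model, T_bins, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- model$embedding$d
  kinds <- state_kinds(model)
  N <- length(model$states)
  cap <- 2L * T_bins + 10L
  Xs <- matrix(0, d, cap)
  rs <- integer(cap)
  nx <- 0L
  nr <- 0L
  s <- sample.int(N, 1L, prob = model$initial)
  repeat {
    st <- model$states[[s]]
    if (kinds[s] == "X") {
      nx <- nx + 1L
      Xs[, nx] <- gm_draw(st$emission)
    } else if (kinds[s] == "R") {
      nr <- nr + 1L
      rs[nr] <- sample.int(model$V, 1L, prob = st$emission$probs) - 1L
    } else {
      v <- sample.int(model$V, 1L, prob = st$emission$marginal$probs) - 1L
      nx <- nx + 1L
      nr <- nr + 1L
      Xs[, nx] <- gm_draw(st$emission$conditional[[v + 1L]])
      rs[nr] <- v
    }
    if ((nx >= T_bins && nr >= T_bins) || nx >= cap || nr >= cap) break
    A <- model$transitions[s, ]
    if (sum(A) <= 0) break  # absorbing end
    s <- sample.int(N, 1L, prob = A)
  }
  Tn <- min(nx, nr, T_bins)
  mph_pair(Xs[, seq_len(Tn), drop = FALSE], rs[seq_len(Tn)], V = model$V)
}

# one draw from a Gaussian mixture
gm_draw <- function(em) {
  k <- sample.int(length(em$weights), 1L, prob = em$weights)
  mu <- em$means[, k]
  L <- chol(em$covs[, , k])
  mu + drop(crossprod(L, rnorm(length(mu))))
}
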