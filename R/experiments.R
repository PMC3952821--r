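# End-to-end synthetic experiments: jittered LNP responses (white and
# correlated stimuli), Markov-switching responses, and cascade calibration.
# These drivers are used by the test suite and the acceptance script.

# Gabor-like spectrotemporal filter on a channels x window grid with fine
# temporal structure (period ~3 bins), scaled to a fixed norm.  Fine
# structure matters: spike-time jitter only degrades receptive fields whose
# temporal detail is comparable to the jitter scale, and that same detail
# is what makes misaligned stimuli distinguishable for the aligner.
make_rf <- function(channels, window, norm = 2) {
  u <- seq_len(window)
  env <- exp(-(u - window * 0.6)^2 / (2 * (window / 3.5)^2))
  w <- matrix(0, channels, window)
  for (ch in seq_len(channels))
    w[ch, ] <- env * cos(2 * pi * u / 3 + (ch - 1) * pi / 2)
  v <- as.numeric(w)
  v / sqrt(sum(v^2)) * norm
}

# unit bump filter over d dims centered at ctr (switching experiment)
make_bump <- function(d, ctr, width = 2.5, norm = 2) {
  v <- exp(-(seq_len(d) - ctr)^2 / (2 * width^2))
  v / sqrt(sum(v^2)) * norm
}

split_train_val <- function(pairs, val_frac) {
  n <- length(pairs)
  nval <- max(1L, round(val_frac * n))
  list(train = pairs[seq_len(n - nval)],
       val = pairs[(n - nval + 1L):n])
}

#' Spike-time-jitter experiment (MXR-MPH versus STA / reverse correlation)
#'
#' Simulates LNP spiking to a white-noise (or correlated Gaussian) stimulus,
#' jitters the spikes with a discretized log-normal kernel, fits an MXR-MPH
#' and the moment-based STA/RC predictor on training sequences, and
#' evaluates receptive-field recovery and response prediction on held-out
#' sequences.
#'
#' @param sigma2 jitter variance in bins^2 (0 disables jitter).
#' @param T_bins total number of time bins.
#' @param channels,window stimulus channels and embedding window (d =
#'   channels x window).
#' @param rate target LNP mean rate (spikes/bin).
#' @param slope LNP sigmoid steepness.
#' @param seq_len sequence length the data is split into.
#' @param val_frac fraction of sequences held out for validation.
#' @param band_width DP band width W.
#' @param correlated use a correlated Gaussian stimulus and the
#'   reverse-correlation baseline (shared fixed covariance in the model).
#' @param lam covariance regularization weight (correlated mode).
#' @param seed integer seed for all randomness.
#' @param control \code{\link{mph_control}} for the EM fit.
#' @return List of metrics: validation correlations (\code{cc_mph},
#'   \code{cc_base}, \code{cc_upper}), filter cosines (\code{cos_mph},
#'   \code{cos_base}), the pooled alignment \code{kernel}, the generating
#'   \code{pmf}, their total-variation distance \code{tv}, spike counts,
#'   and the fitted objects.
#' @export
run_jitter_experiment <- function(sigma2, T_bins = 2e4, channels = 2L,
                                  window = 10L, rate = 0.015, slope = 4,
                                  seq_len = 500L, val_frac = 0.1,
                                  band_width = 8L, correlated = FALSE,
                                  lam = 0.1, seed = 1L,
                                  control = mph_control(max_iters = 60L,
                                                        seed = seed)) {
  set.seed(seed)
  emb <- stimulus_embedding(window, channels)
  stim <- if (correlated)
    correlated_stimulus(channels, T_bins, rho_time = 0.8, channel_scale = 1)
  else white_noise_stimulus(channels, T_bins)
  X <- embed_stimulus(stim, emb)
  w_true <- make_rf(channels, window)
  lnp <- lnp_simulate(lnp_spec(w_true, slope = slope, target_rate = rate), X)
  pmf <- discretized_lognormal_kernel(sigma2, support = -band_width:band_width)
  jittered <- apply_jitter(lnp$spikes, pmf)
  pairs <- split_pair(mph_pair(X, jittered), seq_len)
  sv <- split_train_val(pairs, val_frac)

  if (correlated) {
    C <- regularize_covariance(pooled_cov(sv$train), lam)
    mu <- pooled_mean(sv$train)
    model <- mph_mxr(emb, data_mean = mu, data_cov = C,
                     cov_mode = "fixed_shared", band_width = band_width)
    base_filter <- rc_fit(sv$train, lam = lam)
    base_pred <- lnp_from_moments(sv$train, "shared", lam = lam)
  } else {
    model <- mph_mxr(emb, band_width = band_width)
    base_filter <- sta_fit(sv$train)
    base_pred <- lnp_from_moments(sv$train, "identity")
  }
  fit <- mph_fit(model, sv$train, control)
  rf_mph <- mph_rf(fit$model)

  val_stim <- lapply(sv$val, `[[`, "stimulus")
  val_resp <- unlist(lapply(sv$val, `[[`, "response"))
  pred_mph <- unlist(lapply(val_stim, function(S)
    response_probabilities(fit$model, S)$spike_prob))
  pred_base <- unlist(lapply(val_stim, function(S) predict(base_pred, S)))

  # ideal (unjittered) spikes on the validation span for the upper bound
  val_len <- length(val_resp)
  ideal_val <- lnp$spikes[(T_bins - val_len + 1L):T_bins]

  kern <- pooled_alignment_kernel(fit$model, sv$train)
  # shift-invariant cosine: asymmetric jitter kernels can anchor the model's
  # lag reference (and hence the RF position) off by a bin or two without
  # changing the model's predictions; discount such pure latency shifts
  list(cc_mph = evaluate_cc(pred_mph, val_resp),
       cc_base = evaluate_cc(pred_base, val_resp),
       cc_upper = cc_upper_bound(ideal_val, pmf, n_samples = 8L),
       cos_mph = cosine_similarity(rf_mph, w_true, shift_invariant = TRUE,
                                   channels = channels),
       cos_base = cosine_similarity(base_filter, w_true,
                                    shift_invariant = TRUE,
                                    channels = channels),
       kernel = kern, pmf = pmf,
       tv = tv_distance(kern, pmf),
       n_spikes = sum(unlist(lapply(sv$train, `[[`, "response"))),
       w_true = w_true, fit = fit)
}

# receptive field of the first M-state: covariance-corrected difference of
# spike- and no-spike-conditioned means
mph_rf <- function(model, state = which(state_kinds(model) == "M")[1]) {
  em <- model$states[[state]]$emission
  mu1 <- em$conditional[[2]]$means[, 1]
  mu0 <- em$conditional[[1]]$means[, 1]
  S <- em$conditional[[2]]$covs[, , 1]
  drop(solve(S, mu1 - mu0))
}

#' Switching-receptive-field experiment (M^2-MPH versus STA and STC)
#'
#' Simulates a neuron that switches between two LNP receptive fields under
#' a first-order Markov process with equal probabilities, fits an M^2-MPH
#' (multiple restarts), and compares receptive-field recovery and response
#' prediction against STA and STC baselines.
#'
#' @param angle_deg rotation angle (degrees) between the two generating
#'   filters, in the plane spanned by the base filter and an orthogonal
#'   direction; 180 gives the antipodal pooling counter-example.
#' @param T_bins,d total bins and stimulus dimension (window 1, d channels).
#' @param rate target mean rate per active model (spikes/bin).
#' @param slope LNP sigmoid steepness.
#' @param seq_len,val_frac sequence split.
#' @param seed integer seed.
#' @param control \code{\link{mph_control}}; defaults to 3 restarts.
#' @return List of metrics: best-match mean filter cosines (\code{cos_mph},
#'   \code{cos_sta}, \code{cos_stc}), validation correlations
#'   (\code{cc_mph}, \code{cc_sta}, \code{cc_stc}), \code{sta_norm}, the
#'   generating filters, and the fitted objects.
#' @export
run_switching_experiment <- function(angle_deg, T_bins = 1e4, d = 21L,
                                     rate = 0.044, slope = 4,
                                     seq_len = 500L, val_frac = 0.1,
                                     seed = 1L,
                                     control = mph_control(max_iters = 60L,
                                                           n_restarts = 3L,
                                                           seed = seed)) {
  set.seed(seed)
  emb <- stimulus_embedding(1L, d)
  stim <- white_noise_stimulus(d, T_bins)
  X <- stim  # window 1: embedding is the frame itself
  w1 <- make_bump(d, ctr = 0.4 * d)
  ortho <- make_bump(d, ctr = 0.7 * d)
  ortho <- ortho - w1 * sum(ortho * w1) / sum(w1^2)
  ortho <- ortho / sqrt(sum(ortho^2)) * sqrt(sum(w1^2))
  th <- angle_deg * pi / 180
  w2 <- cos(th) * w1 + sin(th) * ortho
  sim <- switching_lnp_simulate(
    list(lnp_spec(w1, slope = slope, target_rate = rate),
         lnp_spec(w2, slope = slope, target_rate = rate)), X)
  pairs <- split_pair(mph_pair(X, sim$spikes), seq_len)
  sv <- split_train_val(pairs, val_frac)

  fit <- mph_fit(mph_mn(2L, emb), sv$train, control)
  rf_fit <- vapply(1:2, function(s) mph_rf(fit$model, s), numeric(d))
  sta <- sta_fit(sv$train)
  stc <- stc_fit(sv$train, 2L)

  best_match <- function(est, true, use_abs = FALSE) {
    # est: d x m estimated filters; match each true filter to its closest
    # estimate and average the cosines
    cosm <- function(a, b) {
      v <- cosine_similarity(a, b)
      if (use_abs) abs(v) else v
    }
    mean(vapply(true, function(w)
      max(apply(est, 2, cosm, a = w)), 0))
  }
  true_list <- list(w1, w2)

  val_stim <- lapply(sv$val, `[[`, "stimulus")
  val_resp <- unlist(lapply(sv$val, `[[`, "response"))
  pred_mph <- unlist(lapply(val_stim, function(S)
    response_probabilities(fit$model, S)$spike_prob))
  # cascaded MPH: remap the posterior spike probability through the
  # histogram-estimated output nonlinearity (the model's own sigmoid shape
  # is tied to the fitted means and can be shallower than the truth)
  casc <- fit_cascade(fit$model, sv$train)
  pred_cmph <- apply_cascade(casc, pred_mph)
  sta_pred <- lnp_from_moments(sv$train, "identity")
  pred_sta <- unlist(lapply(val_stim, function(S) predict(sta_pred, S)))
  stc_fun <- stc_predict(sv$train, stc)
  pred_stc <- unlist(lapply(val_stim, stc_fun))

  list(cos_mph = best_match(rf_fit, true_list),
       cos_sta = best_match(matrix(sta, ncol = 1), true_list),
       cos_stc = best_match(stc, true_list, use_abs = TRUE),
       cc_mph = evaluate_cc(pred_mph, val_resp),
       cc_cmph = evaluate_cc(pred_cmph, val_resp),
       cc_sta = evaluate_cc(pred_sta, val_resp),
       cc_stc = evaluate_cc(pred_stc, val_resp),
       sta_norm = sqrt(sum(sta^2)),
       w1 = w1, w2 = w2, fit = fit)
}

#' Cascade calibration and steep-nonlinearity experiment
#'
#' Part one: data sampled from a known single-M-state MPH; the estimated
#' cascade mapping should be close to the identity (the model is already
#' calibrated).  Part two: LNP data with a sigmoid steeper than the
#' M-MPH's own; remapping posterior spike probabilities through the
#' estimated cascade should not hurt (and typically helps) validation
#' correlation.
#'
#' @param T_cal bins for the calibration part.
#' @param T_lnp bins for the steep-LNP part.
#' @param d stimulus dimension.
#' @param steep_slope slope of the (steeper) generating sigmoid.
#' @param rate target mean rate.
#' @param seed integer seed.
#' @return List with \code{mad_identity} (histogram-weighted mean absolute
#'   deviation of the mapping from identity), \code{cc_plain},
#'   \code{cc_cascaded}, and the fitted mappings.
#' @export
run_cascade_experiment <- function(T_cal = 1e5, T_lnp = 3e4, d = 10L,
                                   steep_slope = 12, rate = 0.02,
                                   seed = 1L) {
  set.seed(seed)
  emb <- stimulus_embedding(1L, d)
  # calibration: model-generated data
  w <- make_bump(d, ctr = d / 2)
  truth <- mph_mn(1L, emb, spike_prob = rate)
  truth$states[[1]]$emission$conditional[[2]]$means[, 1] <- w
  cal_pair <- mph_sample(truth, T_cal)
  map_cal <- fit_cascade(truth, cal_pair)
  wts <- map_cal$den / sum(map_cal$den)
  mad_identity <- sum(wts * abs(map_cal$g - map_cal$centers))

  # steep LNP: fit M-MPH, then cascade, compare validation CCs
  stim <- white_noise_stimulus(d, T_lnp)
  lnp <- lnp_simulate(lnp_spec(w, slope = steep_slope, target_rate = rate),
                      stim)
  pairs <- split_pair(mph_pair(stim, lnp$spikes), 1000L)
  sv <- split_train_val(pairs, 0.2)
  fit <- mph_fit(mph_mn(1L, emb), sv$train,
                 mph_control(max_iters = 5L, seed = seed))
  map_lnp <- fit_cascade(fit$model, sv$train)
  val_resp <- unlist(lapply(sv$val, `[[`, "response"))
  pred <- unlist(lapply(sv$val, function(p)
    response_probabilities(fit$model, p$stimulus)$spike_prob))
  list(mad_identity = mad_identity,
       cc_plain = evaluate_cc(pred, val_resp),
       cc_cascaded = evaluate_cc(apply_cascade(map_lnp, pred), val_resp),
       map_cal = map_cal, map_lnp = map_lnp, fit = fit)
}
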