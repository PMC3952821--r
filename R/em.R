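# EM parameter estimation for MPHs over one or many stimulus-response
# pairs, honoring constraint flags.

#' EM control parameters
#'
#' @param max_iters maximum EM iterations (0 returns the input model
#'   unchanged).
#' @param tol relative log-likelihood change below which EM stops.
#' @param n_restarts number of restarts from jittered initializations; the
#'   restart with the highest training log-likelihood is returned.
#' @param seed integer seed controlling initialization randomness.
#' @param cov_floor eigenvalue floor for free covariances, as a fraction of
#'   the mean diagonal, applied after every M-step.
#' @param init_from_data initialize free spike-conditioned means from
#'   spike-triggered averages and free response marginals from the empirical
#'   spike rate.
#' @param verbose print per-iteration log-likelihoods.
#' @return List of class \code{"mph_control"}.
#' @export
mph_control <- function(max_iters = 200L, tol = 1e-6, n_restarts = 1L,
                        seed = 1L, cov_floor = 1e-6,
                        init_from_data = TRUE, verbose = FALSE) {
  stopifnot(max_iters >= 0, tol > 0, n_restarts >= 1)
  structure(list(max_iters = as.integer(max_iters), tol = tol,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), cov_floor = cov_floor,
                 init_from_data = init_from_data, verbose = verbose),
            class = "mph_control")
}

#' Expectation step
#'
#' Runs forward-backward on every pair and collects state posteriors,
#' expected transition counts (summed over banded positions), and start /
#' terminal occupancies.
#'
#' @param model an \code{\link{mph_model}}.
#' @param pairs an \code{\link{mph_pair}} or list thereof.
#' @return List with one element per pair, each holding \code{gamma}
#'   (banded posterior array), \code{xi} (N x N expected transition counts),
#'   \code{init_occ}, \code{final_occ}, \code{loglik}, and geometry.
#' @export
mph_estep <- function(model, pairs) {
  pairs <- as_pair_list(pairs)
  lapply(seq_along(pairs), function(pi_) {
    pair <- pairs[[pi_]]
    p <- prep_dp(model, pair)
    W <- model$band_width
    check_band(p$Tx, p$Tr, W)
    lb <- lag_bounds_of(model, W)
    fw <- dp_forward_cpp(p$kinds, p$logA, p$logrho, p$logtau,
                         p$Tx, p$Tr, W, p$EX, p$ER, p$EM, p$r, lb$lo, lb$hi)
    if (!is.finite(fw$loglik))
      stop("pair ", pi_, " impossible under model")
    bw <- dp_backward_cpp(p$kinds, p$logA, p$logrho, p$logtau,
                          p$Tx, p$Tr, W, p$EX, p$ER, p$EM, p$r,
                          lb$lo, lb$hi)
    xi <- dp_xi_cpp(p$kinds, p$logA, p$logrho, p$logtau,
                    p$Tx, p$Tr, W, p$EX, p$ER, p$EM, p$r, lb$lo, lb$hi,
                    fw$alpha, bw$beta, fw$loglik)
    g <- exp(fw$alpha + bw$beta - fw$loglik)
    g[!is.finite(g)] <- 0
    list(gamma = g, xi = xi$xi, init_occ = drop(xi$init_occ),
         final_occ = drop(xi$final_occ), loglik = fw$loglik,
         Tx = p$Tx, Tr = p$Tr, W = W)
  })
}

# occupancy weights over stimulus positions i = 1..Tx for one state slice,
# optionally restricted to cells whose response symbol equals v.
# gslice: (Tx+1) x (2W+1); cell (row i + 1, col k) has j = i + k - 1 - W.
occupancy_by_i <- function(gslice, Tx, Tr, W, r = NULL, v = NULL) {
  gslice <- matrix(gslice, ncol = 2L * W + 1L)
  out <- numeric(Tx)
  for (k in seq_len(2 * W + 1)) {
    iis <- seq_len(Tx)
    js <- iis + k - 1L - W
    ok <- js >= 1L & js <= Tr
    idx <- iis[ok]
    if (!is.null(v)) idx <- idx[r[js[ok]] == v]
    if (!length(idx)) next
    out[idx] <- out[idx] + gslice[idx + 1L, k]
  }
  out
}

# occupancy weights over response positions j = 1..Tr for one state slice
occupancy_by_j <- function(gslice, Tx, Tr, W) {
  gslice <- matrix(gslice, ncol = 2L * W + 1L)
  out <- numeric(Tr)
  for (k in seq_len(2 * W + 1)) {
    iis <- 0:Tx
    js <- iis + k - 1L - W
    ok <- js >= 1L & js <= Tr
    if (!any(ok)) next
    out[js[ok]] <- out[js[ok]] + gslice[iis[ok] + 1L, k]
  }
  out
}

# weighted Gaussian-mixture sufficient statistics accumulator
gm_stats_init <- function(d, K)
  list(N = numeric(K), M1 = matrix(0, d, K),
       M2 = array(0, dim = c(d, d, K)))

gm_stats_add <- function(st, em, X, u) {
  keep <- u > 0
  if (!any(keep)) return(st)
  Xk <- X[, keep, drop = FALSE]
  uk <- u[keep]
  K <- length(em$weights)
  if (K == 1L) {
    resp <- matrix(uk, 1)
  } else {
    lc <- gm_component_logdens(em, Xk)
    m <- apply(lc, 2, max)
    pk <- exp(sweep(lc, 2, m))
    pk <- sweep(pk, 2, colSums(pk), "/")
    resp <- sweep(pk, 2, uk, "*")
  }
  for (k in seq_len(K)) {
    rk <- resp[k, ]
    st$N[k] <- st$N[k] + sum(rk)
    st$M1[, k] <- st$M1[, k] + Xk %*% rk
    Xw <- sweep(Xk, 2, rk, "*")
    st$M2[, , k] <- st$M2[, , k] + tcrossprod(Xw, Xk)
  }
  st
}

gm_update <- function(em, st, cov_floor) {
  K <- length(em$weights)
  tot <- sum(st$N)
  for (k in seq_len(K)) {
    if (st$N[k] <= 0) {
      if (em$weights[k] > 0 && K > 1L)
        warning("mixture component ", k, " collapsed (zero responsibility)")
      if (K > 1L) em$weights[k] <- 0
      next
    }
    if (K > 1L) em$weights[k] <- st$N[k] / tot
    m1 <- st$M1[, k] / st$N[k]
    if (em$mean_mode[k] == "free") em$means[, k] <- m1
    if (em$cov_mode[k] == "free") {
      # responsibility-weighted scatter about the stored (new or fixed) mean
      mu <- em$means[, k]
      C <- st$M2[, , k] / st$N[k] - tcrossprod(mu, m1) -
        tcrossprod(m1, mu) + tcrossprod(mu)
      C <- (C + t(C)) / 2
      e <- eigen(C, symmetric = TRUE)
      floor_val <- cov_floor * mean(diag(C))
      vals <- pmax(e$values, max(floor_val, 1e-12))
      em$covs[, , k] <- e$vectors %*% (vals * t(e$vectors))
    }
  }
  if (K > 1L && sum(em$weights) > 0)
    em$weights <- em$weights / sum(em$weights)
  em
}

#' Maximization step
#'
#' Re-estimates all free parameters from expectation-step outputs:
#' transition rows and final probabilities from expected transition counts
#' and terminal occupancies (jointly normalized so each row plus tau sums to
#' one), initial probabilities from start occupancies, discrete emissions
#' from expected symbol counts, and Gaussian-mixture weights, means, and
#' covariances from responsibility-weighted moments.  M-state mixtures for
#' response symbol v sum only over cells whose response symbol is v.
#' Sufficient statistics are pooled across pairs before normalization, and
#' constraint flags are enforced.
#'
#' @param model the current \code{\link{mph_model}}.
#' @param es output of \code{\link{mph_estep}} for \code{model}.
#' @param pairs the pairs used in the E-step.
#' @param control an \code{\link{mph_control}}.
#' @return The updated \code{\link{mph_model}}.
#' @export
mph_mstep <- function(model, es, pairs, control = mph_control()) {
  pairs <- as_pair_list(pairs)
  N <- length(model$states)
  kinds <- state_kinds(model)
  V <- model$V
  d <- model$embedding$d

  xi <- Reduce(`+`, lapply(es, `[[`, "xi"))
  init_occ <- Reduce(`+`, lapply(es, `[[`, "init_occ"))
  final_occ <- Reduce(`+`, lapply(es, `[[`, "final_occ"))

  denom <- rowSums(xi) + final_occ
  A <- model$transitions
  tau <- model$final
  for (s in seq_len(N)) {
    if (denom[s] > 0) {
      A[s, ] <- xi[s, ] / denom[s]
      tau[s] <- final_occ[s] / denom[s]
    }
  }
  rho <- if (sum(init_occ) > 0) init_occ / sum(init_occ) else model$initial

  states <- model$states
  for (s in seq_len(N)) {
    st <- states[[s]]
    if (kinds[s] == "X") {
      acc <- gm_stats_init(d, length(st$emission$weights))
      for (pi_ in seq_along(pairs)) {
        e <- es[[pi_]]
        u <- occupancy_by_i(e$gamma[, , s], e$Tx, e$Tr, e$W)
        acc <- gm_stats_add(acc, st$emission, pairs[[pi_]]$stimulus, u)
      }
      st$emission <- gm_update(st$emission, acc, control$cov_floor)
    } else if (kinds[s] == "R") {
      if (st$emission$mode == "free") {
        cnt <- numeric(V)
        for (pi_ in seq_along(pairs)) {
          e <- es[[pi_]]
          uj <- occupancy_by_j(e$gamma[, , s], e$Tx, e$Tr, e$W)
          cnt <- cnt + vapply(0:(V - 1L), function(v)
            sum(uj[pairs[[pi_]]$response == v]), 0)
        }
        if (sum(cnt) > 0) st$emission$probs <- cnt / sum(cnt)
      }
    } else {  # M-state
      cnt <- numeric(V)
      for (v in 0:(V - 1L)) {
        em_v <- st$emission$conditional[[v + 1L]]
        acc <- gm_stats_init(d, length(em_v$weights))
        for (pi_ in seq_along(pairs)) {
          e <- es[[pi_]]
          u <- occupancy_by_i(e$gamma[, , s], e$Tx, e$Tr, e$W,
                              r = pairs[[pi_]]$response, v = v)
          acc <- gm_stats_add(acc, em_v, pairs[[pi_]]$stimulus, u)
        }
        cnt[v + 1L] <- sum(acc$N)
        st$emission$conditional[[v + 1L]] <-
          gm_update(em_v, acc, control$cov_floor)
      }
      if (st$emission$marginal$mode == "free" && sum(cnt) > 0)
        st$emission$marginal$probs <- cnt / sum(cnt)
    }
    states[[s]] <- st
  }

  model$states <- states
  model$transitions <- A
  model$initial <- rho
  model$final <- tau
  model
}

# spike-triggered mean of embedded stimuli pooled over pairs (internal; the
# exported estimator with centering lives in baselines.R)
spike_triggered_mean <- function(pairs, v = 1L) {
  pairs <- as_pair_list(pairs)
  num <- 0
  den <- 0
  for (p in pairs) {
    w <- as.numeric(p$response >= v)
    num <- num + p$stimulus %*% w
    den <- den + sum(w)
  }
  if (den == 0) stop("no spikes in pairs")
  drop(num / den)
}

# seeded initialization: free spike-conditioned means from the
# spike-triggered mean (+ noise after the first restart), free marginals
# from the empirical spike rate, transitions jittered after the first
# restart
mph_init <- function(model, pairs, control, restart) {
  pairs <- as_pair_list(pairs)
  set.seed(control$seed + 1000L * (restart - 1L))
  kinds <- state_kinds(model)
  rate <- mean(unlist(lapply(pairs, function(p) p$response >= 1L)))
  stm <- tryCatch(spike_triggered_mean(pairs), error = function(e) NULL)
  noise_sd <- if (restart == 1L) 0.1 else 0.5
  for (s in which(kinds == "M")) {
    em <- model$states[[s]]$emission
    if (control$init_from_data) {
      if (em$marginal$mode == "free")
        em$marginal$probs <- c(1 - rate, rate)
      for (v in seq_along(em$conditional)) {
        gm <- em$conditional[[v]]
        free <- gm$mean_mode == "free"
        if (any(free) && !is.null(stm) && v == 2L)
          gm$means[, free] <- stm +
            rnorm(sum(free) * nrow(gm$means), sd = noise_sd)
        em$conditional[[v]] <- gm
      }
    }
    model$states[[s]]$emission <- em
  }
  if (restart > 1L) {
    N <- length(model$states)
    for (s in seq_len(N)) {
      g <- -log(runif(N + 1L))
      mix <- 0.5
      row <- (1 - mix) * c(model$transitions[s, ], model$final[s]) +
        mix * g / sum(g)
      model$transitions[s, ] <- row[seq_len(N)] / sum(row)
      model$final[s] <- row[N + 1L] / sum(row)
    }
    g <- -log(runif(length(model$initial)))
    rho <- 0.5 * model$initial + 0.5 * g / sum(g)
    model$initial <- rho / sum(rho)
  }
  model
}

#' Fit an MPH by expectation-maximization
#'
#' Iterates \code{\link{mph_estep}} / \code{\link{mph_mstep}} until the
#' relative training log-likelihood change drops below \code{tol} or
#' \code{max_iters} is reached, optionally over several seeded restarts,
#' returning the restart with the highest training log-likelihood.  The
#' log-likelihood trace is non-decreasing up to numerical tolerance.
#'
#' @param model an \code{\link{mph_model}} template (constraint flags decide
#'   which parameters are re-estimated).
#' @param pairs an \code{\link{mph_pair}} or list thereof.
#' @param control an \code{\link{mph_control}}.
#' @return Object of class \code{"mph_fit"}: list with \code{model} (fitted),
#'   \code{loglik}, \code{trace} (per-iteration log-likelihoods),
#'   \code{n_iter}, \code{converged}, \code{restarts} (per-restart summary
#'   data frame), \code{pairs}, and \code{control}.
#' @export
mph_fit <- function(model, pairs, control = mph_control()) {
  pairs <- as_pair_list(pairs)
  bad <- mph_validate(model)
  if (length(bad))
    stop("invalid MPH model:\n  ", paste(bad, collapse = "\n  "))
  if (control$max_iters == 0L) {
    return(structure(list(model = model, loglik = NA_real_,
                          trace = numeric(0), n_iter = 0L, converged = FALSE,
                          restarts = data.frame(), pairs = pairs,
                          control = control),
                     class = "mph_fit"))
  }
  best <- NULL
  rows <- list()
  for (rs in seq_len(control$n_restarts)) {
    m <- mph_init(model, pairs, control, rs)
    trace <- numeric(0)
    converged <- FALSE
    res <- try({
      for (it in seq_len(control$max_iters)) {
        es <- mph_estep(m, pairs)
        ll <- sum(vapply(es, `[[`, 0, "loglik"))
        trace <- c(trace, ll)
        if (control$verbose)
          message(sprintf("restart %d iter %d loglik %.6f", rs, it, ll))
        if (it > 1L) {
          rel <- (ll - trace[it - 1L]) / max(1, abs(trace[it - 1L]))
          if (abs(rel) < control$tol) {
            converged <- TRUE
            break
          }
        }
        if (it < control$max_iters) m <- mph_mstep(m, es, pairs, control)
      }
      TRUE
    }, silent = TRUE)
    ok <- !inherits(res, "try-error") && length(trace) > 0
    rows[[rs]] <- data.frame(restart = rs,
                             loglik = if (ok) trace[length(trace)] else NA,
                             n_iter = length(trace), converged = converged,
                             error = if (ok) "" else as.character(res))
    if (ok && (is.null(best) || trace[length(trace)] > best$loglik)) {
      best <- list(model = m, loglik = trace[length(trace)], trace = trace,
                   n_iter = length(trace), converged = converged)
    }
  }
  restarts <- do.call(rbind, rows)
  if (is.null(best))
    stop("all EM restarts failed:\n",
         paste(restarts$error, collapse = "\n"))
  structure(c(best, list(restarts = restarts, pairs = pairs,
                         control = control)),
            class = "mph_fit")
}
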