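# Stimulus-response pair container and CSV/JSON readers/writers.

#' Stimulus-response pair
#'
#' Holds an embedded stimulus sequence (d x Tx matrix, one embedded vector
#' per stimulus bin) and a binned response sequence on the same time base.
#'
#' @param stimulus d x Tx numeric matrix of embedded stimulus vectors (use
#'   \code{\link{embed_stimulus}} to build it from a raw channels x T
#'   stimulus).
#' @param response integer vector of response symbols in \code{0..V-1}
#'   (typically 0/1 spike counts).
#' @param bin_width bin width in seconds.
#' @param V response alphabet size.
#' @return An object of class \code{"mph_pair"}.
#' @export
mph_pair <- function(stimulus, response, bin_width = 1, V = 2L) {
  stimulus <- as.matrix(stimulus)
  response <- as.integer(response)
  if (ncol(stimulus) < 1L || length(response) < 1L)
    stop("stimulus and response must be non-empty")
  if (anyNA(stimulus) || anyNA(response)) stop("missing values in pair")
  if (any(response < 0L | response >= V))
    stop("response symbols outside alphabet 0..", V - 1L)
  structure(list(stimulus = stimulus, response = response,
                 bin_width = bin_width, V = as.integer(V)),
            class = "mph_pair")
}

as_pair_list <- function(pairs) {
  if (inherits(pairs, "mph_pair")) list(pairs) else pairs
}

#' Split one long pair into equal-length sequences
#'
#' @param pair an \code{\link{mph_pair}}.
#' @param len sequence length in bins; a trailing remainder shorter than
#'   \code{len} is dropped.
#' @return List of \code{mph_pair} objects.
#' @export
split_pair <- function(pair, len) {
  Tn <- ncol(pair$stimulus)
  starts <- seq(1L, Tn - len + 1L, by = len)
  lapply(starts, function(s) {
    idx <- s:(s + len - 1L)
    mph_pair(pair$stimulus[, idx, drop = FALSE], pair$response[idx],
             pair$bin_width, pair$V)
  })
}

#' Write / read a stimulus-response pair as CSV
#'
#' Plain-text interchange format: one row per time bin, first column the
#' response symbol, remaining columns the embedded stimulus dimensions.  The
#' bin width is kept in a \code{# bin_width=} comment header.
#'
#' @param pair an \code{\link{mph_pair}}.
#' @param path file path.
#' @return \code{read_pair_csv} returns an \code{mph_pair};
#'   \code{write_pair_csv} returns \code{path} invisibly.
#' @export
write_pair_csv <- function(pair, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width=%.17g", pair$bin_width), con)
  df <- data.frame(response = pair$response,
                   t(pair$stimulus), check.names = FALSE)
  names(df) <- c("response", paste0("s", seq_len(nrow(pair$stimulus))))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pair_csv
#' @export
read_pair_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# bin_width=", first))
    stop("missing bin_width header in ", path)
  bw <- as.numeric(sub("^# bin_width=", "", first))
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"response" %in% names(df)) stop("missing response column in ", path)
  num <- as.matrix(df[setdiff(names(df), "response")])
  if (anyNA(num) || !is.numeric(num))
    stop("non-numeric stimulus values in ", path)
  r <- df$response
  if (anyNA(r) || any(r != round(r)))
    stop("non-integer response values in ", path)
  stim <- t(num)
  dimnames(stim) <- NULL
  mph_pair(stim, as.integer(r), bin_width = bw,
           V = max(2L, max(r) + 1L))
}

# ---- model JSON serialization -------------------------------------------

# matrices/arrays are flattened column-major for JSON; dims are implied by
# the model structure
emission_to_list <- function(em) {
  if (inherits(em, "mph_gm")) {
    list(type = "gm", weights = em$weights, means = as.numeric(em$means),
         covs = as.numeric(em$covs), cov_mode = em$cov_mode,
         mean_mode = em$mean_mode)
  } else if (inherits(em, "mph_discrete")) {
    list(type = "discrete", probs = em$probs, mode = em$mode)
  } else {
    list(type = "mixed", marginal = emission_to_list(em$marginal),
         conditional = lapply(em$conditional, emission_to_list))
  }
}

emission_from_list <- function(x, d) {
  if (x$type == "gm") {
    K <- length(x$weights)
    gm_emission(matrix(unlist(x$means), d, K),
                array(unlist(x$covs), dim = c(d, d, K)),
                unlist(x$weights), unlist(x$cov_mode), unlist(x$mean_mode))
  } else if (x$type == "discrete") {
    discrete_emission(unlist(x$probs), x$mode)
  } else {
    mixed_emission(emission_from_list(x$marginal, d),
                   lapply(x$conditional, emission_from_list, d = d))
  }
}

#' Write / read an MPH model as JSON
#'
#' All numeric parameters are written at full precision so a round trip
#' reproduces the model exactly.
#'
#' @param model an \code{\link{mph_model}}.
#' @param path file path.
#' @return \code{read_mph_json} returns an \code{mph_model};
#'   \code{write_mph_json} returns \code{path} invisibly.
#' @export
write_mph_json <- function(model, path) {
  x <- list(
    band_width = model$band_width, V = model$V,
    embedding = unclass(model$embedding),
    transitions = as.numeric(model$transitions), initial = model$initial,
    final = model$final,
    states = lapply(model$states, function(st)
      list(kind = st$kind, label = st$label,
           emission = emission_to_list(st$emission))))
  writeLines(jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_mph_json
#' @export
read_mph_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  emb <- stimulus_embedding(x$embedding$window_length,
                            x$embedding$channels, x$embedding$offset)
  d <- emb$d
  N <- length(x$states)
  states <- lapply(x$states, function(st)
    mph_state(st$kind, emission_from_list(st$emission, d), st$label))
  mph_model(states = states,
            transitions = matrix(unlist(x$transitions), N, N),
            initial = unlist(x$initial), final = unlist(x$final),
            band_width = x$band_width, embedding = emb, V = x$V)
}
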