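#' Train of synaptic events
#'
#' A time-ordered sequence of synaptic events for a set of neurons.  Event
#' `n` occurs at `times[n]` (ms) and delivers the dimensionless jumps
#' `w_e[n, a]`, `w_i[n, a]` to neuron `a`; every event must carry a positive
#' total jump over the neuron set.
#'
#' @param times Strictly increasing event times, ms.
#' @param w_e,w_i Jump matrices (events x neurons); vectors are treated as
#'   single-neuron columns.
#' @param horizon Length-2 numeric `(t_start, t_end)` in ms containing all
#'   event times.
#' @param rate_hz Nominal population event rate b (metadata), Hz.
#' @return An object of class `event_train`.
#' @export
event_train <- function(times, w_e, w_i, horizon = NULL, rate_hz = NA_real_) {
  if (is.vector(w_e)) w_e <- matrix(w_e, ncol = 1L)
  if (is.vector(w_i)) w_i <- matrix(w_i, ncol = 1L)
  stopifnot(length(times) == nrow(w_e), all(dim(w_e) == dim(w_i)))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("event times must be strictly increasing")
  if (any(w_e < 0) || any(w_i < 0) || any(!is.finite(cbind(w_e, w_i))))
    stop("jumps must be finite and nonnegative")
  if (length(times) && any(rowSums(w_e) + rowSums(w_i) <= 0))
    stop("every event must carry a positive total jump")
  if (is.null(horizon))
    horizon <- if (length(times)) range(times) else c(0, 0)
  stopifnot(length(horizon) == 2L, horizon[1] <= horizon[2])
  if (length(times) && (times[1] < horizon[1] || times[length(times)] > horizon[2]))
    stop("event times must lie within the horizon")
  structure(list(times = times, w_e = w_e, w_i = w_i,
                 horizon = horizon, rate_hz = rate_hz),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("Event train: %d events over [%g, %g] ms, %d neuron(s)",
              length(x$times), x$horizon[1], x$horizon[2], ncol(x$w_e)))
  if (is.finite(x$rate_hz)) cat(sprintf(" (nominal rate %.4g Hz)", x$rate_hz))
  cat("\n")
  invisible(x)
}

#' @export
length.event_train <- function(x) length(x$times)

#' Read and write event trains
#'
#' Tab-separated text with one row per (event, neuron) pair and columns
#' `time_ms`, `neuron_id`, `w_e`, `w_i`; `#`-prefixed header lines carry
#' metadata.  Rows sharing a time belong to the same population event.
#'
#' @param train An [event_train()].
#' @param path File path.
#' @return `read_event_train()` returns an [event_train()];
#'   `write_event_train()` returns `path` invisibly.
#' @export
write_event_train <- function(train, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# event_train horizon_ms=%g,%g rate_hz=%g neurons=%d",
                     train$horizon[1], train$horizon[2], train$rate_hz,
                     ncol(train$w_e)), con)
  writeLines("# time_ms\tneuron_id\tw_e\tw_i", con)
  if (length(train$times)) {
    nn <- ncol(train$w_e)
    for (a in seq_len(nn)) {
      sel <- train$w_e[, a] + train$w_i[, a] > 0
      if (!any(sel)) next
      df <- data.frame(time_ms = train$times[sel], neuron_id = a,
                       w_e = train$w_e[sel, a], w_i = train$w_i[sel, a])
      if (a == 1L) all_df <- df else all_df <- rbind(all_df, df)
    }
    all_df <- all_df[order(all_df$time_ms, all_df$neuron_id), ]
    utils::write.table(format(all_df, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_event_train
#' @export
read_event_train <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  horizon <- c(0, 0); rate <- NA_real_; nn <- NA_integer_
  m <- regmatches(meta, regexec("horizon_ms=([-0-9.e+]+),([-0-9.e+]+) rate_hz=([-0-9.eNA+]+) neurons=([0-9]+)", meta))
  m <- Filter(length, m)
  if (length(m)) {
    horizon <- as.numeric(m[[1]][2:3])
    rate <- suppressWarnings(as.numeric(m[[1]][4]))
    nn <- as.integer(m[[1]][5])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    nn <- if (is.na(nn)) 1L else nn
    return(event_train(numeric(0), matrix(0, 0, nn), matrix(0, 0, nn),
                       horizon = horizon, rate_hz = rate))
  }
  df <- utils::read.table(text = body, sep = "\t",
                          col.names = c("time_ms", "neuron_id", "w_e", "w_i"))
  if (is.na(nn)) nn <- max(df$neuron_id)
  times <- sort(unique(df$time_ms))
  idx <- match(df$time_ms, times)
  w_e <- matrix(0, length(times), nn)
  w_i <- matrix(0, length(times), nn)
  w_e[cbind(idx, df$neuron_id)] <- df$w_e
  w_i[cbind(idx, df$neuron_id)] <- df$w_i
  event_train(times, w_e, w_i, horizon = horizon, rate_hz = rate)
}

#' Per-input spike trains
#'
#' A `spike_list` records individual input spikes: time (ms), input id, pool
#' tag (`"e"`/`"i"`) and the neuron set each spike is delivered to.  A
#' `catalog` attribute maps input ids to their weight and rate metadata so
#' spike lists can be folded into synaptic events ([spikes_to_events()]).
#'
#' @param time_ms Spike times, ms.
#' @param input_id Character input identifiers.
#' @param pool `"e"` or `"i"` per spike.
#' @param neurons Character neuron-set labels, comma-separated indices
#'   (e.g. `"1"` or `"1,2"`).
#' @param horizon Length-2 time window, ms.
#' @param catalog Optional data frame `(input_id, pool, neurons, w, rate_hz)`.
#' @return An object of class `spike_list` (a data frame, sorted by time).
#' @export
spike_list <- function(time_ms, input_id, pool, neurons, horizon = NULL,
                       catalog = NULL) {
  df <- data.frame(time_ms = time_ms, input_id = as.character(input_id),
                   pool = as.character(pool), neurons = as.character(neurons),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time_ms, df$input_id), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(horizon))
    horizon <- if (nrow(df)) range(df$time_ms) else c(0, 0)
  structure(df, horizon = horizon, catalog = catalog,
            class = c("spike_list", "data.frame"))
}

#' @export
print.spike_list <- function(x, ...) {
  cat(sprintf("Spike list: %d spikes from %d input(s) over [%g, %g] ms\n",
              nrow(x), length(unique(x$input_id)),
              attr(x, "horizon")[1], attr(x, "horizon")[2]))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @rdname spike_list
#' @param spikes A `spike_list`.
#' @param path File path (tab-separated:
#'   `time_ms  input_id  pool  neuron_ids`).
#' @export
write_spike_list <- function(spikes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  h <- attr(spikes, "horizon")
  writeLines(sprintf("# spike_list horizon_ms=%g,%g", h[1], h[2]), con)
  writeLines("# time_ms\tinput_id\tpool\tneuron_ids", con)
  if (nrow(spikes))
    utils::write.table(format(as.data.frame(spikes), digits = 17,
                              scientific = FALSE, trim = TRUE),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname spike_list
#' @export
read_spike_list <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  horizon <- NULL
  m <- Filter(length, regmatches(meta, regexec("horizon_ms=([-0-9.e+]+),([-0-9.e+]+)", meta)))
  if (length(m)) horizon <- as.numeric(m[[1]][2:3])
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(spike_list(numeric(0), character(0), character(0), character(0),
                      horizon = horizon))
  df <- utils::read.table(text = body, sep = "\t", colClasses =
                            c("numeric", "character", "character", "character"),
                          col.names = c("time_ms", "input_id", "pool", "neurons"))
  spike_list(df$time_ms, df$input_id, df$pool, df$neurons, horizon = horizon)
}
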