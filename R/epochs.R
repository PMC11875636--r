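#' Labelled single-subject EEG epochs
#'
#' The universal exchange container: a `trials x channels x samples` array of
#' epoched EEG with a uniform time grid relative to the motor-imagery cue
#' (cue at t = 0), binary condition labels (0 = natural thumb, 1 =
#' supernumerary thumb) and a pre-cue baseline window.
#'
#' @param subject_id subject label.
#' @param data numeric array `trials x channels x samples`.
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_names ordered channel labels, length = `dim(data)[2]`.
#' @param times sample times in seconds relative to the cue; strictly
#'   increasing uniform grid with step `1/sampling_rate`, length =
#'   `dim(data)[3]`.
#' @param labels integer vector in `{0, 1}`, length = `dim(data)[1]`.
#' @param baseline_window `c(start, end)` in seconds; must precede the cue
#'   (`end <= 0`).
#' @return An object of class `bfn_epochs`.
#' @export
epochs_set <- function(subject_id, data, sampling_rate, channel_names,
                       times, labels, baseline_window) {
  data <- unname(data)
  if (length(dim(data)) != 3)
    stop_config("data must be a trials x channels x samples array")
  d <- dim(data)
  if (length(channel_names) != d[2])
    stop_config("channel_names length (%d) != channel dimension (%d)",
                length(channel_names), d[2])
  if (length(times) != d[3])
    stop_config("times length (%d) != sample dimension (%d)",
                length(times), d[3])
  if (length(labels) != d[1])
    stop_config("labels length (%d) != trial dimension (%d)",
                length(labels), d[1])
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop_config("labels must be 0 (natural) or 1 (supernumerary)")
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1 / sampling_rate)) > 1e-6 / sampling_rate)
    stop_config("times must be strictly increasing with step 1/sampling_rate")
  if (length(baseline_window) != 2 || baseline_window[2] > 1e-12)
    stop_config("baseline_window must end at or before the cue (t = 0)")
  if (baseline_window[1] < times[1] - 1e-9)
    stop_config("baseline_window starts before the epoch")
  structure(list(subject_id = as.character(subject_id),
                 sampling_rate = sampling_rate,
                 channel_names = as.character(channel_names),
                 times = as.numeric(times),
                 data = data,
                 labels = labels,
                 baseline_window = as.numeric(baseline_window)),
            class = "bfn_epochs")
}

#' @export
print.bfn_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<bfn_epochs> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
    x$subject_id, d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  t = [%.3f, %.3f] s, baseline [%.3f, %.3f] s, labels: %d/%d\n",
              min(x$times), max(x$times), x$baseline_window[1],
              x$baseline_window[2], sum(x$labels == 0), sum(x$labels == 1)))
  invisible(x)
}

#' Restrict epochs to a channel subset and/or time window
#'
#' @param epochs a [epochs_set()] object.
#' @param channels channel labels to keep (order preserved as given);
#'   unknown labels raise an error.
#' @param window `c(start, end)` seconds; samples with
#'   `start <= t < end` are kept. `NULL` keeps everything.
#' @return a new `bfn_epochs` object. The baseline window is clipped into
#'   the retained time range (it may become empty when cropping to the
#'   post-cue period, in which case it is set to the first retained sample).
#' @export
crop_epochs <- function(epochs, channels = NULL, window = NULL) {
  ci <- seq_along(epochs$channel_names)
  if (!is.null(channels)) {
    ci <- match(channels, epochs$channel_names)
    if (anyNA(ci))
      stop_config("unknown channel(s): %s",
                  paste(channels[is.na(ci)], collapse = ", "))
  }
  ti <- seq_along(epochs$times)
  if (!is.null(window))
    ti <- which(epochs$times >= window[1] - 1e-9 & epochs$times < window[2] - 1e-9)
  if (!length(ti)) stop_config("time window retains no samples")
  out <- epochs
  out$data <- epochs$data[, ci, ti, drop = FALSE]
  out$channel_names <- epochs$channel_names[ci]
  out$times <- epochs$times[ti]
  bw <- c(max(epochs$baseline_window[1], out$times[1]),
          min(epochs$baseline_window[2], out$times[length(ti)]))
  if (bw[1] >= bw[2]) bw <- c(out$times[1], out$times[1])
  out$baseline_window <- pmin(bw, 0)
  out
}
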