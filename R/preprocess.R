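#' Continuous multichannel EEG recording
#'
#' Light container for a raw (continuous) recording: a channels-by-time
#' matrix in microvolts, its sampling rate, and the event markers that will
#' later anchor single-trial epochs.
#'
#' @param samples Numeric matrix, channels x time points (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional character vector, one name per channel.
#' @param events Optional data frame with columns `onset` (1-based sample
#'   index of the task cue) and `label` (+1 / -1 class code).
#'
#' @return An object of class `mi_recording`.
#' @export
raw_recording <- function(samples, fs, channel_names = NULL, events = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || nrow(samples) < 1) {
    abort("`samples` must be a numeric matrix with at least one channel.",
          class = "micsp_error_data")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).",
          class = "micsp_error_data")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  stopifnot(length(channel_names) == nrow(samples))
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    if (!all(c("onset", "label") %in% names(events))) {
      abort("`events` needs columns `onset` and `label`.",
            class = "micsp_error_data")
    }
    check_labels(events$label)
    bad <- events$onset < 1 | events$onset > ncol(samples)
    if (any(bad)) {
      abort(sprintf("Event onsets outside the recording: %s.",
                    paste(which(bad), collapse = ", ")),
            class = "micsp_error_epoch")
    }
  }
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         events = events),
    class = "mi_recording"
  )
}

#' @export
print.mi_recording <- function(x, ...) {
  cat(sprintf("<mi_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Band-pass filter specification
#'
#' Describes a Butterworth band-pass. `order` is the overall filter order of
#' the band-pass (an order-6 band-pass uses an order-3 low/high prototype).
#' `zero_phase` applies the filter forward and backward, cancelling group
#' delay at the price of non-causality; `causal` applies a single forward
#' pass.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low_hz < high_hz`.
#' @param order Even overall band-pass order (default 6).
#' @param phase_mode `"zero_phase"` (default) or `"causal"`.
#'
#' @return An object of class `mi_bandpass`.
#' @export
bandpass_spec <- function(low_hz, high_hz, order = 6,
                          phase_mode = c("zero_phase", "causal")) {
  phase_mode <- match.arg(phase_mode)
  if (!(low_hz > 0 && high_hz > low_hz)) {
    abort("Need 0 < low_hz < high_hz.", class = "micsp_error_band")
  }
  if (order < 2 || order %% 2 != 0) {
    abort("`order` must be an even integer >= 2 for a band-pass.",
          class = "micsp_error_band")
  }
  structure(
    list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
         family = "butterworth", phase_mode = phase_mode),
    class = "mi_bandpass"
  )
}

# Butterworth coefficients for a spec at sampling rate fs.
butter_coefficients <- function(spec, fs, call = rlang::caller_env()) {
  if (spec$high_hz >= fs / 2) {
    abort(sprintf("Band edge %g Hz is at or above Nyquist (%g Hz).",
                  spec$high_hz, fs / 2),
          class = "micsp_error_band", call = call)
  }
  signal::butter(spec$order / 2,
                 c(spec$low_hz, spec$high_hz) / (fs / 2),
                 type = "pass")
}

apply_bandpass <- function(x, ba, phase_mode) {
  if (phase_mode == "zero_phase") {
    as.numeric(signal::filtfilt(ba, x))
  } else {
    as.numeric(signal::filter(ba, x))
  }
}

#' Band-pass filter a continuous recording
#'
#' Filters each channel independently with the Butterworth band-pass
#' described by `spec`. Sampling rate, shape, names and events are preserved.
#'
#' @param rec An [raw_recording()] object.
#' @param spec An [bandpass_spec()] object.
#'
#' @return A filtered `mi_recording`.
#' @export
bandpass_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "mi_recording"), inherits(spec, "mi_bandpass"))
  if (!all(is.finite(rec$samples))) {
    abort("Recording contains non-finite samples.",
          class = "micsp_error_data")
  }
  if (ncol(rec$samples) <= 3 * spec$order) {
    abort("Recording shorter than 3x the filter order.",
          class = "micsp_error_data")
  }
  ba <- butter_coefficients(spec, rec$fs)
  filtered <- t(apply(rec$samples, 1, apply_bandpass, ba = ba,
                      phase_mode = spec$phase_mode))
  out <- rec
  out$samples <- filtered
  out
}

#' Extract single-trial epochs around event markers
#'
#' Cuts one trial per event, using a time window stated in seconds relative
#' to the cue (0 s = cue onset). Windows are half-open in samples:
#' `[onset + round(t_start*fs), onset + round(t_start*fs) + K)` with
#' `K = round((t_end - t_start) * fs)`.
#'
#' @param rec An [raw_recording()] with events.
#' @param window Length-2 numeric `(t_start_s, t_end_s)` relative to the cue.
#'
#' @return An [epoch_set()] object.
#' @export
extract_epochs <- function(rec, window) {
  stopifnot(inherits(rec, "mi_recording"))
  if (is.null(rec$events) || nrow(rec$events) == 0) {
    abort("Recording has no events to epoch around.",
          class = "micsp_error_epoch")
  }
  stopifnot(length(window) == 2, window[2] > window[1])
  fs <- rec$fs
  K <- round((window[2] - window[1]) * fs)
  starts <- rec$events$onset + round(window[1] * fs)
  bad <- starts < 1 | (starts + K - 1) > ncol(rec$samples)
  if (any(bad)) {
    abort(sprintf("Window does not fit the recording for events: %s.",
                  paste(which(bad), collapse = ", ")),
          class = "micsp_error_epoch")
  }
  n <- nrow(rec$events)
  data <- array(0, dim = c(n, nrow(rec$samples), K))
  for (i in seq_len(n)) {
    data[i, , ] <- rec$samples[, starts[i]:(starts[i] + K - 1)]
  }
  epoch_set(data, rec$events$label, fs, window = window,
            channel_names = rec$channel_names)
}

#' Epoched two-class EEG trials
#'
#' The unit every downstream stage consumes: a trials x channels x samples
#' array with per-trial +1/-1 labels, the sampling rate and the epoching
#' window.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param labels Numeric vector of +1/-1, one per trial; both classes must
#'   be represented.
#' @param fs Sampling rate in Hz.
#' @param window Optional `(t_start_s, t_end_s)` the epochs were cut with.
#' @param channel_names Optional channel names.
#'
#' @return An object of class `mi_epochs`.
#' @export
epoch_set <- function(data, labels, fs, window = NULL, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("`data` must be a 3-D array (trials x channels x samples).",
          class = "micsp_error_data")
  }
  check_labels(labels)
  if (length(labels) != dim(data)[1]) {
    abort("One label per trial required.", class = "micsp_error_data")
  }
  if (!any(labels == 1) || !any(labels == -1)) {
    abort("Both classes (+1 and -1) must have at least one trial.",
          class = "micsp_error_data")
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(dim(data)[2]))
  structure(
    list(data = data, labels = as.numeric(labels), fs = fs,
         window = window, channel_names = channel_names),
    class = "mi_epochs"
  )
}

#' @export
print.mi_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<mi_epochs> %d trials (%d/+1, %d/-1) x %d channels x %d samples @ %g Hz\n",
    d[1], sum(x$labels == 1), sum(x$labels == -1), d[2], d[3], x$fs))
  invisible(x)
}

#' Band-pass filter epoched trials
#'
#' Applies the band-pass to every channel of every trial. Useful when data
#' arrive already epoched (e.g. from the synthetic generator); for continuous
#' data prefer filtering before [extract_epochs()] so filter transients fall
#' outside the analysis window.
#'
#' @inheritParams bandpass_filter
#' @param epochs An [epoch_set()] object.
#' @return A filtered `mi_epochs`.
#' @export
bandpass_epochs <- function(epochs, spec) {
  stopifnot(inherits(epochs, "mi_epochs"), inherits(spec, "mi_bandpass"))
  ba <- butter_coefficients(spec, epochs$fs)
  d <- dim(epochs$data)
  out <- epochs
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      out$data[i, c, ] <- apply_bandpass(epochs$data[i, c, ], ba,
                                         spec$phase_mode)
    }
  }
  out
}
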