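#' Build an overlapping Butterworth filter bank
#'
#' Equal-width bands `[low + i*step, low + i*step + width]` for
#' `i = 0, 1, ...` while the upper edge stays at or below `high`. The
#' default (8-30 Hz, 4 Hz wide, 2 Hz step) yields the ten 50%-overlapping
#' sensorimotor bands 8-12, 10-14, ..., 26-30 Hz.
#'
#' @param low_hz,high_hz Range covered by the bank (Hz).
#' @param width_hz Width of each band (Hz).
#' @param step_hz Offset between consecutive low edges (Hz).
#' @param order Overall Butterworth order used per band (default 6).
#'
#' @return An object of class `mi_filter_bank`: a `bands` tibble
#'   (`band`, `low_hz`, `high_hz`) and the per-band `order`.
#' @export
make_filter_bank <- function(low_hz = 8, high_hz = 30, width_hz = 4,
                             step_hz = 2, order = 6) {
  if (step_hz <= 0) abort("`step_hz` must be positive.",
                          class = "micsp_error_bank")
  if (width_hz > high_hz - low_hz) {
    abort(sprintf("Band width %g Hz exceeds the range %g-%g Hz: empty bank.",
                  width_hz, low_hz, high_hz),
          class = "micsp_error_bank")
  }
  n <- floor((high_hz - low_hz - width_hz) / step_hz) + 1
  lows <- low_hz + (seq_len(n) - 1) * step_hz
  structure(
    list(bands = tibble::tibble(band = seq_len(n), low_hz = lows,
                                high_hz = lows + width_hz),
         order = as.integer(order)),
    class = "mi_filter_bank"
  )
}

#' @export
print.mi_filter_bank <- function(x, ...) {
  cat(sprintf("<mi_filter_bank> %d bands, order %d:\n",
              nrow(x$bands), x$order))
  cat(paste(sprintf("  %g-%g Hz", x$bands$low_hz, x$bands$high_hz),
            collapse = "\n"), "\n")
  invisible(x)
}
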