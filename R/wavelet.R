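# Daubechies-4 (db4, 8-tap) analysis filters, frozen at full precision.
# Orthonormal pair: sum(lo^2) = 1 and hi is the quadrature mirror of lo.
DB4_DEC_LO <- c(
  -0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
  -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
  0.71484657055291567, 0.23037781330889651)
DB4_DEC_HI <- c(
  -0.23037781330889651, 0.71484657055291567, -0.63088076792985892,
  -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
  -0.032883011666885197, -0.010597401785069032)

# One analysis level, periodized boundary. Odd lengths are padded by
# repeating the last sample. Circular convolution offset F/2 keeps the
# transform orthonormal, so sub-band energies sum exactly to signal energy
# when the length is even at every level.
dwt_step_periodic <- function(x) {
  if (length(x) %% 2 == 1) x <- c(x, x[length(x)])
  n <- length(x)
  Fl <- length(DB4_DEC_LO)
  k <- 2 * (seq_len(n / 2) - 1) + Fl / 2
  idx <- (outer(k, seq_len(Fl) - 1, `-`) %% n) + 1
  xs <- matrix(x[idx], nrow = n / 2)
  list(approx = as.numeric(xs %*% DB4_DEC_LO),
       detail = as.numeric(xs %*% DB4_DEC_HI))
}

# One analysis level, half-point symmetric extension; output length
# floor((n + F - 1) / 2). Not energy-preserving but free of wrap-around.
dwt_step_symmetric <- function(x) {
  n <- length(x)
  Fl <- length(DB4_DEC_LO)
  ext <- c(rev(x[seq_len(Fl - 1)]), x, rev(x[seq(n - Fl + 2, n)]))
  conv_band <- function(h) {
    full <- stats::convolve(ext, rev(h), type = "open")
    valid <- full[Fl:(length(ext))]
    valid[seq(2, length(valid), by = 2)]
  }
  list(approx = conv_band(DB4_DEC_LO), detail = conv_band(DB4_DEC_HI))
}

dwt_step <- function(x, boundary_mode) {
  switch(boundary_mode,
         periodization = dwt_step_periodic(x),
         symmetric = dwt_step_symmetric(x),
         abort(sprintf("Unknown boundary mode `%s`.", boundary_mode),
               class = "micsp_error_plan"))
}

#' Plan a wavelet decomposition for a sampling rate
#'
#' Chooses the decomposition depth and the terminal sub-band layout for a
#' db4 discrete wavelet transform (`dwt`) or wavelet packet decomposition
#' (`wpd`). The default depth is 3 for sampling rates up to 128 Hz and 4
#' above (250 Hz and 256 Hz therefore share a plan), both overridable.
#' Terminal intervals follow the ideal dyadic edges: the DWT tiles
#' `(0, fs/2]` as `A_L, D_L, ..., D_1`, the WPD into `2^L` equal bands.
#' Sub-bands are selected by the rule given: by default every band whose
#' interval intersects the 8-30 Hz sensorimotor range is retained; a
#' stricter fully-within rule and an explicit index list are available.
#'
#' @param fs Sampling rate in Hz.
#' @param transform `"dwt"` or `"wpd"`.
#' @param levels Decomposition depth; default 3 if `fs <= 128` else 4.
#' @param selection_rule `"intersect_8_30"` (default), `"within_8_30"`, or
#'   `"explicit"` (then `selected` must be given).
#' @param selected Integer indices into the frequency-ordered terminal bands
#'   when `selection_rule = "explicit"`.
#' @param boundary_mode `"periodization"` (default; exactly
#'   energy-preserving) or `"symmetric"`.
#' @param band Frequency range of interest for the selection rules
#'   (default `c(8, 30)` Hz).
#'
#' @return An object of class `mi_wavelet_plan`: the depth, an `intervals`
#'   tibble (frequency-ascending terminal bands with labels), and the
#'   `selected` indices.
#' @export
plan_wavelet <- function(fs, transform = c("dwt", "wpd"), levels = NULL,
                         selection_rule = c("intersect_8_30", "within_8_30",
                                            "explicit"),
                         selected = NULL,
                         boundary_mode = c("periodization", "symmetric"),
                         band = c(8, 30)) {
  transform <- match.arg(transform)
  selection_rule <- match.arg(selection_rule)
  boundary_mode <- match.arg(boundary_mode)
  if (is.null(levels)) levels <- if (fs <= 128) 3L else 4L
  levels <- as.integer(levels)
  if (levels < 1) abort("`levels` must be >= 1.", class = "micsp_error_plan")
  width <- fs / 2^(levels + 1)
  if (width < 0.5) {
    abort(sprintf(
      "Sampling rate %g Hz is too low for %d levels (terminal bands %.3g Hz wide).",
      fs, levels, width), class = "micsp_error_plan")
  }
  if (transform == "dwt") {
    lows <- c(0, fs / 2^seq(levels + 1, 2))
    highs <- fs / 2^seq(levels + 1, 1)
    labels <- c(paste0("A", levels), paste0("D", seq(levels, 1)))
  } else {
    nb <- 2^levels
    lows <- (seq_len(nb) - 1) * width
    highs <- seq_len(nb) * width
    labels <- paste0("W", seq_len(nb) - 1)
  }
  intervals <- tibble::tibble(band = seq_along(lows), label = labels,
                              low_hz = lows, high_hz = highs)
  selected <- switch(
    selection_rule,
    intersect_8_30 = which(highs > band[1] & lows < band[2]),
    within_8_30 = which(lows >= band[1] & highs <= band[2]),
    explicit = {
      if (is.null(selected)) {
        abort("`selected` is required with the explicit rule.",
              class = "micsp_error_plan")
      }
      sel <- as.integer(selected)
      if (!all(sel %in% intervals$band)) {
        abort("Explicit `selected` indices outside the terminal bands.",
              class = "micsp_error_plan")
      }
      sel
    }
  )
  if (length(selected) == 0) {
    abort("No sub-band selected by the rule; nothing to extract.",
          class = "micsp_error_plan")
  }
  structure(
    list(wavelet = "db4", levels = levels, transform = transform,
         boundary_mode = boundary_mode, intervals = intervals,
         selected = sort(selected), selection_rule = selection_rule,
         fs = fs),
    class = "mi_wavelet_plan"
  )
}

#' @export
print.mi_wavelet_plan <- function(x, ...) {
  cat(sprintf("<mi_wavelet_plan> db4 %s, %d levels @ %g Hz, %d/%d bands selected\n",
              x$transform, x$levels, x$fs, length(x$selected),
              nrow(x$intervals)))
  sel <- x$intervals[x$intervals$band %in% x$selected, ]
  cat(paste(sprintf("  %s: %.4g-%.4g Hz", sel$label, sel$low_hz, sel$high_hz),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Wavelet coefficients of the selected DWT sub-bands
#'
#' Runs an `L`-level db4 discrete wavelet transform and returns the
#' coefficient vectors of the sub-bands the plan selected, in
#' frequency-ascending order (`A_L`, `D_L`, ..., `D_1`).
#'
#' @param x Numeric signal (one projected channel of one trial).
#' @param plan A [plan_wavelet()] result with `transform = "dwt"`.
#' @return Named list of coefficient vectors, one per selected sub-band.
#' @export
dwt_subband_coeffs <- function(x, plan) {
  stopifnot(inherits(plan, "mi_wavelet_plan"))
  if (plan$transform != "dwt") {
    abort("Plan is not a DWT plan.", class = "micsp_error_plan")
  }
  if (length(x) < 2^plan$levels) {
    abort(sprintf("Signal of length %d too short for %d levels.",
                  length(x), plan$levels),
          class = "micsp_error_decomposition")
  }
  approx <- x
  details <- vector("list", plan$levels)
  for (l in seq_len(plan$levels)) {
    s <- dwt_step(approx, plan$boundary_mode)
    details[[l]] <- s$detail
    approx <- s$approx
  }
  # frequency-ascending: A_L, D_L, ..., D_1
  bands <- c(list(approx), rev(details))
  names(bands) <- plan$intervals$label
  bands[plan$selected]
}

#' Wavelet coefficients of the selected WPD sub-bands
#'
#' Runs a full depth-`L` db4 wavelet packet decomposition. Terminal nodes
#' are kept in natural frequency order (the low/high outputs of a split are
#' swapped at odd positions, undoing the Paley ordering of the raw tree)
#' before intervals are assigned and the selection applied.
#'
#' @inheritParams dwt_subband_coeffs
#' @param plan A [plan_wavelet()] result with `transform = "wpd"`.
#' @return Named list of coefficient vectors, one per selected sub-band.
#' @export
wpd_subband_coeffs <- function(x, plan) {
  stopifnot(inherits(plan, "mi_wavelet_plan"))
  if (plan$transform != "wpd") {
    abort("Plan is not a WPD plan.", class = "micsp_error_plan")
  }
  if (length(x) < 2^plan$levels) {
    abort(sprintf("Signal of length %d too short for %d levels.",
                  length(x), plan$levels),
          class = "micsp_error_decomposition")
  }
  nodes <- list(x)
  for (l in seq_len(plan$levels)) {
    nxt <- vector("list", 2 * length(nodes))
    for (p in seq_along(nodes)) {
      s <- dwt_step(nodes[[p]], plan$boundary_mode)
      if (p %% 2 == 1) {        # frequency position even (0-based): keep order
        nxt[[2 * p - 1]] <- s$approx
        nxt[[2 * p]] <- s$detail
      } else {                  # odd position: spectrum is mirrored, swap
        nxt[[2 * p - 1]] <- s$detail
        nxt[[2 * p]] <- s$approx
      }
    }
    nodes <- nxt
  }
  names(nodes) <- plan$intervals$label
  nodes[plan$selected]
}

#' Energy of a coefficient vector
#'
#' Sum of squared wavelet coefficients of one sub-band.
#'
#' @param coeffs Numeric coefficient vector.
#' @return A scalar, `sum(coeffs^2)`.
#' @export
subband_energy <- function(coeffs) {
  if (length(coeffs) == 0) {
    abort("Empty coefficient vector.", class = "micsp_error_data")
  }
  sum(coeffs^2)
}

#' Sample standard deviation of a coefficient vector
#'
#' Standard deviation with the `n - 1` divisor, as conventional for the
#' sub-band spread statistic.
#'
#' @param coeffs Numeric coefficient vector of length at least 2.
#' @return A scalar standard deviation.
#' @export
subband_std <- function(coeffs) {
  if (length(coeffs) < 2) {
    abort("Need at least 2 coefficients for a standard deviation.",
          class = "micsp_error_data")
  }
  stats::sd(coeffs)
}
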