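#' Wavelet sub-band energy/spread features of CSP-projected trials
#'
#' For every projected channel of every trial, an `L`-level db4 DWT is run
#' and the energy and sample standard deviation of each selected sub-band's
#' coefficients are taken as features. Layout is channel-major: channel 1's
#' `(energy, std)` pairs over the `B` sub-bands (frequency-ascending), then
#' channel 2's, and so on — `P = 2m * B * 2` columns.
#'
#' @param proj An [project()] result.
#' @param plan A [plan_wavelet()] DWT plan (matching `proj`'s sampling rate).
#' @return A feature tibble (`mi_features`) with a `label` column when the
#'   projected trials carry labels.
#' @export
extract_csp_wavelet <- function(proj, plan) {
  stopifnot(inherits(proj, "mi_projected"))
  if (!inherits(plan, "mi_wavelet_plan") || plan$transform != "dwt") {
    abort("`plan` must be a DWT wavelet plan.", class = "micsp_error_plan")
  }
  extract_wavelet_common(proj, plan, dwt_subband_coeffs)
}

#' Wavelet-packet sub-band features of CSP-projected trials
#'
#' Identical layout to [extract_csp_wavelet()] but the sub-bands come from a
#' full wavelet packet decomposition (equal-width bands), giving
#' `P = 2m * B' * 2` columns for `B'` selected packet bands.
#'
#' @inheritParams extract_csp_wavelet
#' @param plan A [plan_wavelet()] WPD plan.
#' @return A feature tibble (`mi_features`).
#' @export
extract_csp_wpd <- function(proj, plan) {
  stopifnot(inherits(proj, "mi_projected"))
  if (!inherits(plan, "mi_wavelet_plan") || plan$transform != "wpd") {
    abort("`plan` must be a WPD wavelet plan.", class = "micsp_error_plan")
  }
  extract_wavelet_common(proj, plan, wpd_subband_coeffs)
}

extract_wavelet_common <- function(proj, plan, coeff_fun) {
  d <- dim(proj$data)
  sel <- plan$intervals[plan$intervals$band %in% plan$selected, ]
  B <- nrow(sel)
  info <- tidyr::expand_grid(
    channel = seq_len(d[2]),
    band_row = seq_len(B),
    statistic = c("energy", "std")
  )
  info <- dplyr::mutate(info,
    low_hz = sel$low_hz[.data$band_row],
    high_hz = sel$high_hz[.data$band_row],
    name = sprintf("ch%d_sb%g-%gHz_%s", .data$channel, .data$low_hz,
                   .data$high_hz, .data$statistic))
  vals <- matrix(0, d[1], nrow(info))
  for (i in seq_len(d[1])) {
    row <- numeric(0)
    for (ch in seq_len(d[2])) {
      coeffs <- coeff_fun(proj$data[i, ch, ], plan)
      for (b in seq_len(B)) {
        row <- c(row, subband_energy(coeffs[[b]]), subband_std(coeffs[[b]]))
      }
    }
    vals[i, ] <- row
  }
  new_features(vals, info[, c("name", "channel", "low_hz", "high_hz",
                              "statistic")],
               proj$labels)
}

#' Filter-bank log-variance features of CSP-projected trials
#'
#' Every projected channel is filtered into each band of the bank with a
#' Butterworth band-pass (zero-phase), and the natural log of the
#' (population) variance of the filtered signal is the feature. Layout is
#' band-major: band 1's `2m` channel features, then band 2's, ... —
#' `P = 2m * B''` columns.
#'
#' @inheritParams extract_csp_wavelet
#' @param bank A [make_filter_bank()] result; all edges must be below
#'   Nyquist.
#' @return A feature tibble (`mi_features`).
#' @export
extract_csp_fb <- function(proj, bank) {
  stopifnot(inherits(proj, "mi_projected"), inherits(bank, "mi_filter_bank"))
  d <- dim(proj$data)
  specs <- lapply(seq_len(nrow(bank$bands)), function(b) {
    bandpass_spec(bank$bands$low_hz[b], bank$bands$high_hz[b],
                  order = bank$order)
  })
  coefs <- lapply(specs, butter_coefficients, fs = proj$fs)
  info <- tidyr::expand_grid(band_row = seq_len(nrow(bank$bands)),
                             channel = seq_len(d[2]))
  info <- dplyr::mutate(info,
    low_hz = bank$bands$low_hz[.data$band_row],
    high_hz = bank$bands$high_hz[.data$band_row],
    statistic = "logvar",
    name = sprintf("fb%g-%gHz_ch%d_logvar", .data$low_hz, .data$high_hz,
                   .data$channel))
  vals <- matrix(0, d[1], nrow(info))
  for (i in seq_len(d[1])) {
    col <- 1L
    for (b in seq_len(nrow(bank$bands))) {
      for (ch in seq_len(d[2])) {
        y <- apply_bandpass(proj$data[i, ch, ], coefs[[b]], "zero_phase")
        vals[i, col] <- log(pop_var(y))
        col <- col + 1L
      }
    }
  }
  new_features(vals, info[, c("name", "channel", "low_hz", "high_hz",
                              "statistic")],
               proj$labels)
}
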