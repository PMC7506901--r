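#' Configuration of the synthetic two-class EEG generator
#'
#' Describes a linear-mixing model of event-related desynchronization
#' (ERD): band-limited Gaussian sources are mixed into channels and white
#' sensor noise is added. One designated source (default: a mu-band 8-12 Hz
#' source) has its variance multiplied by `variance_ratio` for class +1
#' trials only, emulating class-dependent band power. The default setting
#' mirrors a sensorimotor montage: 250 Hz sampling, 2 s trials, 12 channels
#' mixing 12 sources — one mu source (baseline variance 0.2), one beta
#' 18-26 Hz source (0.5), and ten broadband 8-30 Hz background sources
#' (unit variance) — so the discriminative rhythm is a realistically small
#' share of total band power.
#'
#' @param n_channels,n_sources Channel and source counts
#'   (`n_channels >= n_sources`).
#' @param fs Sampling rate in Hz.
#' @param n_trials_per_class Trials per class.
#' @param trial_seconds Trial length in seconds.
#' @param source_bands List of `(low, high)` Hz pairs, one per source.
#' @param source_variances Baseline (class -1) variance per source.
#' @param erd_source_index Which source carries the class effect.
#' @param erd_band Band of the discriminative source (bookkeeping, stored in
#'   the ground truth).
#' @param variance_ratio Class +1 over class -1 variance of the ERD source.
#' @param noise_sd Standard deviation of the white sensor noise.
#' @param seed Integer seed; the mixing matrix and all trial noise derive
#'   from it.
#' @return An object of class `mi_simconfig`.
#' @export
synthetic_config <- function(n_channels = 12, n_sources = 12, fs = 250,
                             n_trials_per_class = 50, trial_seconds = 2,
                             source_bands = NULL, source_variances = NULL,
                             erd_source_index = 1, erd_band = c(8, 12),
                             variance_ratio = 4, noise_sd = 0.1, seed = 1) {
  if (is.null(source_bands)) {
    source_bands <- c(list(c(8, 12), c(18, 26)),
                      rep(list(c(8, 30)), max(0, n_sources - 2)))
    source_bands <- source_bands[seq_len(n_sources)]
  }
  if (is.null(source_variances)) {
    source_variances <- c(0.2, 0.5, rep(1, max(0, n_sources - 2)))
    source_variances <- source_variances[seq_len(n_sources)]
  }
  if (length(source_bands) != n_sources ||
      length(source_variances) != n_sources) {
    abort("Need one band and one variance per source.",
          class = "micsp_error_config")
  }
  if (variance_ratio <= 0) {
    abort("`variance_ratio` must be positive.", class = "micsp_error_config")
  }
  if (erd_source_index > n_sources) {
    abort("`erd_source_index` exceeds the source count.",
          class = "micsp_error_config")
  }
  if (n_channels < n_sources) {
    abort("Need at least as many channels as sources for a full-rank mixing.",
          class = "micsp_error_config")
  }
  nyq <- fs / 2
  if (any(vapply(source_bands, function(b) b[2] >= nyq, logical(1)))) {
    abort("Source bands must lie inside Nyquist.",
          class = "micsp_error_config")
  }
  structure(
    list(n_channels = n_channels, n_sources = n_sources, fs = fs,
         n_trials_per_class = n_trials_per_class,
         trial_seconds = trial_seconds, source_bands = source_bands,
         source_variances = source_variances,
         erd_source_index = as.integer(erd_source_index),
         erd_band = erd_band, variance_ratio = variance_ratio,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "mi_simconfig"
  )
}

# White-noise power gain of the zero-phase band-pass (|H|^4 integrated over
# the digital frequency axis), so filtered unit-variance noise can be
# rescaled to a known target variance without clamping per-trial
# fluctuation.
bandpass_power_gain <- function(spec, fs, n_grid = 4096) {
  ba <- butter_coefficients(spec, fs)
  h <- signal::freqz(ba, n = n_grid, Fs = fs)
  mean(abs(h$h)^4)
}

#' Generate synthetic two-class ERD epochs
#'
#' Draws band-limited Gaussian sources per trial (white noise run through
#' the package's own zero-phase Butterworth band-pass, rescaled by the
#' filter's analytic white-noise power gain so the expected variance equals
#' the configured one), scales the ERD source by `variance_ratio` for class
#' +1 trials, mixes into channels through a random orthonormal-column
#' mixing matrix, and adds white sensor noise. Fully reproducible: the
#' mixing is drawn from `cfg$seed` and trial noise from a seed derived from
#' `(cfg$seed, session)`, so two sessions share the mixing but not the
#' noise.
#'
#' @param cfg A [synthetic_config()].
#' @param session Integer session tag (default 1); use different values for
#'   train/test splits recorded from the same "subject".
#' @return A list with `epochs` (an [epoch_set()]) and `truth` (class
#'   `mi_truth`: the mixing matrix, the discriminative source index and
#'   band, and the per-class source variances).
#' @export
generate_epochs <- function(cfg, session = 1) {
  stopifnot(inherits(cfg, "mi_simconfig"))
  K <- round(cfg$trial_seconds * cfg$fs)
  pad <- min(K, round(cfg$fs))  # transient guard trimmed after filtering
  specs <- lapply(cfg$source_bands, function(b) bandpass_spec(b[1], b[2]))
  gains <- vapply(specs, bandpass_power_gain, numeric(1), fs = cfg$fs)
  coefs <- lapply(specs, butter_coefficients, fs = cfg$fs)

  mixing <- withr::with_seed(cfg$seed, {
    A <- matrix(stats::rnorm(cfg$n_channels * cfg$n_sources),
                cfg$n_channels, cfg$n_sources)
    # orthonormal columns: a well-conditioned forward model, so unmixing
    # directions do not amplify sensor noise
    qr.Q(qr(A))
  })
  if (qr(mixing)$rank < cfg$n_sources) {
    abort("Requested mixing matrix is rank deficient.",
          class = "micsp_error_config")
  }

  n_per <- cfg$n_trials_per_class
  labels <- rep(c(1, -1), each = n_per)
  data <- array(0, dim = c(2 * n_per, cfg$n_channels, K))
  trial_seed <- (cfg$seed * 2203L + as.integer(session) * 379L) %% 2000000011L
  withr::with_seed(trial_seed, {
    for (i in seq_len(2 * n_per)) {
      vars <- cfg$source_variances
      if (labels[i] == 1) {
        vars[cfg$erd_source_index] <-
          vars[cfg$erd_source_index] * cfg$variance_ratio
      }
      sources <- matrix(0, cfg$n_sources, K)
      for (s in seq_len(cfg$n_sources)) {
        white <- stats::rnorm(K + 2 * pad)
        filtered <- apply_bandpass(white, coefs[[s]], "zero_phase")
        core <- filtered[(pad + 1):(pad + K)]
        sources[s, ] <- core * sqrt(vars[s] / gains[s])
      }
      data[i, , ] <- mixing %*% sources +
        cfg$noise_sd * matrix(stats::rnorm(cfg$n_channels * K),
                              cfg$n_channels, K)
    }
  })
  class_vars <- rbind(cfg$source_variances, cfg$source_variances)
  class_vars[1, cfg$erd_source_index] <-
    class_vars[1, cfg$erd_source_index] * cfg$variance_ratio
  rownames(class_vars) <- c("class_pos", "class_neg")
  list(
    epochs = epoch_set(data, labels, cfg$fs,
                       window = c(0, cfg$trial_seconds)),
    truth = structure(
      list(mixing = mixing, erd_source_index = cfg$erd_source_index,
           erd_band = cfg$erd_band, class_variances = class_vars),
      class = "mi_truth")
  )
}

#' Alignment of the top CSP filter with the planted source
#'
#' Absolute cosine between the first spatial filter and the discriminative
#' source's unmixing direction (the corresponding row of the mixing
#' matrix's pseudo-inverse). Near 1 when CSP recovered the planted ERD
#' source; near random alignment under the null.
#'
#' @param filters An [solve_csp()] result.
#' @param truth The `mi_truth` returned by [generate_epochs()].
#' @return Scalar in `[0, 1]`.
#' @export
ground_truth_alignment <- function(filters, truth) {
  stopifnot(inherits(filters, "mi_csp"), inherits(truth, "mi_truth"))
  unmix <- pseudo_inverse(truth$mixing)
  target <- unmix[truth$erd_source_index, ]
  if (length(target) != nrow(filters$W)) {
    abort("Filter and mixing dimensions do not match.",
          class = "micsp_error_shape")
  }
  abs(cosine_similarity(filters$W[, 1], target))
}
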