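# Text-based interchange formats: an epoch container (flat numeric table +
# JSON sidecar), feature CSVs with provenance-encoded headers, YAML pipeline
# configs, and JSON/CSV result records. All round-trip losslessly.

#' Write / read the epoch container
#'
#' `write_epochs()` stores an epoch set as `<prefix>.dat` — a plain-text
#' numeric table with one row per trial, the channels concatenated
#' (value `(c-1)*K + k` of a row is sample `k` of channel `c`) — plus a
#' JSON sidecar `<prefix>.json` holding `fs`, `labels`, `window`,
#' `channel_names` and the array dimensions. `read_epochs()` restores the
#' [epoch_set()].
#'
#' @param epochs An [epoch_set()].
#' @param prefix Path prefix (without extension).
#' @return `write_epochs()` the prefix invisibly; `read_epochs()` an
#'   `mi_epochs`.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "mi_epochs"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1], byrow = TRUE)
  readr::write_delim(as.data.frame(flat), paste0(prefix, ".dat"),
                     delim = " ", col_names = FALSE)
  sidecar <- list(fs = epochs$fs, labels = epochs$labels,
                  window = epochs$window,
                  channel_names = epochs$channel_names,
                  n_trials = d[1], n_channels = d[2], n_samples = d[3],
                  layout = "row per trial; channel-major (K samples per channel block)")
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(readr::read_delim(paste0(prefix, ".dat"), delim = " ",
                                      col_names = FALSE, col_types = readr::cols(
                                        .default = readr::col_double()),
                                      progress = FALSE))
  data <- aperm(array(t(flat), dim = c(meta$n_samples, meta$n_channels,
                                       meta$n_trials)), c(3, 2, 1))
  epoch_set(data, meta$labels, meta$fs,
            window = meta$window, channel_names = meta$channel_names)
}

#' Write / read a feature table as CSV
#'
#' The header carries the provenance-encoded feature names (and the
#' `label` column when present); [read_features()] re-parses the
#' provenance from the names, so the round trip preserves values and
#' metadata.
#'
#' @param features A feature tibble.
#' @param path CSV path.
#' @return `write_features()` the path invisibly; `read_features()` an
#'   `mi_features` tibble.
#' @export
write_features <- function(features, path) {
  readr::write_csv(tibble::as_tibble(features), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nms <- setdiff(names(tb), "label")
  info <- parse_feature_names(nms)   # errors on malformed headers
  structure(tb, mi_info = info, class = c("mi_features", class(tb)))
}

#' Write / read a pipeline configuration as YAML
#'
#' All fields of [pipeline_config()] are preserved, including the filter
#' bank and the lambda grid.
#'
#' @param cfg An `mi_pipeline_config`.
#' @param path YAML path.
#' @return `write_pipeline_config()` the path invisibly;
#'   `read_pipeline_config()` an `mi_pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mi_pipeline_config"))
  out <- unclass(cfg)
  out$bank <- list(bands = as.data.frame(cfg$bank$bands),
                   order = cfg$bank$order)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bank <- structure(
    list(bands = tibble::as_tibble(as.data.frame(raw$bank$bands)),
         order = as.integer(raw$bank$order)),
    class = "mi_filter_bank")
  args <- list(
    extractor = raw$extractor, selector = raw$selector,
    secondary_selection = raw$secondary_selection, m = raw$m,
    band = as.numeric(raw$band), filter_order = raw$filter_order,
    selection_rule = raw$selection_rule, boundary_mode = raw$boundary_mode,
    grid = as.numeric(raw$grid), a = raw$a,
    prox_mode = raw$prox_mode, folds = raw$folds,
    thresholds = as.numeric(raw$thresholds),
    threshold_scale = raw$threshold_scale,
    evaluation_rule = raw$evaluation_rule, seed = raw$seed)
  # extractor-specific settings only where they are meaningful
  if (identical(raw$extractor, "csp_fb")) args$bank <- bank
  if (!is.null(raw$wavelet_levels)) args$wavelet_levels <- raw$wavelet_levels
  do.call(pipeline_config, args)
}

#' Serialize a pipeline result
#'
#' Writes `<prefix>.csv` (the per-threshold report, when present) and
#' `<prefix>.json` (final accuracy, chosen threshold, lambda, support
#' size, sizes).
#'
#' @param result An `mi_result`.
#' @param prefix Path prefix.
#' @return The prefix, invisibly.
#' @export
write_result <- function(result, prefix) {
  stopifnot(inherits(result, "mi_result"))
  if (!is.null(result$report)) {
    readr::write_csv(result$report$by_threshold, paste0(prefix, ".csv"))
  }
  summary <- list(
    extractor = result$config$extractor, selector = result$config$selector,
    secondary_selection = result$config$secondary_selection,
    evaluation_rule = result$config$evaluation_rule,
    final_accuracy = result$final_accuracy,
    chosen_threshold = if (is.null(result$report)) NA else
      result$report$chosen_threshold,
    lambda = result$lambda, n_features = result$n_features,
    support_size = result$support_size, n_train = result$n_train,
    n_test = result$n_test, seed = result$config$seed)
  jsonlite::write_json(summary, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(prefix)
}
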