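# Feature-matrix container: a tibble (one row per trial) whose columns carry
# provenance-encoded names, plus an `mi_info` attribute mapping each column
# to (channel, frequency interval, statistic). Labels, when known, travel as
# a leading `label` column so feature tables pipe naturally through dplyr.

new_features <- function(values, info, labels = NULL) {
  colnames(values) <- info$name
  tb <- tibble::as_tibble(values)
  if (!is.null(labels)) {
    tb <- dplyr::bind_cols(tibble::tibble(label = as.numeric(labels)), tb)
  }
  structure(tb, mi_info = info,
            class = c("mi_features", class(tb)))
}

#' Numeric feature matrix of a feature table
#'
#' Drops the `label` column (if present) and returns the features as a
#' numeric matrix, trials in rows.
#'
#' @param x A feature tibble produced by one of the extractors.
#' @return A numeric matrix with provenance-encoded column names.
#' @export
feature_values <- function(x) {
  stopifnot(inherits(x, "mi_features") || is.data.frame(x))
  cols <- setdiff(names(x), "label")
  as.matrix(as.data.frame(x)[, cols, drop = FALSE])
}

#' Per-column provenance of a feature table
#'
#' @param x A feature tibble.
#' @return A tibble with columns `name`, `channel`, `low_hz`, `high_hz`,
#'   `statistic` (one row per feature column). If the attribute was lost in
#'   a data-frame round-trip the provenance is re-parsed from the names.
#' @export
feature_info <- function(x) {
  info <- attr(x, "mi_info")
  if (!is.null(info)) return(info)
  parse_feature_names(setdiff(names(x), "label"))
}

#' Trial labels of a feature table
#'
#' @param x A feature tibble.
#' @return Numeric +1/-1 vector, or `NULL` when no labels are attached.
#' @export
feature_labels <- function(x) {
  if ("label" %in% names(x)) as.numeric(x[["label"]]) else NULL
}

# Name grammar (kept CSV-safe and reversible):
#   wavelet/WPD : ch<k>_sb<low>-<high>Hz_<energy|std>
#   filter bank : fb<low>-<high>Hz_ch<k>_logvar
#   classic CSP : ch<k>_logvar
parse_feature_names <- function(nms) {
  parse_one <- function(nm) {
    if (grepl("^ch[0-9]+_sb", nm)) {
      m <- regmatches(nm, regexec(
        "^ch([0-9]+)_sb([0-9.]+)-([0-9.]+)Hz_(energy|std)$", nm))[[1]]
      if (length(m)) {
        return(tibble::tibble(name = nm, channel = as.integer(m[2]),
                              low_hz = as.numeric(m[3]),
                              high_hz = as.numeric(m[4]), statistic = m[5]))
      }
    }
    if (grepl("^fb", nm)) {
      m <- regmatches(nm, regexec(
        "^fb([0-9.]+)-([0-9.]+)Hz_ch([0-9]+)_logvar$", nm))[[1]]
      if (length(m)) {
        return(tibble::tibble(name = nm, channel = as.integer(m[4]),
                              low_hz = as.numeric(m[2]),
                              high_hz = as.numeric(m[3]),
                              statistic = "logvar"))
      }
    }
    m <- regmatches(nm, regexec("^ch([0-9]+)_logvar$", nm))[[1]]
    if (length(m)) {
      return(tibble::tibble(name = nm, channel = as.integer(m[2]),
                            low_hz = NA_real_, high_hz = NA_real_,
                            statistic = "logvar"))
    }
    abort(sprintf("Cannot parse feature column name `%s`.", nm),
          class = "micsp_error_parse")
  }
  dplyr::bind_rows(lapply(nms, parse_one))
}
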