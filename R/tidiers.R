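# broom-style tidiers for the fitted objects.

#' @exportS3Method
tidy.mi_csp <- function(x, ...) {
  tibble::tibble(filter = colnames(x$W),
                 eigenvalue = x$eigvals)
}

#' @exportS3Method
tidy.mi_weights <- function(x, ...) {
  nm <- names(x$w) %||% paste0("f", seq_along(x$w))
  tibble::tibble(feature = nm, weight = unname(x$w),
                 abs_weight = abs(unname(x$w)),
                 selected = unname(x$w) != 0)
}

#' @exportS3Method
glance.mi_weights <- function(x, ...) {
  tibble::tibble(penalty = x$penalty, lambda = x$lambda,
                 iterations = x$iterations, converged = x$converged,
                 n_nonzero = sum(x$w != 0),
                 objective = tail(x$objective_trace, 1))
}

#' @exportS3Method
tidy.mi_cv <- function(x, ...) x$table

#' @exportS3Method
glance.mi_cv <- function(x, ...) {
  tibble::tibble(selector = x$selector, folds = x$folds,
                 lambda = x$lambda,
                 best_score = max(x$table$score, na.rm = TRUE))
}

#' @exportS3Method
tidy.mi_flda <- function(x, ...) {
  tibble::tibble(term = x$features %||% paste0("f", seq_along(x$direction)),
                 estimate = unname(x$direction))
}

#' @exportS3Method
tidy.mi_report <- function(x, ...) x$by_threshold

#' @exportS3Method
glance.mi_report <- function(x, ...) {
  tibble::tibble(rule = x$rule, final_accuracy = x$final_accuracy,
                 chosen_threshold = x$chosen_threshold)
}

#' @exportS3Method
tidy.mi_result <- function(x, ...) {
  if (is.null(x$report)) {
    return(tibble::tibble(threshold = NA_real_,
                          n_features = x$support_size,
                          accuracy = x$final_accuracy))
  }
  x$report$by_threshold
}

#' @exportS3Method
glance.mi_result <- function(x, ...) {
  tibble::tibble(extractor = x$config$extractor,
                 selector = x$config$selector,
                 secondary_selection = x$config$secondary_selection,
                 evaluation_rule = x$config$evaluation_rule,
                 lambda = x$lambda, support_size = x$support_size,
                 final_accuracy = x$final_accuracy)
}
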