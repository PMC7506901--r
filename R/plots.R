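# ggplot2 views of the main result types.

#' @exportS3Method
autoplot.mi_csp <- function(object, ...) {
  df <- tibble::tibble(index = seq_along(object$full_eigvals),
                       eigenvalue = object$full_eigvals,
                       kept = seq_along(object$full_eigvals) %in%
                         c(seq_len(object$m),
                           seq(length(object$full_eigvals) - object$m + 1,
                               length(object$full_eigvals))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$eigenvalue,
                                   colour = .data$kept)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "eigenvalue rank", y = "generalized eigenvalue",
                  colour = "retained",
                  title = "CSP eigenvalue spectrum") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.mi_weights <- function(object, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = as.integer(.data$feature),
                                   y = .data$abs_weight)) +
    ggplot2::geom_segment(ggplot2::aes(xend = as.integer(.data$feature),
                                       yend = 0)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected)) +
    ggplot2::labs(x = "feature index", y = "|weight|",
                  title = sprintf("Sparse %s weights (lambda = %.3g)",
                                  object$penalty, object$lambda)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.mi_cv <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = log2(.data$lambda), y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = log2(object$lambda),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2(lambda)", y = "mean CV score",
                  title = sprintf("%s lambda selection (%d-fold CV)",
                                  object$selector, object$folds)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.mi_report <- function(object, ...) {
  ggplot2::ggplot(object$by_threshold,
                  ggplot2::aes(x = .data$threshold, y = .data$accuracy)) +
    ggplot2::geom_col(width = 0.06) +
    ggplot2::geom_hline(yintercept = object$final_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "weight threshold", y = "accuracy",
                  title = sprintf("Threshold ensemble (%s rule): final %.3f",
                                  object$rule, object$final_accuracy)) +
    ggplot2::theme_minimal()
}
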