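#' Fit a Fisher linear discriminant
#'
#' Two-class Fisher discriminant: projection direction
#' `(S_w + ridge * I)^{-1} (mu_+ - mu_-)` with pooled within-class scatter
#' `S_w`, and a bias placing the decision boundary at the midpoint of the
#' projected class means. The ridge loading `1e-8 * trace(S_w) / P` guards
#' against singular scatter on small supports.
#'
#' @param X Numeric matrix (trials x features) or feature tibble.
#' @param y +1/-1 labels; both classes must be present.
#' @param ridge_scale Relative ridge loading (default `1e-8`).
#' @return An object of class `mi_flda` with `direction`, `bias`, `ridge`,
#'   the training feature names, and the sign-to-label `class_order`.
#' @export
flda_fit <- function(X, y, ridge_scale = 1e-8) {
  X <- if (is.data.frame(X)) feature_values(X) else as.matrix(X)
  check_labels(y)
  if (!any(y == 1) || !any(y == -1)) {
    abort("Both classes must be present to fit a discriminant.",
          class = "micsp_error_fit")
  }
  if (ncol(X) == 0) {
    abort("Empty feature subset.", class = "micsp_error_fit")
  }
  P <- ncol(X)
  mu_pos <- colMeans(X[y == 1, , drop = FALSE])
  mu_neg <- colMeans(X[y == -1, , drop = FALSE])
  Sw <- matrix(0, P, P)
  for (cls in c(1, -1)) {
    Xi <- X[y == cls, , drop = FALSE]
    centered <- sweep(Xi, 2, colMeans(Xi))
    Sw <- Sw + crossprod(centered)
  }
  ridge <- ridge_scale * sum(diag(Sw)) / P
  if (ridge <= 0) ridge <- ridge_scale
  direction <- as.numeric(solve(Sw + diag(ridge, P), mu_pos - mu_neg))
  names(direction) <- colnames(X)
  bias <- sum(direction * (mu_pos + mu_neg) / 2)
  structure(
    list(direction = direction, bias = bias, ridge = ridge,
         features = colnames(X), class_order = c(pos = 1, neg = -1)),
    class = "mi_flda"
  )
}

#' Predict labels with a fitted Fisher discriminant
#'
#' Sign of the projection minus the bias; a point exactly on the boundary is
#' assigned +1 (deterministic tie rule). Prediction is invariant to any
#' positive rescaling of `(direction, bias)`.
#'
#' @param model An [flda_fit()] result.
#' @param X Test matrix or feature tibble whose columns match the training
#'   subset.
#' @return Numeric +1/-1 labels.
#' @export
flda_predict <- function(model, X) {
  stopifnot(inherits(model, "mi_flda"))
  X <- if (is.data.frame(X)) feature_values(X) else as.matrix(X)
  if (ncol(X) != length(model$direction)) {
    abort(sprintf("Model expects %d features, got %d.",
                  length(model$direction), ncol(X)),
          class = "micsp_error_shape")
  }
  score <- as.numeric(X %*% model$direction) - model$bias
  ifelse(score >= 0, model$class_order[["pos"]], model$class_order[["neg"]])
}

#' @export
print.mi_flda <- function(x, ...) {
  cat(sprintf("<mi_flda> %d features, bias %.4g\n",
              length(x$direction), x$bias))
  invisible(x)
}
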