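#' Threshold-grid ensemble of Fisher discriminants
#'
#' Secondary feature selection: for each threshold `tau` in the grid the
#' features with `|w_i| > tau` are selected and, when the subset is
#' non-empty, a Fisher discriminant is fitted on them. Subsets are nested
#' non-increasing in the threshold. Thresholds compare against raw absolute
#' weights by default; `scale = "normalized"` divides `|w|` by its maximum
#' first, so the grid spans the weight range regardless of the selector's
#' scale.
#'
#' @param weights An `mi_weights` fit or a bare numeric weight vector.
#' @param X Training feature matrix (standardized as for the selector) or
#'   feature tibble.
#' @param y Training +1/-1 labels.
#' @param thresholds Ascending threshold grid, default `seq(0, 0.8, 0.1)`.
#' @param scale `"raw"` (default) or `"normalized"`.
#' @return An object of class `mi_ensemble`: `thresholds`, per-threshold
#'   `subsets` (integer index vectors), `models` (`NULL` where the subset is
#'   empty), and the source weights.
#' @export
build_ensemble <- function(weights, X, y, thresholds = seq(0, 0.8, by = 0.1),
                           scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  w <- if (inherits(weights, "mi_weights")) weights$w else as.numeric(weights)
  X <- if (is.data.frame(X)) feature_values(X) else as.matrix(X)
  if (ncol(X) != length(w)) {
    abort(sprintf("Weights have length %d but X has %d columns.",
                  length(w), ncol(X)), class = "micsp_error_shape")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly increasing.",
          class = "micsp_error_ensemble")
  }
  aw <- abs(w)
  if (scale == "normalized" && max(aw) > 0) aw <- aw / max(aw)
  subsets <- lapply(thresholds, function(tau) which(aw > tau))
  models <- lapply(subsets, function(idx) {
    if (length(idx) == 0) return(NULL)
    flda_fit(X[, idx, drop = FALSE], y)
  })
  structure(
    list(thresholds = thresholds, subsets = subsets, models = models,
         source_weights = w, scale = scale),
    class = "mi_ensemble"
  )
}

#' @export
print.mi_ensemble <- function(x, ...) {
  cat(sprintf("<mi_ensemble> %d thresholds, subset sizes: %s\n",
              length(x$thresholds),
              paste(lengths(x$subsets), collapse = ", ")))
  invisible(x)
}

#' Evaluate a threshold ensemble by the max-accuracy rule
#'
#' Scores every per-threshold model on the test set (an empty subset scores
#' 0) and reports the maximum as the final accuracy; on ties the smallest
#' threshold is reported. Note that this rule consults the test labels to
#' pick the model — it reproduces the published evaluation; see
#' [evaluate_ensemble_cv()] for a label-blind alternative.
#'
#' @param ens A [build_ensemble()] result.
#' @param X_test,y_test Test features (matching training columns) and
#'   labels.
#' @return An object of class `mi_report`: a `by_threshold` tibble
#'   (`threshold`, `n_features`, `accuracy`), `final_accuracy`,
#'   `chosen_threshold`, and the rule used.
#' @export
evaluate_ensemble_max <- function(ens, X_test, y_test) {
  stopifnot(inherits(ens, "mi_ensemble"))
  X_test <- if (is.data.frame(X_test)) feature_values(X_test) else
    as.matrix(X_test)
  check_labels(y_test)
  if (nrow(X_test) == 0) {
    abort("Empty test set.", class = "micsp_error_ensemble")
  }
  acc <- purrr::map2_dbl(ens$models, ens$subsets, function(model, idx) {
    if (is.null(model)) return(0)
    mean(flda_predict(model, X_test[, idx, drop = FALSE]) == y_test)
  })
  final <- max(acc)
  chosen <- ens$thresholds[which(acc == final)[1]]
  structure(
    list(by_threshold = tibble::tibble(threshold = ens$thresholds,
                                       n_features = lengths(ens$subsets),
                                       accuracy = acc),
         final_accuracy = final, chosen_threshold = chosen, rule = "max"),
    class = "mi_report"
  )
}

#' Evaluate with a label-blind, CV-chosen threshold
#'
#' Chooses the threshold by inner cross-validated accuracy on the training
#' data only (empty subsets score 0; ties go to the smallest threshold),
#' then reports that single model's test accuracy. Provided as the
#' label-blind alternative to the max rule.
#'
#' @param weights Weights driving the subsets (as in [build_ensemble()]).
#' @param X_train,y_train Training features and labels.
#' @param X_test,y_test Test features and labels.
#' @param thresholds Threshold grid.
#' @param scale Weight scale, see [build_ensemble()].
#' @param folds Inner CV folds (default 5).
#' @param seed Seed for the inner fold assignment.
#' @return An `mi_report`; `by_threshold$accuracy` holds the inner CV
#'   accuracies, `final_accuracy` the test accuracy at the chosen threshold.
#' @export
evaluate_ensemble_cv <- function(weights, X_train, y_train, X_test, y_test,
                                 thresholds = seq(0, 0.8, by = 0.1),
                                 scale = "raw", folds = 5, seed = 1) {
  w <- if (inherits(weights, "mi_weights")) weights$w else as.numeric(weights)
  X_train <- if (is.data.frame(X_train)) feature_values(X_train) else
    as.matrix(X_train)
  X_test <- if (is.data.frame(X_test)) feature_values(X_test) else
    as.matrix(X_test)
  check_labels(y_train); check_labels(y_test)
  aw <- abs(w)
  if (scale == "normalized" && max(aw) > 0) aw <- aw / max(aw)
  N <- nrow(X_train)
  fold_id <- integer(N)
  withr::with_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- sample(which(y_train == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  cv_acc <- purrr::map_dbl(thresholds, function(tau) {
    idx <- which(aw > tau)
    if (length(idx) == 0) return(0)
    fold_scores <- purrr::map_dbl(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(y_train[tr])) < 2 || !any(!tr)) return(NA_real_)
      model <- flda_fit(X_train[tr, idx, drop = FALSE], y_train[tr])
      mean(flda_predict(model, X_train[!tr, idx, drop = FALSE]) ==
             y_train[!tr])
    })
    mean(fold_scores, na.rm = TRUE)
  })
  best_tau <- thresholds[which(cv_acc == max(cv_acc))[1]]
  idx <- which(aw > best_tau)
  final <- if (length(idx) == 0) 0 else {
    model <- flda_fit(X_train[, idx, drop = FALSE], y_train)
    mean(flda_predict(model, X_test[, idx, drop = FALSE]) == y_test)
  }
  structure(
    list(by_threshold = tibble::tibble(
           threshold = thresholds,
           n_features = purrr::map_int(thresholds,
                                       function(tau) sum(aw > tau)),
           accuracy = cv_acc),
         final_accuracy = final, chosen_threshold = best_tau, rule = "cv"),
    class = "mi_report"
  )
}

#' @export
print.mi_report <- function(x, ...) {
  cat(sprintf("<mi_report> rule = %s: final accuracy %.3f at threshold %g\n",
              x$rule, x$final_accuracy, x$chosen_threshold))
  print(x$by_threshold)
  invisible(x)
}
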