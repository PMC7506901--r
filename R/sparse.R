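#' Soft thresholding
#'
#' The proximal operator of the L1 penalty:
#' `sign(v) * max(|v| - t, 0)` element-wise.
#'
#' @param v Numeric vector.
#' @param t Non-negative threshold.
#' @return Numeric vector of the same length.
#' @export
soft_threshold <- function(v, t) {
  if (t < 0) abort("`t` must be non-negative.", class = "micsp_error_solver")
  sign(v) * pmax(abs(v) - t, 0)
}

#' Proximal operator of the logarithmic penalty
#'
#' Shrinkage map of the non-convex penalty `log(1 + |x| / a)` at step weight
#' `lambda_over_gamma`. Two modes are provided:
#'
#' * `"paper_prox"` — the closed-form iterative-log-thresholding update
#'   `sign(v)/2 * (|v| - a + sqrt((a - |v|)^2 + 4 * max(a|v| - lambda/gamma, 0)))`,
#'   whose clamp returns exactly 0 when `|v| <= a` and `a|v| <= lambda/gamma`.
#' * `"exact_prox"` — the global minimizer of
#'   `lambda/gamma * log(1 + |x|/a) + (x - v)^2 / 2` per element, obtained by
#'   comparing the admissible stationary point with 0. Unlike the closed
#'   form it may jump to 0 where no root of the stationarity quadratic
#'   exists or where 0 attains a lower objective.
#'
#' @param v Numeric vector.
#' @param lambda_over_gamma Positive penalty weight after step scaling.
#' @param a Positive scale of the log penalty (default 0.001).
#' @param mode `"paper_prox"` (default) or `"exact_prox"`.
#' @return Numeric vector of the same length as `v`.
#' @export
prox_log <- function(v, lambda_over_gamma, a = 0.001,
                     mode = c("paper_prox", "exact_prox")) {
  mode <- match.arg(mode)
  if (lambda_over_gamma <= 0 || a <= 0) {
    abort("`lambda_over_gamma` and `a` must be positive.",
          class = "micsp_error_solver")
  }
  s <- abs(v)
  if (mode == "paper_prox") {
    inner <- (a - s)^2 + 4 * pmax(a * s - lambda_over_gamma, 0)
    return(sign(v) / 2 * (s - a + sqrt(inner)))
  }
  # exact mode: minimize g(x) = lot*log(1 + x/a) + (x - s)^2/2 over x >= 0,
  # stationarity gives x^2 - (s - a) x + (lot - a s) = 0
  lot <- lambda_over_gamma
  disc <- (s - a)^2 - 4 * (lot - a * s)
  out <- numeric(length(v))
  ok <- disc >= 0
  root <- numeric(length(v))
  root[ok] <- ((s[ok] - a) + sqrt(disc[ok])) / 2
  cand <- ok & root > 0
  g_root <- lot * log1p(root[cand] / a) + (root[cand] - s[cand])^2 / 2
  g_zero <- s[cand]^2 / 2
  take <- g_root < g_zero
  idx <- which(cand)[take]
  out[idx] <- root[cand][take]
  sign(v) * out
}

#' Grid of regularization weights
#'
#' The dyadic grid `2^seq(from, to, by)`; the default spans `2^-5` to `2^5`
#' in steps of `2^0.2`, 51 values.
#'
#' @param from,to,by Exponents of the dyadic grid.
#' @return Numeric vector of lambda values, ascending.
#' @export
lambda_grid <- function(from = -5, to = 5, by = 0.2) {
  2^seq(from, to, by = by)
}

#' Column standardization learned on training data
#'
#' Centers to mean 0 and scales to unit sample standard deviation.
#' Constant columns are centered but left unscaled. The returned scaler is
#' applied frozen to test data via [apply_scaler()].
#'
#' @param X Numeric matrix or feature tibble (label column ignored).
#' @return An object of class `mi_scaler` with the standardized matrix in
#'   `$X` and the stored `$center` / `$scale`.
#' @export
fit_scaler <- function(X) {
  X <- if (is.data.frame(X)) feature_values(X) else as.matrix(X)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  structure(
    list(X = sweep(sweep(X, 2, center), 2, scale, "/"),
         center = center, scale = scale),
    class = "mi_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler An `mi_scaler`.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "mi_scaler"))
  X <- if (is.data.frame(X)) feature_values(X) else as.matrix(X)
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

# Shared proximal-gradient engine. Gradient step
#   v = w - (X'X w - X'y) / gamma,  gamma = ||X'X||_2,
# followed by the penalty's shrinkage map. Stops when the relative iterate
# change drops below tol.
ista_engine <- function(X, y, lambda, penalty, a = 0.001,
                        mode = "paper_prox", max_iter = 1000, tol = 1e-6,
                        w_init = NULL, gamma = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("Non-finite values in the design or targets.",
          class = "micsp_error_data")
  }
  if (lambda <= 0) abort("`lambda` must be positive.",
                         class = "micsp_error_solver")
  P <- ncol(X)
  XtX <- crossprod(X)
  Xty <- as.numeric(crossprod(X, y))
  if (is.null(gamma)) gamma <- power_iteration_norm(XtX)
  if (gamma <= 0) gamma <- .Machine$double.eps
  prox <- switch(penalty,
    lasso = function(v) soft_threshold(v, lambda / gamma),
    log = function(v) prox_log(v, lambda / gamma, a = a, mode = mode))
  objective <- switch(penalty,
    lasso = function(w) 0.5 * sum((y - X %*% w)^2) + lambda * sum(abs(w)),
    log = function(w) 0.5 * sum((y - X %*% w)^2) +
      lambda * sum(log1p(abs(w) / a)))
  w <- if (is.null(w_init)) numeric(P) else as.numeric(w_init)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (t in seq_len(max_iter)) {
    iter <- t
    v <- w - (as.numeric(XtX %*% w) - Xty) / gamma
    w_new <- prox(v)
    trace[t] <- objective(w_new)
    delta <- sqrt(sum((w_new - w)^2)) / max(sqrt(sum(w^2)), 1e-12)
    w <- w_new
    if (delta <= tol) { converged <- TRUE; break }
  }
  names(w) <- colnames(X)
  nonsep <- if (penalty == "log") {
    0.5 * sum((y - X %*% w)^2) + lambda * log1p(sum(abs(w)) / a)
  } else NA_real_
  structure(
    list(w = w, iterations = iter, objective_trace = trace,
         converged = converged, mode = if (penalty == "log") mode else NA,
         penalty = penalty, lambda = lambda, gamma = gamma,
         a = if (penalty == "log") a else NA_real_,
         nonseparable_objective = nonsep),
    class = "mi_weights"
  )
}

#' LASSO feature weights by proximal gradient descent (ISTA)
#'
#' Minimizes `0.5 * ||y - X w||^2 + lambda * ||w||_1` by iterative
#' shrinkage thresholding with step `1 / ||X'X||_2`. Non-convergence within
#' `max_iter` is reported via `converged = FALSE`, not an error.
#'
#' @param X Standardized N x P feature matrix (see [fit_scaler()]).
#' @param y Numeric +1/-1 labels used as regression targets.
#' @param lambda Positive regularization weight.
#' @param max_iter,tol Stopping rule: at most `max_iter` iterations or
#'   relative iterate change below `tol`.
#' @param w_init Optional warm-start weights.
#' @return An object of class `mi_weights` with the weights `w`, the
#'   per-iteration objective trace, and solver metadata.
#' @export
ista_lasso <- function(X, y, lambda, max_iter = 1000, tol = 1e-6,
                       w_init = NULL) {
  ista_engine(X, y, lambda, penalty = "lasso", max_iter = max_iter,
              tol = tol, w_init = w_init)
}

#' Log-penalty feature weights by iterative log thresholding
#'
#' Minimizes `0.5 * ||y - X w||^2 + lambda * sum(log(1 + |w_i| / a))` by
#' alternating a gradient step with the log penalty's shrinkage map
#' ([prox_log()]). The penalty is treated element-wise (separable), the
#' form consistent with the closed-form operator; the non-separable variant
#' `lambda * log(1 + ||w||_1 / a)` is additionally recorded on the result
#' for transparency.
#'
#' @inheritParams ista_lasso
#' @param a Positive scale of the log penalty (default 0.001).
#' @param mode Shrinkage variant, `"paper_prox"` (default) or
#'   `"exact_prox"`; see [prox_log()].
#' @return An object of class `mi_weights`.
#' @export
ista_log <- function(X, y, lambda, a = 0.001,
                     mode = c("paper_prox", "exact_prox"),
                     max_iter = 1000, tol = 1e-6, w_init = NULL) {
  mode <- match.arg(mode)
  ista_engine(X, y, lambda, penalty = "log", a = a, mode = mode,
              max_iter = max_iter, tol = tol, w_init = w_init)
}

#' @export
print.mi_weights <- function(x, ...) {
  cat(sprintf(
    "<mi_weights> %s: %d/%d nonzero, lambda = %.4g, %d iterations%s\n",
    x$penalty, sum(x$w != 0), length(x$w), x$lambda, x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Choose the regularization weight by stratified cross-validation
#'
#' Grid search over `grid`: for each fold, the sparse selector is fitted on
#' the training folds (standardized within those folds), the surviving
#' features (`|w| > 0`) feed a Fisher discriminant, and held-out accuracy is
#' scored; an empty support scores 0. The winner maximizes mean CV
#' accuracy, ties broken toward the larger (sparser) lambda. Fold
#' assignment is stratified by class under the recorded seed. A
#' squared-error scoring rule is available as an alternative.
#'
#' @param X N x P feature matrix or feature tibble (unstandardized;
#'   standardization happens inside each fold).
#' @param y +1/-1 labels.
#' @param selector `"log"` (default) or `"lasso"`.
#' @param folds Number of CV folds (default 10).
#' @param grid Lambda grid, default [lambda_grid()].
#' @param a,mode Passed to [ista_log()] when `selector = "log"`.
#' @param seed Integer seed for the fold assignment.
#' @param scoring `"flda_accuracy"` (default) or `"squared_error"` (then
#'   lower is better and the score is negated internally).
#' @return An object of class `mi_cv`: the chosen `lambda`, a `table`
#'   tibble (`lambda`, `score`), and the settings used.
#' @export
cv_select_lambda <- function(X, y, selector = c("log", "lasso"), folds = 10,
                             grid = lambda_grid(), a = 0.001,
                             mode = "paper_prox", seed = 1,
                             scoring = c("flda_accuracy", "squared_error")) {
  selector <- match.arg(selector)
  scoring <- match.arg(scoring)
  X <- if (is.data.frame(X)) feature_values(X) else as.matrix(X)
  check_labels(y)
  N <- nrow(X)
  if (N < folds) {
    abort(sprintf("Need at least %d trials for %d-fold CV, have %d.",
                  folds, folds, N), class = "micsp_error_cv")
  }
  fold_id <- integer(N)
  withr::with_seed(seed, {
    for (cls in c(1, -1)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  grid <- sort(grid)  # ascending; warm starts run from the sparse end down
  scores <- matrix(NA_real_, length(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) next
    sc <- fit_scaler(X[tr, , drop = FALSE])
    Xtr <- sc$X
    Xva <- apply_scaler(sc, X[!tr, , drop = FALSE])
    ytr <- y[tr]
    yva <- y[!tr]
    XtX <- crossprod(Xtr)
    gamma <- power_iteration_norm(XtX)
    w_prev <- NULL
    for (g in rev(seq_along(grid))) {
      fit <- ista_engine(Xtr, ytr, grid[g], penalty = selector, a = a,
                         mode = mode, w_init = w_prev, gamma = gamma)
      w_prev <- fit$w
      support <- which(abs(fit$w) > 0)
      if (scoring == "squared_error") {
        pred <- as.numeric(Xva %*% fit$w)
        scores[g, f] <- -mean((yva - pred)^2)
      } else if (length(support) == 0) {
        scores[g, f] <- 0
      } else {
        model <- flda_fit(Xtr[, support, drop = FALSE], ytr)
        pred <- flda_predict(model, Xva[, support, drop = FALSE])
        scores[g, f] <- mean(pred == yva)
      }
    }
  }
  mean_score <- rowMeans(scores, na.rm = TRUE)
  best <- max(mean_score)
  lambda_star <- max(grid[mean_score == best])  # tie -> larger lambda
  structure(
    list(lambda = lambda_star,
         table = tibble::tibble(lambda = grid, score = mean_score),
         selector = selector, folds = folds, seed = seed,
         scoring = scoring),
    class = "mi_cv"
  )
}

#' @export
print.mi_cv <- function(x, ...) {
  cat(sprintf("<mi_cv> %s, %d-fold: lambda* = %.4g (score %.3f)\n",
              x$selector, x$folds, x$lambda,
              x$table$score[x$table$lambda == x$lambda][1]))
  invisible(x)
}
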