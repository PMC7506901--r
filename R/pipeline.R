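#' End-to-end decoding pipeline configuration
#'
#' Bundles every tunable of the chain band-pass -> CSP -> feature
#' extraction -> sparse selection -> threshold ensemble. Defaults reproduce
#' the reference setting: 8-30 Hz order-6 Butterworth, `m = 3` filters per
#' end, db4 wavelet plans keyed to the sampling rate, the ten-band 4 Hz /
#' 2 Hz-step filter bank, the dyadic lambda grid with 10-fold CV,
#' `a = 0.001`, and thresholds 0 to 0.8.
#'
#' @param extractor One of `"csp"`, `"csp_wavelet"`, `"csp_wpd"`,
#'   `"csp_fb"`.
#' @param selector `"none"`, `"lasso"`, or `"log"`.
#' @param secondary_selection Build the threshold ensemble? Requires a
#'   selector.
#' @param m CSP filters per end of the eigenvalue spectrum.
#' @param band Band-pass edges in Hz.
#' @param filter_order Overall Butterworth order.
#' @param wavelet_levels Optional override of the wavelet depth.
#' @param selection_rule Sub-band selection rule, see [plan_wavelet()].
#' @param boundary_mode Wavelet boundary handling.
#' @param bank Filter bank for `csp_fb` (default [make_filter_bank()]).
#' @param grid Lambda grid for CV (default [lambda_grid()]).
#' @param a Log-penalty scale.
#' @param prox_mode `"paper_prox"` or `"exact_prox"`.
#' @param folds CV folds for lambda selection.
#' @param thresholds Ensemble threshold grid.
#' @param threshold_scale `"raw"` or `"normalized"` weights.
#' @param evaluation_rule `"max"` (published rule) or `"cv"` (label-blind).
#' @param seed Seed driving fold assignment and any other randomness.
#' @return An object of class `mi_pipeline_config`.
#' @export
pipeline_config <- function(extractor = c("csp_fb", "csp", "csp_wavelet",
                                          "csp_wpd"),
                            selector = c("log", "lasso", "none"),
                            secondary_selection = TRUE, m = 3,
                            band = c(8, 30), filter_order = 6,
                            wavelet_levels = NULL,
                            selection_rule = "intersect_8_30",
                            boundary_mode = "periodization",
                            bank = make_filter_bank(),
                            grid = lambda_grid(), a = 0.001,
                            prox_mode = "paper_prox", folds = 10,
                            thresholds = seq(0, 0.8, by = 0.1),
                            threshold_scale = "raw",
                            evaluation_rule = c("max", "cv"), seed = 1) {
  extractor <- match.arg(extractor)
  selector <- match.arg(selector)
  evaluation_rule <- match.arg(evaluation_rule)
  if (secondary_selection && selector == "none") {
    abort("Secondary selection needs a sparse selector ('lasso' or 'log').",
          class = "micsp_error_config")
  }
  if (extractor != "csp_fb" && !missing(bank)) {
    abort("A filter bank is only meaningful with the 'csp_fb' extractor.",
          class = "micsp_error_config")
  }
  if (extractor %in% c("csp", "csp_fb") &&
      (!missing(wavelet_levels) && !is.null(wavelet_levels))) {
    abort("Wavelet settings apply only to 'csp_wavelet' / 'csp_wpd'.",
          class = "micsp_error_config")
  }
  structure(
    list(extractor = extractor, selector = selector,
         secondary_selection = secondary_selection, m = m, band = band,
         filter_order = filter_order, wavelet_levels = wavelet_levels,
         selection_rule = selection_rule, boundary_mode = boundary_mode,
         bank = bank, grid = grid, a = a, prox_mode = prox_mode,
         folds = folds, thresholds = thresholds,
         threshold_scale = threshold_scale,
         evaluation_rule = evaluation_rule, seed = as.integer(seed)),
    class = "mi_pipeline_config"
  )
}

#' Run a decoding pipeline on a train/test session pair
#'
#' Executes the configured chain. Everything derived from data — spatial
#' filters, column standardization, the CV-chosen lambda, sparse weights,
#' and discriminant models — is fitted on the training session only and
#' applied frozen to the test session. The single documented exception is
#' the `"max"` evaluation rule, which picks the best per-threshold model by
#' its test accuracy (the published protocol); use
#' `evaluation_rule = "cv"` for a fully label-blind report.
#'
#' @param train,test [epoch_set()] objects sharing channel count and
#'   sampling rate.
#' @param cfg A [pipeline_config()].
#' @return An object of class `mi_result`: the final accuracy, the
#'   per-threshold report, lambda and CV table (when a selector ran), the
#'   fitted weights, ensemble, spatial filters, and the configuration.
#' @export
run_pipeline <- function(train, test, cfg = pipeline_config()) {
  stopifnot(inherits(train, "mi_epochs"), inherits(test, "mi_epochs"),
            inherits(cfg, "mi_pipeline_config"))
  if (dim(train$data)[2] != dim(test$data)[2] || train$fs != test$fs) {
    abort("Train and test sessions must share channel count and fs.",
          class = "micsp_error_config")
  }
  spec <- bandpass_spec(cfg$band[1], cfg$band[2], order = cfg$filter_order)
  tr <- bandpass_epochs(train, spec)
  te <- bandpass_epochs(test, spec)

  filters <- solve_csp(compute_class_covariances(tr), m = cfg$m)
  ptr <- project(tr, filters)
  pte <- project(te, filters)

  extract <- switch(cfg$extractor,
    csp = function(p) logvar_features(p),
    csp_wavelet = {
      plan <- plan_wavelet(train$fs, "dwt", levels = cfg$wavelet_levels,
                           selection_rule = cfg$selection_rule,
                           boundary_mode = cfg$boundary_mode)
      function(p) extract_csp_wavelet(p, plan)
    },
    csp_wpd = {
      plan <- plan_wavelet(train$fs, "wpd", levels = cfg$wavelet_levels,
                           selection_rule = cfg$selection_rule,
                           boundary_mode = cfg$boundary_mode)
      function(p) extract_csp_wpd(p, plan)
    },
    csp_fb = function(p) extract_csp_fb(p, cfg$bank))
  f_train <- extract(ptr)
  f_test <- extract(pte)
  y_train <- train$labels
  y_test <- test$labels

  if (cfg$selector == "none") {
    model <- flda_fit(f_train, y_train)
    acc <- mean(flda_predict(model, f_test) == y_test)
    return(structure(
      list(final_accuracy = acc, report = NULL, lambda = NA_real_,
           cv = NULL, weights = NULL, ensemble = NULL, filters = filters,
           n_features = ncol(feature_values(f_train)),
           support_size = ncol(feature_values(f_train)),
           n_train = length(y_train), n_test = length(y_test),
           config = cfg),
      class = "mi_result"))
  }

  scaler <- fit_scaler(f_train)
  X_train <- scaler$X
  X_test <- apply_scaler(scaler, f_test)
  cv <- cv_select_lambda(X_train, y_train, selector = cfg$selector,
                         folds = cfg$folds, grid = cfg$grid, a = cfg$a,
                         mode = cfg$prox_mode, seed = cfg$seed)
  weights <- ista_engine(X_train, y_train, cv$lambda,
                         penalty = cfg$selector, a = cfg$a,
                         mode = cfg$prox_mode)

  if (cfg$secondary_selection) {
    ens <- build_ensemble(weights, X_train, y_train,
                          thresholds = cfg$thresholds,
                          scale = cfg$threshold_scale)
    report <- if (cfg$evaluation_rule == "max") {
      evaluate_ensemble_max(ens, X_test, y_test)
    } else {
      evaluate_ensemble_cv(weights, X_train, y_train, X_test, y_test,
                           thresholds = cfg$thresholds,
                           scale = cfg$threshold_scale, seed = cfg$seed)
    }
    acc <- report$final_accuracy
    support <- sum(weights$w != 0)
  } else {
    ens <- NULL
    support <- sum(weights$w != 0)
    if (support == 0) {
      acc <- 0
      report <- NULL
    } else {
      idx <- which(weights$w != 0)
      model <- flda_fit(X_train[, idx, drop = FALSE], y_train)
      acc <- mean(flda_predict(model, X_test[, idx, drop = FALSE]) == y_test)
      report <- NULL
    }
  }
  structure(
    list(final_accuracy = acc, report = report, lambda = cv$lambda,
         cv = cv, weights = weights, ensemble = ens, filters = filters,
         n_features = ncol(X_train), support_size = support,
         n_train = length(y_train), n_test = length(y_test), config = cfg),
    class = "mi_result"
  )
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf(
    "<mi_result> %s + %s%s: accuracy %.3f (%d features, support %d)\n",
    x$config$extractor, x$config$selector,
    if (x$config$secondary_selection) " + ensemble" else "",
    x$final_accuracy, x$n_features, x$support_size))
  if (!is.na(x$lambda)) cat(sprintf("lambda* = %.4g\n", x$lambda))
  invisible(x)
}
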