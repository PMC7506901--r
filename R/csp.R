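#' Trace-normalized class covariance matrices
#'
#' For each trial `D` (channels x samples) the spatial covariance
#' `D D' / trace(D D')` is computed, then averaged within class. Class 1 is
#' the +1 label, class 2 the -1 label. Both returned matrices have unit
#' trace, which makes the subsequent generalized eigenvalues scale-free.
#'
#' @param epochs An [epoch_set()] object (normally band-pass filtered).
#'
#' @return An object of class `mi_covs` with elements `cov1`, `cov2`
#'   (channels x channels), trial counts `n1`, `n2`, and `channel_names`.
#' @export
compute_class_covariances <- function(epochs) {
  stopifnot(inherits(epochs, "mi_epochs"))
  d <- dim(epochs$data)
  accum <- list(`1` = matrix(0, d[2], d[2]), `-1` = matrix(0, d[2], d[2]))
  counts <- c(`1` = 0, `-1` = 0)
  for (i in seq_len(d[1])) {
    D <- epochs$data[i, , , drop = TRUE]
    if (d[2] == 1) D <- matrix(D, nrow = 1)
    M <- tcrossprod(D)
    tr <- sum(diag(M))
    if (tr <= 0) {
      abort(sprintf("Trial %d has zero power (trace(DD') = 0).", i),
            class = "micsp_error_degenerate_trial")
    }
    key <- as.character(epochs$labels[i])
    accum[[key]] <- accum[[key]] + M / tr
    counts[key] <- counts[key] + 1
  }
  structure(
    list(cov1 = accum[["1"]] / counts["1"],
         cov2 = accum[["-1"]] / counts["-1"],
         n1 = unname(counts["1"]), n2 = unname(counts["-1"]),
         channel_names = epochs$channel_names),
    class = "mi_covs"
  )
}

#' Solve the CSP generalized eigenproblem
#'
#' Finds spatial filters `w` maximizing the variance ratio
#' `w' C1 w / w' C2 w` by solving `C1 w = lambda C2 w`. The problem is
#' solved in symmetric-definite form (whitening by `C2`) rather than via
#' `solve(C2) %*% C1`, which keeps the eigenvectors numerically
#' `C2`-orthogonal. Columns are ordered by descending eigenvalue and the
#' first `m` and last `m` are retained; each filter is normalized so that
#' `w' C2 w = 1` and its largest-magnitude component is positive.
#'
#' @param covs An [compute_class_covariances()] result.
#' @param m Number of filters kept from each end of the spectrum
#'   (default 3); `2 * m` must not exceed the channel count.
#'
#' @return An object of class `mi_csp`: projection matrix `W` (channels x
#'   `2 m`), `m`, the `2 m` retained eigenvalues `eigvals` (descending), and
#'   `full_eigvals` (all channels).
#' @export
solve_csp <- function(covs, m = 3) {
  stopifnot(inherits(covs, "mi_covs"))
  C <- nrow(covs$cov2)
  if (2 * m > C) {
    abort(sprintf("2*m = %d exceeds channel count %d.", 2 * m, C),
          class = "micsp_error_shape")
  }
  ridge <- 1e-10 * sum(diag(covs$cov2)) / C
  C2 <- covs$cov2 + diag(ridge, C)
  e2 <- eigen((C2 + t(C2)) / 2, symmetric = TRUE)
  if (min(e2$values) <= 0) {
    abort("Class-2 covariance is numerically singular beyond ridge loading.",
          class = "micsp_error_singular")
  }
  whiten <- e2$vectors %*% diag(1 / sqrt(e2$values), C)
  S <- t(whiten) %*% covs$cov1 %*% whiten
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)   # descending values
  W_full <- whiten %*% es$vectors
  keep <- c(seq_len(m), seq(C - m + 1, C))
  W <- W_full[, keep, drop = FALSE]
  # sign convention: largest-magnitude component positive
  for (j in seq_len(ncol(W))) {
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- covs$channel_names
  colnames(W) <- paste0("csp", seq_len(2 * m))
  structure(
    list(W = W, m = as.integer(m), eigvals = es$values[keep],
         full_eigvals = es$values, channel_names = covs$channel_names),
    class = "mi_csp"
  )
}

#' @export
print.mi_csp <- function(x, ...) {
  cat(sprintf("<mi_csp> %d channels -> %d spatial filters (m = %d)\n",
              nrow(x$W), ncol(x$W), x$m))
  cat("eigenvalues:", paste(signif(x$eigvals, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project epochs through spatial filters
#'
#' Computes `Z = W' D` for every trial, yielding `2 m` virtual channels.
#'
#' @param epochs An [epoch_set()] object.
#' @param filters An [solve_csp()] result.
#'
#' @return An object of class `mi_projected`: `data` (trials x `2 m` x
#'   samples), `fs`, and the trial `labels`.
#' @export
project <- function(epochs, filters) {
  stopifnot(inherits(epochs, "mi_epochs"), inherits(filters, "mi_csp"))
  d <- dim(epochs$data)
  if (d[2] != nrow(filters$W)) {
    abort(sprintf("Epochs have %d channels but filters expect %d.",
                  d[2], nrow(filters$W)),
          class = "micsp_error_shape")
  }
  p <- ncol(filters$W)
  out <- array(0, dim = c(d[1], p, d[3]))
  for (i in seq_len(d[1])) {
    D <- epochs$data[i, , , drop = TRUE]
    if (d[2] == 1) D <- matrix(D, nrow = 1)
    out[i, , ] <- crossprod(filters$W, D)
  }
  structure(
    list(data = out, fs = epochs$fs, labels = epochs$labels),
    class = "mi_projected"
  )
}

#' @export
print.mi_projected <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mi_projected> %d trials x %d virtual channels x %d samples\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Classic CSP log-variance features
#'
#' Per trial, `f_p = log(var(Z_p) / sum_i var(Z_i))` over the `2 m`
#' projected channels (population variance). The normalization makes
#' `sum_p exp(f_p) = 1` exactly.
#'
#' @param proj An [project()] result.
#'
#' @return A feature tibble (class `mi_features`): a `label` column plus one
#'   `chX_logvar` column per projected channel.
#' @export
logvar_features <- function(proj) {
  stopifnot(inherits(proj, "mi_projected"))
  d <- dim(proj$data)
  vals <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    v <- apply(proj$data[i, , , drop = FALSE][1, , , drop = TRUE], 1, pop_var)
    if (any(v <= 0)) {
      abort(sprintf("Trial %d has a zero-variance projected channel.", i),
            class = "micsp_error_degenerate_feature")
    }
    vals[i, ] <- log(v / sum(v))
  }
  info <- tibble::tibble(
    name = sprintf("ch%d_logvar", seq_len(d[2])),
    channel = seq_len(d[2]),
    low_hz = NA_real_, high_hz = NA_real_,
    statistic = "logvar"
  )
  new_features(vals, info, proj$labels)
}
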