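# Internal helpers shared across modules.

# Largest eigenvalue of a symmetric PSD matrix by power iteration.
# Deterministic start; tol is on the relative change of the eigenvalue.
power_iteration_norm <- function(M, tol = 1e-10, max_iter = 5000) {
  p <- nrow(M)
  v <- rep(1 / sqrt(p), p)
  lam <- 0
  for (i in seq_len(max_iter)) {
    u <- M %*% v
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(0)
    v <- as.numeric(u / nu)
    lam_new <- as.numeric(crossprod(v, M %*% v))
    if (abs(lam_new - lam) <= tol * max(1, abs(lam_new))) return(lam_new)
    lam <- lam_new
  }
  lam
}

# Moore-Penrose pseudo-inverse via SVD (kept tiny; used for unmixing geometry).
pseudo_inverse <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Population variance (divide by n); the normalized log-variance ratio is
# insensitive to the n vs n-1 choice but we fix one for reproducibility.
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

check_labels <- function(labels, call = rlang::caller_env()) {
  if (!is.numeric(labels) || !all(labels %in% c(-1, 1))) {
    abort("`labels` must be a numeric vector of -1/+1 values.",
          class = "micsp_error_labels", call = call)
  }
  invisible(labels)
}

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
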