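test_that("class covariances are trace-normalized per trial then averaged", {
  # single trial with DD' = diag(3, 1): normalized covariance diag(.75, .25)
  D <- rbind(c(sqrt(3), 0), c(0, 1)) %*% diag(c(1, 1))
  data <- array(0, c(2, 2, 2))
  data[1, , ] <- D
  data[2, , ] <- matrix(rnorm(4), 2)
  ep <- epoch_set(data, c(1, -1), fs = 100)
  covs <- compute_class_covariances(ep)
  expect_equal(covs$cov1, diag(c(0.75, 0.25)), tolerance = 1e-12)
  # duplicated trials: average equals the single-trial normalized covariance
  data2 <- array(0, c(3, 2, 2))
  data2[1, , ] <- D; data2[2, , ] <- D; data2[3, , ] <- matrix(rnorm(4), 2)
  covs2 <- compute_class_covariances(epoch_set(data2, c(1, 1, -1), 100))
  expect_equal(covs2$cov1, covs$cov1, tolerance = 1e-12)
})

test_that("class covariances match a direct loop over the defining average", {
  ep <- random_epochs(n_trials = 10, n_channels = 5, n_samples = 40, seed = 2)
  covs <- compute_class_covariances(ep)
  for (cls in c(1, -1)) {
    idx <- which(ep$labels == cls)
    acc <- matrix(0, 5, 5)
    for (i in idx) {
      D <- ep$data[i, , ]
      acc <- acc + tcrossprod(D) / sum(D^2)
    }
    ref <- acc / length(idx)
    got <- if (cls == 1) covs$cov1 else covs$cov2
    expect_equal(got, ref, tolerance = 1e-12)
    expect_equal(sum(diag(got)), 1, tolerance = 1e-10)
    expect_equal(got, t(got), tolerance = 1e-10)
  }
})

test_that("an all-zero trial is rejected by name", {
  data <- array(rnorm(3 * 2 * 10), c(3, 2, 10))
  data[2, , ] <- 0
  err <- expect_error(
    compute_class_covariances(epoch_set(data, c(1, -1, 1), 100)),
    class = "micsp_error_degenerate_trial")
  expect_match(conditionMessage(err), "2")
})

test_that("diagonal covariance pair gives the known eigenvalues and axes", {
  covs <- structure(list(cov1 = diag(c(0.8, 0.2)), cov2 = diag(c(0.2, 0.8)),
                         n1 = 1, n2 = 1, channel_names = c("a", "b")),
                    class = "mi_covs")
  f <- solve_csp(covs, m = 1)
  expect_equal(f$eigvals, c(4, 0.25), tolerance = 1e-8)
  expect_equal(unname(abs(f$W[, 1] / sqrt(sum(f$W[, 1]^2)))), c(1, 0),
               tolerance = 1e-8)
  expect_equal(unname(abs(f$W[, 2] / sqrt(sum(f$W[, 2]^2)))), c(0, 1),
               tolerance = 1e-8)
})

test_that("identical class covariances give unit eigenvalues", {
  C <- random_spd(5, seed = 3); C <- C / sum(diag(C))
  covs <- structure(list(cov1 = C, cov2 = C, n1 = 1, n2 = 1,
                         channel_names = paste0("ch", 1:5)),
                    class = "mi_covs")
  f <- solve_csp(covs, m = 2)
  expect_equal(f$full_eigvals, rep(1, 5), tolerance = 1e-8)
})

test_that("top filter maximizes the Rayleigh variance ratio", {
  covs <- random_cov_pair(6, seed = 11)
  f <- solve_csp(covs, m = 1)
  J <- function(w) as.numeric((t(w) %*% covs$cov1 %*% w) /
                                (t(w) %*% covs$cov2 %*% w))
  j_top <- J(f$W[, 1])
  set.seed(12)
  for (i in 1:1000) {
    u <- rnorm(6); u <- u / sqrt(sum(u^2))
    expect_gte(j_top, J(u) - 1e-10)
  }
  expect_equal(j_top, f$eigvals[1], tolerance = 1e-8)
})

test_that("filters simultaneously diagonalize both covariances", {
  for (seed in 1:10) {
    covs <- random_cov_pair(6, seed = 100 + seed)
    f <- solve_csp(covs, m = 3)
    B2 <- t(f$W) %*% covs$cov2 %*% f$W
    expect_lt(max(abs(B2 - diag(diag(B2)))), 1e-8)
    expect_equal(unname(diag(B2)), rep(1, 6), tolerance = 1e-8)
    B1 <- t(f$W) %*% covs$cov1 %*% f$W
    expect_lt(max(abs(B1 - diag(diag(B1)))), 1e-8)
    expect_equal(unname(diag(B1)), f$eigvals, tolerance = 1e-8)
  }
})

test_that("eigenvalues are invariant to consistent channel permutation", {
  covs <- random_cov_pair(6, seed = 21)
  perm <- c(3, 1, 6, 2, 5, 4)
  covs_p <- covs
  covs_p$cov1 <- covs$cov1[perm, perm]
  covs_p$cov2 <- covs$cov2[perm, perm]
  expect_equal(solve_csp(covs, 2)$full_eigvals,
               solve_csp(covs_p, 2)$full_eigvals, tolerance = 1e-8)
})

test_that("2m filters cannot exceed the channel count", {
  expect_error(solve_csp(random_cov_pair(4, seed = 1), m = 3),
               class = "micsp_error_shape")
})

test_that("projection is the per-trial matrix product W'D", {
  ep <- random_epochs(n_trials = 4, n_channels = 4, n_samples = 16, seed = 5)
  covs <- compute_class_covariances(ep)
  f <- solve_csp(covs, m = 2)
  pr <- project(ep, f)
  expect_equal(dim(pr$data)[2], 4)
  # explicit loop oracle on one trial / one filter
  w <- f$W[, 1]
  manual <- vapply(seq_len(16), function(k) sum(w * ep$data[2, , k]),
                   numeric(1))
  expect_equal(pr$data[2, 1, ], manual, tolerance = 1e-12)
  # identity filters reproduce the data
  f_id <- f
  f_id$W <- diag(4)
  expect_equal(project(ep, f_id)$data, ep$data, tolerance = 1e-12)
  # zero trial projects to zero
  ep0 <- ep
  ep0$data[1, , ] <- 0
  expect_error(expect_equal(project(ep0, f)$data[1, , ],
                            matrix(0, 4, 16)), NA)
  # dimension mismatch
  ep_bad <- random_epochs(n_trials = 4, n_channels = 3, n_samples = 16)
  expect_error(project(ep_bad, f), class = "micsp_error_shape")
})

test_that("log-variance features satisfy the normalization identity", {
  set.seed(6)
  pr <- as_projected(array(rnorm(6 * 4 * 100), c(6, 4, 100)), fs = 100,
                     labels = rep(c(1, -1), 3))
  fm <- logvar_features(pr)
  vals <- feature_values(fm)
  expect_equal(rowSums(exp(vals)), rep(1, 6), tolerance = 1e-10)
  # equal-variance channels give log(1/2m)
  x <- rnorm(50)
  eq <- array(0, c(1, 4, 50))
  for (c in 1:4) eq[1, c, ] <- x * c(1, -1, 1, -1)[c]
  fm_eq <- logvar_features(as_projected(eq, 100))
  expect_equal(unname(feature_values(fm_eq)[1, ]), rep(log(1 / 4), 4),
               tolerance = 1e-10)
  # direct substitution: variances (1, 3) -> log(1/4), log(3/4)
  z1 <- rnorm(2000); z1 <- (z1 - mean(z1)) / sqrt(micsp:::pop_var(z1))
  z2 <- rnorm(2000); z2 <- (z2 - mean(z2)) / sqrt(micsp:::pop_var(z2))
  two <- array(0, c(1, 2, 2000))
  two[1, 1, ] <- z1; two[1, 2, ] <- sqrt(3) * z2
  fm2 <- logvar_features(as_projected(two, 100))
  expect_equal(unname(feature_values(fm2)[1, ]), log(c(1 / 4, 3 / 4)),
               tolerance = 1e-10)
  # zero-variance channel errors
  degen <- array(rnorm(1 * 2 * 10), c(1, 2, 10))
  degen[1, 2, ] <- 5
  expect_error(logvar_features(as_projected(degen, 100)),
               class = "micsp_error_degenerate_feature")
})
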