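test_that("soft thresholding matches its definition", {
  expect_equal(soft_threshold(2, 0.5), 1.5)
  expect_equal(soft_threshold(c(-0.3, 0.2), 0.5), c(0, 0))
  set.seed(14)
  v <- runif(50, -5, 5)
  expect_equal(soft_threshold(v, 1.2), sign(v) * pmax(abs(v) - 1.2, 0))
})

test_that("closed-form log prox collapses to zero under the clamp", {
  a <- 0.001
  expect_equal(prox_log(0, 0.1, a), 0)
  # |v| < a with an active clamp: the square root cancels to a - |v|
  v <- c(5e-4, -8e-4)
  expect_equal(prox_log(v, lambda_over_gamma = 0.01, a = a), c(0, 0))
  # |v| > a with active clamp: shrink by exactly a
  v2 <- c(0.5, -2)
  expect_equal(prox_log(v2, lambda_over_gamma = 10, a = a),
               v2 - a * sign(v2), tolerance = 1e-12)
  expect_error(prox_log(1, -0.1), class = "micsp_error_solver")
})

test_that("exact-mode prox matches the brute-force scalar minimizer", {
  set.seed(15)
  vs <- runif(120, -10, 10)
  for (lot in c(0.01, 0.1, 1)) {
    got <- prox_log(vs, lot, a = 0.001, mode = "exact_prox")
    ref <- vapply(vs, brute_force_prox_log, numeric(1), lot = lot, a = 0.001)
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("large-a exact prox reduces to soft thresholding", {
  set.seed(16)
  v <- runif(100, -3, 3)
  a <- 1e4
  lambda_over_gamma <- 50
  expect_equal(prox_log(v, lambda_over_gamma, a = a, mode = "exact_prox"),
               soft_threshold(v, lambda_over_gamma / a), tolerance = 1e-6)
})

test_that("LASSO solver reproduces closed-form solutions", {
  # zero targets: zero weights after one iteration
  set.seed(17)
  X <- matrix(rnorm(40 * 6), 40)
  fit0 <- ista_lasso(X, rep(0, 40), lambda = 0.5)
  expect_equal(unname(fit0$w), rep(0, 6))
  expect_true(fit0$converged)
  # null threshold: lambda >= ||X'y||_inf gives w = 0
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(30 * 5), 30)
    y <- sample(c(-1, 1), 30, replace = TRUE)
    lam <- max(abs(crossprod(X, y))) * 1.001
    expect_equal(unname(ista_lasso(X, y, lam)$w), rep(0, 5))
  }
  # orthonormal design: w = soft_threshold(X'y, lambda)
  for (seed in 1:10) {
    set.seed(100 + seed)
    Q <- qr.Q(qr(matrix(rnorm(50 * 8), 50)))
    y <- rnorm(50)
    lam <- 0.7
    fit <- ista_lasso(Q, y, lam, tol = 1e-10)
    expect_equal(unname(fit$w),
                 unname(soft_threshold(as.numeric(crossprod(Q, y)), lam)),
                 tolerance = 1e-8)
  }
})

test_that("LASSO objective trace is non-increasing", {
  set.seed(18)
  X <- matrix(rnorm(50 * 10), 50)
  y <- sample(c(-1, 1), 50, replace = TRUE)
  fit <- ista_lasso(X, y, lambda = 0.3)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
})

test_that("log solver fixed points behave as predicted", {
  # zero targets from zero start: one-iteration fixed point
  set.seed(19)
  X <- matrix(rnorm(30 * 5), 30)
  fit <- ista_log(X, rep(0, 30), lambda = 0.5)
  expect_equal(unname(fit$w), rep(0, 5))
  expect_equal(fit$iterations, 1L)
  # identity design: the iteration map is the prox of y
  y <- c(2, -1.5, 0.0004, 0.8, -3)
  fit_id <- ista_log(diag(5), y, lambda = 0.05, a = 0.001)
  expect_equal(unname(fit_id$w), prox_log(y, 0.05, 0.001),
               tolerance = 1e-6)
})

test_that("exact-mode log descent is monotone on random instances", {
  for (seed in 1:50) {
    set.seed(400 + seed)
    X <- matrix(rnorm(25 * 8), 25)
    y <- sample(c(-1, 1), 25, replace = TRUE)
    fit <- ista_log(X, y, lambda = 2^runif(1, -4, 2), mode = "exact_prox",
                    max_iter = 200)
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
  }
})

test_that("paper-mode log solver converges on well-conditioned problems", {
  for (seed in 1:10) {
    set.seed(500 + seed)
    N <- 100; P <- 60
    X <- matrix(rnorm(N * P), N)
    w_true <- c(rep(1, 3), rep(0, P - 3))
    y <- sign(X %*% w_true + 0.3 * rnorm(N))
    fit <- ista_log(scale(X), as.numeric(y), lambda = 0.5)
    expect_true(fit$converged)
  }
})

test_that("log solutions are locally optimal under random probes", {
  set.seed(20)
  X <- matrix(rnorm(20 * 5), 20)
  y <- sample(c(-1, 1), 20, replace = TRUE)
  lam <- 0.4
  fit <- ista_log(X, y, lam, mode = "exact_prox", tol = 1e-10,
                  max_iter = 5000)
  obj <- function(w) 0.5 * sum((y - X %*% w)^2) + lam * sum(log1p(abs(w) / 0.001))
  o_hat <- obj(fit$w)
  set.seed(21)
  for (i in 1:10000) {
    probe <- fit$w + rnorm(5, sd = 0.01 * sample(c(0.1, 1, 10), 1))
    expect_gte(obj(probe), o_hat - 1e-9)
  }
})

test_that("column permutation permutes weights identically", {
  set.seed(22)
  X <- matrix(rnorm(40 * 8), 40)
  y <- sample(c(-1, 1), 40, replace = TRUE)
  perm <- sample(8)
  for (pen in c("lasso", "log")) {
    f1 <- micsp:::ista_engine(X, y, 0.3, penalty = pen, tol = 1e-10)
    f2 <- micsp:::ista_engine(X[, perm], y, 0.3, penalty = pen, tol = 1e-10)
    expect_equal(unname(f2$w), unname(f1$w[perm]), tolerance = 1e-6)
  }
})

test_that("the dyadic lambda grid has 51 points spanning 2^-5..2^5", {
  g <- lambda_grid()
  expect_length(g, 51)
  expect_equal(range(g), c(2^-5, 2^5))
})

test_that("CV selects a support containing the informative features", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(600 + seed)
    N <- 60; P <- 60
    X <- matrix(rnorm(N * P), N)
    y <- rep(c(1, -1), each = N / 2)
    X[, 1:3] <- X[, 1:3] + 1.5 * y       # 3 informative columns
    cv <- cv_select_lambda(X, y, selector = "log", folds = 10,
                           grid = lambda_grid(-5, 5, 0.5), seed = seed)
    w <- ista_log(fit_scaler(X)$X, y, cv$lambda)$w
    if (all(abs(w[1:3]) > 0)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("constant features yield a deterministic fallback lambda", {
  X <- matrix(1, 20, 4)
  y <- rep(c(1, -1), 10)
  cv1 <- cv_select_lambda(X, y, folds = 5, grid = lambda_grid(-2, 2, 1),
                          seed = 3)
  cv2 <- cv_select_lambda(X, y, folds = 5, grid = lambda_grid(-2, 2, 1),
                          seed = 3)
  expect_equal(cv1$lambda, cv2$lambda)
  expect_true(is.finite(cv1$lambda))
})

test_that("CV refuses fewer trials than folds", {
  expect_error(cv_select_lambda(matrix(rnorm(8 * 2), 8),
                                rep(c(1, -1), 4), folds = 10),
               class = "micsp_error_cv")
})

test_that("scaler standardizes training columns and applies frozen", {
  set.seed(23)
  X <- matrix(rnorm(30 * 4, mean = 5, sd = 3), 30)
  sc <- fit_scaler(X)
  expect_equal(colMeans(sc$X), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(sc$X, 2, sd), rep(1, 4), tolerance = 1e-12)
  X_new <- matrix(rnorm(10 * 4), 10)
  expect_equal(apply_scaler(sc, X_new),
               sweep(sweep(X_new, 2, sc$center), 2, sc$scale, "/"))
})
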