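# Shared fixtures, generated in code.

# Random symmetric positive-definite matrix with moderate conditioning.
random_spd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(0.1, n)
}

# Trace-normalized SPD pair wrapped as an mi_covs object.
random_cov_pair <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  c1 <- random_spd(n); c2 <- random_spd(n)
  structure(list(cov1 = c1 / sum(diag(c1)), cov2 = c2 / sum(diag(c2)),
                 n1 = 1, n2 = 1, channel_names = paste0("ch", seq_len(n))),
            class = "mi_covs")
}

# Small random epoch set.
random_epochs <- function(n_trials = 10, n_channels = 4, n_samples = 64,
                          fs = 100, seed = 1) {
  set.seed(seed)
  labels <- rep(c(1, -1), length.out = n_trials)
  epoch_set(array(rnorm(n_trials * n_channels * n_samples),
                  c(n_trials, n_channels, n_samples)),
            labels, fs)
}

# Wrap a trials x channels x samples array of projected signals.
as_projected <- function(data, fs, labels = NULL) {
  structure(list(data = data, fs = fs, labels = labels),
            class = "mi_projected")
}

# Sinusoid helper.
sinusoid <- function(freq, fs, seconds, amplitude = 1) {
  amplitude * sin(2 * pi * freq * seq(0, seconds, by = 1 / fs))
}

# Scalar objective of the log-penalty proximal problem; the brute-force
# minimizer (dense grid + local refinement, 0 always a candidate) serves as
# the independent oracle for prox_log's exact mode.
prox_log_objective <- function(x, v, lot, a) {
  lot * log1p(abs(x) / a) + 0.5 * (x - v)^2
}

brute_force_prox_log <- function(v, lot, a) {
  xs <- seq(-abs(v) - 1, abs(v) + 1, length.out = 4001)
  best <- xs[which.min(prox_log_objective(xs, v, lot, a))]
  step <- xs[2] - xs[1]
  refined <- stats::optimize(prox_log_objective,
                             c(best - step, best + step),
                             v = v, lot = lot, a = a, tol = 1e-10)$minimum
  cands <- c(refined, 0)
  cands[which.min(prox_log_objective(cands, v, lot, a))]
}

# Frozen independent-oracle vectors for the periodized db4 analysis step
# (input: a fixed 16-sample standard-normal draw).
pywt_fixture <- list(
  x = c(1.764052345967664, 0.4001572083672233, 0.9787379841057392,
        2.240893199201458, 1.8675579901499675, -0.977277879876411,
        0.9500884175255894, -0.1513572082976979, -0.10321885179355784,
        0.41059850193837233, 0.144043571160878, 1.454273506962975,
        0.7610377251469934, 0.12167501649282841, 0.44386323274542566,
        0.33367432737426683),
  approx = c(0.5157075743548873, 1.1592293633906585, 2.361513738963637,
             1.2452375077862405, 0.3288265662008981, -0.1028782412832954,
             1.0769480574769146, 0.93818241133043),
  detail = c(0.8673311911941248, -2.0245420494891015, -0.274476318907728,
             0.3920852530081245, 0.7170330634079192, -0.49149466441049094,
             -0.2731977877298371, -1.0153389038719602)
)
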