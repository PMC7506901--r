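test_that("filter bank construction matches the overlap arithmetic", {
  fb <- make_filter_bank(8, 30, 4, 2)
  expect_equal(nrow(fb$bands), 10)
  expect_equal(fb$bands$low_hz, seq(8, 26, by = 2))
  expect_equal(fb$bands$high_hz, seq(12, 30, by = 2))
  expect_equal(nrow(make_filter_bank(4, 40, 4, 2)$bands), 17)
  one <- make_filter_bank(8, 12, 4, 2)
  expect_equal(nrow(one$bands), 1)
  expect_equal(c(one$bands$low_hz, one$bands$high_hz), c(8, 12))
  expect_error(make_filter_bank(8, 10, 4, 2), class = "micsp_error_bank")
})

test_that("DWT plan tiles Nyquist dyadically and selects the sensorimotor bands", {
  p <- plan_wavelet(100, "dwt")
  expect_equal(p$levels, 3L)
  expect_equal(p$intervals$low_hz, c(0, 6.25, 12.5, 25))
  expect_equal(p$intervals$high_hz, c(6.25, 12.5, 25, 50))
  expect_equal(p$intervals$label, c("A3", "D3", "D2", "D1"))
  expect_equal(p$selected, 2:4)   # intersect rule keeps D3, D2, D1
  # the within rule additionally drops partially-overlapping bands
  p_within <- plan_wavelet(100, "dwt", selection_rule = "within_8_30")
  sel <- p_within$intervals[p_within$intervals$band %in% p_within$selected, ]
  expect_true(all(sel$low_hz >= 8 & sel$high_hz <= 30))
})

test_that("WPD plan yields 2^L equal bands with the documented selection", {
  p <- plan_wavelet(100, "wpd")
  expect_equal(nrow(p$intervals), 8)
  expect_equal(unique(round(p$intervals$high_hz - p$intervals$low_hz, 10)),
               6.25)
  # intersect rule keeps the 4 bands covering 6.25-31.25 Hz
  sel <- p$intervals[p$intervals$band %in% p$selected, ]
  expect_equal(nrow(sel), 4)
  expect_equal(min(sel$low_hz), 6.25)
  expect_equal(max(sel$high_hz), 31.25)
})

test_that("selected frequency intervals are depth-invariant at both rates", {
  sel_intervals <- function(fs, L) {
    p <- plan_wavelet(fs, "dwt", levels = L)
    s <- p$intervals[p$intervals$band %in% p$selected,
                     c("low_hz", "high_hz")]
    s[order(s$low_hz), ]
  }
  expect_equal(sel_intervals(100, 3), sel_intervals(100, 4),
               ignore_attr = TRUE)
  expect_equal(sel_intervals(250, 4), sel_intervals(250, 5),
               ignore_attr = TRUE)
  # 256 Hz is planned like 250 Hz: same number of selected bands
  expect_equal(length(plan_wavelet(256, "dwt")$selected),
               length(plan_wavelet(250, "dwt")$selected))
})

test_that("planning fails when the rate cannot support the depth", {
  expect_error(plan_wavelet(4, "dwt", levels = 6),
               class = "micsp_error_plan")
  expect_error(plan_wavelet(100, "dwt", selection_rule = "explicit"),
               class = "micsp_error_plan")
})

test_that("periodized analysis step reproduces the independent oracle vectors", {
  s <- micsp:::dwt_step_periodic(pywt_fixture$x)
  expect_equal(s$approx, pywt_fixture$approx, tolerance = 1e-12)
  expect_equal(s$detail, pywt_fixture$detail, tolerance = 1e-12)
})

test_that("constant signals put no energy in detail bands", {
  plan <- plan_wavelet(100, "dwt", selection_rule = "explicit",
                       selected = 1:4)
  bands <- dwt_subband_coeffs(rep(3, 128), plan)
  detail_energy <- sum(vapply(bands[-1], subband_energy, numeric(1)))
  expect_lt(detail_energy, 1e-10 * subband_energy(rep(3, 128)))
  # WPD: all non-lowest bands vanish too
  plan_w <- plan_wavelet(100, "wpd", selection_rule = "explicit",
                         selected = 1:8)
  bands_w <- wpd_subband_coeffs(rep(3, 128), plan_w)
  expect_lt(sum(vapply(bands_w[-1], subband_energy, numeric(1))), 1e-10)
})

test_that("Parseval holds for DWT and WPD under periodization", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(256)
    plan <- plan_wavelet(100, "dwt", selection_rule = "explicit",
                         selected = 1:4)
    e <- sum(vapply(dwt_subband_coeffs(x, plan), subband_energy, numeric(1)))
    expect_equal(e, sum(x^2), tolerance = 1e-8)
    plan_w <- plan_wavelet(100, "wpd", selection_rule = "explicit",
                           selected = 1:8)
    ew <- sum(vapply(wpd_subband_coeffs(x, plan_w), subband_energy,
                     numeric(1)))
    expect_equal(ew, sum(x^2), tolerance = 1e-8)
  }
})

test_that("a pure tone's energy localizes in the containing sub-band", {
  # 20 Hz at fs = 100: DWT band D2 (12.5-25 Hz)
  x <- sinusoid(20, 100, seconds = 10.23)   # 1024 samples
  plan <- plan_wavelet(100, "dwt", selection_rule = "explicit",
                       selected = 1:4)
  bands <- dwt_subband_coeffs(x[1:1024], plan)
  energies <- vapply(bands, subband_energy, numeric(1))
  target <- which(plan$intervals$low_hz <= 20 & plan$intervals$high_hz > 20)
  expect_gte(energies[target] / sum(energies), 0.7)
  # 20 Hz at fs = 250, depth 4 WPD: catches missing frequency reordering
  y <- sinusoid(20, 250, seconds = 5)[1:1024]
  plan_w <- plan_wavelet(250, "wpd", levels = 4,
                         selection_rule = "explicit", selected = 1:16)
  bands_w <- wpd_subband_coeffs(y, plan_w)
  energies_w <- vapply(bands_w, subband_energy, numeric(1))
  target_w <- which(plan_w$intervals$low_hz <= 20 &
                      plan_w$intervals$high_hz > 20)
  expect_equal(unname(which.max(energies_w)), target_w)
  expect_gte(energies_w[target_w] / sum(energies_w), 0.6)
})

test_that("sub-band statistics match their definitions", {
  expect_equal(subband_energy(c(1, 2, 2)), 9)
  expect_equal(subband_energy(rep(0, 5)), 0)
  expect_equal(subband_std(c(1, 2, 3)), 1)
  expect_equal(subband_std(rep(4, 6)), 0)
  set.seed(8)
  v <- rnorm(37)
  expect_equal(subband_energy(v), sum(vapply(v, function(z) z^2, numeric(1))),
               tolerance = 1e-12)
  mu <- sum(v) / length(v)
  expect_equal(subband_std(v),
               sqrt(sum((v - mu)^2) / (length(v) - 1)), tolerance = 1e-12)
  expect_error(subband_energy(numeric(0)), class = "micsp_error_data")
  expect_error(subband_std(1), class = "micsp_error_data")
})

test_that("signals shorter than the depth requires are rejected", {
  plan <- plan_wavelet(100, "dwt", levels = 5)
  expect_error(dwt_subband_coeffs(rnorm(16), plan),
               class = "micsp_error_decomposition")
})

test_that("symmetric boundary mode stays close to energy preservation", {
  set.seed(55)
  x <- rnorm(256)
  plan <- plan_wavelet(100, "dwt", boundary_mode = "symmetric",
                       selection_rule = "explicit", selected = 1:4)
  e <- sum(vapply(dwt_subband_coeffs(x, plan), subband_energy, numeric(1)))
  expect_equal(e / sum(x^2), 1, tolerance = 0.2)
})
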