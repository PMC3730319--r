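# Spectral post-processing chain: alignment, TMSP scaling, water removal,
# baseline correction, robust-mean normalization, binning.

render_one <- function(conc = NULL, params = render_params(), seed = 5) {
  lib <- metabolite_library()
  if (is.null(conc)) {
    conc <- setNames(rep(1, length(lib)), names(lib))
  }
  render_spectrum(conc, lib, params, seed = seed)
}

test_that("alignment recovers a planted calibration shift", {
  s <- render_one(params = quiet_params())
  a0 <- align_to_reference(s, "glucose_5.223")
  expect_lt(abs(attr(a0, "shift_applied")), 0.001)   # already aligned: ~zero shift

  sh <- render_one(params = quiet_params(shift = 0.02))
  a <- align_to_reference(sh, "glucose_5.223")
  expect_lt(abs(attr(a, "shift_applied") + 0.02), 0.001)  # recovered -0.02

  flat <- new_spectrum(seq(10, -0.5, by = -0.01), rep(0, 1051))
  expect_error(align_to_reference(flat, "glucose_5.223"),
               class = "hypoxiaNMR_reference_not_found")
})

test_that("glucose-depleted spectra fall back to the TMSP reference", {
  lib <- metabolite_library()
  conc <- setNames(rep(1, length(lib)), names(lib))
  conc["glucose"] <- 0.005   # below detection, as after 48 h of hypoxia
  s <- render_spectrum(conc, lib, render_params(shift = 0.015), seed = 2)
  a <- align_spectrum(s)
  expect_identical(attr(a, "align_mode"), "tmsp_0")
  expect_lt(abs(attr(a, "shift_applied") + 0.015), 0.001)
})

test_that("TMSP scaling normalizes the apex to 1 and cancels global gain", {
  s1 <- render_one(params = render_params(gain = 1), seed = 9)
  s7 <- render_one(params = render_params(gain = 7.3), seed = 9)
  t1 <- scale_to_tmsp(s1)
  t7 <- scale_to_tmsp(s7)
  expect_equal(max(t1$intensity[abs(t1$ppm) < 0.05]), 1, tolerance = 1e-12)
  expect_equal(t1$intensity, t7$intensity, tolerance = 1e-9)
  expect_equal(scale_to_tmsp(t1)$intensity, t1$intensity, tolerance = 1e-12)
})

test_that("water removal excises the closed interval and is idempotent", {
  ppm <- rev(0:10000) / 1000          # exact thousandths over 0-10 ppm
  s <- new_spectrum(ppm, seq_along(ppm))
  expected <- sum(ppm >= 4.5 & ppm <= 5.0)  # enumeration oracle
  expect_identical(expected, 501L)
  r <- remove_water(s)
  expect_length(r$ppm, length(ppm) - expected)
  expect_identical(remove_water(r)$ppm, r$ppm)
  # spectrum entirely outside the window is unchanged
  s2 <- new_spectrum(seq(4, 0, by = -0.01), rep(1, 401))
  expect_identical(remove_water(s2), s2)
})

test_that("baseline correction recovers planted smooth drift", {
  s0 <- render_one(params = quiet_params(), seed = 3)
  # zero baseline: spectrum unchanged within tolerance
  b0 <- baseline_correct(s0)
  expect_lt(max(abs(b0$intensity - s0$intensity)), 0.05 * max(s0$intensity))

  # a pure flat offset is absorbed into the baseline entirely
  flat <- new_spectrum(s0$ppm, rep(5, length(s0$ppm)))
  bflat <- baseline_correct(flat)
  expect_lt(max(abs(bflat$intensity)), 1e-3)

  # quadratic drift: residual RMS below 5% of the drift amplitude off-peak
  amp <- 3
  drift <- amp * ((s0$ppm - min(s0$ppm)) / diff(range(s0$ppm)))^2
  sd0 <- s0; sd0$intensity <- s0$intensity + drift
  bd <- baseline_correct(sd0)
  offpeak <- s0$intensity < 0.01
  expect_lt(sqrt(mean(bd$intensity[offpeak]^2)), 0.05 * amp)
})

test_that("robust-mean normalization matches a brute-force trimmed mean", {
  # 20-point toy: drop 1 point per tail, average the central 18
  y <- c(101, 3, 7, 2, 9, 4, 8, 5, 6, 10, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5, 8.5, 9.5, -50)
  ppm <- seq(4.39, by = -0.2, length.out = 20)
  s <- new_spectrum(ppm, y)
  oracle <- mean(sort(y)[2:19])
  n <- robust_mean_normalize(s, trim = 0.05)
  expect_equal(n$intensity, y / oracle, tolerance = 1e-12)

  # scale invariance and idempotence
  sk <- s; sk$intensity <- 17 * y
  expect_equal(robust_mean_normalize(sk, trim = 0.05)$intensity, n$intensity,
               tolerance = 1e-12)
  expect_equal(robust_mean_normalize(n, trim = 0.05)$intensity, n$intensity,
               tolerance = 1e-12)
  neg <- s; neg$intensity <- -y
  expect_error(robust_mean_normalize(neg), class = "hypoxiaNMR_degenerate_spectrum")
})

test_that("binning yields 420 bins and conserves in-range intensity", {
  s <- render_one(seed = 21)
  b <- bin_spectrum(s)
  expect_length(b, 420)
  expect_length(attr(b, "bin_edges"), 421)
  expect_equal(diff(attr(b, "bin_edges")), rep(0.01, 420), tolerance = 1e-12)

  # conservation against a brute-force loop oracle
  inr <- s$ppm >= 0.2 & s$ppm <= 4.4
  expect_equal(sum(b), sum(s$intensity[inr]), tolerance = 1e-9)
  oracle <- vapply(1:420, function(j) {
    lo <- 0.2 + 0.01 * (0:420)[j]; hi <- 0.2 + 0.01 * (0:420)[j + 1]
    keep <- if (j < 420) s$ppm >= lo & s$ppm < hi else s$ppm >= lo & s$ppm <= hi
    sum(s$intensity[keep])
  }, 0)
  expect_equal(as.numeric(b), oracle, tolerance = 1e-9)

  # constant intensity, 10 points per bin
  ppm <- rev(0:10500) / 1000 + 0.0005
  su <- new_spectrum(ppm, rep(1, length(ppm)))
  expect_true(all(bin_spectrum(su) == 10))

  short <- new_spectrum(seq(4, 1, by = -0.01), rep(1, 301))
  expect_error(bin_spectrum(short), class = "hypoxiaNMR_coverage")
})

test_that("full chain is invariant to global gain and axis shift (2% RMS)", {
  lib <- metabolite_library()
  conc <- conc_values(get_study1()$truth)[1, ]
  pa <- render_params(gain = 1, shift = 0)
  pb <- render_params(gain = 7.3, shift = 0.012)
  sa <- render_spectrum(conc, lib, pa, seed = 4)
  sb <- render_spectrum(conc, lib, pb, seed = 4)
  ba <- bin_spectrum(preprocess_spectrum(sa))
  bb <- bin_spectrum(preprocess_spectrum(sb))
  rms_rel <- sqrt(mean((ba - bb)^2)) / sqrt(mean(ba^2))
  expect_lt(rms_rel, 0.02)
})
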