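test_that("noise-free simulation puts the peak maximum at its position", {
  ax <- shift_axis()
  pos <- ax$ppm[590]                      # exactly on an axis point
  pk <- peak_model("W106", pos, 60, 2.5)
  sp <- simulate_spectrum(pk, ax, noise_sigma = 0)
  i <- which.max(sp$intensity)
  expect_equal(sp$ppm[i], pos)
  expect_equal(max(sp$intensity), 2.5, tolerance = 1e-6)
  expect_false(sp$meta$narrow_peaks)
  expect_error(simulate_spectrum(pk[0, ], ax), "at least one peak")
  # a width below two axis steps is flagged
  narrow <- simulate_spectrum(peak_model("x", -124, 1, 1), ax)
  expect_true(narrow$meta$narrow_peaks)
})

test_that("noise estimation recovers the generator sigma", {
  ax <- shift_axis(n = 20000)
  pk <- peak_model("far", -127.9, 30, 1)   # peak far from the region
  zero <- simulate_spectrum(peak_model("none", -124, 30, 0), ax, 0)
  expect_equal(estimate_noise(zero, c(-123, -120)), 0)
  noisy <- simulate_spectrum(pk, ax, noise_sigma = 1, seed = 5)
  # ~7500 points: sample sd within ~3/sqrt(2n) of truth
  expect_equal(estimate_noise(noisy, c(-123, -120)), 1, tolerance = 0.03)
  small <- simulate_spectrum(pk, ax, noise_sigma = 0.05, seed = 9)
  expect_equal(estimate_noise(small, c(-123, -120)), 0.05, tolerance = 0.1)
  expect_error(estimate_noise(noisy, c(50, 60)), "outside")
  expect_error(estimate_noise(noisy, c(-120.001, -120)), ">= 32 points")
})

test_that("free peak fitting round-trips the generator", {
  ax <- shift_axis()
  truth <- peak_model(c("A", "B"), c(-122.8, -124.9), c(70, 90), c(1.4, 0.8))
  sp <- simulate_spectrum(truth, ax, 0)
  fit <- fit_peaks(sp, truth)
  expect_true(attr(fit, "converged"))
  expect_equal(fit$amplitude, truth$amplitude, tolerance = 1e-6)
  expect_equal(fit$position_ppm, truth$position_ppm, tolerance = 1e-6)
  expect_equal(fit$fwhm_Hz, truth$fwhm_Hz, tolerance = 1e-6)
  # perturbed initial guesses: overlapping peaks 3 fwhm apart
  sep_ppm <- 3 * 90 / ax$frequency_MHz
  truth2 <- peak_model(c("A", "B"), c(-123, -123 - sep_ppm), c(90, 90),
                       c(1, 0.6))
  sp2 <- simulate_spectrum(truth2, ax, 0)
  init2 <- truth2
  init2$amplitude <- init2$amplitude * 0.7
  init2$position_ppm <- init2$position_ppm + 0.03
  fit2 <- fit_peaks(sp2, init2)
  expect_equal(fit2$amplitude, truth2$amplitude, tolerance = 0.01)
  expect_error(fit_peaks(sp, peak_model("x", -150, 50, 1)), "axis range")
})

test_that("locked-position fitting never moves a peak and is linear", {
  ax <- shift_axis()
  truth <- peak_model(c("A", "B"), c(-122.8, -124.9), c(70, 90), c(1.4, 0.8))
  sp <- simulate_spectrum(truth, ax, 0)
  init <- truth; init$amplitude <- c(1, 1)
  fit <- fit_peaks(sp, init, lock_positions = TRUE)
  expect_identical(fit$position_ppm, init$position_ppm)
  expect_identical(fit$fwhm_Hz, init$fwhm_Hz)
  expect_equal(fit$amplitude, truth$amplitude, tolerance = 1e-8)
  # scaling the slice scales the extracted amplitudes
  sp3 <- sp; sp3$intensity <- 3 * sp$intensity
  fit3 <- fit_peaks(sp3, init, lock_positions = TRUE)
  expect_equal(fit3$amplitude, 3 * fit$amplitude, tolerance = 1e-10)
})

test_that("strong doping broadens the four peaks beyond resolvability", {
  d <- default_design()
  ax <- shift_axis()
  r2_0 <- 1 / d$t2_0
  strong <- peak_model(d$residues, d$shifts_ppm[d$residues],
                       (r2_0 + 8 * 556.2) / pi, rep(1, 4))
  sp <- simulate_spectrum(strong, ax, 0)
  fit <- fit_peaks(sp, strong, lock_positions = TRUE)
  expect_gte(sum(!fit$resolvable), 1)
  mild <- peak_model(d$residues, d$shifts_ppm[d$residues],
                     (r2_0 + 8 * 38.2) / pi, rep(1, 4))
  fit_mild <- fit_peaks(simulate_spectrum(mild, ax, 0), mild,
                        lock_positions = TRUE)
  expect_true(all(fit_mild$resolvable))
})

test_that("pseudo-2D containers validate their invariants", {
  ax <- shift_axis()
  pk <- peak_model("A", -123, 60, 1)
  mk <- function(a) simulate_spectrum(peak_model("A", -123, 60, a), ax, 0)
  slices <- lapply(c(0.2, 0.5, 0.8, 1), mk)
  p <- pseudo2d(c(0.1, 0.3, 1, 3), slices, "satrec_T1", "none", 0)
  expect_s3_class(p, "pseudo2d")
  expect_error(pseudo2d(c(0.1, 0.3, 1), slices[1:3], "satrec_T1"), ">= 4")
  expect_error(pseudo2d(c(0.3, 0.1, 1, 3), slices, "satrec_T1"),
               "increasing")
  other <- simulate_spectrum(pk, shift_axis(n = 128), 0)
  expect_error(pseudo2d(c(0.1, 0.3, 1, 3), c(slices[1:3], list(other)),
                        "satrec_T1"), "share one axis")
})

test_that("intensity extraction inverts the exponential generator", {
  ax <- shift_axis()
  d <- default_design()
  delays <- d$delays_T1
  t1 <- c(A = 2, B = 0.8)
  pos <- c(A = -122.5, B = -125)
  slices <- lapply(delays, function(tau) {
    amp <- 1 - exp(-tau / t1)
    simulate_spectrum(peak_model(names(t1), pos, c(60, 80), amp), ax, 0)
  })
  p2d <- pseudo2d(delays, slices, "satrec_T1")
  iss <- extract_intensity_series(
    p2d, peak_model(names(t1), pos, c(60, 80), c(1, 1)))
  for (lab in names(t1)) {
    expect_equal(iss$series[[lab]]$intensities,
                 1 - exp(-delays / t1[[lab]]), tolerance = 1e-6)
  }
  # echo decay: monotone non-increasing at zero noise
  slices2 <- lapply(d$delays_T2, function(tau) {
    amp <- exp(-tau / c(A = 5e-3, B = 4e-3))
    simulate_spectrum(peak_model(names(t1), pos, c(60, 80), amp), ax, 0)
  })
  p2d2 <- pseudo2d(d$delays_T2, slices2, "echo_T2")
  iss2 <- extract_intensity_series(
    p2d2, peak_model(names(t1), pos, c(60, 80), c(1, 1)))
  expect_true(all(diff(iss2$series$A$intensities) <= 1e-9))
  expect_true(all(diff(iss2$series$B$intensities) <= 1e-9))
})

test_that("P2D-CSV interchange round-trips bit-exactly", {
  ax <- shift_axis(n = 128)
  delays <- c(0.01, 0.1, 1, 5)
  slices <- lapply(seq_along(delays), function(i) {
    simulate_spectrum(peak_model("A", -123, 60, 1), ax,
                      noise_sigma = 0.03, seed = i)
  })
  p2d <- pseudo2d(delays, slices, "satrec_T1", "Gd(DTPA-BMA)", 4)
  base <- file.path(tempdir(), "p2d_roundtrip")
  write_p2d(p2d, base)
  back <- read_p2d(base)
  expect_identical(back$delays, p2d$delays)
  expect_identical(back$experiment, "satrec_T1")
  expect_identical(back$dopant, "Gd(DTPA-BMA)")
  expect_identical(back$concentration_mM, 4)
  for (i in seq_along(delays)) {
    expect_identical(back$slices[[i]]$intensity, p2d$slices[[i]]$intensity)
    expect_equal(back$slices[[i]]$ppm, p2d$slices[[i]]$ppm,
                 tolerance = 1e-15)
  }
})
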