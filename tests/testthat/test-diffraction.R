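# Expected lattice spacings computed independently from d = lambda/(2 sin theta)
# at full double precision (frozen):
#   d(25.886 deg) = 3.455194 A, d(32.912 deg) = 2.731936 A, d(60 deg) = lambda.

test_that("Bragg's law reproduces the reference reflections", {
  expect_equal(bragg_d(25.886), 3.455194, tolerance = 1e-6)
  expect_equal(bragg_d(32.912), 2.731936, tolerance = 1e-6)
  expect_equal(bragg_d(60), 1.5478)          # sin 30 deg = 1/2
  expect_error(bragg_d(0), "0, 180")
  expect_error(bragg_d(181), "0, 180")
})

test_that("Bragg's law and its inverse compose to the identity", {
  for (tt in c(10, 25.886, 32.912, 60, 120)) {
    expect_equal(bragg_two_theta(bragg_d(tt)), tt, tolerance = 1e-10)
  }
})

test_that("hexagonal lattice constants follow from (002) and (300) spacings", {
  expect_equal(lattice_from_d(3.4552, c(0, 0, 2)),
               list(constant = "c", value_A = 6.9104))
  a <- lattice_from_d(2.7320, c(3, 0, 0))
  expect_equal(a$constant, "a")
  expect_equal(a$value_A, 2.7320 * sqrt(12), tolerance = 1e-12)
  expect_equal(a$value_A / 10, 0.94639, tolerance = 1e-4)
  expect_error(lattice_from_d(1, c(1, 1, 1)), "supported")
})

test_that("Scherrer equation matches frozen direct evaluations", {
  expect_equal(scherrer_size(0.7603, 25.886), 10.7714, tolerance = 1e-4)
  expect_equal(scherrer_size(0.4405, 25.886), 18.5913, tolerance = 1e-4)
  # D is inversely proportional to the width at fixed angle
  expect_equal(scherrer_size(0.7603 / 2, 25.886),
               2 * scherrer_size(0.7603, 25.886))
  expect_error(scherrer_size(0, 25.886), "positive")
})

test_that("Scherrer size is monotone: decreasing in width, increasing in angle", {
  widths <- seq(0.1, 2, length.out = 20)
  D <- scherrer_size(widths, 26)
  expect_true(all(diff(D) < 0))
  angles <- seq(10, 170, length.out = 20)
  D2 <- vapply(angles, function(a) scherrer_size(0.5, a), 0)
  expect_true(all(diff(D2) > 0))
})

test_that("Gaussian reflection fit recovers generation parameters and corrects broadening", {
  x <- seq(24, 28, by = 0.078)
  sig <- 0.7645 / (2 * sqrt(2 * log(2)))
  dg <- new_spectrum(seq(6, 110, by = 0.078),
                     50 + 1000 * exp(-(seq(6, 110, by = 0.078) - 25.886)^2 /
                                       (2 * sig^2)),
                     "XRD")
  f <- fit_reflection(dg, c(0, 0, 2), c(24, 28))
  expect_equal(f$center_2theta, 25.886, tolerance = 1e-4)
  expect_equal(f$fwhm_obs, 0.7645, tolerance = 1e-3)
  # quadrature removal of the 0.08 deg apparatus broadening
  expect_equal(f$fwhm_corrected, sqrt(0.7645^2 - 0.08^2), tolerance = 1e-3)
  expect_equal(f$fwhm_corrected, 0.760303, tolerance = 1e-3)
  expect_lt(f$fwhm_corrected, f$fwhm_obs)
})

test_that("degenerate windows fail loudly", {
  x <- seq(6, 110, by = 0.078)
  flat <- new_spectrum(x, rep(50, length(x)), "XRD")
  expect_error(fit_reflection(flat, c(0, 0, 2), c(24, 28)), "no peak")
  # width at the resolution limit is rejected after fitting
  sig <- 0.08 / (2 * sqrt(2 * log(2)))
  narrow <- new_spectrum(x, 50 + 1000 * exp(-(x - 26)^2 / (2 * sig^2)), "XRD")
  expect_error(fit_reflection(narrow, c(0, 0, 2), c(24, 28)),
               "instrument resolution")
})

test_that("noise-free simulated diffractograms round-trip the day anchors", {
  cfg <- noise_free_config()
  r0 <- analyze_diffractogram(simulate_diffractogram(0, cfg))
  expect_equal(r0$D_nm, 10.77, tolerance = 5e-3)
  expect_equal(r0$a_nm, 0.9457, tolerance = 5e-3)
  expect_equal(r0$c_nm * 10, 6.846, tolerance = 5e-3)
  r28 <- analyze_diffractogram(simulate_diffractogram(28, cfg))
  expect_equal(r28$D_nm, 18.59, tolerance = 5e-3)
  expect_equal(r28$a_nm, 0.9428, tolerance = 5e-3)
})

test_that("Poisson-noisy diffractograms recover crystallite size on average", {
  sizes <- vapply(1:20, function(i) {
    cfg <- sim_config(seed = 100 + i, noise_scale = 1)
    analyze_diffractogram(simulate_diffractogram(0, cfg))$D_nm
  }, 0)
  expect_lt(abs(mean(sizes) - 10.77) / 10.77, 0.02)
})

test_that("simulated diffractograms are deterministic given (seed, config)", {
  cfg <- sim_config(seed = 3, noise_scale = 1)
  a <- simulate_diffractogram(5, cfg)
  b <- simulate_diffractogram(5, cfg)
  expect_identical(a$intensity, b$intensity)
  expect_error(simulate_diffractogram(30, cfg), "outside")
})
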