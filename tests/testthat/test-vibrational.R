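ftir_grid <- seq(460, 4000, by = 4)
raman_grid <- seq(146, 1930, by = 1)

test_that("FTIR preprocessing normalizes at 1010 and flattens polynomial baselines", {
  # flat-baselined band spectrum with value 2.0 at 1010 normalizes to 1.0
  s <- gaussian_spectrum(ftir_grid, 2.0, 1010, 120)
  out <- preprocess_ftir(s)
  expect_equal(out$intensity[which.min(abs(out$axis - 1010))], 1.0,
               tolerance = 1e-6)
  expect_match(tail(out$preprocessing_log, 1), "preprocess_ftir")
  # a pure quadratic baseline with no bands is fully removed, which makes the
  # spectrum non-normalizable (nothing left at 1010)
  base <- new_spectrum(ftir_grid, 1 + 1e-3 * ftir_grid + 1e-7 * ftir_grid^2,
                       "FTIR")
  expect_error(preprocess_ftir(base), "non-normalizable")
  # the same baseline under a band is removed without distorting the band
  withband <- new_spectrum(ftir_grid, base$intensity +
                             gaussian_spectrum(ftir_grid, 1, 1010, 120)$intensity,
                           "FTIR")
  out2 <- preprocess_ftir(withband)
  away <- abs(out2$axis - 1010) > 400
  expect_lt(max(abs(out2$intensity[away])), 0.02)
})

test_that("second derivative resolves band centers with the expected sign", {
  s <- gaussian_spectrum(ftir_grid, 1, 1450, 40)
  d2 <- second_derivative(s)
  expect_lte(abs(d2$axis[which.min(d2$intensity)] - 1450), 4)
  # linear input maps to zero
  lin <- new_spectrum(ftir_grid, 0.1 + 2e-4 * ftir_grid, "FTIR")
  expect_lt(max(abs(second_derivative(lin)$intensity)), 1e-10)
  # overlapping bands at 1410/1450 are resolved into two local minima
  two <- new_spectrum(ftir_grid,
                      gaussian_spectrum(ftir_grid, 1, 1410, 30)$intensity +
                        gaussian_spectrum(ftir_grid, 0.8, 1450, 30)$intensity,
                      "FTIR")
  d2b <- second_derivative(two)
  idx <- which(d2b$axis >= 1380 & d2b$axis <= 1480)
  v <- d2b$intensity[idx]
  minima <- which(diff(sign(diff(v))) == 2) + 1
  expect_gte(length(minima), 2)
})

test_that("FTIR C/P ratio matches closed-form band areas and is scale invariant", {
  # carbonate area 0.06, phosphate area 1.0 by construction
  a_phos <- 1 / gaussian_area(1, 60)
  a_carb <- 0.06 / gaussian_area(1, 25)
  y <- gaussian_spectrum(ftir_grid, a_phos, 1030, 60)$intensity +
    gaussian_spectrum(ftir_grid, a_carb, 1425, 25)$intensity
  s <- new_spectrum(ftir_grid, y, "FTIR")
  expect_equal(cp_ratio_ftir(s), 0.06, tolerance = 1e-3 / 0.06)
  s3 <- new_spectrum(ftir_grid, 3 * y, "FTIR")
  expect_equal(cp_ratio_ftir(s3), cp_ratio_ftir(s), tolerance = 1e-12)
  # zero carbonate amplitude gives a zero ratio
  s0 <- gaussian_spectrum(ftir_grid, a_phos, 1030, 60)
  expect_equal(cp_ratio_ftir(s0), 0, tolerance = 1e-9)
})

test_that("splitting-factor arithmetic is exact on constructed doublets", {
  # spectrum taking values A603=0.8, A567=0.9, A590=0.5 over a zero baseline
  mk <- function(a603, a567, a590) {
    y <- numeric(length(ftir_grid))
    put <- function(x0, v) y[which.min(abs(ftir_grid - x0))] <<- v
    put(603, a603); put(567, a567); put(590, a590)
    new_spectrum(ftir_grid, y, "FTIR")
  }
  expect_equal(ci_ftir(mk(0.8, 0.9, 0.5)), 3.4)
  expect_equal(ci_ftir(mk(0.7, 0.7, 0.7)), 2.0)
  expect_error(ci_ftir(mk(0.8, 0.9, 0)), "degenerate valley")
})

test_that("splitting factor is >= 2 whenever the doublet maxima exceed the valley", {
  for (w in seq(8, 30, by = 2)) {
    s <- new_spectrum(ftir_grid,
                      gaussian_spectrum(ftir_grid, 1, 603, w)$intensity +
                        gaussian_spectrum(ftir_grid, 1, 567, w)$intensity,
                      "FTIR")
    expect_gte(ci_ftir(s), 2 - 1e-9)
  }
})

test_that("noise-free simulated FTIR spectra reproduce their CI and C/P draws", {
  cfg <- noise_free_config()
  tr <- default_trajectories()
  for (d in c(0, 7, 14, 28)) {
    s <- simulate_ftir_spectrum(d, cfg)
    expect_equal(ci_ftir(s), traj_at(tr$CI_FTIR, d), tolerance = 2e-3)
    expect_equal(cp_ratio_ftir(preprocess_ftir(s)), traj_at(tr$CP_FTIR, d),
                 tolerance = 5e-3)
  }
  # mature-enamel splitting factor exceeds the reported bound
  for (d in c(7, 10, 14, 21, 28)) {
    expect_gt(ci_ftir(simulate_ftir_spectrum(d, cfg)), 3.25)
  }
})

test_that("despiking removes isolated spikes and is identity on clean spectra", {
  cfg <- sim_config(seed = 11, noise_scale = 1, spike_rate = 0)
  clean <- simulate_raman_spectrum(10, cfg)
  expect_equal(despike(clean)$intensity, clean$intensity, tolerance = 1e-12)
  spiky <- clean
  hits <- c(300, 900, 1500)
  spiky$intensity[hits] <- spiky$intensity[hits] + 5
  fixed <- despike(spiky)
  expect_lt(max(abs(fixed$intensity[hits] - clean$intensity[hits])), 0.1)
  untouched <- setdiff(seq_along(clean$axis), hits)
  expect_equal(fixed$intensity[untouched], spiky$intensity[untouched])
})

test_that("fluorescence subtraction annihilates exact polynomials", {
  u <- (raman_grid - 1000) / 1000
  poly6 <- 2 + u - 0.5 * u^2 + 0.2 * u^3 - 0.1 * u^4 + 0.05 * u^5 + 0.01 * u^6
  s <- new_spectrum(raman_grid, poly6, "Raman")
  out <- subtract_fluorescence(s, order = 6)
  expect_lt(max(abs(out$intensity)), 1e-8)
})

test_that("rubber-band correction preserves well-separated peak areas", {
  y <- gaussian_spectrum(raman_grid, 1, 500, 20, "Raman")$intensity +
    gaussian_spectrum(raman_grid, 0.8, 1200, 25, "Raman")$intensity
  s <- new_spectrum(raman_grid, y, "Raman")
  out <- rubber_band(s)
  a1 <- band_integral(out, 400, 600, baseline = "none")$area
  a2 <- band_integral(out, 1100, 1300, baseline = "none")$area
  expect_equal(a1, gaussian_area(1, 20), tolerance = 0.01)
  expect_equal(a2, gaussian_area(0.8, 25), tolerance = 0.01)
})

test_that("pseudo-Voigt deconvolution recovers noise-free generation parameters", {
  a1 <- 0.5; a2 <- 0.2
  y <- gaussian_spectrum(raman_grid, a1, 1044, 14, "Raman")$intensity +
    gaussian_spectrum(raman_grid, a2, 1070, 16, "Raman")$intensity
  pair <- fit_carbonate_region(new_spectrum(raman_grid, y, "Raman"))
  centers <- vapply(pair$components, `[[`, 0, "center")
  expect_lt(abs(centers[1] - 1044), 0.2)
  expect_lt(abs(centers[2] - 1070), 0.2)
  areas <- vapply(pair$components, `[[`, 0, "area")
  expect_equal(areas[1], gaussian_area(a1, 14), tolerance = 0.01)
  expect_equal(areas[2], gaussian_area(a2, 16), tolerance = 0.01)
})

test_that("Raman metrics recover generation values and scale invariance holds", {
  cfg <- noise_free_config()
  tr <- default_trajectories()
  for (d in c(0, 14, 28)) {
    s <- raman_preprocess(simulate_raman_spectrum(d, cfg))
    expect_equal(ci_raman(s), traj_at(tr$CI_Raman, d), tolerance = 0.1 / 11)
    expect_equal(cp_ratio_raman(s), traj_at(tr$CP_Raman, d),
                 tolerance = 0.01 / 0.2)
  }
  # generated area ratio 0.3 recovers to 0.3
  a961 <- 1.0; f961 <- 11
  a1070 <- 0.3 * gaussian_area(a961, f961) / gaussian_area(1, 16)
  y <- gaussian_spectrum(raman_grid, a961, 961, f961, "Raman")$intensity +
    gaussian_spectrum(raman_grid, 0.15, 1044, 14, "Raman")$intensity +
    gaussian_spectrum(raman_grid, a1070, 1070, 16, "Raman")$intensity
  s <- new_spectrum(raman_grid, y, "Raman")
  expect_equal(cp_ratio_raman(s), 0.3, tolerance = 0.01 / 0.3)
  expect_equal(ci_raman(s), 11, tolerance = 0.1 / 11)
  # zero carbonate amplitude
  s0 <- new_spectrum(raman_grid,
                     gaussian_spectrum(raman_grid, a961, 961, f961,
                                       "Raman")$intensity +
                       gaussian_spectrum(raman_grid, 0.15, 1044, 14,
                                         "Raman")$intensity, "Raman")
  expect_lt(abs(cp_ratio_raman(s0)), 0.005)
  # global intensity scaling leaves ratios and CI untouched
  for (k in c(0.2, 3, 17)) {
    sk <- new_spectrum(raman_grid, k * y, "Raman")
    expect_equal(cp_ratio_raman(sk), cp_ratio_raman(s), tolerance = 1e-6)
    expect_equal(ci_raman(sk), ci_raman(s), tolerance = 1e-6)
  }
})
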