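test_that("roughness closed forms hold", {
  # constant map: zero roughness
  flat <- height_map(matrix(5, 16, 16), 2)
  r <- roughness(flat)
  expect_equal(r$sa_nm, 0)
  expect_equal(r$sq_nm, 0)
  # checkerboard +/- h (zero mean plane): Sa = Sq = h
  h <- 2.5
  cb <- outer(1:16, 1:16, function(i, j) h * (-1)^(i + j))
  r2 <- roughness(height_map(cb, 2), detrend = "mean")
  expect_equal(r2$sa_nm, h)
  expect_equal(r2$sq_nm, h)
  # i.i.d. Gaussian heights: Sq -> sigma, Sa -> sigma * sqrt(2/pi)
  set.seed(99)
  g <- matrix(rnorm(512^2, sd = 3), 512, 512)
  r3 <- roughness(height_map(g, 2))
  expect_equal(r3$sq_nm, 3, tolerance = 0.02 / 3)
  expect_equal(r3$sa_nm, 3 * sqrt(2 / pi), tolerance = 0.02 / 3)
})

test_that("roughness is invariant under adding any plane and Sa <= Sq always", {
  set.seed(7)
  z <- matrix(rnorm(64^2), 64, 64)
  base <- roughness(height_map(z, 1))
  tilted <- z + outer(1:64, 1:64, function(i, j) 0.3 * i - 0.7 * j + 4)
  r <- roughness(height_map(tilted, 1))
  expect_equal(r$sa_nm, base$sa_nm, tolerance = 1e-10)
  expect_equal(r$sq_nm, base$sq_nm, tolerance = 1e-10)
  for (k in 1:5) {
    set.seed(k)
    zz <- matrix(rnorm(32^2) * runif(1, 0.1, 5), 32, 32)
    rr <- roughness(height_map(zz, 1))
    expect_lte(rr$sa_nm, rr$sq_nm + 1e-12)
  }
  expect_error(height_map(matrix(c(1, NA, 2, 3), 2, 2), 1), "non-finite")
})

test_that("DMT fit recovers modulus and adhesion from a noiseless curve", {
  delta <- seq(0, 4, length.out = 150)
  f <- dmt_force(delta, E_star = 50, tip_radius_nm = 30, F_adh = 2)
  fc <- force_curve(delta, f, branch = "unload", tip_radius_nm = 30)
  fit <- dmt_fit(fc)
  expect_equal(fit$E_star_gpa, 50, tolerance = 0.1 / 50)
  expect_equal(fit$F_adh_nN, 2, tolerance = 1e-6)
  # no contact regime
  zero <- force_curve(rep(0, 100), rep(0, 100), branch = "unload")
  expect_error(dmt_fit(zero), "no contact")
})

test_that("DMT fit is unbiased under force noise", {
  set.seed(123)
  delta <- seq(0, 4, length.out = 200)
  f0 <- dmt_force(delta, 50, 30, 2)
  est <- vapply(1:100, function(i) {
    fc <- force_curve(delta, f0 + rnorm(length(f0), sd = 0.05 * max(f0)),
                      branch = "unload", tip_radius_nm = 30)
    dmt_fit(fc)$E_star_gpa
  }, 0)
  expect_lt(abs(mean(est) - 50) / 50, 0.02)
})

test_that("two-Gaussian histogram decomposition recovers the reported widths", {
  set.seed(2024)
  n <- 512^2
  s1 <- 9.8 / (2 * sqrt(2 * log(2))); s2 <- 5.4 / (2 * sqrt(2 * log(2)))
  pick <- runif(n) < 0.5
  v <- ifelse(pick, rnorm(n, 38, s1), rnorm(n, 41.5, s2))
  dec <- decompose_modulus(modulus_map(matrix(v, 512, 512), 2))
  expect_equal(dec$components[[1]]$fwhm_gpa, 9.8, tolerance = 0.3 / 9.8)
  expect_equal(dec$components[[2]]$fwhm_gpa, 5.4, tolerance = 0.3 / 5.4)
  expect_lt(dec$components[[1]]$mean_gpa, dec$components[[2]]$mean_gpa)
  # separation between fitted maxima stays in the generated 2-4 GPa range
  sep <- dec$components[[2]]$mean_gpa - dec$components[[1]]$mean_gpa
  expect_gte(sep, 2); expect_lte(sep, 4)
  expect_false(dec$unimodal)
})

test_that("single-Gaussian input is flagged effectively unimodal", {
  set.seed(5)
  v <- rnorm(200^2, 40, 3)
  dec <- decompose_modulus(modulus_map(matrix(v, 200, 200), 2))
  expect_true(dec$unimodal)
})

test_that("decomposition is permutation invariant and label order deterministic", {
  set.seed(31)
  n <- 150^2
  v <- c(rnorm(n / 2, 35, 4), rnorm(n / 2, 40, 2))
  m1 <- modulus_map(matrix(v, 150, 150), 2)
  m2 <- modulus_map(matrix(sample(v), 150, 150), 2)
  d1 <- decompose_modulus(m1); d2 <- decompose_modulus(m2)
  expect_equal(d1$components[[1]]$mean_gpa, d2$components[[1]]$mean_gpa,
               tolerance = 1e-9)
  expect_equal(d1$components[[2]]$fwhm_gpa, d2$components[[2]]$fwhm_gpa,
               tolerance = 1e-9)
  expect_lt(d1$components[[1]]$mean_gpa, d1$components[[2]]$mean_gpa)
})

test_that("EM cross-check agrees with the histogram fit on well-separated mixtures", {
  set.seed(8)
  n <- 150^2
  v <- c(rnorm(0.4 * n, 30, 3), rnorm(0.6 * n, 42, 2.5))
  m <- modulus_map(matrix(v, 150, 150), 2)
  dh <- decompose_modulus(m, method = "histogram")
  de <- decompose_modulus(m, method = "em")
  expect_equal(dh$components[[1]]$mean_gpa, de$components[[1]]$mean_gpa,
               tolerance = 0.02)
  expect_equal(dh$components[[2]]$mean_gpa, de$components[[2]]$mean_gpa,
               tolerance = 0.02)
})

test_that("simulated maps carry their truth and height maps hit the Sa draw", {
  cfg <- sim_config(seed = 4, noise_scale = 0, map_size = 128L)
  hm <- simulate_height_map(10, cfg)
  r <- roughness(hm)
  expect_equal(r$sa_nm, attr(hm, "truth")$sa_nm, tolerance = 1e-9)
  mm <- simulate_modulus_map(28, cfg)
  expect_equal(attr(mm, "truth")$fwhm_I, 9.8)
  expect_equal(attr(mm, "truth")$fwhm_II, 5.4)
})
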