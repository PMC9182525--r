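#' Simulation configuration
#'
#' Declarative configuration shared by all signal simulators. The same
#' (seed, config) pair always yields bit-identical output; with
#' \code{noise_scale = 0} every specimen sits exactly on the trajectory means.
#'
#' @param seed Integer RNG seed.
#' @param n_specimens_per_day Specimens per sampled day (default 14, the
#'   benchmark group size).
#' @param distances_um Measurement distances from the incisor tip in um
#'   (subset of 100/500/1000/1500).
#' @param noise_scale Nonnegative multiplier applied to every trajectory SD
#'   and measurement-noise amplitude.
#' @param map_size AFM map resolution per side (default 512).
#' @param spike_rate Per-point cosmic-ray probability for Raman spectra.
#' @param trajectories Feature trajectory registry
#'   (default \code{\link{default_trajectories}}).
#' @param aux Auxiliary trajectory registry
#'   (default \code{\link{aux_trajectories}}).
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L, n_specimens_per_day = 14L,
                       distances_um = c(100, 500, 1000, 1500),
                       noise_scale = 1, map_size = 512L,
                       spike_rate = 0.001,
                       trajectories = default_trajectories(),
                       aux = aux_trajectories()) {
  stopifnot(n_specimens_per_day > 0, noise_scale >= 0,
            all(distances_um %in% c(100, 500, 1000, 1500)),
            spike_rate >= 0, spike_rate <= 1)
  structure(list(seed = as.integer(seed),
                 n_specimens_per_day = as.integer(n_specimens_per_day),
                 distances_um = distances_um, noise_scale = noise_scale,
                 map_size = as.integer(map_size), spike_rate = spike_rate,
                 trajectories = trajectories, aux = aux),
            class = "sim_config")
}

# Run expr under a deterministic sub-seed derived from (config seed, day,
# stage tag), restoring the caller's RNG state afterwards.
.with_seed <- function(seed, dpn, tag, expr) {
  tag_hash <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  sub <- (as.numeric(seed) * 7919 + dpn * 104729 + tag_hash * 131) %% 2147483647
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub))
  expr
}

# Draw a specimen-level true feature value: trajectory mean at dpn plus
# noise_scale * trajectory SD * standard normal.
.draw_truth <- function(traj, dpn, noise_scale) {
  traj_at(traj, dpn) + noise_scale * traj_at(traj, dpn, "sd") * stats::rnorm(1)
}

# Gaussian band evaluated on a grid.
.gauss <- function(x, amplitude, center, fwhm) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * exp(-(x - center)^2 / (2 * sig^2))
}

# Analytic area of a Gaussian band over [lo, hi] above the chord joining the
# band values at lo and hi (the same quantity the trapezoid integrator
# measures, in closed form).
.gauss_window_area <- function(amplitude, center, fwhm, lo, hi) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  full <- amplitude * sig * sqrt(2 * pi) *
    (stats::pnorm((hi - center) / sig) - stats::pnorm((lo - center) / sig))
  chord <- (.gauss(lo, amplitude, center, fwhm) +
              .gauss(hi, amplitude, center, fwhm)) / 2 * (hi - lo)
  full - chord
}

#' Simulate an X-ray diffractogram
#'
#' Two Gaussian reflections, (002) and (300), on a flat counting background
#' over 6-110 deg at 0.078 deg sampling. The (002) center follows the
#' specimen's c constant via Bragg's law and its observed width is the
#' quadrature sum of the size broadening implied by the specimen's corrected
#' FWHM draw and the 0.08 deg apparatus broadening; the (300) center follows
#' the a constant. Counting noise is Poisson, scaled by \code{noise_scale}.
#'
#' @param dpn Day of postnatal life (inside the trajectory anchor range).
#' @param config A \code{sim_config}.
#' @param specimen Integer specimen index (decorrelates replicate draws).
#' @return \code{spectrum} (modality XRD) with attribute \code{truth}.
#' @export
simulate_diffractogram <- function(dpn, config = sim_config(), specimen = 1L) {
  tr <- config$trajectories; aux <- config$aux
  .with_seed(config$seed, dpn, paste0("xrd", specimen), {
    ns <- config$noise_scale
    fwhm_corr <- .draw_truth(tr$FWHM002, dpn, ns)
    a_nm <- .draw_truth(tr$a_lattice, dpn, ns)
    c_A <- .draw_truth(aux$c_lattice, dpn, ns)

    center002 <- bragg_two_theta(c_A / 2)
    center300 <- bragg_two_theta(a_nm * 10 / sqrt(12))
    fwhm002_obs <- sqrt(fwhm_corr^2 + APPARATUS_BROADENING_DEG^2)

    x <- seq(6, 110, by = 0.078)
    mu <- 50 +
      .gauss(x, 1500, center002, fwhm002_obs) +
      .gauss(x, 700, center300, 0.9)
    y <- if (ns > 0) mu + ns * (stats::rpois(length(mu), mu) - mu) else mu
    s <- new_spectrum(x, y, "XRD")
    attr(s, "truth") <- list(dpn = dpn, fwhm002_corrected = fwhm_corr,
                             a_nm = a_nm, c_A = c_A,
                             D_nm = scherrer_size(fwhm_corr, center002))
    s
  })
}

# Solve the nu4 doublet width so the splitting factor computed on the FTIR
# grid (equal 603/567 amplitudes, chord baseline from the nearest-500 to the
# nearest-750 grid point) equals the target CI. Closed form in the band
# parameters; monotone decreasing in the width.
.solve_doublet_fwhm <- function(ci_target, grid) {
  nearest <- function(x0) grid[which.min(abs(grid - x0))]
  x500 <- nearest(500); x750 <- nearest(750)
  x603 <- nearest(603); x567 <- nearest(567); x590 <- nearest(590)
  ci_of <- function(fwhm) {
    g <- function(x) .gauss(x, 1, 603, fwhm) + .gauss(x, 1, 567, fwhm)
    chord <- function(x) g(x500) + (g(x750) - g(x500)) * (x - x500) / (x750 - x500)
    (g(x603) - chord(x603) + g(x567) - chord(x567)) / (g(x590) - chord(x590))
  }
  stats::uniroot(function(w) ci_of(w) - ci_target,
                 lower = 5, upper = 40, tol = 1e-10)$root
}

#' Simulate an ATR-FTIR enamel spectrum
#'
#' Sum of Gaussian bands on a 460-4000 cm^-1 grid (4 cm^-1 step): the nu3/nu1
#' phosphate bands (~1012, 961 cm^-1) with an early-age amorphous shoulder at
#' 992 cm^-1, a nu4 phosphate doublet (603/567 cm^-1) whose valley depth is
#' solved so the splitting factor matches the specimen's CI_FTIR draw, B-type
#' carbonate bands (1410/1450 cm^-1) calibrated so the 1485-1365 over
#' 1180-890 area ratio matches the C/P draw, and amide I/II/III bands that
#' fade with age; a gentle quadratic baseline and white noise are added.
#'
#' @inheritParams simulate_diffractogram
#' @return \code{spectrum} (modality FTIR) with attribute \code{truth}.
#' @export
simulate_ftir_spectrum <- function(dpn, config = sim_config(), specimen = 1L) {
  tr <- config$trajectories; aux <- config$aux
  .with_seed(config$seed, dpn, paste0("ftir", specimen), {
    ns <- config$noise_scale
    ci <- .draw_truth(tr$CI_FTIR, dpn, ns)
    cp <- max(.draw_truth(tr$CP_FTIR, dpn, ns), 0)
    amide <- max(.draw_truth(aux$amide_rel, dpn, ns), 0)

    x <- seq(460, 4000, by = 4)
    w_doublet <- .solve_doublet_fwhm(ci, x)

    # phosphate block (main nu3 at 1012, nu1 shoulder emerging after 2 dpn,
    # early amorphous component at 992 fading by 21 dpn)
    a961 <- 0.05 + 0.20 * min(max((dpn - 2) / 12, 0), 1)
    a992 <- 0.12 * (1 - min(max((dpn - 10) / 11, 0), 1))
    phos <- list(c(1.00, 1012, 90), c(a961, 961, 30), c(a992, 992, 26))
    amides <- list(c(0.9 * amide, 1650, 60), c(0.7 * amide, 1545, 44),
                   c(0.4 * amide, 1240, 44))
    doublet <- list(c(0.55, 603, w_doublet), c(0.55, 567, w_doublet))

    eff <- function(bands, lo, hi) {
      sum(vapply(bands, function(b) .gauss_window_area(b[1], b[2], b[3], lo, hi), 0))
    }
    phos_eff <- eff(c(phos, amides, doublet), 890, 1180)
    # carbonate amplitude solved so the window-area ratio equals cp exactly;
    # amide tails contribute to the carbonate window and are accounted for
    carb_shape <- list(c(1.0, 1410, 30), c(0.8, 1450, 30))
    other_in_carb <- eff(amides, 1365, 1485)
    per_unit <- eff(carb_shape, 1365, 1485)
    a_carb <- max((cp * phos_eff - other_in_carb) / per_unit, 0)
    carb <- lapply(carb_shape, function(b) c(b[1] * a_carb, b[2], b[3]))

    bands <- c(phos, amides, doublet, carb)
    y <- Reduce(`+`, lapply(bands, function(b) .gauss(x, b[1], b[2], b[3])))
    baseline <- 0.01 + 0.02 * ((x - 460) / 3540)^2
    y <- y + baseline
    if (ns > 0) y <- y + stats::rnorm(length(x), sd = 0.004 * ns)
    s <- new_spectrum(x, y, "FTIR")
    attr(s, "truth") <- list(dpn = dpn, ci_ftir = ci, cp_ftir = cp,
                             doublet_fwhm = w_doublet, amide_rel = amide)
    s
  })
}

#' Simulate a Raman enamel spectrum
#'
#' Gaussian bands on a 146-1930 cm^-1 grid (1 cm^-1 step): nu2/nu4 phosphate
#' bending modes (~430, 580 cm^-1), the strong nu1 phosphate band at
#' 961 cm^-1 whose FWHM equals the specimen's CI_Raman draw, the nu3
#' phosphate band at 1044 cm^-1, and the B-type carbonate band at 1070 cm^-1
#' whose area is the C/P draw times the nu1 area. A polynomial fluorescence
#' background, white noise, and single-pixel cosmic-ray spikes (>= 10x local
#' SD) are added.
#'
#' @inheritParams simulate_diffractogram
#' @param spike_rate Overrides \code{config$spike_rate} if not \code{NULL}.
#' @return \code{spectrum} (modality Raman) with attribute \code{truth}.
#' @export
simulate_raman_spectrum <- function(dpn, config = sim_config(), specimen = 1L,
                                    spike_rate = NULL) {
  tr <- config$trajectories
  if (is.null(spike_rate)) spike_rate <- config$spike_rate
  .with_seed(config$seed, dpn, paste0("raman", specimen), {
    ns <- config$noise_scale
    ci <- .draw_truth(tr$CI_Raman, dpn, ns)
    cp <- max(.draw_truth(tr$CP_Raman, dpn, ns), 0)

    x <- seq(146, 1930, by = 1)
    a961 <- 0.8 + 0.7 * min(max(dpn / 28, 0), 1) # nu1 intensity grows with age
    sig961 <- ci / (2 * sqrt(2 * log(2)))
    area961 <- a961 * sig961 * sqrt(2 * pi)
    fwhm1070 <- 16
    a1070 <- cp * area961 / (fwhm1070 / (2 * sqrt(2 * log(2))) * sqrt(2 * pi))
    bands <- list(c(0.25, 430, 20), c(0.30, 580, 25),
                  c(a961, 961, ci), c(0.15, 1044, 14),
                  c(a1070, 1070, fwhm1070))
    y <- Reduce(`+`, lapply(bands, function(b) .gauss(x, b[1], b[2], b[3])))
    # slowly varying fluorescence, removable by a low-order polynomial
    u <- (x - 146) / 1784
    fluor <- 0.30 - 0.25 * u + 0.10 * u^2 - 0.05 * u^3
    y <- y + fluor
    if (ns > 0) y <- y + stats::rnorm(length(x), sd = 0.003 * ns)
    if (spike_rate > 0) {
      hit <- which(stats::runif(length(x)) < spike_rate)
      y[hit] <- y[hit] + stats::runif(length(hit), 0.5, 2.0)
    }
    s <- new_spectrum(x, y, "Raman")
    attr(s, "truth") <- list(dpn = dpn, ci_raman = ci, cp_raman = cp,
                             n_spikes = if (spike_rate > 0) length(hit) else 0L)
    s
  })
}

#' Simulate a per-pixel DMT modulus map
#'
#' Pixels drawn i.i.d. from a two-component Gaussian mixture whose means
#' follow the DMTI/DMTII trajectories (component I lower by 2-4 GPa), FWHMs
#' follow the component-width trajectories, and weight follows the
#' component-I weight trajectory.
#'
#' @inheritParams simulate_diffractogram
#' @return \code{modulus_map} with attribute \code{truth}.
#' @export
simulate_modulus_map <- function(dpn, config = sim_config(), specimen = 1L) {
  tr <- config$trajectories; aux <- config$aux
  .with_seed(config$seed, dpn, paste0("qnm", specimen), {
    ns <- config$noise_scale
    m1 <- .draw_truth(tr$DMTI, dpn, ns)
    m2 <- .draw_truth(tr$DMTII, dpn, ns)
    f1 <- .draw_truth(aux$FWHM_DMTI, dpn, ns)
    f2 <- .draw_truth(aux$FWHM_DMTII, dpn, ns)
    w1 <- min(max(.draw_truth(aux$weight_DMTI, dpn, ns), 0.05), 0.95)
    n <- config$map_size^2
    pick <- stats::runif(n) < w1
    sig1 <- f1 / (2 * sqrt(2 * log(2))); sig2 <- f2 / (2 * sqrt(2 * log(2)))
    v <- ifelse(pick, stats::rnorm(n, m1, sig1), stats::rnorm(n, m2, sig2))
    mm <- modulus_map(matrix(v, config$map_size, config$map_size),
                      pixel_size_nm = 1000 / config$map_size)
    attr(mm, "truth") <- list(dpn = dpn, mean_I = m1, mean_II = m2,
                              fwhm_I = f1, fwhm_II = f2, weight_I = w1)
    mm
  })
}

#' Simulate an AFM height map
#'
#' Smoothed Gaussian ridge texture rescaled (after mean-plane removal) so the
#' average roughness Sa equals the specimen's roughness draw exactly, plus a
#' small tilt plane that the roughness stage must remove.
#'
#' @inheritParams simulate_diffractogram
#' @return \code{height_map} with attribute \code{truth}.
#' @export
simulate_height_map <- function(dpn, config = sim_config(), specimen = 1L) {
  aux <- config$aux
  .with_seed(config$seed, dpn, paste0("afm", specimen), {
    ns <- config$noise_scale
    sa_target <- max(.draw_truth(aux$Sa, dpn, ns), 1e-3)
    n <- config$map_size
    z <- matrix(stats::rnorm(n * n), n, n)
    # separable running-mean smoothing -> correlated ridge-like texture
    k <- 9
    sm <- function(m) {
      t(apply(apply(m, 2, function(col) stats::filter(col, rep(1 / k, k),
                                                      circular = TRUE)),
              1, function(row) stats::filter(row, rep(1 / k, k),
                                             circular = TRUE)))
    }
    z <- sm(z)
    # remove mean plane, then scale to the target Sa
    xi <- rep(seq_len(n), times = n); yi <- rep(seq_len(n), each = n)
    X <- cbind(1, xi, yi)
    z <- z - matrix(drop(X %*% stats::lm.fit(X, as.vector(z))$coefficients), n, n)
    z <- z * sa_target / mean(abs(z))
    # add back a tilt plane (dominant AFM artifact)
    tilt <- outer(seq_len(n), seq_len(n),
                  function(i, j) 0.02 * i + 0.01 * j)
    hm <- height_map(z + tilt, pixel_size_nm = 1000 / n)
    attr(hm, "truth") <- list(dpn = dpn, sa_nm = sa_target,
                              sq_nm = sqrt(mean(z^2)))
    hm
  })
}

#' Simulate DMT force curves
#'
#' Unloading branches generated from the DMT force law at the nominal
#' 30 nm tip radius; each curve's true reduced modulus is drawn from the
#' day's two-component modulus mixture, with additive force noise.
#'
#' @inheritParams simulate_diffractogram
#' @param n_curves Number of curves (default 10).
#' @return List of \code{force_curve} objects, each with attribute
#'   \code{truth}.
#' @export
simulate_force_curves <- function(dpn, config = sim_config(), specimen = 1L,
                                  n_curves = 10) {
  tr <- config$trajectories; aux <- config$aux
  .with_seed(config$seed, dpn, paste0("fc", specimen), {
    ns <- config$noise_scale
    m1 <- traj_at(tr$DMTI, dpn); m2 <- traj_at(tr$DMTII, dpn)
    s1 <- ns * traj_at(tr$DMTI, dpn, "sd"); s2 <- ns * traj_at(tr$DMTII, dpn, "sd")
    w1 <- traj_at(aux$weight_DMTI, dpn)
    lapply(seq_len(n_curves), function(i) {
      from_I <- stats::runif(1) < w1
      e_true <- if (from_I) m1 + s1 * stats::rnorm(1) else m2 + s2 * stats::rnorm(1)
      delta <- seq(0, 5, length.out = 200)
      f <- dmt_force(delta, e_true, tip_radius_nm = 30, F_adh = 2)
      if (ns > 0) f <- f + stats::rnorm(length(f), sd = 0.5 * ns)
      fc <- force_curve(delta, f, branch = "unload", tip_radius_nm = 30)
      attr(fc, "truth") <- list(E_star_gpa = e_true, F_adh_nN = 2,
                                component = if (from_I) "I" else "II")
      fc
    })
  })
}

# Distance multipliers for iron: undetectable far from the tip before 7 dpn
# (near-tip shares doubled so the day mean matches the base trajectory);
# uniform at 7-10 dpn; from 14 dpn lower at 100 um, higher farther out.
.fe_distance_multiplier <- function(dpn, distance_um) {
  if (dpn < 7) {
    if (distance_um %in% c(1000, 1500)) 0 else 2
  } else if (dpn < 14) {
    1
  } else {
    c(`100` = 0.8, `500` = 1.05, `1000` = 1.05, `1500` = 1.1)[[as.character(distance_um)]]
  }
}

#' Simulate EDS composition records
#'
#' One \code{composition_record} per (specimen, distance) cell: P, C, O, Fe
#' drawn from their trajectories (SD x \code{noise_scale}), Ca derived as the
#' Ca/P-ratio draw times P so the weight ratio follows its trajectory
#' exactly, and the iron x distance interaction applied via deterministic
#' distance multipliers.
#'
#' @param dpn Vector of days to simulate.
#' @param config A \code{sim_config}.
#' @return List of \code{composition_record} objects.
#' @export
simulate_eds_records <- function(dpn, config = sim_config()) {
  tr <- config$trajectories; aux <- config$aux
  out <- list()
  for (day in dpn) {
    recs <- .with_seed(config$seed, day, "eds", {
      ns <- config$noise_scale
      day_recs <- list()
      for (sp in seq_len(config$n_specimens_per_day)) {
        for (dist in config$distances_um) {
          p <- max(.draw_truth(tr$P, day, ns), 0.1)
          ratio <- max(.draw_truth(tr$CaP, day, ns), 0.1)
          cc <- max(.draw_truth(tr$C, day, ns), 0)
          o <- max(.draw_truth(aux$O, day, ns), 0)
          fe_base <- max(.draw_truth(tr$Fe, day, ns), 0)
          fe <- fe_base * .fe_distance_multiplier(day, dist)
          # cap oxygen so the analyzed total stays physical (< 100 wt%)
          o <- min(o, 100 - (ratio * p + p + cc + fe) - 0.1)
          day_recs[[length(day_recs) + 1]] <- composition_record(
            day, dist, c(Ca = ratio * p, P = p, C = cc, O = o, Fe = fe))
        }
      }
      day_recs
    })
    out <- c(out, recs)
  }
  out
}

#' Simulate a ready feature table
#'
#' One row per specimen per day with all thirteen model features plus the dpn
#' label, drawn from the trajectory registry (means interpolated at anchor
#' days, SDs scaled by \code{noise_scale}). Ca is derived as CaP x P so the
#' three EDS quantities stay mutually consistent.
#'
#' @param config A \code{sim_config}.
#' @param days Days to include (default: all eight anchors).
#' @return data.frame with columns \code{\link{feature_names}()} and
#'   \code{dpn}.
#' @export
simulate_feature_table <- function(config = sim_config(),
                                   days = c(0, 2, 5, 7, 10, 14, 21, 28)) {
  tr <- config$trajectories
  rows <- list()
  for (day in days) {
    block <- .with_seed(config$seed, day, "features", {
      ns <- config$noise_scale
      n <- config$n_specimens_per_day
      df <- data.frame(matrix(NA_real_, n, length(feature_names())))
      names(df) <- feature_names()
      for (f in setdiff(feature_names(), "Ca")) {
        df[[f]] <- traj_at(tr[[f]], day) +
          ns * traj_at(tr[[f]], day, "sd") * stats::rnorm(n)
      }
      df$Fe <- pmax(df$Fe, 0)
      df$Ca <- df$CaP * df$P
      df$dpn <- day
      df
    })
    rows[[length(rows) + 1]] <- block
  }
  do.call(rbind, rows)
}

#' Simulate a full multimodal sample set
#'
#' Per-specimen bundles of raw signals (diffractogram, FTIR, Raman, modulus
#' map, height map, force curves, EDS records) together with the generator's
#' true feature values, plus a provenance echo of the configuration. Intended
#' for end-to-end pipeline runs; for the regression stage alone,
#' \code{\link{simulate_feature_table}} is much cheaper.
#'
#' @param config A \code{sim_config}.
#' @param days Days to simulate.
#' @param n_specimens Specimens per day (default
#'   \code{config$n_specimens_per_day}).
#' @param modalities Character subset of
#'   \code{c("xrd", "ftir", "raman", "afm", "eds")}.
#' @return Object of class \code{sample_set}: list of records plus
#'   \code{provenance}.
#' @export
simulate_sample_set <- function(config = sim_config(),
                                days = c(0, 2, 5, 7, 10, 14, 21, 28),
                                n_specimens = NULL,
                                modalities = c("xrd", "ftir", "raman",
                                               "afm", "eds")) {
  if (is.null(n_specimens)) n_specimens <- config$n_specimens_per_day
  eds_cfg <- config; eds_cfg$n_specimens_per_day <- as.integer(n_specimens)
  records <- list()
  for (day in days) {
    for (sp in seq_len(n_specimens)) {
      rec <- list(dpn = day, specimen = sp)
      if ("xrd" %in% modalities) {
        rec$diffractogram <- simulate_diffractogram(day, config, sp)
      }
      if ("ftir" %in% modalities) {
        rec$ftir <- simulate_ftir_spectrum(day, config, sp)
      }
      if ("raman" %in% modalities) {
        rec$raman <- simulate_raman_spectrum(day, config, sp)
      }
      if ("afm" %in% modalities) {
        rec$modulus_map <- simulate_modulus_map(day, config, sp)
        rec$height_map <- simulate_height_map(day, config, sp)
        rec$force_curves <- simulate_force_curves(day, config, sp)
      }
      records[[length(records) + 1]] <- rec
    }
  }
  eds <- if ("eds" %in% modalities) simulate_eds_records(days, eds_cfg) else list()
  structure(list(records = records, eds_records = eds,
                 provenance = config[c("seed", "n_specimens_per_day",
                                       "distances_um", "noise_scale",
                                       "map_size", "spike_rate")]),
            class = "sample_set")
}
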