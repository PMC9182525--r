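# Pseudo-Voigt profile: eta * Lorentzian + (1 - eta) * Gaussian, both with
# common center, FWHM and unit peak amplitude.
.pseudo_voigt <- function(x, center, fwhm, eta) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  g <- exp(-(x - center)^2 / (2 * sig^2))
  l <- 1 / (1 + ((x - center) / (fwhm / 2))^2)
  eta * l + (1 - eta) * g
}

# Analytic area of an amplitude-A pseudo-Voigt component.
.pv_area <- function(A, fwhm, eta) {
  g_area <- fwhm / 2 * sqrt(pi / log(2))
  l_area <- pi * fwhm / 2
  A * (eta * l_area + (1 - eta) * g_area)
}

# Iterative polynomial baseline (fit, clip above the fit, refit): standard
# modified-polyfit scheme. Returns the baseline vector.
.poly_baseline <- function(x, y, order, max_iter = 100, tol = 1e-10) {
  xs <- (x - mean(x)) / stats::sd(x) # conditioning
  X <- cbind(1, stats::poly(xs, degree = order, simple = TRUE))
  yw <- y
  base <- rep(0, length(y))
  for (i in seq_len(max_iter)) {
    base_new <- drop(X %*% stats::lm.fit(X, yw)$coefficients)
    yw_new <- pmin(yw, base_new)
    base <- base_new
    if (max(abs(yw_new - yw)) < tol * max(abs(y), 1)) break
    yw <- yw_new
  }
  base
}

#' Standard ATR-FTIR preprocessing
#'
#' Savitzky-Golay smoothing over a 9-point window (order 2 by default, moving
#' average available), iterative polynomial baseline subtraction, and
#' normalization to the intensity at the grid point nearest 1010 cm^-1.
#'
#' @param raw \code{spectrum} with modality \code{"FTIR"} covering
#'   600-4000 cm^-1.
#' @param smooth_points Odd smoothing window (default 9).
#' @param smoother \code{"savitzky-golay"} (order 2) or \code{"moving-average"}.
#' @param baseline_order Polynomial baseline order (default 2).
#' @return Preprocessed \code{spectrum} with updated log.
#' @export
preprocess_ftir <- function(raw, smooth_points = 9,
                            smoother = c("savitzky-golay", "moving-average"),
                            baseline_order = 2) {
  smoother <- match.arg(smoother)
  stopifnot(inherits(raw, "spectrum"), raw$modality == "FTIR")
  if (min(raw$axis) > 600 || max(raw$axis) < 4000) {
    stop("FTIR spectrum must cover 600-4000 cm^-1")
  }
  y <- raw$intensity
  y <- switch(smoother,
    "savitzky-golay" = signal::sgolayfilt(y, p = 2, n = smooth_points),
    "moving-average" = stats::filter(y, rep(1 / smooth_points, smooth_points),
                                     sides = 2) |>
      (\(v) { v[is.na(v)] <- y[is.na(v)]; as.numeric(v) })())
  base <- .poly_baseline(raw$axis, y, order = baseline_order)
  y <- y - base
  ref <- y[which.min(abs(raw$axis - 1010))]
  if (ref <= 0) stop("non-normalizable: intensity at 1010 cm^-1 <= 0 after baseline")
  s <- new_spectrum(raw$axis, y / ref, "FTIR", raw$preprocessing_log)
  .log_step(s, sprintf("preprocess_ftir(smooth=%d %s, baseline order %d, norm 1010)",
                       smooth_points, smoother, baseline_order))
}

#' Smoothed second derivative of a spectrum
#'
#' Savitzky-Golay second derivative; with this sign convention a Gaussian
#' absorption band yields a negative extremum at its center, so overlapping
#' bands appear as resolved local minima.
#'
#' @param s A \code{spectrum} on a uniform grid.
#' @param window Odd filter window (\code{> polyorder}).
#' @param polyorder Polynomial order (\code{>= 2}).
#' @return \code{spectrum} holding d2 intensity / d axis^2.
#' @export
second_derivative <- function(s, window = 9, polyorder = 2) {
  stopifnot(inherits(s, "spectrum"))
  if (window %% 2 == 0 || window <= polyorder || polyorder < 2) {
    stop("window must be odd and > polyorder >= 2")
  }
  if (window > length(s$axis)) stop("window exceeds spectrum length")
  h <- stats::median(diff(s$axis))
  d2 <- signal::sgolayfilt(s$intensity, p = polyorder, n = window, m = 2,
                           ts = abs(h))
  out <- new_spectrum(s$axis, d2, s$modality, s$preprocessing_log)
  .log_step(out, sprintf("second_derivative(window=%d, polyorder=%d)",
                         window, polyorder))
}

#' FTIR carbonate-to-phosphate ratio
#'
#' Ratio of the B-type carbonate band area (1485-1365 cm^-1) to the composite
#' phosphate band area (1180-890 cm^-1), each integrated above a local linear
#' baseline joining the interval endpoints.
#'
#' @param s Preprocessed FTIR \code{spectrum}.
#' @return Unitless area ratio.
#' @export
cp_ratio_ftir <- function(s) {
  stopifnot(inherits(s, "spectrum"), s$modality == "FTIR")
  carb <- .band_area(s, 1365, 1485)
  phos <- .band_area(s, 890, 1180)
  if (phos <= 0) stop("phosphate band area <= 0")
  carb / phos
}

#' FTIR crystallinity index (splitting factor)
#'
#' Draws a straight baseline between the intensities at 500 and 750 cm^-1 and
#' returns \code{(A603 + A567) / A590}, where each \code{A_x} is the
#' baseline-subtracted absorbance at the grid point nearest \code{x}. Equals
#' 2 in the limit of a completely unresolved nu4 phosphate doublet and grows
#' as the 590 cm^-1 valley deepens with increasing crystallinity.
#'
#' @param s FTIR \code{spectrum} covering 500-750 cm^-1.
#' @return Unitless splitting factor.
#' @export
ci_ftir <- function(s) {
  stopifnot(inherits(s, "spectrum"), s$modality == "FTIR")
  if (min(s$axis) > 500 || max(s$axis) < 750) {
    stop("spectrum must cover 500-750 cm^-1")
  }
  x1 <- s$axis[which.min(abs(s$axis - 500))]
  x2 <- s$axis[which.min(abs(s$axis - 750))]
  y1 <- .at_nearest(s, 500); y2 <- .at_nearest(s, 750)
  baseline_at <- function(x) y1 + (y2 - y1) * (x - x1) / (x2 - x1)
  a_of <- function(x0) {
    i <- which.min(abs(s$axis - x0))
    s$intensity[i] - baseline_at(s$axis[i])
  }
  a603 <- a_of(603); a567 <- a_of(567); a590 <- a_of(590)
  if (a590 <= 0) stop("degenerate valley: baseline-corrected absorbance at 590 cm^-1 <= 0")
  (a603 + a567) / a590
}

#' Remove cosmic-ray spikes from a Raman spectrum
#'
#' Points lying more than \code{k} robust standard deviations (MAD) above a
#' running median are replaced by that median. Identity on spike-free input.
#'
#' @param s Raman \code{spectrum}.
#' @param k Detection threshold in MAD units (default 8).
#' @param window Odd running-median window (default 7).
#' @return Despiked \code{spectrum}.
#' @export
despike <- function(s, k = 8, window = 7) {
  stopifnot(inherits(s, "spectrum"), s$modality == "Raman")
  med <- stats::runmed(s$intensity, window, endrule = "median")
  resid <- s$intensity - med
  # a spike is an isolated excursion: its residual dwarfs both the global
  # residual scale and the residuals of its immediate neighbours. Band tops
  # survive because their neighbours carry comparable smoothing residuals,
  # even on noiseless input where the MAD of the residuals degenerates to 0.
  scale <- max(stats::mad(resid), mean(abs(resid)))
  n <- length(resid)
  neighbour <- pmax(abs(c(0, resid[-n])), abs(c(resid[-1], 0)))
  y <- s$intensity
  bad <- resid > k * scale & resid > 4 * neighbour
  y[bad] <- med[bad]
  out <- new_spectrum(s$axis, y, "Raman", s$preprocessing_log)
  .log_step(out, sprintf("despike(k=%g, window=%d)", k, window))
}

#' Subtract a polynomial fluorescence background
#'
#' Iterative (peak-clipping) least-squares polynomial of the given order,
#' subtracted from the spectrum. A spectrum that is exactly a polynomial of
#' that order maps to zero.
#'
#' @param s Raman \code{spectrum}.
#' @param order Polynomial order (default 6).
#' @return Background-corrected \code{spectrum}.
#' @export
subtract_fluorescence <- function(s, order = 6) {
  stopifnot(inherits(s, "spectrum"), s$modality == "Raman")
  base <- .poly_baseline(s$axis, s$intensity, order = order)
  out <- new_spectrum(s$axis, s$intensity - base, "Raman", s$preprocessing_log)
  .log_step(out, sprintf("subtract_fluorescence(order=%d)", order))
}

# Lower convex hull (Andrew's monotone chain) of (x, y); returns indices.
.lower_hull <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      # cross product; pop if b is above the a-i chord
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0) {
        hull <- hull[-length(hull)]
      } else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Rubber-band baseline correction
#'
#' Subtracts the lower convex-hull envelope of the spectrum (linear
#' interpolation through the hull support points), repeated for the requested
#' number of refinement rounds. Peaks standing on a zero baseline are left
#' essentially untouched because the hull rides along the between-peak zeros.
#'
#' @param s Raman \code{spectrum}.
#' @param iterations Number of hull-subtraction rounds (default 15).
#' @return Baseline-corrected \code{spectrum}.
#' @export
rubber_band <- function(s, iterations = 15) {
  stopifnot(inherits(s, "spectrum"), s$modality == "Raman")
  x <- s$axis; y <- s$intensity
  if (is.unsorted(x)) stop("axis must be ascending for rubber-band correction")
  for (i in seq_len(iterations)) {
    h <- .lower_hull(x, y)
    base <- stats::approx(x[h], y[h], xout = x)$y
    y <- y - base
    if (max(abs(base)) < 1e-12 * max(abs(s$intensity), 1)) break
  }
  out <- new_spectrum(x, y, "Raman", s$preprocessing_log)
  .log_step(out, sprintf("rubber_band(iterations=%d)", iterations))
}

#' Two-component pseudo-Voigt deconvolution of the 1030-1100 cm^-1 region
#'
#' Fits the superposition of the nu3 phosphate (~1044 cm^-1) and nu1 B-type
#' carbonate (~1070 cm^-1) bands with two Gaussian-Lorentzian (pseudo-Voigt)
#' components, each with its own mixing parameter eta in [0, 1].
#'
#' @param s Baseline-corrected Raman \code{spectrum}.
#' @param region Fit window (default \code{c(1030, 1100)}).
#' @param centers Starting centers for the two components.
#' @return A \code{pseudo_voigt_pair}: per component center, fwhm, eta,
#'   amplitude, analytic \code{area}; plus \code{fit_rss}.
#' @export
fit_carbonate_region <- function(s, region = c(1030, 1100),
                                 centers = c(1044, 1070)) {
  stopifnot(inherits(s, "spectrum"), s$modality == "Raman")
  idx <- which(s$axis >= region[1] & s$axis <= region[2])
  if (length(idx) < 12) stop("deconvolution region contains too few points")
  x <- s$axis[idx]; y <- s$intensity[idx]
  a0 <- max(y) * 0.8
  # the constant term b absorbs any residual baseline offset; without it the
  # heavy Lorentzian tails soak up the offset and bias the component areas.
  # The Jacobian can be singular at unlucky starting shapes (e.g. when one
  # component is absent), so try a fixed grid of starts and keep the best fit.
  fit <- NULL
  for (st in list(c(e = 0.2, w = 12), c(e = 0.5, w = 12),
                  c(e = 0.2, w = 8), c(e = 0.5, w = 20))) {
    cand <- tryCatch(minpack.lm::nlsLM(
      y ~ A1 * .pseudo_voigt(x, c1, w1, e1) +
        A2 * .pseudo_voigt(x, c2, w2, e2) + b,
      start = list(A1 = a0, c1 = centers[1], w1 = st[["w"]], e1 = st[["e"]],
                   A2 = a0 / 2, c2 = centers[2], w2 = st[["w"]],
                   e2 = st[["e"]], b = min(y)),
      lower = c(0, region[1], 2, 0, 0, region[1], 2, 0, -Inf),
      upper = c(Inf, region[2], diff(region), 1,
                Inf, region[2], diff(region), 1, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
      fit <- cand
    }
  }
  if (is.null(fit)) stop("carbonate-region deconvolution failed to converge")
  p <- stats::coef(fit)
  comp <- function(sfx) {
    A <- p[[paste0("A", sfx)]]; w <- p[[paste0("w", sfx)]]
    e <- p[[paste0("e", sfx)]]
    list(center = p[[paste0("c", sfx)]], fwhm = w, eta = e, amplitude = A,
         area = .pv_area(A, w, e))
  }
  comps <- list(comp(1), comp(2))
  comps <- comps[order(vapply(comps, `[[`, 0, "center"))]
  structure(list(components = comps, fit_rss = sum(stats::resid(fit)^2)),
            class = "pseudo_voigt_pair")
}

#' Raman carbonate-to-phosphate ratio
#'
#' With \code{cp_mode = "window"} (default) the numerator is the analytic
#' area of the ~1070 cm^-1 carbonate component obtained from the two-component
#' pseudo-Voigt deconvolution of the 1030-1100 cm^-1 region, and the
#' denominator the nu1 phosphate window integral (980-920 cm^-1). With
#' \code{cp_mode = "caption"} the denominator is instead the analytic area of
#' the Gaussian fitted to the 960 cm^-1 band.
#'
#' @param s Rubber-band-corrected Raman \code{spectrum}.
#' @param cp_mode \code{"window"} or \code{"caption"}.
#' @return Unitless area ratio.
#' @export
cp_ratio_raman <- function(s, cp_mode = c("window", "caption")) {
  cp_mode <- match.arg(cp_mode)
  pair <- fit_carbonate_region(s)
  centers <- vapply(pair$components, `[[`, 0, "center")
  carb <- pair$components[[which.min(abs(centers - 1070))]]
  denom <- if (cp_mode == "window") {
    .band_area(s, 920, 980)
  } else {
    f <- .fit_gaussian_band(s, center0 = 961, window = c(930, 990))
    f$area
  }
  if (denom <= 0) stop("phosphate band area <= 0")
  carb$area / denom
}

# Gaussian + constant fit of a single band; returns center, fwhm, area.
.fit_gaussian_band <- function(s, center0, window) {
  idx <- which(s$axis >= window[1] & s$axis <= window[2])
  if (length(idx) < 8) stop("band window contains too few points")
  x <- s$axis[idx]; y <- s$intensity[idx]
  fit <- tryCatch(minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sig^2)) + b,
    start = list(A = max(y), mu = center0, sig = 5, b = min(y)),
    lower = c(0, window[1], 0.5, -Inf),
    upper = c(Inf, window[2], diff(window), Inf),
    control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) stop("band fit failed to converge: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  list(center = p[["mu"]], fwhm = 2 * sqrt(2 * log(2)) * p[["sig"]],
       area = p[["A"]] * p[["sig"]] * sqrt(2 * pi),
       rss = sum(stats::resid(fit)^2))
}

#' Raman crystallinity index
#'
#' FWHM (cm^-1) of a Gaussian fitted to the nu1 phosphate band near
#' 960 cm^-1; narrower bands indicate higher crystallinity.
#'
#' @param s Rubber-band-corrected Raman \code{spectrum}.
#' @return FWHM in cm^-1.
#' @export
ci_raman <- function(s) {
  stopifnot(inherits(s, "spectrum"), s$modality == "Raman")
  .fit_gaussian_band(s, center0 = 961, window = c(930, 990))$fwhm
}
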