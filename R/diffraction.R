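#' Fit a single Gaussian reflection in a diffractogram window
#'
#' Least-squares fit of a Gaussian plus constant background to the counts in
#' \code{window_deg}, followed by quadrature removal of the apparatus
#' broadening: \code{fwhm_corrected = sqrt(fwhm_obs^2 - b^2)} (Gaussian
#' instrumental profile; \code{broadening_mode = "linear"} subtracts
#' \code{b} instead, for sensitivity checks).
#'
#' @param dg A \code{spectrum} with modality \code{"XRD"} (axis in deg
#'   2-theta, 6-110, spacing <= 0.1 deg).
#' @param hkl Integer Miller triple, e.g. \code{c(0, 0, 2)}.
#' @param window_deg Length-2 fit window in deg 2-theta.
#' @param broadening_deg Apparatus broadening in deg (default 0.08).
#' @param broadening_mode \code{"quadrature"} (default) or \code{"linear"}.
#' @return A \code{reflection_fit} list: \code{hkl}, \code{center_2theta},
#'   \code{fwhm_obs}, \code{fwhm_corrected}, \code{amplitude},
#'   \code{background}, \code{fit_rss}.
#' @export
fit_reflection <- function(dg, hkl, window_deg,
                           broadening_deg = APPARATUS_BROADENING_DEG,
                           broadening_mode = c("quadrature", "linear")) {
  broadening_mode <- match.arg(broadening_mode)
  stopifnot(inherits(dg, "spectrum"), dg$modality == "XRD",
            length(window_deg) == 2)
  idx <- which(dg$axis >= window_deg[1] & dg$axis <= window_deg[2])
  if (length(idx) < 8) stop("fit window contains too few points")
  x <- dg$axis[idx]; y <- dg$intensity[idx]

  bg0 <- stats::median(c(utils::head(y, 5), utils::tail(y, 5)))
  noise <- stats::mad(c(utils::head(y, 8), utils::tail(y, 8)))
  if (max(y) - bg0 <= 5 * max(noise, 1e-12)) {
    stop(sprintf("no peak found above background in window [%g, %g] deg",
                 window_deg[1], window_deg[2]))
  }
  c0 <- x[which.max(y)]
  # initial sigma from half-maximum crossing width
  half <- bg0 + (max(y) - bg0) / 2
  above <- range(x[y >= half])
  s0 <- max(diff(above) / 2.3548, diff(x)[1])

  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-(x - mu)^2 / (2 * sig^2)) + b,
    start = list(A = max(y) - bg0, mu = c0, sig = s0, b = bg0),
    lower = c(0, window_deg[1], 1e-6, -Inf),
    upper = c(Inf, window_deg[2], diff(window_deg), Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  fwhm_obs <- 2 * sqrt(2 * log(2)) * p[["sig"]]
  if (fwhm_obs <= broadening_deg) {
    stop("observed width below instrument resolution (apparatus broadening)")
  }
  fwhm_corr <- switch(broadening_mode,
                      quadrature = sqrt(fwhm_obs^2 - broadening_deg^2),
                      linear = fwhm_obs - broadening_deg)
  structure(list(hkl = as.integer(hkl), center_2theta = p[["mu"]],
                 fwhm_obs = fwhm_obs, fwhm_corrected = fwhm_corr,
                 amplitude = p[["A"]], background = p[["b"]],
                 fit_rss = sum(stats::resid(fit)^2)),
            class = "reflection_fit")
}

#' Lattice spacing from Bragg's law
#'
#' \code{d = lambda / (2 sin(theta))} with \code{theta = two_theta/2}.
#'
#' @param two_theta_deg Reflection position in deg 2-theta, in (0, 180).
#' @param wavelength_A X-ray wavelength in Angstrom (default 1.5478).
#' @return Lattice spacing d in Angstrom.
#' @export
#' @examples
#' bragg_d(25.886)  # 3.4552 A, hydroxyapatite (002) reference
#' bragg_d(32.912)  # 2.7320 A, (300) reference
bragg_d <- function(two_theta_deg, wavelength_A = XRD_WAVELENGTH_A) {
  if (any(two_theta_deg <= 0) || any(two_theta_deg >= 180)) {
    stop("two_theta must lie in (0, 180) deg")
  }
  wavelength_A / (2 * sin(two_theta_deg / 2 * pi / 180))
}

#' Inverse of Bragg's law
#'
#' 2-theta position (deg) of the reflection with lattice spacing \code{d_A}.
#'
#' @param d_A Lattice spacing in Angstrom (\code{> wavelength/2}).
#' @param wavelength_A X-ray wavelength in Angstrom.
#' @return 2-theta in degrees.
#' @export
bragg_two_theta <- function(d_A, wavelength_A = XRD_WAVELENGTH_A) {
  r <- wavelength_A / (2 * d_A)
  if (any(r >= 1) || any(d_A <= 0)) stop("d too small for this wavelength")
  2 * asin(r) * 180 / pi
}

#' Hexagonal lattice constant from a lattice spacing
#'
#' For the hexagonal cell, \code{1/d^2 = 4/3 (h^2+hk+k^2)/a^2 + l^2/c^2};
#' the (002) plane determines \code{c = 2 d} and the (300) plane
#' \code{a = d sqrt(12)}. Other planes mix both constants and are rejected.
#'
#' @param d_A Lattice spacing in Angstrom.
#' @param hkl Integer Miller triple: \code{c(0,0,2)} or \code{c(3,0,0)}.
#' @return List with \code{constant} (\code{"a"} or \code{"c"}) and
#'   \code{value_A} in Angstrom.
#' @export
lattice_from_d <- function(d_A, hkl) {
  if (d_A <= 0) stop("d must be positive")
  hkl <- as.integer(hkl)
  if (identical(hkl, c(0L, 0L, 2L))) {
    list(constant = "c", value_A = 2 * d_A)
  } else if (identical(hkl, c(3L, 0L, 0L))) {
    list(constant = "a", value_A = d_A * sqrt(12))
  } else {
    stop("unsupported plane; supported Miller indices: (0,0,2), (3,0,0)")
  }
}

#' Scherrer crystallite size
#'
#' \code{D = K lambda / (FWHM cos(theta))} with the corrected FWHM converted
#' from degrees to radians; returns the mean ordered-domain size in nm.
#'
#' @param fwhm_corrected_deg Apparatus-corrected FWHM in deg 2-theta
#'   (\code{> 0}).
#' @param center_2theta_deg Reflection position in deg 2-theta.
#' @param wavelength_A X-ray wavelength in Angstrom.
#' @param K Crystallite shape factor (default 0.9).
#' @return Crystallite size D in nm.
#' @export
#' @examples
#' scherrer_size(0.7603, 25.886)  # 10.77 nm
scherrer_size <- function(fwhm_corrected_deg, center_2theta_deg,
                          wavelength_A = XRD_WAVELENGTH_A, K = SCHERRER_K) {
  if (any(fwhm_corrected_deg <= 0)) stop("corrected FWHM must be positive")
  fwhm_rad <- fwhm_corrected_deg * pi / 180
  theta <- center_2theta_deg / 2 * pi / 180
  K * (wavelength_A / 10) / (fwhm_rad * cos(theta))
}

#' Full crystallographic analysis of a diffractogram
#'
#' Fits the (002) and (300) reflections in their default windows, converts
#' the fitted centers to lattice spacings via Bragg's law, derives the
#' hexagonal \code{a} and \code{c} constants, and applies the Scherrer
#' equation to the corrected (002) width.
#'
#' @param dg A \code{spectrum} with modality \code{"XRD"}.
#' @param window_002,window_300 Fit windows in deg 2-theta.
#' @param ... Passed to \code{\link{fit_reflection}}.
#' @return A \code{lattice_result} list: \code{D_nm}, \code{a_nm},
#'   \code{c_nm}, \code{d002_A}, \code{d300_A}, \code{fit_002},
#'   \code{fit_300}.
#' @export
analyze_diffractogram <- function(dg, window_002 = c(24, 28),
                                  window_300 = c(31, 35), ...) {
  f002 <- tryCatch(fit_reflection(dg, c(0, 0, 2), window_002, ...),
                   error = function(e) stop("(002) fit: ", conditionMessage(e)))
  f300 <- tryCatch(fit_reflection(dg, c(3, 0, 0), window_300, ...),
                   error = function(e) stop("(300) fit: ", conditionMessage(e)))
  d002 <- bragg_d(f002$center_2theta)
  d300 <- bragg_d(f300$center_2theta)
  c_A <- lattice_from_d(d002, c(0, 0, 2))$value_A
  a_A <- lattice_from_d(d300, c(3, 0, 0))$value_A
  D <- scherrer_size(f002$fwhm_corrected, f002$center_2theta)
  structure(list(D_nm = D, a_nm = a_A / 10, c_nm = c_A / 10,
                 d002_A = d002, d300_A = d300,
                 fit_002 = f002, fit_300 = f300),
            class = "lattice_result")
}

#' @export
print.lattice_result <- function(x, ...) {
  cat(sprintf("<lattice_result> D = %.3f nm, a = %.5f nm, c = %.4f A\n",
              x$D_nm, x$a_nm, x$c_nm * 10))
  invisible(x)
}
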