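#' Sampled 1-D signal (spectrum or diffractogram)
#'
#' The carrier object for the FTIR, Raman, and XRD stages: a strictly
#' monotone axis (cm^-1 or deg 2-theta), intensities, a modality tag, and an
#' append-only preprocessing log for auditability.
#'
#' @param axis Strictly monotone numeric grid.
#' @param intensity Numeric intensities, same length as \code{axis}.
#' @param modality One of \code{"FTIR"}, \code{"Raman"}, \code{"XRD"}.
#' @param log Character vector of preprocessing steps already applied.
#' @return An object of class \code{spectrum}.
#' @export
new_spectrum <- function(axis, intensity, modality = c("FTIR", "Raman", "XRD"),
                         log = character()) {
  modality <- match.arg(modality)
  axis <- as.numeric(axis); intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity)) {
    stop("axis and intensity must have equal length")
  }
  dx <- diff(axis)
  if (length(dx) && !(all(dx > 0) || all(dx < 0))) {
    stop("axis must be strictly monotone")
  }
  structure(list(axis = axis, intensity = intensity, modality = modality,
                 preprocessing_log = log),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s, %d points, axis [%g, %g]\n", x$modality,
              length(x$axis), min(x$axis), max(x$axis)))
  if (length(x$preprocessing_log)) {
    cat("  log:", paste(x$preprocessing_log, collapse = " -> "), "\n")
  }
  invisible(x)
}

# Append a step to the audit trail, returning the updated spectrum.
.log_step <- function(s, step) {
  s$preprocessing_log <- c(s$preprocessing_log, step)
  s
}

# Intensity at the grid point nearest to x (no interpolation, by design:
# reproducible on the instrument's native grid).
.at_nearest <- function(s, x) {
  s$intensity[which.min(abs(s$axis - x))]
}

# Trapezoidal integral of intensity over [lo, hi], optionally above the chord
# (local linear baseline) joining the interval endpoints.
.band_area <- function(s, lo, hi, baseline = c("local-linear", "none")) {
  baseline <- match.arg(baseline)
  if (lo >= hi) stop("band interval requires lo < hi")
  idx <- which(s$axis >= lo & s$axis <= hi)
  if (length(idx) < 3) stop("band interval contains too few grid points")
  x <- s$axis[idx]; y <- s$intensity[idx]
  if (is.unsorted(x)) { o <- order(x); x <- x[o]; y <- y[o] }
  if (baseline == "local-linear") {
    chord <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
    y <- y - chord
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Band area above a local baseline
#'
#' Trapezoidal integral of a spectrum over a closed interval, by default above
#' the straight line joining the interval endpoints.
#'
#' @param s A \code{spectrum}.
#' @param lo,hi Interval bounds on the axis (\code{lo < hi}).
#' @param baseline \code{"local-linear"} (default) or \code{"none"}.
#' @return List with \code{lo}, \code{hi}, \code{area}, \code{baseline_mode}.
#' @export
band_integral <- function(s, lo, hi, baseline = c("local-linear", "none")) {
  baseline <- match.arg(baseline)
  list(lo = lo, hi = hi, area = .band_area(s, lo, hi, baseline),
       baseline_mode = baseline)
}
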