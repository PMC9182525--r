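#' AFM height map
#'
#' @param grid Numeric matrix of heights in nm (finite, at least 2x2).
#' @param pixel_size_nm Lateral pixel size in nm (\code{> 0}).
#' @return Object of class \code{height_map}.
#' @export
height_map <- function(grid, pixel_size_nm) {
  grid <- as.matrix(grid)
  if (any(!is.finite(grid))) stop("height map contains non-finite entries")
  if (nrow(grid) < 2 || ncol(grid) < 2) stop("height map must be at least 2x2")
  if (pixel_size_nm <= 0) stop("pixel size must be positive")
  structure(list(grid = grid, pixel_size_nm = pixel_size_nm),
            class = "height_map")
}

#' Per-pixel DMT modulus map
#'
#' @param grid Numeric matrix of reduced moduli in GPa.
#' @param pixel_size_nm Lateral pixel size in nm.
#' @return Object of class \code{modulus_map}.
#' @export
modulus_map <- function(grid, pixel_size_nm) {
  grid <- as.matrix(grid)
  if (any(!is.finite(grid))) stop("modulus map contains non-finite entries")
  structure(list(grid = grid, pixel_size_nm = pixel_size_nm),
            class = "modulus_map")
}

#' Areal surface roughness Sa and Sq
#'
#' Detrends the height map (least-squares mean plane by default, the dominant
#' AFM artifact being sample tilt) and returns the average roughness
#' \code{Sa = mean(|Z|)} and root-mean-square roughness
#' \code{Sq = sqrt(mean(Z^2))} of the residual heights. \code{Sa <= Sq}
#' always, with equality iff |Z| is constant.
#'
#' @param h A \code{height_map}.
#' @param detrend \code{"plane"} (default), \code{"mean"}, or \code{"none"}.
#' @return List with \code{sa_nm} and \code{sq_nm}.
#' @export
roughness <- function(h, detrend = c("plane", "mean", "none")) {
  detrend <- match.arg(detrend)
  stopifnot(inherits(h, "height_map"))
  z <- h$grid
  if (detrend == "plane") {
    nx <- nrow(z); ny <- ncol(z)
    xi <- rep(seq_len(nx), times = ny); yi <- rep(seq_len(ny), each = nx)
    X <- cbind(1, xi, yi)
    z <- z - matrix(drop(X %*% stats::lm.fit(X, as.vector(z))$coefficients),
                    nx, ny)
  } else if (detrend == "mean") {
    z <- z - mean(z)
  }
  list(sa_nm = mean(abs(z)), sq_nm = sqrt(mean(z^2)))
}

#' DMT contact-mechanics force law
#'
#' \code{F(delta) = 4/3 E* sqrt(R) delta^(3/2) - F_adh}, with deformation in
#' nm, force in nN, tip radius in nm and modulus in GPa (1 nN/nm^2 = 1 GPa).
#'
#' @param deformation Deformation in nm (\code{>= 0}).
#' @param E_star Reduced modulus in GPa.
#' @param tip_radius_nm Tip radius in nm.
#' @param F_adh Adhesion force in nN.
#' @return Force in nN.
#' @export
dmt_force <- function(deformation, E_star, tip_radius_nm = 30, F_adh = 0) {
  4 / 3 * E_star * sqrt(tip_radius_nm) * deformation^1.5 - F_adh
}

#' AFM force curve
#'
#' @param deformation Deformation in nm, monotone within the branch.
#' @param force Force in nN.
#' @param branch \code{"unload"} or \code{"load"}.
#' @param tip_radius_nm Tip radius (default 30 nm).
#' @param spring_constant Cantilever spring constant (default 200 N/m).
#' @return Object of class \code{force_curve}.
#' @export
force_curve <- function(deformation, force, branch = c("unload", "load"),
                        tip_radius_nm = 30, spring_constant = 200) {
  branch <- match.arg(branch)
  if (length(deformation) != length(force)) stop("deformation/force length mismatch")
  if (is.unsorted(deformation) && is.unsorted(rev(deformation))) {
    stop("deformation must be monotone within a branch")
  }
  structure(list(deformation = as.numeric(deformation),
                 force = as.numeric(force), branch = branch,
                 tip_radius_nm = tip_radius_nm,
                 spring_constant = spring_constant),
            class = "force_curve")
}

#' Reduced modulus from a force curve (DMT model)
#'
#' Restricts the unloading branch to the points whose force lies between 30%
#' and 90% of the branch's force range and fits the DMT law
#' \code{F = 4/3 E* sqrt(R) delta^(3/2) - F_adh} by linear least squares in
#' the basis \code{(delta^(3/2), 1)}.
#'
#' @param fc A \code{force_curve} (unload branch).
#' @param force_window Force-range fraction window (default \code{c(0.3, 0.9)}).
#' @param min_points Minimum points required inside the window (default 20).
#' @return List with \code{E_star_gpa}, \code{F_adh_nN}, \code{n_points},
#'   \code{rss}.
#' @export
dmt_fit <- function(fc, force_window = c(0.3, 0.9), min_points = 20) {
  stopifnot(inherits(fc, "force_curve"))
  if (fc$branch != "unload") stop("DMT fit expects the unload branch")
  if (all(fc$deformation <= 0)) stop("no contact regime: zero deformation everywhere")
  f <- fc$force
  # window on the force predicted by a first-pass fit, not the raw force:
  # selecting on noisy values correlates selection with the residuals and
  # biases the regression
  contact <- which(fc$deformation > 0)
  c0 <- stats::lm.fit(cbind(fc$deformation[contact]^1.5, -1),
                      f[contact])$coefficients
  fhat <- c0[[1]] * fc$deformation^1.5 - c0[[2]]
  lo <- min(fhat[contact]) + force_window[1] * diff(range(fhat[contact]))
  hi <- min(fhat[contact]) + force_window[2] * diff(range(fhat[contact]))
  sel <- which(fhat >= lo & fhat <= hi & fc$deformation > 0)
  if (length(sel) < min_points) {
    stop(sprintf("insufficient points in the %g-%g%% force window (%d < %d)",
                 100 * force_window[1], 100 * force_window[2],
                 length(sel), min_points))
  }
  X <- cbind(fc$deformation[sel]^1.5, -1)
  coefs <- stats::lm.fit(X, f[sel])$coefficients
  a <- coefs[[1]]
  E_star <- 3 * a / (4 * sqrt(fc$tip_radius_nm))
  if (!is.finite(E_star) || E_star <= 0) stop("fitted modulus is non-positive")
  rss <- sum((f[sel] - drop(X %*% coefs))^2)
  list(E_star_gpa = E_star, F_adh_nN = coefs[[2]], n_points = length(sel),
       rss = rss)
}

# Freedman-Diaconis histogram of a numeric vector.
.fd_hist <- function(v) {
  bw <- 2 * stats::IQR(v) / length(v)^(1 / 3)
  if (bw <= 0) bw <- diff(range(v)) / 100
  breaks <- seq(min(v) - bw, max(v) + bw, by = bw)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(mids = h$mids, counts = h$counts, binwidth = bw)
}

#' Two-component Gaussian decomposition of a modulus histogram
#'
#' Builds a Freedman-Diaconis histogram of the per-pixel moduli and fits a
#' sum of two Gaussians to the bin counts by least squares (mirroring the
#' histogram-based peak location of the measurement protocol). Components are
#' sorted by mean; component I is the lower-mean one (the broader component
#' breaks ties). An EM fit on the raw pixels (\code{method = "em"}, via
#' \pkg{mclust}) is available as a cross-check.
#'
#' @param map A \code{modulus_map} with at least 1e4 pixels.
#' @param n_components Number of components (2 supported).
#' @param method \code{"histogram"} (default) or \code{"em"}.
#' @return A \code{modulus_decomposition}: per component \code{mean_gpa},
#'   \code{fwhm_gpa}, \code{weight}; plus \code{rss}, \code{binwidth},
#'   \code{unimodal} flag.
#' @export
decompose_modulus <- function(map, n_components = 2,
                              method = c("histogram", "em")) {
  method <- match.arg(method)
  stopifnot(inherits(map, "modulus_map"))
  if (n_components != 2) stop("only the two-component decomposition is supported")
  v <- as.vector(map$grid)
  if (length(v) < 1e4) stop("decomposition requires at least 1e4 pixels")

  if (method == "em") {
    if (!requireNamespace("mclust", quietly = TRUE)) {
      stop("method = 'em' requires the mclust package")
    }
    # Mclust re-evaluates the unqualified symbol `mclustBIC` in the calling
    # frame, which fails when mclust is not attached; a local alias fixes it
    mclustBIC <- mclust::mclustBIC
    em <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
    mu <- unname(em$parameters$mean)
    sig <- unname(sqrt(em$parameters$variance$sigmasq))
    w <- unname(em$parameters$pro)
    o <- order(mu)
    comps <- lapply(o, function(i) list(mean_gpa = mu[i],
                                        fwhm_gpa = 2 * sqrt(2 * log(2)) * sig[i],
                                        weight = w[i]))
    return(structure(list(components = comps, rss = NA_real_,
                          binwidth = NA_real_,
                          unimodal = any(w < 0.01)),
                     class = "modulus_decomposition"))
  }

  hh <- .fd_hist(v)
  x <- hh$mids; y <- hh$counts
  # heavily overlapping mixtures have local minima, so try a small
  # deterministic grid of moment/quantile starting values and keep the
  # lowest-residual fit
  m <- mean(v); s <- stats::sd(v)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  starts <- list(
    list(m1 = m - s,       s1 = s * 0.8, m2 = m + s,       s2 = s * 0.6),
    list(m1 = m - 0.5 * s, s1 = s,       m2 = m + 0.5 * s, s2 = s * 0.5),
    list(m1 = q[1],        s1 = s,       m2 = q[2],        s2 = s * 0.5),
    list(m1 = m - 0.3 * s, s1 = s * 1.2, m2 = m + 0.6 * s, s2 = s * 0.4),
    list(m1 = m - 1.5 * s, s1 = s * 0.6, m2 = m + 0.3 * s, s2 = s * 0.8))
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(minpack.lm::nlsLM(
      y ~ A1 * exp(-(x - m1)^2 / (2 * s1^2)) +
        A2 * exp(-(x - m2)^2 / (2 * s2^2)),
      start = c(list(A1 = max(y) * 0.6, A2 = max(y) * 0.8), st),
      lower = c(0, 0, min(v), 1e-3, min(v), 1e-3),
      upper = c(Inf, Inf, max(v), diff(range(v)), max(v), diff(range(v))),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
      fit <- cand
    }
  }
  if (is.null(fit)) stop("histogram decomposition failed to converge")
  p <- stats::coef(fit)
  areas <- c(p[["A1"]] * p[["s1"]], p[["A2"]] * p[["s2"]]) * sqrt(2 * pi)
  w <- areas / sum(areas)
  comp <- list(
    list(mean_gpa = p[["m1"]], fwhm_gpa = 2 * sqrt(2 * log(2)) * p[["s1"]],
         weight = w[1]),
    list(mean_gpa = p[["m2"]], fwhm_gpa = 2 * sqrt(2 * log(2)) * p[["s2"]],
         weight = w[2]))
  means <- vapply(comp, `[[`, 0, "mean_gpa")
  fwhms <- vapply(comp, `[[`, 0, "fwhm_gpa")
  # component I = lower mean; on an exact tie, the broader component
  o <- order(means, -fwhms)
  comp <- comp[o]
  # degenerate outcomes: a vanishing component, or two coincident components
  # (a single Gaussian split arbitrarily between them)
  unimodal <- any(w < 0.01) || abs(diff(means)) < 0.25 * min(fwhms)
  structure(list(components = comp, rss = sum(stats::resid(fit)^2),
                 binwidth = hh$binwidth,
                 unimodal = unimodal),
            class = "modulus_decomposition")
}

#' @export
print.modulus_decomposition <- function(x, ...) {
  for (i in seq_along(x$components)) {
    c_ <- x$components[[i]]
    cat(sprintf("  component %s: mean %.2f GPa, FWHM %.2f GPa, weight %.3f\n",
                c("I", "II")[i], c_$mean_gpa, c_$fwhm_gpa, c_$weight))
  }
  if (isTRUE(x$unimodal)) cat("  flag: effectively unimodal\n")
  invisible(x)
}
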