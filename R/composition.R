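# Atomic weights (g/mol) used in the molar conversion.
M_CA <- 40.078
M_P <- 30.974

#' EDS composition record
#'
#' Element weight-percent shares for one specimen/site, labeled with the day
#' of postnatal life and distance from the incisor tip.
#'
#' @param dpn Day of postnatal life.
#' @param distance_um Distance from incisor tip (100, 500, 1000, or 1500 um).
#' @param wt_percent Named numeric vector of element weight percents
#'   (each in [0, 100], total at most 100).
#' @return Object of class \code{composition_record}.
#' @export
composition_record <- function(dpn, distance_um, wt_percent) {
  if (!distance_um %in% c(100, 500, 1000, 1500)) {
    stop("distance_um must be one of 100, 500, 1000, 1500")
  }
  if (is.null(names(wt_percent)) || any(names(wt_percent) == "")) {
    stop("wt_percent must be a named vector")
  }
  if (any(wt_percent < 0) || any(wt_percent > 100)) {
    stop("each weight percent must lie in [0, 100]")
  }
  if (sum(wt_percent) > 100 + 1e-9) stop("weight percents exceed 100 in total")
  structure(list(dpn = dpn, distance_um = distance_um,
                 wt_percent = wt_percent),
            class = "composition_record")
}

#' Calcium-to-phosphorus ratio
#'
#' Weight-scale ratio \code{wt(Ca)/wt(P)} and molar ratio
#' \code{(wt(Ca)/40.078) / (wt(P)/30.974)}. For stoichiometric hydroxyapatite
#' the molar ratio is 1.67 (weight ratio 2.157); the weight-scale quantity is
#' the one EDS summaries report here.
#'
#' @param r A \code{composition_record} with positive P.
#' @return List with \code{weight_ratio} and \code{molar_ratio}.
#' @export
ca_p_ratio <- function(r) {
  stopifnot(inherits(r, "composition_record"))
  ca <- r$wt_percent[["Ca"]]; p <- r$wt_percent[["P"]]
  if (is.na(p) || p <= 0) stop("zero phosphorus: Ca/P ratio undefined")
  list(weight_ratio = ca / p,
       molar_ratio = (ca / M_CA) / (p / M_P))
}

#' Group summaries of composition records
#'
#' Long-format mean and SD per (dpn x distance) cell for every element plus
#' the Ca/P weight and molar ratios. Cells with a single record report
#' \code{NA} SD; absent cells are simply missing (never imputed).
#'
#' @param records List of \code{composition_record} objects.
#' @return data.frame with columns \code{dpn}, \code{distance_um},
#'   \code{quantity}, \code{mean}, \code{sd}, \code{n}.
#' @export
summarize_by_group <- function(records) {
  stopifnot(length(records) >= 1,
            all(vapply(records, inherits, TRUE, "composition_record")))
  rows <- lapply(records, function(r) {
    ratio <- ca_p_ratio(r)
    vals <- c(r$wt_percent, CaP_weight = ratio$weight_ratio,
              CaP_molar = ratio$molar_ratio)
    data.frame(dpn = r$dpn, distance_um = r$distance_um,
               quantity = names(vals), value = as.numeric(vals))
  })
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ dpn + distance_um + quantity, data = long,
                          FUN = function(v) c(mean = mean(v),
                                              sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                                              n = length(v)))
  out <- data.frame(dpn = agg$dpn, distance_um = agg$distance_um,
                    quantity = agg$quantity,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]))
  out[order(out$dpn, out$distance_um, out$quantity), , drop = FALSE]
}
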