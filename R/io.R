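#' Write a spectrum to a two-column CSV
#'
#' Format: a \code{# modality: <tag>} header line, optional
#' \code{# log: <step>} lines, then \code{axis,intensity} rows with full
#' double precision.
#'
#' @param s A \code{spectrum}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# modality: ", s$modality), con)
  for (step in s$preprocessing_log) writeLines(paste0("# log: ", step), con)
  writeLines("axis,intensity", con)
  writeLines(paste(sprintf("%.17g", s$axis), sprintf("%.17g", s$intensity),
                   sep = ","), con)
  invisible(path)
}

#' Read a spectrum from a two-column CSV
#'
#' @param path File written by \code{\link{write_spectrum_csv}} (or any CSV
#'   with a \code{# modality:} header and axis,intensity columns).
#' @return A \code{spectrum}.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  mod_line <- grep("^# modality:", lines, value = TRUE)
  if (!length(mod_line)) stop(path, ": missing '# modality:' header (line 1)")
  modality <- trimws(sub("^# modality:", "", mod_line[1]))
  log_steps <- trimws(sub("^# log:", "", grep("^# log:", lines, value = TRUE)))
  body_idx <- which(!startsWith(lines, "#"))
  body <- lines[body_idx]
  header <- which(body == "axis,intensity")
  if (!length(header)) stop(path, ": missing 'axis,intensity' column header")
  sel <- (header[1] + 1):length(body)
  rows <- body[sel]
  row_idx <- body_idx[sel]
  row_idx <- row_idx[nzchar(rows)]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop(sprintf("%s: malformed row at line %d", path, row_idx[bad[1]]))
  }
  axis <- as.numeric(vapply(parts, `[[`, "", 1))
  intensity <- as.numeric(vapply(parts, `[[`, "", 2))
  if (any(is.na(axis)) || any(is.na(intensity))) {
    stop(path, ": non-numeric entries in data rows")
  }
  new_spectrum(axis, intensity, modality, log = log_steps)
}

#' Write a 2-D map (height or modulus) to a CSV grid plus JSON sidecar
#'
#' @param m A \code{height_map} or \code{modulus_map}.
#' @param path CSV path; the sidecar is written at \code{<path>.json} with
#'   the pixel size and units.
#' @return \code{path}, invisibly.
#' @export
write_map_csv <- function(m, path) {
  stopifnot(inherits(m, "height_map") || inherits(m, "modulus_map"))
  units <- if (inherits(m, "height_map")) "nm" else "GPa"
  utils::write.table(format(m$grid, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(pixel_size_nm = m$pixel_size_nm, units = units,
                            kind = class(m)[1]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 2-D map written by \code{\link{write_map_csv}}
#'
#' @param path CSV path with a \code{<path>.json} sidecar.
#' @return A \code{height_map} or \code{modulus_map}.
#' @export
read_map_csv <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  grid <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(grid) <- NULL
  if (identical(meta$kind, "height_map")) {
    height_map(grid, meta$pixel_size_nm)
  } else {
    modulus_map(grid, meta$pixel_size_nm)
  }
}

#' Write EDS composition records to CSV
#'
#' @param records List of \code{composition_record}s.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_composition_csv <- function(records, path) {
  elems <- unique(unlist(lapply(records, function(r) names(r$wt_percent))))
  rows <- lapply(records, function(r) {
    v <- stats::setNames(rep(NA_real_, length(elems)), elems)
    v[names(r$wt_percent)] <- r$wt_percent
    data.frame(dpn = r$dpn, distance_um = r$distance_um, t(v))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read EDS composition records from CSV
#'
#' @param path CSV with columns \code{dpn}, \code{distance_um}, then element
#'   weight percents.
#' @return List of \code{composition_record}s.
#' @export
read_composition_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("dpn", "distance_um")
  if (!all(need %in% names(df))) {
    stop(path, ": required columns missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  elems <- setdiff(names(df), need)
  lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, elems]); names(v) <- elems
    composition_record(as.numeric(df$dpn[i]), as.numeric(df$distance_um[i]),
                       v[!is.na(v)])
  })
}

#' Write / read a feature table
#'
#' Plain CSV with the thirteen feature columns plus \code{dpn}.
#'
#' @param table Feature data.frame.
#' @param path CSV path.
#' @return \code{path} (write) or the data.frame (read).
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"dpn" %in% names(df)) stop(path, ": missing 'dpn' column")
  df
}

#' Serialize a trained MLP to JSON (and back)
#'
#' Stores the network weights, architecture, and standardization parameters;
#' a round trip reproduces predictions exactly.
#'
#' @param model An \code{age_mlp}.
#' @param path JSON output path.
#' @return \code{path} (write) or the restored \code{age_mlp} (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "age_mlp"))
  # 17 significant digits so the doubles survive the text round trip exactly
  payload <- list(
    features = model$features, hidden = model$hidden,
    wts = sprintf("%.17g", model$net$wts), n = model$net$n,
    params = list(column = model$params$column,
                  mean = sprintf("%.17g", model$params$mean),
                  sd = sprintf("%.17g", model$params$sd)),
    seed = model$seed, maxit = model$maxit, decay = model$decay,
    converged = model$converged)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  # rebuild an nnet skeleton and install the stored weights
  k <- length(p$features)
  dummy_x <- matrix(0, max(p$hidden + 2, 4), k)
  dummy_y <- seq_len(nrow(dummy_x)) * 1.0
  net <- nnet::nnet(dummy_x, dummy_y, size = p$hidden, linout = TRUE,
                    maxit = 1, trace = FALSE, MaxNWts = 10000)
  stopifnot(length(net$wts) == length(p$wts))
  net$wts <- as.numeric(p$wts)
  params <- data.frame(column = p$params$column,
                       mean = as.numeric(p$params$mean),
                       sd = as.numeric(p$params$sd),
                       row.names = p$params$column)
  structure(list(net = net, params = params, features = p$features,
                 hidden = p$hidden, seed = p$seed, maxit = p$maxit,
                 decay = p$decay, converged = p$converged),
            class = "age_mlp")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a multimodal sample set, runs each per-modality
#' extraction stage, assembles the per-specimen feature rows, trains the
#' 13-input network, runs the sensitivity analysis, prunes, retrains, and
#' returns predictions, writing CSV/JSON outputs and a run manifest when
#' \code{out_dir} is given. Per-specimen stage failures are collected and
#' reported; the pipeline continues with the remaining specimens.
#'
#' @param config A \code{sim_config}.
#' @param days Days to process.
#' @param n_specimens Specimens per day for the signal stages (kept small by
#'   default; the regression stage uses a full feature table).
#' @param out_dir Optional output directory.
#' @param n_drop Number of features pruned greedily by lowest sensitivity
#'   (default 4). Ignored when \code{prune_threshold} is given.
#' @param prune_threshold Optional sensitivity threshold; when set, one-shot
#'   threshold pruning is used instead of the greedy rank-based prune.
#' @return List with \code{extracted} (per-specimen feature rows from raw
#'   signals), \code{feature_table}, \code{model_full}, \code{sensitivity},
#'   \code{model_pruned}, \code{predictions}, \code{failures},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = sim_config(), days = c(0, 7, 28),
                         n_specimens = 2, out_dir = NULL, n_drop = 4,
                         prune_threshold = NULL) {
  set_ <- simulate_sample_set(config, days = days, n_specimens = n_specimens)
  failures <- list()
  extracted <- lapply(set_$records, function(rec) {
    row <- list(dpn = rec$dpn, specimen = rec$specimen)
    step <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        failures[[length(failures) + 1]] <<- sprintf(
          "dpn %s specimen %s stage %s: %s", rec$dpn, rec$specimen, name,
          conditionMessage(e))
        NULL
      })
    }
    xr <- step("xrd", analyze_diffractogram(rec$diffractogram))
    if (!is.null(xr)) {
      row$FWHM002 <- xr$fit_002$fwhm_corrected
      row$a_lattice <- xr$a_nm
      row$D_nm <- xr$D_nm
    }
    ft <- step("ftir", {
      s <- preprocess_ftir(rec$ftir)
      list(ci = ci_ftir(s), cp = cp_ratio_ftir(s))
    })
    if (!is.null(ft)) { row$CI_FTIR <- ft$ci; row$CP_FTIR <- ft$cp }
    rm_ <- step("raman", {
      s <- rec$raman |> despike() |> subtract_fluorescence() |> rubber_band()
      list(ci = ci_raman(s), cp = cp_ratio_raman(s))
    })
    if (!is.null(rm_)) { row$CI_Raman <- rm_$ci; row$CP_Raman <- rm_$cp }
    dm <- step("afm", decompose_modulus(rec$modulus_map))
    if (!is.null(dm)) {
      row$DMTI <- dm$components[[1]]$mean_gpa
      row$DMTII <- dm$components[[2]]$mean_gpa
    }
    rg <- step("roughness", roughness(rec$height_map))
    if (!is.null(rg)) { row$Sa <- rg$sa_nm; row$Sq <- rg$sq_nm }
    as.data.frame(row)
  })
  extracted <- do.call(rbind, lapply(extracted, function(d) {
    all_cols <- c("dpn", "specimen", "FWHM002", "a_lattice", "D_nm",
                  "CI_FTIR", "CP_FTIR", "CI_Raman", "CP_Raman",
                  "DMTI", "DMTII", "Sa", "Sq")
    for (cn in setdiff(all_cols, names(d))) d[[cn]] <- NA_real_
    d[all_cols]
  }))

  eds_summary <- summarize_by_group(set_$eds_records)

  table <- simulate_feature_table(config)
  splits <- split_table(table, seed = config$seed)
  model_full <- train_mlp(splits$train, splits$valid, splits$test,
                          seed = config$seed)
  sens <- sensitivity_analysis(model_full, splits$train, splits$valid,
                               seed = config$seed)
  pruned <- if (is.null(prune_threshold)) {
    prune_and_retrain(table, sens, n_drop = n_drop, recompute = TRUE,
                      seed = config$seed)
  } else {
    prune_and_retrain(table, sens, threshold = prune_threshold,
                      seed = config$seed)
  }
  preds <- data.frame(dpn = splits$test$dpn,
                      predicted = predict(pruned$model, splits$test))

  manifest <- list(package_version = as.character(utils::packageVersion("enameldev")),
                   r_version = as.character(getRversion()),
                   config = set_$provenance, days = days,
                   n_specimens = n_specimens,
                   n_drop = n_drop, prune_threshold = prune_threshold,
                   dropped = pruned$dropped)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_csv(table, file.path(out_dir, "feature_table.csv"))
    write_feature_csv(extracted, file.path(out_dir, "extracted_features.csv"))
    utils::write.csv(eds_summary, file.path(out_dir, "eds_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
    utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    write_model_json(pruned$model, file.path(out_dir, "model.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(extracted = extracted, eds_summary = eds_summary,
       feature_table = table, model_full = model_full, sensitivity = sens,
       model_pruned = pruned$model, dropped = pruned$dropped,
       predictions = preds, failures = failures, manifest = manifest)
}
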