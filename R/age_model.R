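#' Z-score standardization of a feature table
#'
#' Standardizes every feature column as \code{z = (x - mean) / sd} (sample
#' SD), using parameters estimated from the supplied rows (the training split
#' in the modeling workflow). The transform is invertible via
#' \code{\link{unstandardize}}.
#'
#' @param table data.frame of features (and optionally a \code{dpn} column,
#'   which is standardized too when \code{include_dpn = TRUE}).
#' @param params Optional previously estimated parameters to apply instead of
#'   re-estimating.
#' @param include_dpn Standardize the \code{dpn} column as well (default TRUE
#'   when present).
#' @return List with \code{table} (standardized) and \code{params}
#'   (data.frame of per-column mean and sd).
#' @export
standardize <- function(table, params = NULL,
                        include_dpn = "dpn" %in% names(table)) {
  cols <- setdiff(names(table), if (include_dpn) character() else "dpn")
  cols <- cols[vapply(table[cols], is.numeric, TRUE)]
  if (is.null(params)) {
    mu <- vapply(table[cols], mean, 0)
    sg <- vapply(table[cols], stats::sd, 0)
    bad <- cols[!is.finite(sg) | sg <= 0]
    if (length(bad)) {
      stop("constant feature(s) cannot be standardized: ",
           paste(bad, collapse = ", "))
    }
    params <- data.frame(column = cols, mean = mu, sd = sg,
                         row.names = cols)
  }
  out <- table
  for (cn in params$column) {
    if (cn %in% names(out)) {
      out[[cn]] <- (out[[cn]] - params[cn, "mean"]) / params[cn, "sd"]
    }
  }
  list(table = out, params = params)
}

#' Invert a standardization
#'
#' @param table Standardized data.frame (or numeric vector with
#'   \code{column} given).
#' @param params Parameters from \code{\link{standardize}}.
#' @param column When \code{table} is a bare numeric vector, the column whose
#'   parameters to apply.
#' @return Data on the original scale.
#' @export
unstandardize <- function(table, params, column = NULL) {
  if (is.numeric(table) && !is.data.frame(table)) {
    stopifnot(!is.null(column))
    return(table * params[column, "sd"] + params[column, "mean"])
  }
  out <- table
  for (cn in intersect(params$column, names(out))) {
    out[[cn]] <- out[[cn]] * params[cn, "sd"] + params[cn, "mean"]
  }
  out
}

# Largest-remainder apportionment of n rows into fractions.
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Random train/validation/test split stratified by day
#'
#' Seeded random partition into training, validation and test sets with
#' largest-remainder rounding of the requested fractions. Stratification by
#' dpn keeps every day represented in the training split; groups smaller than
#' 3 rows relax stratification with a warning.
#'
#' @param table Feature table with a \code{dpn} column.
#' @param fractions Length-3 fractions summing to 1 (default 70/15/15).
#' @param seed RNG seed for the partition.
#' @return List of data.frames \code{train}, \code{valid}, \code{test}.
#' @export
split_table <- function(table, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, "dpn" %in% names(table))
  n <- nrow(table)
  sizes <- .apportion(n, fractions)
  idx <- seq_len(n)
  small <- any(table(table$dpn) < 3)
  if (small && length(unique(table$dpn)) > 1) {
    warning("some dpn groups have fewer than 3 rows; stratification relaxed")
  }
  perm <- .with_seed(seed, 0, "split", {
    if (small) {
      sample(idx)
    } else {
      # interleave a within-day shuffle so train gets filled across all days
      by_day <- split(idx, table$dpn)
      by_day <- lapply(by_day, sample)
      maxlen <- max(lengths(by_day))
      order_mat <- unlist(lapply(seq_len(maxlen), function(k) {
        vapply(by_day, function(v) if (k <= length(v)) v[k] else NA_integer_,
               0L)
      }))
      as.integer(order_mat[!is.na(order_mat)])
    }
  })
  train <- sort(perm[seq_len(sizes[1])])
  valid <- sort(perm[sizes[1] + seq_len(sizes[2])])
  test <- sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  list(train = table[train, , drop = FALSE],
       valid = table[valid, , drop = FALSE],
       test = table[test, , drop = FALSE])
}

# Split metrics on the dpn (day) scale.
.split_metrics <- function(pred_days, true_days) {
  n <- length(true_days)
  if (n == 0) {
    return(list(R2 = NA_real_, SSE = NA_real_, RMSE = NA_real_, n = 0L))
  }
  sse <- sum((true_days - pred_days)^2)
  sst <- sum((true_days - mean(true_days))^2)
  list(R2 = if (sst > 0) 1 - sse / sst else NA_real_,
       SSE = sse, RMSE = sqrt(sse / n), n = as.integer(n))
}

#' Train a day-of-life MLP regressor
#'
#' One-hidden-layer perceptron with logistic sigmoid hidden units and a
#' linear output, trained on standardized features and standardized dpn with
#' a quasi-Newton (BFGS-family) optimizer capped at \code{maxit} iterations
#' (via \pkg{nnet}). \code{n_starts} networks are trained from different
#' random initializations and the one with the maximum validation R-squared
#' (minimum validation SSE breaking ties; training metrics when no validation
#' split is supplied) is retained. Metrics (R-squared, SSE, RMSE) are
#' reported on the day scale after inverse-standardizing the predictions.
#'
#' @param train,valid,test Feature tables with a \code{dpn} column (valid and
#'   test may be empty data.frames).
#' @param hidden Hidden-layer size (default 5).
#' @param features Feature columns to use (default all 13).
#' @param seed Seed for the weight initialization.
#' @param maxit Optimizer iteration cap (default 100 "epochs").
#' @param decay Small L2 weight penalty stabilizing the quasi-Newton fit.
#' @param n_starts Number of random restarts to select among (default 20).
#' @return Object of class \code{age_mlp}: fitted network, standardization
#'   parameters, feature list, and a \code{report} of per-split metrics.
#' @export
train_mlp <- function(train, valid = train[0, ], test = train[0, ],
                      hidden = 5, features = feature_names(), seed = 1L,
                      maxit = 100, decay = 0.08, n_starts = 20L) {
  stopifnot(all(c(features, "dpn") %in% names(train)), n_starts >= 1)
  if (any(!stats::complete.cases(train[c(features, "dpn")]))) {
    stop("missing values are not allowed in training data")
  }
  if (stats::sd(train$dpn) == 0) stop("zero-variance target: R2 undefined")
  std <- standardize(train[c(features, "dpn")])
  # the split used to pick among restarts: validation when available,
  # otherwise the training split itself
  sel <- if (nrow(valid) > 0) valid else train
  best <- NULL
  for (r in seq_len(n_starts)) {
    net <- .with_seed(seed, r, "mlp", {
      nnet::nnet(x = as.matrix(std$table[features]),
                 y = std$table$dpn, size = hidden, linout = TRUE,
                 maxit = maxit, decay = decay, trace = FALSE,
                 MaxNWts = 10000)
    })
    cand <- structure(list(net = net, params = std$params,
                           features = features, hidden = hidden,
                           seed = seed, maxit = maxit, decay = decay,
                           n_starts = n_starts,
                           converged = net$convergence == 0),
                      class = "age_mlp")
    m <- .split_metrics(predict(cand, sel), sel$dpn)
    if (is.null(best) || m$R2 > best_m$R2 ||
        (m$R2 == best_m$R2 && m$SSE < best_m$SSE)) {
      best <- cand; best_m <- m
    }
  }
  model <- best
  report <- lapply(list(train = train, valid = valid, test = test),
                   function(d) {
                     if (nrow(d) == 0) return(.split_metrics(numeric(0), numeric(0)))
                     .split_metrics(predict(model, d), d$dpn)
                   })
  model$report <- report
  model
}

#' Predict day of postnatal life
#'
#' Standardizes the supplied features with the model's stored parameters,
#' evaluates the network, and inverse-standardizes the output to days.
#' \code{snap = TRUE} rounds each prediction to the nearest sampled day.
#'
#' @param object An \code{age_mlp}.
#' @param newdata data.frame containing the model's feature columns.
#' @param snap Snap to the nearest anchor day (default FALSE).
#' @param ... Unused.
#' @return Numeric vector of predicted days.
#' @export
predict.age_mlp <- function(object, newdata, snap = FALSE, ...) {
  missing_f <- setdiff(object$features, names(newdata))
  if (length(missing_f)) {
    stop("missing feature(s): ", paste(missing_f, collapse = ", "))
  }
  std <- standardize(newdata[object$features], params = object$params,
                     include_dpn = FALSE)
  z <- drop(stats::predict(object$net, as.matrix(std$table[object$features])))
  days <- unstandardize(z, object$params, column = "dpn")
  if (snap) {
    anchors <- c(0, 2, 5, 7, 10, 14, 21, 28)
    days <- vapply(days, function(d) anchors[which.min(abs(anchors - d))], 0)
  }
  days
}

#' @export
print.age_mlp <- function(x, ...) {
  cat(sprintf("<age_mlp> %d-%d-1 network (%s)\n", length(x$features),
              x$hidden, if (x$converged) "converged" else "iteration cap reached"))
  for (s in names(x$report)) {
    r <- x$report[[s]]
    if (r$n > 0) {
      cat(sprintf("  %s: n=%d R2=%.4f SSE=%.3f RMSE=%.3f days\n",
                  s, r$n, r$R2, r$SSE, r$RMSE))
    }
  }
  invisible(x)
}

#' Growth-method architecture search
#'
#' Trains networks of increasing hidden-layer size and selects the size with
#' the maximum validation R-squared (minimum validation SSE breaking ties),
#' the turnover point beyond which added neurons over-fit. The full
#' size-vs-metric curve is returned for inspection.
#'
#' @param train,valid Feature tables with a \code{dpn} column.
#' @param hidden_range Candidate hidden sizes (default 1:15).
#' @param features Feature columns (default all 13).
#' @param seeds Seeds averaged per size (default 1).
#' @param ... Passed to \code{\link{train_mlp}}.
#' @return List with \code{best_hidden}, \code{curve} (data.frame of size,
#'   mean validation R2 and SSE), and \code{best_model}.
#' @export
growth_search <- function(train, valid, hidden_range = 1:15,
                          features = feature_names(), seeds = 1L, ...) {
  rows <- lapply(hidden_range, function(h) {
    fits <- lapply(seeds, function(s) {
      train_mlp(train, valid, features = features, hidden = h, seed = s, ...)
    })
    r2 <- mean(vapply(fits, function(f) f$report$valid$R2, 0))
    sse <- mean(vapply(fits, function(f) f$report$valid$SSE, 0))
    list(hidden = h, valid_R2 = r2, valid_SSE = sse,
         model = fits[[which.max(vapply(fits, function(f) f$report$valid$R2, 0))]])
  })
  curve <- data.frame(hidden = vapply(rows, `[[`, 0, "hidden"),
                      valid_R2 = vapply(rows, `[[`, 0, "valid_R2"),
                      valid_SSE = vapply(rows, `[[`, 0, "valid_SSE"))
  o <- order(-curve$valid_R2, curve$valid_SSE)
  best <- rows[[o[1]]]
  list(best_hidden = best$hidden, curve = curve, best_model = best$model)
}

#' Sensitivity analysis of network inputs
#'
#' For each feature, the network error without that feature divided by the
#' full-model error (both RMSE on the pooled training + validation rows).
#' Ratios above one mark informative inputs; ratios near or below one mark
#' inputs whose removal does not hurt (or helps). \code{mode = "retrain"}
#' (default) retrains the network without the feature;
#' \code{mode = "permute"} re-evaluates the trained network with the feature
#' column permuted (cheaper).
#'
#' @param model A fitted \code{age_mlp}.
#' @param train,valid The splits used to fit the model.
#' @param mode \code{"retrain"} or \code{"permute"}.
#' @param seed Seed for retraining / permutation.
#' @param reps Replicates averaged per feature (different retraining seeds /
#'   permutations); stabilizes the ranking (default 3).
#' @return data.frame with columns \code{feature} and \code{ratio}, sorted by
#'   descending ratio.
#' @export
sensitivity_analysis <- function(model, train, valid = train[0, ],
                                 mode = c("retrain", "permute"), seed = 1L,
                                 reps = 3L) {
  mode <- match.arg(mode)
  stopifnot(reps >= 1)
  pooled <- rbind(train, valid)
  err_full <- .split_metrics(predict(model, pooled), pooled$dpn)$RMSE
  ratios <- vapply(model$features, function(f) {
    one <- vapply(seq_len(reps), function(r) {
      if (mode == "retrain") {
        sub <- train_mlp(train, valid, hidden = model$hidden,
                         features = setdiff(model$features, f),
                         seed = seed + 1000L * (r - 1L),
                         maxit = model$maxit, decay = model$decay,
                         n_starts = model$n_starts)
        .split_metrics(predict(sub, pooled), pooled$dpn)$RMSE / err_full
      } else {
        shuffled <- pooled
        shuffled[[f]] <- .with_seed(seed, r, paste0("perm", f),
                                    sample(shuffled[[f]]))
        .split_metrics(predict(model, shuffled), pooled$dpn)$RMSE / err_full
      }
    }, 0)
    mean(one)
  }, 0)
  out <- data.frame(feature = model$features, ratio = ratios)
  out[order(-out$ratio), , drop = FALSE]
}

#' Prune uninformative features and retrain
#'
#' Drops every feature whose sensitivity ratio falls below the threshold
#' (default 1.1) and retrains the network on the remaining inputs. With the
#' published sensitivity table this removes exactly the two crystallinity
#' indices plus carbon and calcium, yielding the 9-input network. Refuses to
#' drop more than half of the features.
#'
#' @param table Full feature table with \code{dpn}.
#' @param report Sensitivity report (\code{feature}, \code{ratio}).
#' @param threshold Drop features with \code{ratio < threshold}
#'   (default 1.1). Alternatively set \code{n_drop} to drop a fixed count of
#'   lowest-ratio features.
#' @param n_drop Optional number of lowest-ratio features to drop (overrides
#'   \code{threshold}).
#' @param recompute With \code{n_drop}, drop greedily: remove the single
#'   lowest-ratio feature, retrain, recompute sensitivities, repeat. This
#'   avoids discarding both members of a redundant pair (each looks
#'   dispensable alone while the pair is jointly informative). Ignored for
#'   threshold pruning.
#' @param hidden Hidden size of the retrained network (default 5).
#' @param fractions,seed Split specification for retraining.
#' @param ... Passed to \code{\link{train_mlp}}.
#' @return List with \code{model} (the retrained \code{age_mlp}),
#'   \code{dropped}, \code{kept}.
#' @export
prune_and_retrain <- function(table, report, threshold = 1.1, n_drop = NULL,
                              recompute = FALSE, hidden = 5,
                              fractions = c(0.70, 0.15, 0.15),
                              seed = 1L, ...) {
  stopifnot(all(c("feature", "ratio") %in% names(report)))
  if (recompute && !is.null(n_drop)) {
    if (n_drop > length(report$feature) / 2) {
      stop(sprintf("refusing to drop %d of %d features; lower the threshold",
                   n_drop, length(report$feature)))
    }
    splits <- split_table(table, fractions, seed = seed)
    feats <- report$feature
    dropped <- character(0)
    for (j in seq_len(n_drop)) {
      m <- train_mlp(splits$train, splits$valid, hidden = hidden,
                     features = feats, seed = seed, ...)
      rep_j <- sensitivity_analysis(m, splits$train, splits$valid, seed = seed)
      worst <- rep_j$feature[which.min(rep_j$ratio)]
      dropped <- c(dropped, worst)
      feats <- setdiff(feats, worst)
    }
    model <- train_mlp(splits$train, splits$valid, splits$test,
                       hidden = hidden, features = feats, seed = seed, ...)
    return(list(model = model, dropped = dropped, kept = feats))
  }
  dropped <- if (is.null(n_drop)) {
    report$feature[report$ratio < threshold]
  } else {
    report$feature[order(report$ratio)][seq_len(n_drop)]
  }
  if (length(dropped) > length(report$feature) / 2) {
    stop(sprintf("refusing to drop %d of %d features; lower the threshold",
                 length(dropped), length(report$feature)))
  }
  kept <- setdiff(report$feature, dropped)
  splits <- split_table(table, fractions, seed = seed)
  model <- train_mlp(splits$train, splits$valid, splits$test,
                     hidden = hidden, features = kept, seed = seed, ...)
  list(model = model, dropped = dropped, kept = kept)
}
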