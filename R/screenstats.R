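# Screen-level statistics: well aggregation, replicate combination,
# Z-score normalization to DMSO controls, toxicity filtering, z-prime
# assay quality, PCA phenotype embedding and hit classification.

#' Aggregate per-cell records to a well summary
#'
#' @param cells data.frame of per-cell features from one well (border
#'   cells already excluded).
#' @param features Feature columns to summarize; defaults to all numeric
#'   columns except identifiers/flags.
#' @return One-row data.frame: `cell_count`, then `mean_<f>` and
#'   `median_<f>` per feature. A well with zero cells yields
#'   `cell_count = 0` and `NA` summaries.
#' @export
aggregate_well <- function(cells, features = NULL) {
  abort_if(!is.data.frame(cells), "'cells' must be a data.frame")
  if (is.null(features)) {
    skip <- c("cell_id", "field", "well_id", "border_flag",
              "ring_empty_flag", "plate")
    features <- setdiff(names(cells)[vapply(cells, is.numeric, TRUE)], skip)
  }
  out <- data.frame(cell_count = nrow(cells))
  for (f in features) {
    v <- if (nrow(cells) > 0) cells[[f]] else NA_real_
    out[[paste0("mean_", f)]] <- if (nrow(cells) > 0) mean(v) else NA_real_
    out[[paste0("median_", f)]] <- if (nrow(cells) > 0)
      stats::median(v) else NA_real_
  }
  out
}

#' Combine replicate wells into a compound summary
#'
#' Unweighted mean of well-level summaries across replicate wells (the
#' replicate averaging of duplicate plates). Compounds analysed on fewer
#' than `min_cells` total cells are flagged as failing QC (default 600).
#'
#' @param well_summaries data.frame with one row per replicate well:
#'   `compound_id`, `cell_count`, and summary columns.
#' @param min_cells Minimum total cell count across replicates.
#' @return One-row data.frame: `compound_id`, `n_replicates`,
#'   `total_cells`, `qc_pass`, and replicate-averaged summary columns.
#' @export
combine_replicates <- function(well_summaries, min_cells = 600) {
  abort_if(!is.data.frame(well_summaries) || nrow(well_summaries) == 0,
           "need at least one replicate well")
  ids <- unique(well_summaries$compound_id)
  abort_if(length(ids) != 1,
           "mixed compound_ids in replicate set: ",
           paste(ids, collapse = ", "))
  num <- setdiff(names(well_summaries)[vapply(well_summaries,
                                              is.numeric, TRUE)],
                 "cell_count")
  out <- data.frame(compound_id = ids,
                    n_replicates = nrow(well_summaries),
                    total_cells = sum(well_summaries$cell_count))
  for (f in num) out[[f]] <- mean(well_summaries[[f]], na.rm = TRUE)
  out$qc_pass <- out$total_cells >= min_cells
  out
}

#' Z-score normalization against negative controls
#'
#' Per plate and per feature: `z = (x - mu_neg) / sigma_neg`, where the
#' moments come from that plate's negative-control wells. Control wells
#' themselves are scored too.
#'
#' @param plate_summaries data.frame of well summaries with columns
#'   `well`, `role`, and feature columns; if a `plate` column is present
#'   normalization is done within each plate.
#' @param features Feature columns to normalize.
#' @return `plate_summaries` with added `z_<feature>` columns.
#' @export
zscore_normalize <- function(plate_summaries, features) {
  abort_if(!is.data.frame(plate_summaries), "need a data.frame")
  abort_if(!all(features %in% names(plate_summaries)),
           "unknown feature(s): ",
           paste(setdiff(features, names(plate_summaries)), collapse = ", "))
  plates <- if ("plate" %in% names(plate_summaries))
    plate_summaries$plate else rep(1L, nrow(plate_summaries))
  out <- plate_summaries
  for (f in features) out[[paste0("z_", f)]] <- NA_real_
  for (p in unique(plates)) {
    sel <- plates == p
    neg <- sel & plate_summaries$role == "negative_control"
    abort_if(sum(neg) < 2,
             "need >= 2 negative-control wells per plate for z-scoring")
    for (f in features) {
      mu <- mean(plate_summaries[[f]][neg])
      s <- stats::sd(plate_summaries[[f]][neg])
      abort_if(!is.finite(s) || s == 0,
               "zero negative-control SD for feature: ", f)
      out[[paste0("z_", f)]][sel] <- (plate_summaries[[f]][sel] - mu) / s
    }
  }
  out
}

#' Toxicity filter
#'
#' Toxicity of a compound is the fractional reduction of its cell count
#' relative to the mean negative-control cell count:
#' `1 - cell_count / mean(neg)`. Replicate toxicities are averaged before
#' thresholding. Compounds with toxicity strictly greater than
#' `threshold` (default 0.20) are excluded; the boundary case is retained.
#'
#' @param compound_summaries data.frame with `compound_id` and
#'   `mean_toxicity` columns, or precomputed per-compound toxicity in a
#'   column named `toxicity`.
#' @param threshold Exclusion threshold (default 0.2).
#' @return Input with logical column `excluded_toxicity` added.
#' @export
toxicity_filter <- function(compound_summaries, threshold = 0.2) {
  tox_col <- intersect(c("toxicity", "mean_toxicity"),
                       names(compound_summaries))
  abort_if(length(tox_col) == 0, "no toxicity column found")
  tox <- compound_summaries[[tox_col[1]]]
  compound_summaries$excluded_toxicity <- tox > threshold
  compound_summaries
}

#' Compute per-well toxicity from cell counts
#'
#' @param cell_count Numeric vector of well cell counts.
#' @param neg_mean_count Mean negative-control cell count (> 0).
#' @return `1 - cell_count / neg_mean_count` (can be negative for wells
#'   outgrowing the controls; capped at 1 from above by construction).
#' @export
toxicity_from_counts <- function(cell_count, neg_mean_count) {
  check_scalar_number(neg_mean_count, "neg_mean_count", lower = 1e-12)
  1 - cell_count / neg_mean_count
}

#' Z-prime (z-factor) assay window
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`, the standard
#' screening-window quality metric.
#'
#' @param positive_values,negative_values Numeric vectors (>= 2 values
#'   each).
#' @return Z-prime factor (<= 1; 1 only for zero variance).
#' @export
zprime <- function(positive_values, negative_values) {
  abort_if(length(positive_values) < 2 || length(negative_values) < 2,
           "need >= 2 values per group")
  mp <- mean(positive_values); mn <- mean(negative_values)
  abort_if(mp == mn, "z-prime undefined: group means are equal")
  1 - 3 * (stats::sd(positive_values) + stats::sd(negative_values)) /
    abs(mp - mn)
}

#' PCA embedding of compound phenotypes
#'
#' Z-scores each feature column (dropping constant features with a
#' warning), then computes principal components with a deterministic sign
#' convention: the largest-magnitude loading of each component is
#' positive.
#'
#' @param x Numeric matrix or data.frame, compounds in rows, features in
#'   columns.
#' @param n_components Number of components to keep (default all).
#' @return List with `scores` (coordinates), `loadings`,
#'   `explained_variance` (per component), `total_variance` and
#'   `dropped_features`.
#' @export
pca_embed <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  abort_if(nrow(x) < 2 || ncol(x) < 2,
           "need >= 2 compounds and >= 2 features")
  abort_if(any(!is.finite(x)), "non-finite values in feature matrix")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping constant feature(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    abort_if(ncol(x) < 2, "fewer than 2 non-constant features")
  }
  xs <- scale(x)
  p <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  k <- if (is.null(n_components)) ncol(p$x)
       else min(n_components, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       explained_variance = p$sdev^2,
       total_variance = sum(apply(xs, 2, stats::var)),
       dropped_features = dropped)
}

#' Classify compounds as lipid hits
#'
#' Rule-based classification on the LBPA and cholesterol z-scores:
#' `lbpa_selective` if `z_lbpa >= z_hit` and `|z_chol| < z_neutral`;
#' `chol_selective` symmetrically; `dual_lipid` if both z-scores are at
#' least `z_hit`; otherwise `none`. Toxicity-excluded compounds carry no
#' class (`NA`).
#'
#' @param screen_result data.frame with columns `z_lbpa`, `z_chol` and
#'   `excluded_toxicity`.
#' @param z_hit Hit threshold (default 3).
#' @param z_neutral Neutrality bound on the other lipid (default 2).
#' @return Input with character column `hit_class` added.
#' @export
call_hits <- function(screen_result, z_hit = 3, z_neutral = 2) {
  abort_if(!all(c("z_lbpa", "z_chol") %in% names(screen_result)),
           "need z_lbpa and z_chol columns")
  zl <- screen_result$z_lbpa; zc <- screen_result$z_chol
  ok <- function(cond) !is.na(cond) & cond
  cls <- rep("none", nrow(screen_result))
  cls[is.na(zl) | is.na(zc)] <- NA_character_
  cls[ok(zl >= z_hit & abs(zc) < z_neutral)] <- "lbpa_selective"
  cls[ok(zc >= z_hit & abs(zl) < z_neutral)] <- "chol_selective"
  cls[ok(zl >= z_hit & zc >= z_hit)] <- "dual_lipid"
  if ("excluded_toxicity" %in% names(screen_result))
    cls[screen_result$excluded_toxicity] <- NA_character_
  screen_result$hit_class <- cls
  screen_result
}
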