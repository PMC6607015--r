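# End-to-end pipeline: simulation -> segmentation -> per-cell features ->
# well/compound statistics -> screen result, with CSV artifacts.

#' Pipeline configuration
#'
#' All tunable parameters of the pipeline with their defaults. Unknown
#' keys in any section are rejected, and a config round-trips losslessly
#' through its JSON form ([write_config()] / [read_config()]).
#'
#' @param seed Master seed for all randomness.
#' @param n_replicates Number of replicate plates (default 2).
#' @param compounds data.frame with columns `compound_id`, `lbpa_factor`,
#'   `chol_factor`, `endosome_count_factor`, `perinuclear_factor`,
#'   `toxicity_fraction` (one row per library compound).
#' @param neg_col,pos_col Control columns (defaults 2 and 23).
#' @param sim Named list of [sim_params()] overrides.
#' @param seg Named list of [seg_params()] overrides.
#' @param min_cells QC threshold on total cells per compound (default 600).
#' @param toxicity_threshold Exclusion threshold (default 0.2).
#' @param z_hit,z_neutral Hit-calling thresholds (defaults 3 and 2).
#' @param lbpa_feature,chol_feature Well-summary columns used as the LBPA
#'   and cholesterol readouts for z-scoring and hit calling. Defaults:
#'   the per-cell endosomal (top-hat-masked) LBPA integrated intensity and
#'   the whole-cell filipin integrated intensity.
#' @param perinuclear_width_um Analysis annulus width (default 4).
#' @param out_dir Output directory (`NULL` = no artifacts written).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_replicates = 2L,
                            compounds = NULL,
                            neg_col = 2L, pos_col = 23L,
                            sim = list(), seg = list(),
                            min_cells = 600,
                            toxicity_threshold = 0.2,
                            z_hit = 3, z_neutral = 2,
                            lbpa_feature = "mean_endo_lbpa_int",
                            chol_feature = "mean_cell_chol_int",
                            perinuclear_width_um = 4,
                            out_dir = NULL) {
  sp <- do.call(sim_params, sim)    # validates the overrides
  gp <- do.call(seg_params, seg)
  abort_if(n_replicates < 1, "'n_replicates' must be >= 1")
  if (!is.null(compounds)) {
    need <- c("compound_id", "lbpa_factor", "chol_factor",
              "endosome_count_factor", "perinuclear_factor",
              "toxicity_fraction")
    missing_cols <- setdiff(need, names(compounds))
    abort_if(length(missing_cols) > 0, "compounds table missing column(s): ",
             paste(missing_cols, collapse = ", "))
    abort_if(any(duplicated(compounds$compound_id)),
             "duplicate compound_id in compounds table")
  }
  structure(list(seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 compounds = compounds,
                 neg_col = as.integer(neg_col),
                 pos_col = as.integer(pos_col),
                 sim = sp, seg = gp,
                 min_cells = min_cells,
                 toxicity_threshold = toxicity_threshold,
                 z_hit = z_hit, z_neutral = z_neutral,
                 lbpa_feature = lbpa_feature, chol_feature = chol_feature,
                 perinuclear_width_um = perinuclear_width_um,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` invisibly; [read_config()] returns the restored
#'   `pipeline_config` (unknown keys are rejected).
#' @export
write_config <- function(config, path) {
  abort_if(!inherits(config, "pipeline_config"), "not a pipeline_config")
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$seg <- unclass(x$seg)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  abort_if(length(unknown) > 0, "unknown config key(s): ",
           paste(unknown, collapse = ", "))
  for (sect in c("sim", "seg")) {
    fun <- if (sect == "sim") sim_params else seg_params
    bad <- setdiff(names(x[[sect]]), names(formals(fun)))
    abort_if(length(bad) > 0, sprintf("unknown %s key(s): ", sect),
             paste(bad, collapse = ", "))
  }
  if (!is.null(x$compounds)) x$compounds <- as.data.frame(x$compounds)
  do.call(pipeline_config, x)
}

# short content hash (rolling polynomial over the serialized object) for
# report headers
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Segment and measure one well
#'
#' Runs the full segmentation chain (nuclei, cell territories, top-hat
#' endosome detection, perinuclear annulus) and feature extraction on
#' every field of a well.
#'
#' @param images A [well_image_set()].
#' @param seg A [seg_params()].
#' @param perinuclear_width_um Annulus width (default 4).
#' @return List with `cells` (per-cell feature table, `field` column
#'   added) and `endosomes` (per-endosome table), plus `n_nuclei` per
#'   field.
#' @export
analyze_well <- function(images, seg = seg_params(),
                         perinuclear_width_um = 4) {
  abort_if(!inherits(images, "well_image_set"), "need a well_image_set")
  px <- images$pixel_size
  cell_tabs <- list(); endo_tabs <- list(); n_nuclei <- integer(0)
  for (f in seq_along(images$fields)) {
    img <- images$fields[[f]]
    nuc <- segment_nuclei(img[, , 1], seg)
    n_nuclei[f] <- n_objects(nuc)
    cells <- assign_cells(nuc, img[, , 2], seg)
    endo <- detect_endosomes(img[, , 3], cells, seg)
    ring <- perinuclear_ring(nuc, perinuclear_width_um, px)
    feats <- measure_cells(list(nuclei = nuc, cells = cells,
                                endosomes = endo, ring = ring),
                           img, px)
    if (nrow(feats) > 0) feats <- cbind(field = f, feats)
    cell_tabs[[f]] <- feats
    et <- endosome_cholesterol(endo, img[, , 4], lbpa_img = img[, , 3],
                               ring = ring)
    if (nrow(et) > 0) endo_tabs[[f]] <- cbind(field = f, et)
  }
  cells <- do.call(rbind, cell_tabs[vapply(cell_tabs, nrow, 1L) > 0])
  endos <- do.call(rbind, endo_tabs)
  list(cells = cells, endosomes = endos, n_nuclei = n_nuclei)
}

# Build the layout + effects implied by a config.
config_layout <- function(config) {
  ids <- if (is.null(config$compounds)) character(0)
         else config$compounds$compound_id
  default_plate_layout(ids, neg_col = config$neg_col,
                       pos_col = config$pos_col)
}

config_effects <- function(config) {
  if (is.null(config$compounds)) return(list())
  eff <- lapply(seq_len(nrow(config$compounds)), function(i) {
    r <- config$compounds[i, ]
    compound_effect(r$lbpa_factor, r$chol_factor, r$endosome_count_factor,
                    r$perinuclear_factor, r$toxicity_fraction)
  })
  names(eff) <- config$compounds$compound_id
  eff
}

#' Run the full screen pipeline
#'
#' Simulates every replicate plate well by well, segments and measures
#' each well, aggregates cells to wells and compounds, z-scores against
#' the plate's DMSO column, applies the toxicity filter, calls hits,
#' embeds compound phenotypes by PCA and (optionally) writes all
#' artifacts (per-cell CSV, screen CSV, QC report, log) under
#' `config$out_dir`. Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param progress Print per-well progress to stderr.
#' @return A `screen_result` list: `wells` (well summaries with z-scores
#'   and per-well hit classes), `compounds` (per-compound z-scores,
#'   toxicity, QC and hit classes), `pca`, `qc` (per-plate z-prime and
#'   control CVs), `config`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  abort_if(!inherits(config, "pipeline_config"), "not a pipeline_config")
  layout <- config_layout(config)
  effects <- config_effects(config)
  ctl <- control_effects()
  n_cols <- attr(layout, "n_cols")
  todo <- layout[layout$role != "empty", , drop = FALSE]

  well_rows <- list(); cell_tabs <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    plate_seed <- derive_seed(config$seed, rep_i, stream = 7L)
    for (i in seq_len(nrow(todo))) {
      wid <- todo$well[i]
      e <- switch(todo$role[i],
                  negative_control = ctl$negative,
                  positive_control = ctl$positive,
                  compound = effects[[todo$compound_id[i]]])
      widx <- (todo$row[i] - 1L) * n_cols + todo$col[i]
      sw <- tryCatch(
        simulate_well(todo[i, ], e, config$sim,
                      seed = derive_seed(plate_seed, widx)),
        error = function(err) stop("stage simulate failed at well ", wid,
                                   ": ", conditionMessage(err),
                                   call. = FALSE))
      an <- tryCatch(
        analyze_well(sw$images, config$seg, config$perinuclear_width_um),
        error = function(err) stop("stage segment/measure failed at well ",
                                   wid, ": ", conditionMessage(err),
                                   call. = FALSE))
      ws <- aggregate_well(an$cells)
      row <- data.frame(plate = rep_i, well = wid, role = todo$role[i],
                        compound_id = if (todo$role[i] == "compound")
                          todo$compound_id[i]
                        else if (todo$role[i] == "negative_control") "DMSO"
                        else "POSCTL",
                        stringsAsFactors = FALSE)
      well_rows[[length(well_rows) + 1]] <- cbind(row, ws)
      if (!is.null(an$cells) && nrow(an$cells) > 0)
        cell_tabs[[length(cell_tabs) + 1]] <-
          cbind(plate = rep_i, well_id = wid, an$cells)
      if (progress)
        message(sprintf("plate %d well %s: %d cells", rep_i, wid,
                        ws$cell_count))
    }
  }
  wells <- do.call(rbind, well_rows)
  cells <- do.call(rbind, cell_tabs)
  res <- screen_from_wells(wells, config)
  res$cells <- cells
  res$config <- config
  if (!is.null(config$out_dir)) write_screen_artifacts(res, config)
  res
}

#' Compute screen statistics from well summaries
#'
#' The statistics half of the pipeline, separated so that it can run on
#' any well-summary table (measured or ground-truth-derived): per-plate
#' z-scoring against the DMSO column, toxicity computation and filtering,
#' replicate combination, per-well and per-compound hit calls, per-plate
#' z-prime QC, and compound PCA.
#'
#' @param wells data.frame with columns `plate`, `well`, `role`,
#'   `compound_id`, `cell_count` and `mean_<feature>` columns.
#' @param config A [pipeline_config()].
#' @return A `screen_result` list (see [run_pipeline()]).
#' @export
screen_from_wells <- function(wells, config) {
  feat_cols <- grep("^mean_", names(wells), value = TRUE)
  usable <- feat_cols[vapply(feat_cols, function(f)
    all(is.finite(wells[[f]][wells$role == "negative_control"])) &&
      stats::sd(wells[[f]][wells$role == "negative_control"]) > 0, TRUE)]
  wells <- zscore_normalize(wells, usable)

  # toxicity from raw cell counts, per plate
  wells$toxicity <- NA_real_
  for (p in unique(wells$plate)) {
    sel <- wells$plate == p
    neg_mean <- mean(wells$cell_count[sel &
                                        wells$role == "negative_control"])
    wells$toxicity[sel] <- toxicity_from_counts(wells$cell_count[sel],
                                                neg_mean)
  }

  z_lbpa_col <- paste0("z_", config$lbpa_feature)
  z_chol_col <- paste0("z_", config$chol_feature)
  abort_if(!all(c(z_lbpa_col, z_chol_col) %in% names(wells)),
           "configured readout feature(s) missing from well summaries")
  wells$z_lbpa <- wells[[z_lbpa_col]]
  wells$z_chol <- wells[[z_chol_col]]
  wells <- call_hits(wells, config$z_hit, config$z_neutral)

  # per-compound aggregation (controls included as pseudo-compounds)
  zcols <- grep("^z_", names(wells), value = TRUE)
  comp_rows <- list()
  for (cid in unique(wells$compound_id)) {
    sel <- wells$compound_id == cid
    sub <- wells[sel, c("compound_id", "cell_count", zcols, "toxicity")]
    cs <- combine_replicates(sub, min_cells = config$min_cells)
    cs$role <- wells$role[sel][1]
    comp_rows[[cid]] <- cs
  }
  compounds <- do.call(rbind, comp_rows)
  rownames(compounds) <- NULL
  compounds <- toxicity_filter(compounds,
                               threshold = config$toxicity_threshold)
  compounds <- call_hits(compounds, config$z_hit, config$z_neutral)

  # QC: per-plate z-prime on the well-level LBPA readout feature
  qc_rows <- list()
  for (p in unique(wells$plate)) {
    sel <- wells$plate == p
    pos <- wells[[config$lbpa_feature]][sel &
                                          wells$role == "positive_control"]
    neg <- wells[[config$lbpa_feature]][sel &
                                          wells$role == "negative_control"]
    zp <- if (length(pos) >= 2 && length(neg) >= 2 &&
                mean(pos) != mean(neg)) zprime(pos, neg) else NA_real_
    qc_rows[[p]] <- data.frame(
      plate = p, zprime_lbpa = zp,
      neg_cv_lbpa = stats::sd(neg) / mean(neg),
      pos_cv_lbpa = if (length(pos) > 1) stats::sd(pos) / mean(pos)
                    else NA_real_,
      neg_mean_cell_count =
        mean(wells$cell_count[sel & wells$role == "negative_control"]))
  }
  qc <- do.call(rbind, qc_rows)

  # PCA over the compound-level z-scored phenotype (the aliased z_lbpa /
  # z_chol shortcut columns are left out to avoid double-weighting)
  pca <- NULL
  pca_cols <- setdiff(zcols, c("z_lbpa", "z_chol"))
  zmat <- as.matrix(compounds[, pca_cols, drop = FALSE])
  rownames(zmat) <- compounds$compound_id
  keep <- !compounds$excluded_toxicity & apply(is.finite(zmat), 1, all)
  if (sum(keep) >= 2 && ncol(zmat) >= 2) {
    pca <- suppressWarnings(pca_embed(zmat[keep, , drop = FALSE]))
    for (j in seq_len(min(3, ncol(pca$scores)))) {
      compounds[[paste0("PC", j)]] <- NA_real_
      compounds[[paste0("PC", j)]][keep] <- pca$scores[, j]
    }
  }
  structure(list(wells = wells, compounds = compounds, qc = qc, pca = pca),
            class = "screen_result")
}

# write per-cell CSV, screen CSV, QC report + log under config$out_dir
write_screen_artifacts <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# lbpascreen %s config=%s seed=%d",
                 as.character(utils::packageVersion("lbpascreen")),
                 config_hash(config), config$seed)
  write_with_header <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  if (!is.null(res$cells))
    utils::write.csv(res$cells, file.path(config$out_dir, "cells.csv"),
                     row.names = FALSE)
  write_with_header(res$compounds,
                    file.path(config$out_dir, "screen_results.csv"))
  write_with_header(res$wells, file.path(config$out_dir, "wells.csv"))
  write_with_header(res$qc, file.path(config$out_dir, "qc_report.csv"))
  log_path <- file.path(config$out_dir, "pipeline.log")
  cfg <- unclass(config); cfg$compounds <- NULL
  writeLines(c(hdr, paste0("n_compounds=", nrow(config$compounds)),
               paste(utils::capture.output(utils::str(cfg)),
                     collapse = "\n")),
             log_path)
  invisible(NULL)
}

#' Ground-truth screen (no rendering)
#'
#' Runs the simulator without rendering pixels and builds the well-summary
#' table directly from the generator's per-cell ground truth. Used for
#' statistical calibration (toxicity-filter behaviour, z-prime against
#' analytic moments) where image segmentation is not the quantity under
#' study.
#'
#' @param config A [pipeline_config()].
#' @return A `screen_result` (see [run_pipeline()]); `cells` is `NULL`.
#' @export
run_truth_screen <- function(config) {
  layout <- config_layout(config)
  effects <- config_effects(config)
  ctl <- control_effects()
  n_cols <- attr(layout, "n_cols")
  todo <- layout[layout$role != "empty", , drop = FALSE]
  well_rows <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    plate_seed <- derive_seed(config$seed, rep_i, stream = 7L)
    for (i in seq_len(nrow(todo))) {
      e <- switch(todo$role[i],
                  negative_control = ctl$negative,
                  positive_control = ctl$positive,
                  compound = effects[[todo$compound_id[i]]])
      widx <- (todo$row[i] - 1L) * n_cols + todo$col[i]
      sw <- simulate_well(todo[i, ], e, config$sim,
                          seed = derive_seed(plate_seed, widx),
                          render = FALSE)
      tc <- sw$truth$cells
      n <- nrow(tc)
      row <- data.frame(
        plate = rep_i, well = todo$well[i], role = todo$role[i],
        compound_id = if (todo$role[i] == "compound") todo$compound_id[i]
                      else if (todo$role[i] == "negative_control") "DMSO"
                      else "POSCTL",
        cell_count = n,
        mean_cell_lbpa_int = if (n > 0) mean(tc$lbpa_true) else NA_real_,
        mean_endo_lbpa_int = if (n > 0) mean(tc$lbpa_true) else NA_real_,
        mean_cell_chol_int = if (n > 0) mean(tc$chol_true) else NA_real_,
        mean_endosome_count = if (n > 0) mean(tc$endosome_count)
                              else NA_real_,
        stringsAsFactors = FALSE)
      well_rows[[length(well_rows) + 1]] <- row
    }
  }
  wells <- do.call(rbind, well_rows)
  screen_from_wells(wells, config)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result: %d wells, %d compounds, %d plates>\n",
              nrow(x$wells), nrow(x$compounds),
              length(unique(x$wells$plate))))
  tab <- table(x$compounds$hit_class[x$compounds$role == "compound"],
               useNA = "ifany")
  if (length(tab)) { cat("compound hit classes:\n"); print(tab) }
  invisible(x)
}
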