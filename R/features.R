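# Per-cell feature extraction: the 50-measurement feature vector
# (integrated/mean intensity per channel x mask, areas, counts, shape),
# per-endosome cross-channel intensities and positive-cell fractions.

FEATURE_CHANNELS <- c(nuclei = 1L, cyto = 2L, lbpa = 3L, chol = 4L)
FEATURE_MASKS <- c("cell", "nucleus", "ring", "endo")

#' The per-cell feature schema
#'
#' The fixed 50-column measurement vector extracted for every cell:
#' integrated and mean intensity for each of the 4 channels within each of
#' the 4 masks (whole cell, nucleus, perinuclear ring, endosomal; 32
#' features), mask areas in px and um^2 (8), endosome count and per-cell
#' endosome summaries (mean spot area, mean spot LBPA integrated
#' intensity, perinuclear spot count and fraction), nucleus/cell
#' eccentricity and equivalent diameter, and the perinuclear fraction of
#' total cellular LBPA.
#'
#' @return data.frame with columns `name` and `description` (50 rows).
#' @export
feature_schema <- function() {
  rows <- list()
  for (m in FEATURE_MASKS) for (ch in names(FEATURE_CHANNELS)) {
    rows[[length(rows) + 1]] <- c(
      sprintf("%s_%s_int", m, ch),
      sprintf("integrated %s intensity in %s mask (a.u.)", ch, m))
    rows[[length(rows) + 1]] <- c(
      sprintf("%s_%s_mean", m, ch),
      sprintf("mean %s intensity in %s mask (a.u.)", ch, m))
  }
  for (m in FEATURE_MASKS)
    rows[[length(rows) + 1]] <- c(sprintf("%s_area_px", m),
                                  sprintf("%s mask area (px)", m))
  for (m in FEATURE_MASKS)
    rows[[length(rows) + 1]] <- c(sprintf("%s_area_um2", m),
                                  sprintf("%s mask area (um^2)", m))
  extra <- list(
    c("endosome_count", "number of LBPA-positive spots in the cell"),
    c("endo_mean_spot_area_px", "mean spot area (px), 0 if no spots"),
    c("endo_mean_spot_lbpa_int", "mean spot LBPA integrated intensity"),
    c("endo_perinuclear_count", "spots whose centroid lies in the ring"),
    c("endo_perinuclear_frac", "fraction of spots in the ring"),
    c("nucleus_eccentricity", "nucleus eccentricity (0 = circle)"),
    c("cell_eccentricity", "cell eccentricity (0 = circle)"),
    c("nucleus_equiv_diameter_um", "diameter of equal-area circle (um)"),
    c("cell_equiv_diameter_um", "diameter of equal-area circle (um)"),
    c("ring_lbpa_frac", "perinuclear share of whole-cell LBPA intensity"))
  rows <- c(rows, extra)
  out <- data.frame(name = vapply(rows, `[`, "", 1),
                    description = vapply(rows, `[`, "", 2))
  stopifnot(nrow(out) == 50L)
  out
}

# Sum of img over each label 1..n of L (0 where a label has no pixels).
masked_sums <- function(L, img, n) {
  out <- numeric(n)
  idx <- which(L > 0)
  if (length(idx) == 0 || n == 0) return(out)
  s <- rowsum(img[idx], L[idx])
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

label_areas <- function(L, n) tabulate(L[L > 0], nbins = n)

# Eccentricity sqrt(1 - l2/l1) from second central moments of each label.
label_eccentricity <- function(L, n) {
  out <- numeric(n)
  idx <- which(L > 0)
  if (length(idx) == 0 || n == 0) return(out)
  lv <- L[idx]
  r <- ((idx - 1) %% nrow(L)) + 1
  c_ <- ((idx - 1) %/% nrow(L)) + 1
  a <- label_areas(L, n)
  acc <- function(v) { s <- rowsum(v, lv); o <- numeric(n)
    o[as.integer(rownames(s))] <- s[, 1]; o }
  sr <- acc(r); sc <- acc(c_)
  srr <- acc(r * r); scc <- acc(c_ * c_); src <- acc(r * c_)
  ok <- a > 0
  mr <- sr / pmax(a, 1); mc <- sc / pmax(a, 1)
  mu20 <- srr / pmax(a, 1) - mr^2
  mu02 <- scc / pmax(a, 1) - mc^2
  mu11 <- src / pmax(a, 1) - mr * mc
  tr <- mu20 + mu02
  det <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + det) / 2; l2 <- (tr - det) / 2
  e <- sqrt(pmax(1 - l2 / pmax(l1, .Machine$double.eps), 0))
  out[ok] <- e[ok]
  out
}

#' Measure the per-cell feature vector
#'
#' Computes the 50 features of [feature_schema()] for every non-border
#' cell of one field. Cells with no endosomes (or an empty ring) get zero
#' intensities, never missing values.
#'
#' @param masks List with elements `nuclei`, `cells`, `endosomes`, `ring`
#'   ([label_mask()] objects from the same field; cell, nucleus and ring
#'   labels share ids).
#' @param images `h x w x 4` array, channel order nuclei, cytoplasm, LBPA,
#'   cholesterol.
#' @param pixel_size Micrometres per pixel.
#' @param drop_border Exclude border-touching cells (default `TRUE`).
#' @return data.frame with columns `cell_id`, `border_flag`,
#'   `ring_empty_flag` and the 50 schema features.
#' @export
measure_cells <- function(masks, images, pixel_size, drop_border = TRUE) {
  abort_if(!all(c("nuclei", "cells", "endosomes", "ring") %in% names(masks)),
           "'masks' needs elements nuclei, cells, endosomes, ring")
  abort_if(length(dim(images)) != 3L || dim(images)[3] != 4L,
           "'images' must be an h x w x 4 array")
  dm <- dim(masks$cells$labels)
  for (nm in c("nuclei", "endosomes", "ring"))
    abort_if(!all(dim(masks[[nm]]$labels) == dm),
             "mask shapes are inconsistent: ", nm)
  abort_if(!all(dim(images)[1:2] == dm), "image and mask shapes differ")
  check_scalar_number(pixel_size, "pixel_size", lower = 1e-9)

  n <- n_objects(masks$cells)
  schema <- feature_schema()$name
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(schema) + 3))
    names(out) <- c("cell_id", "border_flag", "ring_empty_flag", schema)
    return(out)
  }
  Lm <- list(cell = masks$cells$labels, nucleus = masks$nuclei$labels,
             ring = masks$ring$labels)
  # endosomal mask per cell: spot labels mapped to their parent cell
  endo_lab <- masks$endosomes$labels
  parent <- masks$endosomes$parent
  Lendo <- matrix(0L, dm[1], dm[2])
  if (length(parent) > 0) {
    idx <- which(endo_lab > 0)
    Lendo[idx] <- parent[endo_lab[idx]]
  }
  Lm$endo <- Lendo

  feats <- list()
  areas_px <- list()
  for (m in FEATURE_MASKS) {
    a <- label_areas(Lm[[m]], n)
    areas_px[[m]] <- a
    for (ch in names(FEATURE_CHANNELS)) {
      s <- masked_sums(Lm[[m]], images[, , FEATURE_CHANNELS[[ch]]], n)
      feats[[sprintf("%s_%s_int", m, ch)]] <- s
      feats[[sprintf("%s_%s_mean", m, ch)]] <- ifelse(a > 0, s / a, 0)
    }
  }
  for (m in FEATURE_MASKS) feats[[sprintf("%s_area_px", m)]] <- areas_px[[m]]
  for (m in FEATURE_MASKS)
    feats[[sprintf("%s_area_um2", m)]] <- areas_px[[m]] * pixel_size^2

  # endosome summaries
  k <- numeric(n); spot_area <- numeric(n); spot_int <- numeric(n)
  k_peri <- numeric(n)
  if (length(parent) > 0) {
    n_spots <- length(parent)
    sa <- label_areas(endo_lab, n_spots)
    si <- masked_sums(endo_lab, images[, , FEATURE_CHANNELS[["lbpa"]]],
                      n_spots)
    # spot centroid in ring?
    idx <- which(endo_lab > 0)
    lv <- endo_lab[idx]
    r <- ((idx - 1) %% dm[1]) + 1
    c_ <- ((idx - 1) %/% dm[1]) + 1
    cy <- round(rowsum(r, lv)[, 1] / sa[sort(unique(lv))])
    cx <- round(rowsum(c_, lv)[, 1] / sa[sort(unique(lv))])
    in_ring <- masks$ring$labels[cbind(cy, cx)] > 0
    kk <- tabulate(parent, nbins = n)
    k <- kk
    spot_area <- ifelse(kk > 0, masked_sums(matrix(parent), sa,
                                            n)[seq_len(n)] / pmax(kk, 1), 0)
    spot_int <- ifelse(kk > 0, masked_sums(matrix(parent), si,
                                           n)[seq_len(n)] / pmax(kk, 1), 0)
    k_peri <- masked_sums(matrix(parent), as.numeric(in_ring), n)
  }
  feats$endosome_count <- k
  feats$endo_mean_spot_area_px <- spot_area
  feats$endo_mean_spot_lbpa_int <- spot_int
  feats$endo_perinuclear_count <- k_peri
  feats$endo_perinuclear_frac <- ifelse(k > 0, k_peri / pmax(k, 1), 0)
  feats$nucleus_eccentricity <- label_eccentricity(Lm$nucleus, n)
  feats$cell_eccentricity <- label_eccentricity(Lm$cell, n)
  feats$nucleus_equiv_diameter_um <-
    2 * sqrt(areas_px$nucleus * pixel_size^2 / pi)
  feats$cell_equiv_diameter_um <- 2 * sqrt(areas_px$cell * pixel_size^2 / pi)
  feats$ring_lbpa_frac <- ifelse(feats$cell_lbpa_int > 0,
                                 feats$ring_lbpa_int / feats$cell_lbpa_int, 0)

  border <- attr(masks$cells, "border_labels")
  out <- data.frame(cell_id = seq_len(n),
                    border_flag = seq_len(n) %in% border,
                    ring_empty_flag = areas_px$ring == 0)
  out <- cbind(out, as.data.frame(feats[schema]))
  if (drop_border) out <- out[!out$border_flag, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-endosome cross-channel intensities
#'
#' Applies the LBPA-derived spot mask to the cholesterol (filipin) channel
#' and reports, per endosome, its area, LBPA and filipin integrated
#' intensities, centroid and whether it lies in the perinuclear ring.
#'
#' @param endosomes An endosome [label_mask()].
#' @param cholesterol_img 2-D filipin intensity matrix (same field).
#' @param lbpa_img Optional LBPA channel for the spot's own intensity.
#' @param ring Optional perinuclear [label_mask()] for the in-ring flag.
#' @return data.frame with one row per endosome.
#' @export
endosome_cholesterol <- function(endosomes, cholesterol_img,
                                 lbpa_img = NULL, ring = NULL) {
  abort_if(!inherits(endosomes, "label_mask") ||
             endosomes$kind != "endosome",
           "'endosomes' must be an endosome label_mask")
  check_matrix2d(cholesterol_img, "cholesterol_img")
  abort_if(!all(dim(cholesterol_img) == dim(endosomes$labels)),
           "image and mask shapes differ")
  n <- length(endosomes$parent)
  if (n == 0)
    return(data.frame(cell_id = integer(0), endosome_id = integer(0),
                      area_px = numeric(0), lbpa_int = numeric(0),
                      chol_int = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0),
                      in_perinuclear_ring = logical(0)))
  L <- endosomes$labels
  a <- label_areas(L, n)
  chol <- masked_sums(L, cholesterol_img, n)
  lbpa <- if (is.null(lbpa_img)) rep(NA_real_, n)
          else masked_sums(L, lbpa_img, n)
  idx <- which(L > 0)
  lv <- L[idx]
  r <- ((idx - 1) %% nrow(L)) + 1
  c_ <- ((idx - 1) %/% nrow(L)) + 1
  cy <- rowsum(r, lv)[, 1] / a
  cx <- rowsum(c_, lv)[, 1] / a
  in_ring <- if (is.null(ring)) rep(NA, n)
             else ring$labels[cbind(round(cy), round(cx))] > 0
  data.frame(cell_id = endosomes$parent, endosome_id = seq_len(n),
             area_px = a, lbpa_int = lbpa, chol_int = chol,
             centroid_x = cx, centroid_y = cy,
             in_perinuclear_ring = in_ring)
}

#' Perinuclear LBPA intensity per cell
#'
#' LBPA integrated intensity within each cell's perinuclear annulus.
#' Cells whose annulus was clipped to zero pixels (e.g. nucleus at the
#' image border) get value 0 and `ring_empty = TRUE`.
#'
#' @param ring A perinuclear [label_mask()].
#' @param lbpa_img 2-D LBPA intensity matrix (same field).
#' @param n_cells Number of cells; defaults to the largest ring label.
#' @return data.frame with columns `cell_id`, `ring_lbpa_int`,
#'   `ring_area_px`, `ring_empty`.
#' @export
perinuclear_intensity <- function(ring, lbpa_img, n_cells = NULL) {
  abort_if(!inherits(ring, "label_mask") || ring$kind != "perinuclear",
           "'ring' must be a perinuclear label_mask")
  check_matrix2d(lbpa_img, "lbpa_img")
  abort_if(!all(dim(lbpa_img) == dim(ring$labels)),
           "image and mask shapes differ")
  n <- if (is.null(n_cells)) n_objects(ring) else n_cells
  a <- label_areas(ring$labels, n)
  data.frame(cell_id = seq_len(n),
             ring_lbpa_int = masked_sums(ring$labels, lbpa_img, n),
             ring_area_px = a, ring_empty = a == 0)
}

#' Fraction of positive cells
#'
#' Fraction of cells whose `feature` exceeds `threshold` (strictly),
#' e.g. the fraction of infected cells or of cells above a granule-count
#' cutoff.
#'
#' @param cells data.frame of per-cell records.
#' @param feature Feature column name.
#' @param threshold Finite numeric threshold.
#' @return Fraction in \[0, 1\].
#' @export
fraction_positive <- function(cells, feature, threshold) {
  abort_if(!is.data.frame(cells) || nrow(cells) == 0,
           "empty cell list: fraction undefined")
  abort_if(!feature %in% names(cells), "unknown feature: ", feature)
  check_scalar_number(threshold, "threshold")
  mean(cells[[feature]] > threshold)
}
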