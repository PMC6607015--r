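# Segmentation: nuclei, per-cell territories, top-hat spot detection for
# LBPA endosomes, perinuclear annulus masks. Morphological and watershed
# primitives come from EBImage.

#' Segmentation parameters
#'
#' @param nucleus_blur_sigma Gaussian smoothing sigma (px) before
#'   thresholding the nuclear channel.
#' @param nucleus_min_area_px Minimum nucleus area in px; smaller objects
#'   (noise, watershed neck fragments) are removed. The default suits
#'   0.5 um/px sampling; scale it with the pixel area for other
#'   resolutions.
#' @param watershed_tolerance,watershed_ext Tolerance and neighbourhood
#'   radius of the distance-transform watershed used to split touching
#'   nuclei.
#' @param nucleus_split_tolerance Intensity-watershed tolerance (a.u.)
#'   used to split merged nuclei whose outline is too round for the
#'   distance-based split but whose smoothed intensity still shows two
#'   peaks. Must exceed smoothed-noise dips within one nucleus.
#' @param nucleus_erode_px Erosion radius applied to the thresholded
#'   nucleus mask to compensate the systematic dilation introduced by the
#'   Gaussian smoothing (roughly the smoothing sigma; default 2).
#' @param tophat_radius_px Disk radius of the white top-hat structuring
#'   element (must exceed the endosome radius; default 5 px, i.e. 2.5 um
#'   at 0.5 um/px).
#' @param spot_threshold_floor Absolute spot threshold on the top-hat
#'   image (a.u.); should sit well above the camera noise. Also acts as
#'   the lower bound when `spot_threshold_method = "otsu"`.
#' @param spot_threshold_method `"absolute"` (default; threshold =
#'   `spot_threshold_floor`) or `"otsu"` (Otsu on the in-cell top-hat,
#'   floored at `spot_threshold_floor`).
#' @param spot_min_area_px,spot_max_area_px Size filter for endosome spots.
#' @param spot_split_tolerance Intensity-watershed tolerance (a.u.) for
#'   splitting merged spots with distinct peaks; `0` disables declumping
#'   (plain connected components). Must exceed noise-induced dips on the
#'   top-hat image.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(nucleus_blur_sigma = 1.5,
                       nucleus_min_area_px = 150,
                       nucleus_split_tolerance = 50,
                       nucleus_erode_px = 2,
                       watershed_tolerance = 1,
                       watershed_ext = 1,
                       tophat_radius_px = 5,
                       spot_threshold_floor = 150,
                       spot_threshold_method = c("absolute", "otsu"),
                       spot_min_area_px = 2,
                       spot_max_area_px = 400,
                       spot_split_tolerance = 100) {
  spot_threshold_method <- match.arg(spot_threshold_method)
  check_scalar_number(nucleus_blur_sigma, "nucleus_blur_sigma", lower = 0)
  check_scalar_number(nucleus_min_area_px, "nucleus_min_area_px", lower = 0)
  check_scalar_number(tophat_radius_px, "tophat_radius_px", lower = 1)
  check_scalar_number(spot_threshold_floor, "spot_threshold_floor", lower = 0)
  structure(list(nucleus_blur_sigma = nucleus_blur_sigma,
                 nucleus_min_area_px = nucleus_min_area_px,
                 nucleus_split_tolerance = nucleus_split_tolerance,
                 nucleus_erode_px = nucleus_erode_px,
                 watershed_tolerance = watershed_tolerance,
                 watershed_ext = watershed_ext,
                 tophat_radius_px = tophat_radius_px,
                 spot_threshold_floor = spot_threshold_floor,
                 spot_threshold_method = spot_threshold_method,
                 spot_min_area_px = spot_min_area_px,
                 spot_max_area_px = spot_max_area_px,
                 spot_split_tolerance = spot_split_tolerance),
            class = "seg_params")
}

#' Label mask
#'
#' A labelled segmentation mask: an integer matrix with 0 background and
#' contiguous positive labels, plus its object kind and (for endosomes) a
#' parent mapping.
#'
#' @param labels Integer matrix of labels.
#' @param kind One of `"nucleus"`, `"cell"`, `"endosome"`, `"perinuclear"`.
#' @param parent Optional integer vector mapping each label to its parent
#'   object id (e.g. endosome to cell).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, kind, parent = NULL) {
  check_matrix2d(labels, "labels")
  abort_if(!kind %in% c("nucleus", "cell", "endosome", "perinuclear"),
           "unknown mask kind: ", kind)
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  abort_if(any(labels < 0), "labels must be non-negative")
  structure(list(labels = labels, kind = kind, parent = parent),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask kind=%s objects=%d dim=%dx%d>\n", x$kind,
              max(x$labels), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

n_objects <- function(mask) max(mask$labels)

# Otsu threshold on an arbitrary-range image (EBImage::otsu expects the
# range to be supplied); returns NA on a constant image.
otsu_threshold <- function(img) {
  rg <- range(img)
  if (diff(rg) <= 0) return(NA_real_)
  EBImage::otsu(EBImage::Image(img), range = rg, levels = 256L)
}

# Foreground threshold via Otsu on the log intensities. Cell-to-cell
# brightness varies multiplicatively over several fold, which makes plain
# Otsu overshoot (dim cells land below the split); on the log scale the
# background and stained classes are both compact and the split is stable
# across densities. Returns a threshold on the original intensity scale.
log_otsu_threshold <- function(img) {
  rg <- range(img)
  if (diff(rg) <= 0) return(NA_real_)
  lg <- log1p(img - rg[1])
  th <- EBImage::otsu(EBImage::Image(lg), range = range(lg), levels = 256L)
  expm1(th) + rg[1]
}

# Relabel to contiguous 1..n and return the matrix.
relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- match(lab, u, nomatch = 0L)
  matrix(as.integer(out), nrow(lab), ncol(lab))
}

#' Segment nuclei
#'
#' Standard high-content recipe: Gaussian smoothing, Otsu threshold, hole
#' filling, distance-transform watershed to split touching nuclei, and a
#' minimum-area filter.
#'
#' @param nuclei_img 2-D intensity matrix (nuclear stain channel).
#' @param params A [seg_params()].
#' @return A [label_mask()] of kind `"nucleus"`.
#' @export
segment_nuclei <- function(nuclei_img, params = seg_params()) {
  check_matrix2d(nuclei_img, "nuclei_img")
  img <- EBImage::Image(nuclei_img)
  if (params$nucleus_blur_sigma > 0)
    img <- EBImage::gblur(img, sigma = params$nucleus_blur_sigma)
  th <- log_otsu_threshold(imageData(img))
  if (is.na(th))  # constant image: nothing to segment
    return(label_mask(matrix(0L, nrow(nuclei_img), ncol(nuclei_img)),
                      "nucleus"))
  mask <- EBImage::fillHull(img > th)
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = params$watershed_ext)
  lab <- imageData(lab)
  # second declumping route: touching nuclei whose fused outline is too
  # round for the shape-based split can still show two smoothed-intensity
  # peaks; refine the labels by the intensity watershed (the final
  # partition is the intersection of the two)
  if (params$nucleus_split_tolerance > 0) {
    masked <- imageData(img)
    masked[!mask] <- 0
    lab_i <- imageData(EBImage::watershed(
      EBImage::Image(masked), tolerance = params$nucleus_split_tolerance,
      ext = params$watershed_ext))
    lab <- relabel(lab + (max(lab) + 1L) * lab_i)
    lab[!mask] <- 0L
  }
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < params$nucleus_min_area_px)
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  if (params$nucleus_erode_px > 0) {
    # shrink back the halo added by the pre-threshold smoothing
    keep <- EBImage::erode(lab > 0,
                           EBImage::makeBrush(
                             2L * as.integer(params$nucleus_erode_px) + 1L,
                             "disc"))
    lab[!keep] <- 0L
  }
  label_mask(relabel(lab), "nucleus")
}

#' Assign per-cell territories
#'
#' Propagates the nucleus seeds through the cytoplasm foreground (seeded
#' watershed on the cytoplasm intensity, as in the two-channel
#' nuclei-plus-cytoplasm segmentation of HCS pipelines). Every nucleus
#' seeds exactly one cell territory; territories partition the cytoplasm
#' foreground. Cells touching the image border are flagged.
#'
#' @param nuclei A nucleus [label_mask()].
#' @param cytoplasm_img 2-D intensity matrix (cytoplasm channel).
#' @param params A [seg_params()].
#' @return A [label_mask()] of kind `"cell"` with attribute
#'   `border_labels` (integer vector of border-touching cell labels).
#' @export
assign_cells <- function(nuclei, cytoplasm_img, params = seg_params()) {
  abort_if(!inherits(nuclei, "label_mask") || nuclei$kind != "nucleus",
           "'nuclei' must be a nucleus label_mask")
  check_matrix2d(cytoplasm_img, "cytoplasm_img")
  abort_if(!all(dim(cytoplasm_img) == dim(nuclei$labels)),
           "cytoplasm image and nuclei mask shapes differ")
  th <- log_otsu_threshold(cytoplasm_img)
  fg <- if (is.na(th))
    matrix(TRUE, nrow(cytoplasm_img), ncol(cytoplasm_img))
  else cytoplasm_img > th
  fg <- fg | nuclei$labels > 0   # territories must contain their seed
  lab <- EBImage::propagate(EBImage::Image(cytoplasm_img),
                            seeds = nuclei$labels, mask = fg)
  lab <- relabel(imageData(lab))
  border <- sort(unique(c(lab[1, ], lab[nrow(lab), ],
                          lab[, 1], lab[, ncol(lab)])))
  out <- label_mask(lab, "cell")
  attr(out, "border_labels") <- border[border > 0]
  out
}

#' White top-hat enhancement
#'
#' Image minus its morphological opening by a disk, suppressing smooth
#' background and keeping bright granules smaller than the structuring
#' element. Output is non-negative and exactly zero on flat regions.
#'
#' @param img 2-D intensity matrix.
#' @param radius_px Disk radius of the structuring element (>= 1, smaller
#'   than the image).
#' @return Matrix of the same shape.
#' @export
tophat_enhance <- function(img, radius_px) {
  check_matrix2d(img, "img")
  check_scalar_number(radius_px, "radius_px", lower = 1)
  abort_if(2 * radius_px + 1 > min(dim(img)),
           "'radius_px' larger than the image")
  kern <- EBImage::makeBrush(2 * as.integer(radius_px) + 1L, shape = "disc")
  # EBImage grayscale morphology clips at 1; scale into [0, 1] and back
  top <- max(img)
  if (top <= 0) return(matrix(0, nrow(img), ncol(img)))
  out <- EBImage::whiteTopHat(EBImage::Image(img / top), kern) * top
  out <- imageData(out)
  out[out < 0] <- 0
  out
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally (union-find over diagonal adjacencies).
label_components8 <- function(mask) {
  lab <- imageData(EBImage::bwlabel(mask))
  n <- max(lab)
  if (n == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal pairs
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal pairs
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  lab[lab > 0] <- root[lab[lab > 0]]
  relabel(lab)
}

#' Detect LBPA endosome spots
#'
#' Thresholds the white top-hat of the LBPA channel (Otsu restricted to
#' the cell foreground, with an absolute floor), labels 8-connected
#' components, filters them by size, and assigns each spot to the cell
#' containing its centroid. Spots outside any cell are discarded. Two
#' spots merging below the resolution limit count as one component.
#'
#' @param lbpa_img 2-D intensity matrix (LBPA channel).
#' @param cells A cell [label_mask()] from the same field.
#' @param params A [seg_params()].
#' @return A [label_mask()] of kind `"endosome"` whose `parent` element
#'   maps each spot label to its cell label.
#' @export
detect_endosomes <- function(lbpa_img, cells, params = seg_params()) {
  check_matrix2d(lbpa_img, "lbpa_img")
  abort_if(!inherits(cells, "label_mask") || cells$kind != "cell",
           "'cells' must be a cell label_mask")
  abort_if(!all(dim(lbpa_img) == dim(cells$labels)),
           "image and cell mask shapes differ")
  th_img <- tophat_enhance(lbpa_img, params$tophat_radius_px)
  inside <- cells$labels > 0
  empty <- label_mask(matrix(0L, nrow(lbpa_img), ncol(lbpa_img)),
                      "endosome", parent = integer(0))
  if (!any(inside)) return(empty)
  thr <- if (params$spot_threshold_method == "otsu")
    max(params$spot_threshold_floor,
        otsu_threshold(matrix(th_img[inside], ncol = 1)), na.rm = TRUE)
  else params$spot_threshold_floor
  mask <- th_img > thr
  if (!any(mask)) return(empty)
  if (params$spot_split_tolerance > 0) {
    # intensity watershed on the masked top-hat: labels connected spots
    # and splits merged ones with distinct peaks (granule declumping)
    th_masked <- th_img
    th_masked[!mask] <- 0
    lab <- imageData(EBImage::watershed(EBImage::Image(th_masked),
                                        tolerance =
                                          params$spot_split_tolerance,
                                        ext = 1))
    lab <- relabel(lab)
  } else {
    lab <- label_components8(mask)
  }
  n <- max(lab)
  idx <- which(lab > 0)
  lv <- lab[idx]
  areas <- tabulate(lv, nbins = n)
  rows <- ((idx - 1) %% nrow(lab)) + 1
  cols <- ((idx - 1) %/% nrow(lab)) + 1
  cy <- round(rowsum(rows, lv)[, 1] / areas)
  cx <- round(rowsum(cols, lv)[, 1] / areas)
  parent_cell <- cells$labels[cbind(cy, cx)]
  keep <- which(areas >= params$spot_min_area_px &
                  areas <= params$spot_max_area_px & parent_cell > 0)
  if (length(keep) == 0) return(empty)
  new_id <- integer(n)
  new_id[keep] <- seq_along(keep)
  lab[idx] <- new_id[lv]
  label_mask(lab, "endosome", parent = as.integer(parent_cell[keep]))
}

#' Perinuclear annulus mask
#'
#' For each nucleus, the region within `width_um` of the nucleus but
#' outside it (the nucleus dilated by `width_um / pixel_size` pixels minus
#' all nucleus pixels). Overlapping annuli between neighbouring nuclei are
#' split by nearest-nucleus assignment. Ring labels match nucleus labels.
#'
#' @param nuclei A nucleus [label_mask()].
#' @param width_um Radial annulus width in micrometres (default 4).
#' @param pixel_size Micrometres per pixel (> 0).
#' @return A [label_mask()] of kind `"perinuclear"`.
#' @export
perinuclear_ring <- function(nuclei, width_um = 4, pixel_size) {
  abort_if(!inherits(nuclei, "label_mask") || nuclei$kind != "nucleus",
           "'nuclei' must be a nucleus label_mask")
  check_scalar_number(width_um, "width_um", lower = 1e-9)
  abort_if(!is.numeric(pixel_size) || length(pixel_size) != 1 ||
             !is.finite(pixel_size) || pixel_size <= 0,
           "'pixel_size' must be > 0")
  lab <- nuclei$labels
  if (max(lab) == 0) return(label_mask(lab * 0L, "perinuclear"))
  width_px <- width_um / pixel_size
  fg <- lab > 0
  dm <- imageData(EBImage::distmap(1 - fg))
  # 0.25 px compensates for distances being measured to foreground pixel
  # centres while the object boundary lies ~a quarter pixel further out
  ring_region <- dm > 0 & dm <= width_px + 0.25
  if (!any(ring_region)) return(label_mask(lab * 0L, "perinuclear"))
  # nearest-nucleus assignment of ring pixels (geodesic propagation on a
  # constant image reduces to distance to the seeds)
  flat <- EBImage::Image(matrix(0, nrow(lab), ncol(lab)))
  ringlab <- EBImage::propagate(flat, seeds = lab, mask = ring_region | fg)
  ringlab <- imageData(ringlab)
  ringlab[!ring_region] <- 0L
  label_mask(ringlab, "perinuclear")
}
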