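# On-disk formats: multi-page 16-bit TIFF per field (one page per
# channel) with a JSON sidecar recording channel order and pixel size;
# label masks as 16-bit TIFF.

#' Write a well image set to disk
#'
#' One multi-page TIFF per field (pages in the fixed channel order
#' nuclei, cytoplasm, LBPA, cholesterol; 16-bit), plus a sidecar JSON with
#' channel roles, pixel size and the intensity scale.
#'
#' @param ws A [well_image_set()].
#' @param dir Output directory (created if needed).
#' @param max_intensity Intensity ceiling used to scale to 16-bit
#'   (default 4095, the simulator's 12-bit scale).
#' @return Paths of the written TIFF files, invisibly.
#' @export
write_well_images <- function(ws, dir, max_intensity = 4095) {
  abort_if(!inherits(ws, "well_image_set"), "'ws' must be a well_image_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ws$fields))
  for (f in seq_along(ws$fields)) {
    pages <- lapply(1:4, function(j)
      pmin(pmax(ws$fields[[f]][, , j] / max_intensity, 0), 1))
    paths[f] <- file.path(dir, sprintf("%s_f%02d.tiff", ws$well_id, f))
    tiff::writeTIFF(pages, paths[f], bits.per.sample = 16L)
  }
  sidecar <- list(well_id = ws$well_id, channel_roles = ws$channel_roles,
                  pixel_size_um = ws$pixel_size,
                  max_intensity = max_intensity,
                  n_fields = length(ws$fields))
  jsonlite::write_json(sidecar,
                       file.path(dir, sprintf("%s.json", ws$well_id)),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a well image set from disk
#'
#' Counterpart of [write_well_images()]; restores intensities to the
#' original scale recorded in the sidecar.
#'
#' @param dir Directory containing the TIFFs and sidecar.
#' @param well_id Well identifier.
#' @return A [well_image_set()].
#' @export
read_well_images <- function(dir, well_id) {
  sc_path <- file.path(dir, sprintf("%s.json", well_id))
  abort_if(!file.exists(sc_path), "sidecar not found: ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  fields <- vector("list", sc$n_fields)
  for (f in seq_len(sc$n_fields)) {
    pages <- tiff::readTIFF(file.path(dir,
                                      sprintf("%s_f%02d.tiff", well_id, f)),
                            all = TRUE)
    img <- array(0, dim = c(dim(pages[[1]]), 4))
    for (j in 1:4) img[, , j] <- pages[[j]] * sc$max_intensity
    fields[[f]] <- img
  }
  well_image_set(fields, pixel_size = sc$pixel_size_um, well_id = well_id)
}

#' Write a label mask as 16-bit TIFF
#'
#' @param mask A [label_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  abort_if(!inherits(mask, "label_mask"), "'mask' must be a label_mask")
  abort_if(max(mask$labels) > 65535, "too many labels for 16-bit storage")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_label_mask()]
#'
#' @param path TIFF path.
#' @param kind Mask kind.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, kind) {
  lab <- round(tiff::readTIFF(path) * 65535)
  label_mask(lab, kind)
}
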