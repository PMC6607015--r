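#!/usr/bin/env Rscript
# Read the example plate back from disk, run the segmentation chain on
# every well and extract the 50-feature per-cell table. Also writes the
# label masks of one well for visual inspection.

suppressMessages(library(lbpascreen))

plate_dir <- "results/example_plate"
stopifnot(file.exists(file.path(plate_dir, "plate_map.csv")))
layout <- read_plate_map(file.path(plate_dir, "plate_map.csv"),
                         n_rows = 4, n_cols = 6)

seg <- seg_params(nucleus_min_area_px = 40)  # 1 um/px sampling
cell_tabs <- list()
for (w in layout$well[layout$role != "empty"]) {
  ws <- read_well_images(file.path(plate_dir, "images"), w)
  an <- analyze_well(ws, seg)
  if (!is.null(an$cells) && nrow(an$cells) > 0)
    cell_tabs[[w]] <- cbind(well = w, an$cells)
}
cells <- do.call(rbind, cell_tabs)
write.csv(cells, file.path(plate_dir, "cells.csv"), row.names = FALSE)

# masks of the first analysed well, for inspection
w1 <- names(cell_tabs)[1]
ws <- read_well_images(file.path(plate_dir, "images"), w1)
img <- ws$fields[[1]]
nuc <- segment_nuclei(img[, , 1], seg)
cls <- assign_cells(nuc, img[, , 2], seg)
endo <- detect_endosomes(img[, , 3], cls, seg)
ring <- perinuclear_ring(nuc, 4, ws$pixel_size)
dir.create(file.path(plate_dir, "masks"), showWarnings = FALSE)
for (m in list(nuc, cls, endo, ring))
  write_label_mask(m, file.path(plate_dir, "masks",
                                sprintf("%s_%s.tiff", w1, m$kind)))

# ground-truth comparison
truth <- read.csv(file.path(plate_dir, "ground_truth_cells.csv"))
message(sprintf("measured %d cells in %d wells (ground truth %d cells)",
                nrow(cells), length(cell_tabs), nrow(truth)))
message(sprintf("mean endosome count: measured %.2f vs true %.2f",
                mean(cells$endosome_count), mean(truth$endosome_count)))
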