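#!/usr/bin/env Rscript
# Simulate a small demonstration plate and write its raw artifacts:
# per-field multi-page TIFFs with JSON sidecars, the plate map, and the
# generator's ground-truth tables. Uses a 6-compound mini-layout so the
# output stays small; the full-screen analysis lives in 03_screen.R.

suppressMessages(library(lbpascreen))

out <- "results/example_plate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

compounds <- rbind(
  data.frame(compound_id = "THIO-like", lbpa_factor = 2.5,
             chol_factor = 1.0, endosome_count_factor = 1,
             perinuclear_factor = 0.3, toxicity_fraction = 0),
  data.frame(compound_id = paste0("C", 1:5), lbpa_factor = 1,
             chol_factor = 1, endosome_count_factor = 1,
             perinuclear_factor = 0.3, toxicity_fraction = 0))
effects <- lapply(seq_len(nrow(compounds)), function(i)
  compound_effect(compounds$lbpa_factor[i], compounds$chol_factor[i],
                  compounds$endosome_count_factor[i],
                  compounds$perinuclear_factor[i],
                  compounds$toxicity_fraction[i]))
names(effects) <- compounds$compound_id

layout <- default_plate_layout(compounds$compound_id, n_rows = 4,
                               n_cols = 6, neg_col = 2, pos_col = 5)
write_plate_map(layout, file.path(out, "plate_map.csv"))

params <- sim_params(image_size = c(256L, 256L), pixel_size = 1.0,
                     fields_per_well = 2L, cells_per_field = 60)
plate <- simulate_plate(layout, effects, params, seed = 42)

truth_rows <- list()
for (w in names(plate$wells)) {
  pw <- plate$wells[[w]]
  write_well_images(pw$images, file.path(out, "images"))
  tc <- pw$truth$cells
  if (nrow(tc) > 0)
    truth_rows[[w]] <- cbind(well = w, tc)
}
truth <- do.call(rbind, truth_rows)
write.csv(truth, file.path(out, "ground_truth_cells.csv"),
          row.names = FALSE)

message(sprintf("simulated %d wells; %d cells total; mean true LBPA %.0f a.u.",
                length(plate$wells), nrow(truth), mean(truth$lbpa_true)))
message("raw images under ", file.path(out, "images"))
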