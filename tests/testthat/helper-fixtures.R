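# Shared fixtures: small, fast simulator settings and hand-built masks.

# Reduced-scale acquisition: same 256 um field of view as the default
# parameters, sampled at 1 um/px instead of 0.5.
reduced_sim <- function(...) {
  sim_params(image_size = c(256L, 256L), pixel_size = 1.0, ...)
}

reduced_seg <- function(...) {
  seg_params(nucleus_min_area_px = 40, ...)
}

# A tiny plate for smoke tests: 2 columns of controls + a few compounds.
tiny_config <- function(compounds, seed = 11, n_replicates = 1L,
                        fields = 1L, cells = 30, ...) {
  pipeline_config(
    seed = seed, n_replicates = n_replicates, compounds = compounds,
    sim = list(image_size = c(128L, 128L), pixel_size = 1.0,
               fields_per_well = fields, cells_per_field = cells),
    seg = list(nucleus_min_area_px = 40),
    min_cells = 10, ...)
}

inert_compounds <- function(n, prefix = "C") {
  data.frame(compound_id = paste0(prefix, seq_len(n)),
             lbpa_factor = 1, chol_factor = 1, endosome_count_factor = 1,
             perinuclear_factor = 0.3, toxicity_fraction = 0)
}

# Two touching blurred nuclei with distinct peaks.
two_nuclei_image <- function() {
  img <- matrix(100, 64, 64)
  d1 <- sqrt(outer((1:64 - 28)^2, (1:64 - 32)^2, "+"))
  d2 <- sqrt(outer((1:64 - 42)^2, (1:64 - 32)^2, "+"))
  img <- img + 1200 * exp(-d1^2 / (2 * 6^2)) + 1200 * exp(-d2^2 / (2 * 6^2))
  img
}

# Random label matrix + image for brute-force masked-sum oracles.
random_labels_fixture <- function(seed = 4, n_labels = 5, size = 64) {
  set.seed(seed)
  L <- matrix(sample(0:n_labels, size * size, replace = TRUE), size, size)
  V <- matrix(runif(size * size, 0, 1000), size, size)
  list(labels = L, img = V)
}
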