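#!/usr/bin/env Rscript
# Downstream tabular arithmetic on a synthetic lipidomics table and a
# synthetic RT-PCR plate: mol% of total phospholipid, acyl-chain species
# grouping, LBPA/cholesterol ratios, and comparative-CT fold changes.
# Input tables are generated here (synthetic), mirroring the shapes such
# data takes after instrument processing.

suppressMessages(library(lbpascreen))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
set.seed(60)

# synthetic lipid class/species table for two conditions
species <- c("36:2", "36:3", "36:4", "38:4", "38:5", "40:6", "e38:2",
             "p40:4")
lip <- rbind(
  data.frame(sample_id = "control", lipid_class = "LBPA",
             species = species, amount = runif(8, 0.05, 0.3)),  # ~1% of PL
  data.frame(sample_id = "control", lipid_class = "PC",
             species = species, amount = runif(8, 5, 20)),
  data.frame(sample_id = "disease", lipid_class = "LBPA",
             species = species, amount = runif(8, 0.5, 3)),     # ~10x up
  data.frame(sample_id = "disease", lipid_class = "PC",
             species = species, amount = runif(8, 5, 20)))
write.csv(lip, "results/tables/lipid_species.csv", row.names = FALSE)

mp <- do.call(rbind, lapply(split(lip, lip$sample_id), function(d)
  cbind(sample_id = d$sample_id[1], mol_percent(d))))
write.csv(mp, "results/tables/mol_percent.csv", row.names = FALSE)
message("mol% per class (sums to 100 within each sample):")
print(mp, row.names = FALSE)

gr <- do.call(rbind, lapply(split(lip, lip$sample_id), function(d)
  cbind(sample_id = d$sample_id[1], group_species(d, "chain_length"))))
write.csv(gr, "results/tables/species_by_chain_length.csv",
          row.names = FALSE)

# LBPA / cholesterol ratio, normalized to the control group
lbpa <- tapply(lip$amount[lip$lipid_class == "LBPA"],
               lip$sample_id[lip$lipid_class == "LBPA"], sum)
chol <- c(control = 12, disease = 240)   # synthetic cholesterol totals
rr <- ratio_feature(as.numeric(lbpa), as.numeric(chol),
                    group = names(lbpa), reference_group = "control")
message(sprintf("LBPA/cholesterol ratio (control-normalized): %s",
                paste(sprintf("%s=%.2f", names(lbpa), rr),
                      collapse = ", ")))

# synthetic comparative-CT table: a transcript induced ~4x in treated
ct <- data.frame(
  sample = paste0("s", 1:6),
  condition = rep(c("control", "treated"), each = 3),
  ct_target = c(24.1, 24.3, 23.9, 22.2, 22.0, 22.3),
  ct_ref = c(11.0, 11.2, 10.9, 11.1, 11.0, 11.2))
fc <- ddct_fold_change(ct)
write.csv(fc, "results/tables/ddct_fold_change.csv", row.names = FALSE)
message("fold changes (2^-ddCT):")
print(fc, row.names = FALSE)
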