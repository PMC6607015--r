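# Downstream tabular arithmetic: mol% of total phospholipid, acyl-chain
# species grouping, ratio features, and comparative-CT fold changes.

#' Parse lipid species labels
#'
#' Species labels use the dialect `"Cc:d"` — total acyl carbons, a colon,
#' number of double bonds — with an optional ether prefix `"e"`
#' (1-O-alkyl) or `"p"` (1-O-alkenyl), e.g. `"36:2"`, `"e38:4"`.
#'
#' @param labels Character vector of species labels.
#' @return data.frame with columns `label`, `prefix` (`""`, `"e"` or
#'   `"p"`), `carbons`, `double_bonds`.
#' @export
parse_species <- function(labels) {
  m <- regmatches(labels, regexec("^([ep]?)([0-9]+):([0-9]+)$", labels))
  bad <- vapply(m, length, 1L) == 0
  abort_if(any(bad), "unparseable species label in row(s): ",
           paste(which(bad), collapse = ", "),
           " (", paste(labels[bad], collapse = ", "), ")")
  carbons <- as.integer(vapply(m, `[`, "", 3))
  abort_if(any(carbons <= 0), "species carbons must be > 0")
  data.frame(label = labels,
             prefix = vapply(m, `[`, "", 2),
             carbons = carbons,
             double_bonds = as.integer(vapply(m, `[`, "", 4)))
}

#' Mol percent of total phospholipid
#'
#' Expresses each lipid class as a percentage of the summed phospholipid
#' amount: `100 * class_amount / total`. The amount scale is arbitrary
#' (phosphate-normalized upstream); percentages over classes sum to 100.
#'
#' @param table data.frame with columns `lipid_class` and `amount`
#'   (>= 0); multiple rows per class (species) are summed.
#' @return data.frame with columns `lipid_class`, `amount`, `mol_percent`.
#' @export
mol_percent <- function(table) {
  abort_if(!all(c("lipid_class", "amount") %in% names(table)),
           "need columns lipid_class and amount")
  abort_if(any(!is.finite(table$amount)) || any(table$amount < 0),
           "amounts must be finite and >= 0")
  by_class <- rowsum(table$amount, table$lipid_class)
  total <- sum(by_class)
  abort_if(total <= 0, "all-zero table: mol percent undefined")
  data.frame(lipid_class = rownames(by_class),
             amount = by_class[, 1],
             mol_percent = 100 * by_class[, 1] / total,
             row.names = NULL)
}

#' Group lipid species by chain length or saturation
#'
#' Aggregates within-class species percentages by total acyl carbons
#' (`"chain_length"`) or by the number of double bonds
#' (`"double_bonds"`). Group totals conserve the class total exactly.
#'
#' @param table data.frame with columns `lipid_class`, `species`
#'   (labels in the `"Cc:d"` dialect, optional e/p prefix) and `amount`.
#' @param by `"chain_length"` or `"double_bonds"`.
#' @return data.frame with `lipid_class`, `group` (numeric key),
#'   `amount`, and `percent_of_class`.
#' @export
group_species <- function(table, by = c("chain_length", "double_bonds")) {
  by <- match.arg(by)
  abort_if(!all(c("lipid_class", "species", "amount") %in% names(table)),
           "need columns lipid_class, species, amount")
  sp <- parse_species(as.character(table$species))
  key <- if (by == "chain_length") sp$carbons else sp$double_bonds
  out_rows <- list()
  for (cl in unique(table$lipid_class)) {
    sel <- table$lipid_class == cl
    tot <- sum(table$amount[sel])
    g <- rowsum(table$amount[sel], key[sel])
    out_rows[[cl]] <- data.frame(
      lipid_class = cl, group = as.numeric(rownames(g)),
      amount = g[, 1],
      percent_of_class = if (tot > 0) 100 * g[, 1] / tot else 0,
      row.names = NULL)
  }
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  out
}

#' Ratio feature
#'
#' Plain quotient of two values, optionally normalized per group to a
#' designated reference group (ratio of ratios).
#'
#' @param numerator_value,denominator_value Numeric vectors (denominator
#'   > 0).
#' @param group Optional grouping vector (same length).
#' @param reference_group Group whose mean ratio serves as 1.0.
#' @return Numeric vector of ratios (reference-normalized if requested).
#' @export
ratio_feature <- function(numerator_value, denominator_value,
                          group = NULL, reference_group = NULL) {
  abort_if(any(!is.finite(denominator_value)) ||
             any(denominator_value <= 0),
           "denominator must be finite and > 0")
  r <- numerator_value / denominator_value
  if (!is.null(reference_group)) {
    abort_if(is.null(group), "need 'group' to normalize to a reference")
    ref <- mean(r[group == reference_group])
    abort_if(!is.finite(ref) || ref == 0, "invalid reference group mean")
    r <- r / ref
  }
  r
}

#' Comparative-CT fold change
#'
#' The delta-delta-CT method with an internal reference gene:
#' `dCT = CT_target - CT_ref` per sample, `ddCT = dCT - mean(dCT of
#' controls)`, and fold change `2^(-ddCT)` (amplification efficiency
#' fixed at 2 per cycle).
#'
#' @param ct data.frame with columns `sample`, `condition` (must include
#'   `"control"`), `ct_target`, `ct_ref`.
#' @return data.frame with `sample`, `condition`, `dct`, `ddct`,
#'   `fold_change`.
#' @export
ddct_fold_change <- function(ct) {
  need <- c("sample", "condition", "ct_target", "ct_ref")
  missing_cols <- setdiff(need, names(ct))
  abort_if(length(missing_cols) > 0, "missing reference/target column(s): ",
           paste(missing_cols, collapse = ", "))
  abort_if(any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_ref)),
           "CT values must be finite")
  abort_if(!any(ct$condition == "control"), "no control condition present")
  dct <- ct$ct_target - ct$ct_ref
  ddct <- dct - mean(dct[ct$condition == "control"])
  data.frame(sample = ct$sample, condition = ct$condition,
             dct = dct, ddct = ddct, fold_change = 2^(-ddct))
}
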