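# Plate layouts: well roles and compound annotations for a 384-well plate.

VALID_ROLES <- c("compound", "negative_control", "positive_control", "empty")

#' Construct a plate layout
#'
#' A plate layout assigns a role to each well of an `n_rows` x `n_cols`
#' plate and annotates compound wells with a compound id and concentration.
#'
#' @param wells data.frame with columns `well` (id, e.g. "A1"), `role`
#'   (one of `"compound"`, `"negative_control"`, `"positive_control"`,
#'   `"empty"`), `compound_id` (character, `NA` for non-compound wells)
#'   and `conc_um` (numeric, micromolar).
#' @param n_rows,n_cols Plate geometry; defaults are 384-well (16 x 24).
#' @return An object of class `plate_layout`: the validated `wells`
#'   data.frame plus geometry attributes and `row`/`col` columns.
#' @export
plate_layout <- function(wells, n_rows = 16L, n_cols = 24L) {
  abort_if(!is.data.frame(wells), "'wells' must be a data.frame")
  need <- c("well", "role", "compound_id", "conc_um")
  missing_cols <- setdiff(need, names(wells))
  abort_if(length(missing_cols) > 0,
           "layout is missing column(s): ", paste(missing_cols, collapse = ", "))
  wells$well <- normalize_well_id(as.character(wells$well))
  dup <- duplicated(wells$well)
  abort_if(any(dup), "duplicate well id(s) in layout: ",
           paste(unique(wells$well[dup]), collapse = ", "))
  bad_role <- !(wells$role %in% VALID_ROLES)
  abort_if(any(bad_role), "unknown role(s): ",
           paste(unique(wells$role[bad_role]), collapse = ", "))
  rc <- parse_well_id(wells$well)
  abort_if(any(rc$row > n_rows) || any(rc$col > n_cols),
           "well id outside plate geometry")
  wells$row <- rc$row
  wells$col <- rc$col
  need_cmp <- wells$role == "compound" &
    (is.na(wells$compound_id) | wells$compound_id == "")
  abort_if(any(need_cmp), "compound wells without compound_id: ",
           paste(wells$well[need_cmp], collapse = ", "))
  structure(wells[c("well", "role", "compound_id", "conc_um", "row", "col")],
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            class = c("plate_layout", "data.frame"))
}

#' Default 384-well screening layout
#'
#' Builds the standard screen geometry: all wells of one column are DMSO
#' negative controls, all wells of another column positive controls
#' (U18666A-like), and compounds fill the remaining wells column-major.
#' Wells left over after placing all compounds are marked `empty`.
#'
#' @param compound_ids Character vector of compound identifiers to place.
#' @param neg_col,pos_col Columns holding the negative (default 2) and
#'   positive (default 23) control wells.
#' @param conc_um Compound concentration in micromolar (default 10).
#' @param n_rows,n_cols Plate geometry (default 16 x 24).
#' @return A [plate_layout()].
#' @export
default_plate_layout <- function(compound_ids, neg_col = 2L, pos_col = 23L,
                                 conc_um = 10, n_rows = 16L, n_cols = 24L) {
  abort_if(neg_col == pos_col, "control columns must differ")
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  grid <- grid[order(grid$col, grid$row), ]
  role <- rep("empty", nrow(grid))
  role[grid$col == neg_col] <- "negative_control"
  role[grid$col == pos_col] <- "positive_control"
  free <- which(role == "empty")
  abort_if(length(compound_ids) > length(free),
           "more compounds than available wells")
  cmp <- rep(NA_character_, nrow(grid))
  slots <- free[seq_along(compound_ids)]
  role[slots] <- "compound"
  cmp[slots] <- compound_ids
  conc <- ifelse(role == "compound", conc_um, NA_real_)
  plate_layout(data.frame(well = well_id(grid$row, grid$col), role = role,
                          compound_id = cmp, conc_um = conc,
                          stringsAsFactors = FALSE),
               n_rows = n_rows, n_cols = n_cols)
}

#' Read a plate map from CSV
#'
#' Expects a header `well,role,compound_id,conc_um`. Malformed ids,
#' duplicate wells and unknown roles are rejected with the offending
#' row number.
#'
#' @param path CSV file path.
#' @param n_rows,n_cols Plate geometry.
#' @return A [plate_layout()].
#' @export
read_plate_map <- function(path, n_rows = 16L, n_cols = 24L) {
  abort_if(!file.exists(path), "plate map not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(well = "character",
                                       role = "character",
                                       compound_id = "character"))
  need <- c("well", "role", "compound_id", "conc_um")
  abort_if(!all(need %in% names(df)),
           "plate map must have header: ", paste(need, collapse = ","))
  # row-numbered diagnostics (header is line 1, data start at line 2)
  ok_id <- grepl("^[A-P](0?[1-9]|1[0-9]|2[0-4])$", df$well)
  abort_if(any(!ok_id), "malformed well id at row(s): ",
           paste(which(!ok_id) + 1L, collapse = ", "))
  ids <- normalize_well_id(df$well)
  dup <- duplicated(ids)
  abort_if(any(dup), "duplicate well at row(s): ",
           paste(which(dup) + 1L, collapse = ", "))
  bad_role <- !(df$role %in% VALID_ROLES)
  abort_if(any(bad_role), "unknown role at row(s): ",
           paste(which(bad_role) + 1L, collapse = ", "))
  df$well <- ids
  df$compound_id[!is.na(df$compound_id) & df$compound_id == ""] <-
    NA_character_
  plate_layout(df, n_rows = n_rows, n_cols = n_cols)
}

#' Write a plate map to CSV
#'
#' @param layout A [plate_layout()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(layout, path) {
  abort_if(!inherits(layout, "plate_layout"), "'layout' must be a plate_layout")
  utils::write.csv(layout[c("well", "role", "compound_id", "conc_um")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}
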