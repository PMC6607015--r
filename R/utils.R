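#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
#' @importFrom EBImage imageData
NULL

# internal validation helpers -------------------------------------------------

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_zero = TRUE) {
  abort_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
           sprintf("'%s' must be a single finite number", name))
  abort_if(x < lower || x > upper,
           sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  abort_if(!allow_zero && x == 0, sprintf("'%s' must be non-zero", name))
  invisible(x)
}

check_matrix2d <- function(x, name) {
  abort_if(!is.numeric(x) || length(dim(x)) != 2L,
           sprintf("'%s' must be a 2-D numeric matrix", name))
  invisible(x)
}

# Derive a deterministic 32-bit RNG seed from a master seed and an index.
# Order-independent: each (seed, index) pair maps to the same sub-seed no
# matter which wells or fields were simulated before it.
derive_seed <- function(master_seed, index, stream = 0L) {
  s <- (as.double(master_seed) %% 65521) * 32003 +
    as.double(index) * 101 + as.double(stream) * 16127
  as.integer(s %% 2147483647)
}

# Well-id dialect: row letter A..P + 1-based column number, e.g. "A1", "P24".
# Zero-padded columns ("B02") are accepted on input and normalized.

#' Convert row/column indices to well identifiers
#'
#' @param row,col 1-based row and column indices.
#' @return Character well ids in letter-number form (`"A1"` ... `"P24"`).
#' @examples
#' well_id(1, 1)
#' well_id(16, 24)
#' @export
well_id <- function(row, col) paste0(LETTERS[row], col)

#' Parse well identifiers into row/column indices
#'
#' @param id Character vector of well ids such as `"A1"` or `"B02"`.
#' @return A data.frame with columns `row` and `col` (1-based).
#' @export
parse_well_id <- function(id) {
  ok <- grepl("^[A-P](0?[1-9]|1[0-9]|2[0-4])$", id)
  abort_if(any(!ok), "malformed well id(s): ",
           paste(id[!ok], collapse = ", "))
  data.frame(row = match(substr(id, 1, 1), LETTERS),
             col = as.integer(substring(id, 2)))
}

normalize_well_id <- function(id) {
  p <- parse_well_id(id)
  well_id(p$row, p$col)
}
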