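#' Well identifiers on a 96-well plate
#'
#' A well id is the canonical string `"A01"` ... `"H12"`: row letter A-H,
#' zero-padded two-digit column 1-12. `parse_well()` and `format_well()` are
#' exact inverses over the 96 valid ids.
#'
#' @param x character vector of well ids such as `"A01"`.
#' @param row character vector of row letters (`"A"`-`"H"`).
#' @param col integer vector of columns (1-12).
#' @return `parse_well()` returns a data.frame with columns `row` (character)
#'   and `col` (integer); `format_well()` returns the canonical id strings;
#'   `all_wells()` returns the 96 ids in row-major order (A01, A02, ...).
#' @examples
#' parse_well("B07")
#' format_well("B", 7)
#' length(all_wells())
#' @export
parse_well <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[A-H](0[1-9]|1[0-2])$", x)
  if (!all(ok)) {
    stop("invalid well id(s): ", paste(unique(x[!ok]), collapse = ", "),
         " (expected A01-H12)")
  }
  data.frame(row = substr(x, 1, 1),
             col = as.integer(substr(x, 2, 3)),
             stringsAsFactors = FALSE)
}

#' @rdname parse_well
#' @export
format_well <- function(row, col) {
  row <- as.character(row)
  col <- as.integer(col)
  if (any(!row %in% LETTERS[1:8])) stop("row must be a letter A-H")
  if (any(is.na(col) | col < 1 | col > 12)) stop("column must be in 1-12")
  sprintf("%s%02d", row, col)
}

#' @rdname parse_well
#' @export
all_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, format_well)))
}

#' @rdname parse_well
#' @export
is_valid_well <- function(x) {
  grepl("^[A-H](0[1-9]|1[0-2])$", as.character(x))
}
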