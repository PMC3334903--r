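#' Well coordinates on an 8 x 12 microplate
#'
#' PM plates use the standard 96-well layout with rows A-H and columns 1-12.
#' Labels are canonically zero-padded ("A01"); the parser also accepts the
#' unpadded form ("A1").
#'
#' @param row Character vector of row letters ("A"-"H").
#' @param column Integer vector of column numbers (1-12).
#' @return `well_label()` returns canonical labels; `well_labels()` returns all
#'   96 labels in plate order (A01, A02, ..., H12); `parse_well()` returns a
#'   data frame with columns `row`, `column`, `label`.
#' @examples
#' well_label("B", 7)
#' parse_well(c("A1", "H12"))
#' @export
well_label <- function(row, column) {
  row <- toupper(as.character(row))
  column <- as.integer(column)
  if (any(!row %in% LETTERS[1:8]))
    stop("well row must be one of A-H", call. = FALSE)
  if (any(is.na(column) | column < 1L | column > 12L))
    stop("well column must be an integer in 1..12", call. = FALSE)
  sprintf("%s%02d", row, column)
}

#' @rdname well_label
#' @export
well_labels <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, function(r, c) sprintf("%s%02d", r, c))))
}

#' @rdname well_label
#' @param label Character vector of well labels such as "A01" or "A1".
#' @export
parse_well <- function(label) {
  label <- toupper(trimws(as.character(label)))
  m <- regmatches(label, regexec("^([A-H])0?([1-9][0-2]?)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("invalid well label(s): ", paste(label[bad], collapse = ", "),
         call. = FALSE)
  row <- vapply(m, `[`, "", 2L)
  column <- as.integer(vapply(m, `[`, "", 3L))
  if (any(column > 12L))
    stop("well column must be in 1..12", call. = FALSE)
  data.frame(row = row, column = column,
             label = well_label(row, column),
             stringsAsFactors = FALSE)
}
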