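#' Read taxon occurrences on equal-area grid cells
#'
#' Occurrence data link tree terminals to the equal-area spatial units
#' (typically square grid cells, each with weight 1) on which endemism is
#' measured.  Two layouts are supported: long form, with one row per
#' (terminal, cell) record, and matrix form, with one row per terminal
#' and one column per cell holding 0/1 or counts.  Any positive count is
#' treated as presence.  Cell identifiers are opaque strings; gridding
#' point records into equal-area cells happens upstream of this package.
#'
#' @param source path to a delimited text file (UTF-8, header row
#'   required), or a data frame already in the stated layout.
#' @param layout `"long"` (columns: terminal, cell) or `"matrix"`
#'   (first column: terminal label; remaining column names: cell ids).
#' @param delimiter field delimiter for file input; default `","`.
#' @return An object of class `occurrence_table`: a data frame with
#'   character columns `terminal` and `cell`, one row per unique record,
#'   with attribute `cell_ids` (sorted unique cells).
#' @export
read_occurrences <- function(source, layout = c("long", "matrix"),
                             delimiter = ",") {
  layout <- match.arg(layout)
  if (is.data.frame(source)) {
    df <- source
  } else {
    df <- tryCatch(
      read.delim(source, sep = delimiter, header = TRUE,
                 check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = if (layout == "long") "character" else NA),
      error = function(e) stop("failed to read occurrence file: ",
                               conditionMessage(e), call. = FALSE))
    if (nrow(df) == 0L) stop("occurrence file is empty", call. = FALSE)
  }
  if (layout == "long") {
    if (ncol(df) < 2L) stop("long layout needs two columns (terminal, cell)",
                            call. = FALSE)
    rec <- data.frame(terminal = as.character(df[[1L]]),
                      cell = as.character(df[[2L]]),
                      stringsAsFactors = FALSE)
    bad <- which(is.na(rec$terminal) | is.na(rec$cell) |
                   rec$terminal == "" | rec$cell == "")
    if (length(bad) > 0L) {
      stop("malformed occurrence rows (empty terminal or cell) at line(s) ",
           paste(head(bad + 1L, 10L), collapse = ", "), call. = FALSE)
    }
  } else {
    if (ncol(df) < 2L) stop("matrix layout needs a terminal column plus cells",
                            call. = FALSE)
    terms <- as.character(df[[1L]])
    cells <- colnames(df)[-1L]
    vals <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "numeric")
    if (anyNA(vals)) {
      stop("malformed matrix values at row(s) ",
           paste(head(which(rowSums(is.na(vals)) > 0) + 1L, 10L),
                 collapse = ", "), call. = FALSE)
    }
    hit <- which(vals > 0, arr.ind = TRUE)
    rec <- data.frame(terminal = terms[hit[, 1L]],
                      cell = cells[hit[, 2L]],
                      stringsAsFactors = FALSE)
  }
  occurrence_table(rec)
}

#' Construct an occurrence table from (terminal, cell) records
#'
#' @param records data frame with character columns `terminal` and `cell`
#'   (extra columns are dropped).  Duplicate records collapse to presence.
#' @return An `occurrence_table` (see [read_occurrences()]).
#' @export
occurrence_table <- function(records) {
  rec <- data.frame(terminal = as.character(records$terminal),
                    cell = as.character(records$cell),
                    stringsAsFactors = FALSE)
  rec <- unique(rec)
  rec <- rec[order(rec$terminal, rec$cell), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec,
            cell_ids = sort(unique(rec$cell)),
            class = c("occurrence_table", "data.frame"))
}

#' Cross-check an occurrence table against a tree's terminals
#'
#' @param tree an `rwb_tree`.
#' @param occ an `occurrence_table`.
#' @return A list with `missing_from_occurrences` (tree terminals with no
#'   record) and `unknown_terminals` (record labels absent from the tree).
#' @export
match_terminals <- function(tree, occ) {
  tips <- terminal_labels(tree)
  list(missing_from_occurrences = setdiff(tips, unique(occ$terminal)),
       unknown_terminals = setdiff(unique(occ$terminal), tips))
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("Occurrence table: ", nrow(x), " records, ",
      length(unique(x$terminal)), " terminals, ",
      length(attr(x, "cell_ids")), " cells\n", sep = "")
  invisible(x)
}
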