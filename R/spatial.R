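#' Per-grid-cell composition of highly endemic branches
#'
#' For every occupied grid cell, lists the highly endemic branches whose
#' range includes the cell, tallies them by category, and reports the
#' cell's phylogenetic endemism (PE, the sum of RWoT lengths of all
#' branches present).  Cells with no endemic branches are kept: a cell
#' can carry substantial PE from widespread branches yet contain none of
#' the selected highly endemic ones, and such cells are informative.
#'
#' @param fit an object returned by [rwibald()].
#' @param terminal_only restrict the roster to terminal branches
#'   (default `FALSE`: compositions use all branches).
#' @return A data frame of class `cell_composition` with one row per
#'   occupied cell: `cell_id`, `n_neo`, `n_meso`, `n_paleo`, `pe`, and
#'   `roster` (semicolon-joined `branch:category` pairs).  The long-form
#'   per-branch detail (`cell_id`, `branch_id`, `rwibald`, `category`)
#'   is attached as attribute `"detail"` for external plotting, e.g.
#'   per-cell score histograms.
#' @export
cell_composition <- function(fit, terminal_only = FALSE) {
  stopifnot(inherits(fit, "rwibald"))
  b <- fit$branch
  cells <- sort(unique(unlist(fit$ranges$cells, use.names = FALSE)))
  rwot <- setNames(b$rwot_length, b$branch_id)
  pe <- pe_scores(rwot, fit$ranges, cells = cells)

  keep <- b$highly_endemic & (!terminal_only | b$is_terminal)
  endemic <- b[keep, , drop = FALSE]
  # stable roster order: category then branch id
  endemic <- endemic[order(match(endemic$category, CATEGORIES),
                           endemic$branch_id, method = "radix"), ,
                     drop = FALSE]
  detail <- do.call(rbind, c(list(
    data.frame(cell_id = character(0), branch_id = character(0),
               rwibald = numeric(0), category = character(0),
               stringsAsFactors = FALSE)),
    lapply(seq_len(nrow(endemic)), function(i) {
      data.frame(cell_id = fit$ranges$cells[[endemic$branch_id[i]]],
                 branch_id = endemic$branch_id[i],
                 rwibald = endemic$rwibald[i],
                 category = endemic$category[i],
                 stringsAsFactors = FALSE)
    })))

  tally <- function(cat) {
    d <- detail[detail$category == cat, , drop = FALSE]
    cnt <- table(factor(d$cell_id, levels = cells))
    as.integer(cnt)
  }
  roster <- vapply(cells, function(cl) {
    d <- detail[detail$cell_id == cl, , drop = FALSE]
    paste(sprintf("%s:%s", d$branch_id, d$category), collapse = ";")
  }, character(1L))
  out <- data.frame(cell_id = cells,
                    n_neo = tally("neo"),
                    n_meso = tally("meso"),
                    n_paleo = tally("paleo"),
                    pe = unname(pe[cells]),
                    roster = unname(roster),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  detail <- detail[order(detail$cell_id, detail$branch_id,
                         method = "radix"), , drop = FALSE]
  rownames(detail) <- NULL
  structure(out, detail = detail,
            class = c("cell_composition", "data.frame"))
}

#' Grid cells occupied by branches of one endemism category
#'
#' The union of range cells over all branches of the requested category,
#' for mapping the geographic distribution of each endemism type.
#'
#' @param fit an object returned by [rwibald()].
#' @param category `"neo"`, `"meso"`, or `"paleo"`.
#' @param terminal_only restrict to terminal branches (default `TRUE`,
#'   the convention for category maps).
#' @return Sorted character vector of cell ids (possibly empty).
#' @export
category_cells <- function(fit, category = c("neo", "meso", "paleo"),
                           terminal_only = TRUE) {
  stopifnot(inherits(fit, "rwibald"))
  category <- match.arg(category)
  b <- fit$branch
  keep <- b$category == category & (!terminal_only | b$is_terminal)
  sort(unique(unlist(fit$ranges$cells[b$branch_id[keep]],
                     use.names = FALSE)))
}
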