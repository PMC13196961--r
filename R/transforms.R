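#' Equal-length comparison-tree branch lengths
#'
#' The comparison tree keeps the observed topology but gives every branch
#' an equal share of the total tree length: each of the n non-root
#' branches gets T/n, where T is the sum of observed branch lengths.
#' Total length is therefore conserved, an equal-length observed tree is
#' a fixed point, and differences against the comparison tree stay in
#' observed-tree units.
#'
#' @param tree an `rwb_tree`.
#' @return Named numeric vector of comparison lengths (branch_id names).
#' @export
comparison_lengths <- function(tree) {
  b <- tree$branch
  total <- sum(b$length)
  if (total <= 0) {
    stop("degenerate tree: total branch length is zero", call. = FALSE)
  }
  setNames(rep(total / nrow(b), nrow(b)), b$branch_id)
}

#' Observed branch lengths as a named vector
#'
#' @param tree an `rwb_tree`.
#' @return Named numeric vector of observed lengths (branch_id names).
#' @export
observed_lengths <- function(tree) {
  setNames(tree$branch$length, tree$branch$branch_id)
}

#' Range-weight a branch length vector
#'
#' Divides each branch length by the branch's range size (number of
#' occupied grid cells), producing the branch lengths of a range-weighted
#' tree.  Applied to the observed lengths this yields the RWoT; applied
#' to the comparison lengths, the RWcT.
#'
#' @param lengths named numeric vector of branch lengths (branch_id names).
#' @param ranges a `branch_ranges` object, or a named integer vector of
#'   range sizes.
#' @return Named numeric vector of range-weighted lengths.
#' @export
range_weight <- function(lengths, ranges) {
  size <- if (inherits(ranges, "branch_ranges")) ranges$size else ranges
  missing <- setdiff(names(lengths), names(size))
  if (length(missing) > 0L) {
    stop("no range size for branch(es): ",
         paste(head(missing, 10L), collapse = ", "), call. = FALSE)
  }
  r <- size[names(lengths)]
  bad <- names(lengths)[!is.finite(r) | r < 1]
  if (length(bad) > 0L) {
    stop("range size must be >= 1; offending branch(es): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  lengths / r
}

#' Phylogenetic endemism of grid cells
#'
#' The PE score of a cell is the sum, over all branches whose range
#' includes that cell, of the branch's length on the range-weighted
#' observed tree — i.e., phylogenetic diversity measured on the RWoT.
#' Summed over a branch's occupied cells, its contributions recover its
#' unweighted length.  This is a per-cell diagnostic; classification does
#' not use it.
#'
#' @param rw_lengths named numeric vector of range-weighted branch
#'   lengths (the RWoT).
#' @param ranges a `branch_ranges` object.
#' @param cells cell ids to score; default all occupied cells.
#' @return Named numeric vector of PE scores.
#' @export
pe_scores <- function(rw_lengths, ranges, cells = NULL) {
  all_cells <- sort(unique(unlist(ranges$cells, use.names = FALSE)))
  if (is.null(cells)) {
    cells <- all_cells
  } else {
    unknown <- setdiff(cells, all_cells)
    if (length(unknown) > 0L) {
      stop("unknown cell(s): ", paste(head(unknown, 10L), collapse = ", "),
           call. = FALSE)
    }
  }
  pe <- setNames(numeric(length(cells)), cells)
  for (b in names(rw_lengths)) {
    hit <- intersect(ranges$cells[[b]], cells)
    if (length(hit) > 0L) pe[hit] <- pe[hit] + rw_lengths[[b]]
  }
  pe
}
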