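#' Per-branch geographic range sizes
#'
#' Computes, for every branch, the set of grid cells it occupies and the
#' range size (cell count).  A terminal branch occupies the cells where
#' its terminal occurs; an internal branch occupies the union of its
#' descendant terminals' cells, accumulated in a single post-order pass.
#'
#' @param tree an `rwb_tree`.
#' @param occ an `occurrence_table`.
#' @param missing_policy what to do with tree terminals that have no
#'   occurrence record: `"error"` (default) aborts naming them; `"drop"`
#'   prunes them from the tree with a warning.  Occurrence records for
#'   labels absent from the tree are always ignored with a warning.
#' @return A list of class `branch_ranges` with elements `cells` (named
#'   list: branch_id -> sorted character vector of cell ids), `size`
#'   (named integer vector), `tree` (the possibly pruned `rwb_tree`), and
#'   `dropped_terminals`.
#' @export
branch_ranges <- function(tree, occ, missing_policy = c("error", "drop")) {
  missing_policy <- match.arg(missing_policy)
  chk <- match_terminals(tree, occ)
  if (length(chk$unknown_terminals) > 0L) {
    warning("ignoring occurrence records for ", length(chk$unknown_terminals),
            " label(s) absent from the tree: ",
            paste(head(chk$unknown_terminals, 5L), collapse = ", "))
  }
  dropped <- character(0)
  if (length(chk$missing_from_occurrences) > 0L) {
    if (missing_policy == "error") {
      stop("terminal(s) with zero occupied cells: ",
           paste(chk$missing_from_occurrences, collapse = ", "),
           call. = FALSE)
    }
    dropped <- chk$missing_from_occurrences
    if (length(dropped) >= length(terminal_labels(tree)) - 1L) {
      stop("dropping terminals without occurrences would leave fewer ",
           "than two terminals", call. = FALSE)
    }
    warning("pruning ", length(dropped),
            " terminal(s) without occurrence records: ",
            paste(head(dropped, 5L), collapse = ", "))
    phy <- ape::drop.tip(tree$phylo, dropped)
    tree <- as_rwb_tree(phy, tree_kind = tree$tree_kind)
  }

  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  cells_by_tip <- split(occ$cell, occ$terminal)
  node_cells <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) {
    node_cells[[i]] <- unique(cells_by_tip[[phy$tip.label[i]]])
  }
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    node_cells[[p]] <- union(node_cells[[p]], node_cells[[ch]])
  }
  b <- tree$branch
  cells <- lapply(node_cells[b$child_node], sort)
  names(cells) <- b$branch_id
  size <- vapply(cells, length, integer(1L))
  structure(list(cells = cells, size = size, tree = tree,
                 dropped_terminals = dropped),
            class = "branch_ranges")
}

#' @export
print.branch_ranges <- function(x, ...) {
  cat("Branch ranges for ", length(x$size), " branches; ",
      "total occupied cells: ", length(unique(unlist(x$cells))), "\n",
      sep = "")
  invisible(x)
}
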