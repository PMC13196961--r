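#' Read a rooted phylogeny with branch lengths
#'
#' Parses a Newick or Nexus tree and converts it into the branch-centric
#' representation used throughout the package.  A "branch" is a lineage
#' segment: the interval along a lineage between two branching events, or
#' between a branching event and the present.  Every non-root edge of the
#' tree is one branch; a root edge, which sits below the first branching
#' event and contributes nothing to diversity or endemism sums, is never
#' scored (a positive-length root edge triggers a warning and is dropped).
#'
#' @param source path to a tree file, or a character string containing the
#'   tree itself (detected by the presence of a `;`).
#' @param format `"newick"` or `"nexus"`.
#' @param tree_kind `"phylogram"` (branch lengths are inferred character
#'   change), `"chronogram"` (elapsed time), or `"unspecified"`.  Recorded
#'   on the object; scores computed on the two kinds have different
#'   interpretations.
#' @return An object of class `rwb_tree`: a list with elements `phylo`
#'   (the underlying [ape::phylo] object), `branch` (a data frame with one
#'   row per non-root branch: `branch_id`, `parent_id`, `length`,
#'   `is_terminal`, plus internal node bookkeeping), and `tree_kind`.
#' @details Internal branches receive deterministic identifiers of the
#'   form `node:<label>:<k>`, where `<label>` is the lexicographically
#'   smallest descendant terminal label and `<k>` the number of descendant
#'   terminals.  Nested clades on the path to a given terminal share the
#'   smallest label, so the descendant count is included to keep the
#'   identifiers unique; they are stable across runs and parsers.
#' @seealso [write_phylogeny()], [rwibald()]
#' @export
read_phylogeny <- function(source,
                           format = c("newick", "nexus"),
                           tree_kind = c("unspecified", "phylogram", "chronogram")) {
  format <- match.arg(format)
  tree_kind <- match.arg(tree_kind)
  phy <- tryCatch({
    if (format == "newick") {
      if (length(source) == 1L && grepl(";", source, fixed = TRUE)) {
        ape::read.tree(text = source)
      } else {
        ape::read.tree(file = source)
      }
    } else {
      ape::read.nexus(file = source)
    }
  }, error = function(e) {
    stop("failed to parse ", format, " input: ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(phy)) {
    stop("failed to parse ", format, " input: no tree found", call. = FALSE)
  }
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) {
      warning("input contains ", length(phy), " trees; using the first")
    }
    phy <- phy[[1L]]
  }
  as_rwb_tree(phy, tree_kind = tree_kind)
}

#' Convert an ape phylo object to the branch-centric representation
#'
#' @param phy a rooted [ape::phylo] object with branch lengths.
#' @param tree_kind see [read_phylogeny()].
#' @return An `rwb_tree` object.
#' @export
as_rwb_tree <- function(phy,
                        tree_kind = c("unspecified", "phylogram", "chronogram")) {
  tree_kind <- match.arg(tree_kind)
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape phylo object")
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (!ape::is.rooted(phy)) {
    stop("tree must be rooted", call. = FALSE)
  }
  bad <- which(!is.finite(phy$edge.length) | phy$edge.length < 0)
  if (length(bad) > 0L) {
    stop("missing or negative branch lengths on ", length(bad),
         " branch(es): edges ", paste(head(bad, 10L), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("terminal labels are not unique: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(phy$root.edge) && phy$root.edge > 0) {
    warning("tree has a positive-length root edge; it is excluded from scoring")
  }
  phy$root.edge <- NULL

  ids <- branch_identifiers(phy)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  child <- phy$edge[, 2L]
  parent <- phy$edge[, 1L]
  parent_id <- ifelse(parent == root, ROOT_MARKER, ids[parent])
  branch <- data.frame(
    branch_id = ids[child],
    parent_id = parent_id,
    length = phy$edge.length,
    is_terminal = child <= ntip,
    child_node = child,
    parent_node = parent,
    stringsAsFactors = FALSE
  )
  structure(list(phylo = phy, branch = branch, tree_kind = tree_kind),
            class = "rwb_tree")
}

# Deterministic branch ids for every node of a phylo object, indexed by
# node number.  Tips keep their label; internal node ids combine the
# lexicographically smallest descendant terminal label with the number of
# descendant terminals (nested clades toward that terminal would otherwise
# collide).
branch_identifiers <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  min_lab <- character(nnode)
  n_desc <- integer(nnode)
  min_lab[seq_len(ntip)] <- phy$tip.label
  n_desc[seq_len(ntip)] <- 1L
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    if (min_lab[p] == "" || min_lab[ch] < min_lab[p]) min_lab[p] <- min_lab[ch]
    n_desc[p] <- n_desc[p] + n_desc[ch]
  }
  ids <- min_lab
  internal <- seq.int(ntip + 1L, nnode)
  ids[internal] <- sprintf("node:%s:%d", min_lab[internal], n_desc[internal])
  ids
}

#' Write a phylogeny to Newick
#'
#' @param tree an `rwb_tree` or [ape::phylo] object.
#' @param file output path; if `NULL`, the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
write_phylogeny <- function(tree, file = NULL) {
  phy <- if (inherits(tree, "rwb_tree")) tree$phylo else tree
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(file)
  }
}

#' @export
print.rwb_tree <- function(x, ...) {
  b <- x$branch
  cat("Rooted phylogeny (", x$tree_kind, ") with ",
      sum(b$is_terminal), " terminals and ", nrow(b),
      " non-root branches\n", sep = "")
  cat("Total branch length: ", format(sum(b$length)), "\n", sep = "")
  invisible(x)
}

n_branches <- function(tree) nrow(tree$branch)

terminal_labels <- function(tree) tree$phylo$tip.label
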