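#' Select the highly endemic branches (protocol step 2)
#'
#' Ranks all branches by their length on the range-weighted comparison
#' tree (RWcT) in descending order — functionally the same as ranking by
#' inverse range size — applies the elbow threshold to the ranked curve,
#' and selects every branch whose RWcT length is greater than or equal to
#' the curve value at the elbow.  The selection is data-driven: the
#' threshold adapts to the shape of the range-size distribution instead
#' of imposing an absolute cutoff.
#'
#' @param rwct named numeric vector of RWcT branch lengths.
#' @param normalize passed to [elbow_point()].
#' @return A list with `selected` (character vector of branch ids),
#'   `cutoff` (RWcT length at the elbow, `NA` when undefined),
#'   `elbow_index`, and `degenerate`.  A degenerate curve (all range
#'   sizes equal) yields an empty selection with a warning.
#' @export
select_highly_endemic <- function(rwct, normalize = TRUE) {
  if (length(rwct) < 3L) {
    warning("fewer than 3 branches; endemic selection undefined")
    return(list(selected = character(0), cutoff = NA_real_,
                elbow_index = NA_integer_, degenerate = FALSE))
  }
  ord <- order(-rwct, names(rwct), method = "radix")
  curve <- rwct[ord]
  eb <- elbow_point(unname(curve), descending = TRUE, normalize = normalize)
  if (eb$degenerate) {
    warning("degenerate range-size curve (no curvature); ",
            "no branches selected as highly endemic")
    return(list(selected = character(0), cutoff = NA_real_,
                elbow_index = NA_integer_, degenerate = TRUE))
  }
  cutoff <- eb$value
  list(selected = names(rwct)[rwct >= cutoff],
       cutoff = cutoff, elbow_index = eb$index, degenerate = FALSE)
}

#' Elbow thresholds on the RWiBaLD score distribution (protocol step 3)
#'
#' The score distribution is split at zero.  The positive half is ranked
#' descending and its elbow gives the paleo cutoff; the magnitudes of the
#' negative half are ranked descending and the negated elbow value gives
#' the neo cutoff, so the two halves are processed by mirror-image
#' procedures.  Exact zeros belong to neither half.  Thresholds are
#' fitted on the scores of all branches, not only the endemic subset.
#'
#' @param scores named numeric vector of RWiBaLD scores for all branches.
#' @param normalize passed to [elbow_point()].
#' @return A list of class `rwb_thresholds`: `neo_cutoff` (<= 0, `NA`
#'   when undefined), `paleo_cutoff` (>= 0, `NA` when undefined),
#'   `elbow_indices` (per half), and `degenerate` flags.  A half with
#'   fewer than 3 points, or without curvature, leaves its cutoff
#'   undefined with a warning; the corresponding category will be empty.
#' @export
score_thresholds <- function(scores, normalize = TRUE) {
  half <- function(v, side) {
    if (length(v) < 3L) {
      warning("fewer than 3 ", side, " scores; ", side,
              " cutoff undefined and its category will be empty")
      return(list(cutoff = NA_real_, index = NA_integer_, degenerate = FALSE))
    }
    ord <- order(-v, names(v), method = "radix")
    eb <- elbow_point(unname(v[ord]), descending = TRUE,
                      normalize = normalize)
    if (eb$degenerate) {
      warning("degenerate ", side, " score curve; ", side,
              " cutoff undefined and its category will be empty")
      return(list(cutoff = NA_real_, index = NA_integer_, degenerate = TRUE))
    }
    list(cutoff = eb$value, index = eb$index, degenerate = FALSE)
  }
  pos <- half(scores[scores > 0], "positive")
  neg <- half(abs(scores[scores < 0]), "negative")
  structure(list(
    neo_cutoff = if (is.na(neg$cutoff)) NA_real_ else -neg$cutoff,
    paleo_cutoff = pos$cutoff,
    elbow_indices = list(positive = pos$index, negative = neg$index),
    degenerate = list(positive = pos$degenerate, negative = neg$degenerate)
  ), class = "rwb_thresholds")
}

#' Classify highly endemic branches (protocol step 4)
#'
#' Highly endemic branches with RWiBaLD scores at or below the neo cutoff
#' are neo-endemic; at or above the paleo cutoff, paleo-endemic; between
#' the two (including exact zeros), meso-endemic.  Branches outside the
#' endemic set get category `"none"`.  An undefined cutoff on one side
#' empties that category; the other side classifies normally and the
#' in-between branches fall to meso.
#'
#' @param endemic_set character vector of highly endemic branch ids.
#' @param scores named numeric vector of RWiBaLD scores.
#' @param thresholds an `rwb_thresholds` object (or list with
#'   `neo_cutoff` and `paleo_cutoff`).
#' @return Named character vector of categories
#'   (`"neo"`, `"meso"`, `"paleo"`, `"none"`), one per score.  When both
#'   cutoffs are undefined (e.g. on an equal-branch-length tree, where
#'   every score is zero) no branch is classified at all.
#' @export
classify_branches <- function(endemic_set, scores, thresholds) {
  defined <- function(x) !is.null(x) && !is.na(x)
  category <- setNames(rep("none", length(scores)), names(scores))
  if (!defined(thresholds$neo_cutoff) && !defined(thresholds$paleo_cutoff)) {
    return(category)
  }
  idx <- names(scores) %in% endemic_set
  category[idx] <- "meso"
  if (defined(thresholds$neo_cutoff)) {
    category[idx & scores <= thresholds$neo_cutoff] <- "neo"
  }
  if (defined(thresholds$paleo_cutoff)) {
    category[idx & scores >= thresholds$paleo_cutoff] <- "paleo"
  }
  category
}

#' Fit RWiBaLD: score, select, and classify every branch of a phylogeny
#'
#' Runs the full four-step protocol.  For every non-root branch it
#' computes the RWiBaLD score — the branch's length on the range-weighted
#' observed tree (RWoT) minus its length on the range-weighted
#' equal-branch-length comparison tree (RWcT) — together with the
#' unweighted analogue BaLD (observed minus comparison length).  Negative
#' scores point toward neo-endemism, positive toward paleo-endemism.  An
#' elbow threshold on the ranked RWcT lengths selects the highly endemic
#' (most range-restricted) branches; elbow thresholds on the two halves
#' of the score distribution then partition them into neo-, meso-, and
#' paleo-endemic categories.
#'
#' The identity `rwibald = bald / range_size` holds on every branch, so
#' range weighting shrinks the score of widespread branches toward zero.
#'
#' @param tree an `rwb_tree` (see [read_phylogeny()]) or [ape::phylo]
#'   object.
#' @param occurrences an `occurrence_table` (see [read_occurrences()]) or
#'   a data frame with columns `terminal` and `cell`.
#' @param elbow_normalize rescale both axes to \[0, 1\] before elbow
#'   distance computations (default `TRUE`); see [elbow_point()].
#' @param missing_policy `"error"` or `"drop"` for terminals without
#'   occurrence records; see [branch_ranges()].  When dropping, the
#'   comparison length T/n is computed on the pruned tree, so observed
#'   and comparison trees always describe the same branch set.
#' @param tree_kind recorded tree kind when `tree` is a bare `phylo`.
#' @return An object of class `rwibald`: a list with `branch` (data frame
#'   with one row per branch: `branch_id`, `parent_id`, `is_terminal`,
#'   `observed_length`, `comparison_length`, `range_size`, `rwot_length`,
#'   `rwct_length`, `rwibald`, `bald`, `highly_endemic`, `category`),
#'   `thresholds` (endemic/neo/paleo cutoffs, elbow indices, degeneracy
#'   flags), `ranges`, `tree`, `dropped_terminals`, `elbow_normalize`,
#'   and `call`.
#' @examples
#' tree <- read_phylogeny("((A:1,B:2):3,C:4);")
#' occ <- occurrence_table(data.frame(
#'   terminal = c("A", "B", "B", "C"),
#'   cell = c("c1", "c1", "c2", "c3")))
#' fit <- rwibald(tree, occ)
#' branch_table(fit)
#' @seealso [branch_table()], [cell_composition()], [simulate_endemism()],
#'   [run_rwibald()]
#' @export
rwibald <- function(tree, occurrences,
                    elbow_normalize = TRUE,
                    missing_policy = c("error", "drop"),
                    tree_kind = c("unspecified", "phylogram", "chronogram")) {
  missing_policy <- match.arg(missing_policy)
  if (inherits(tree, "phylo")) {
    tree <- as_rwb_tree(tree, tree_kind = match.arg(tree_kind))
  }
  if (!inherits(tree, "rwb_tree")) stop("`tree` must be an rwb_tree or phylo")
  if (!inherits(occurrences, "occurrence_table")) {
    occurrences <- occurrence_table(occurrences)
  }

  ranges <- branch_ranges(tree, occurrences, missing_policy = missing_policy)
  tree <- ranges$tree  # possibly pruned; T/n computed on this branch set

  ot <- observed_lengths(tree)
  ct <- comparison_lengths(tree)
  rwot <- range_weight(ot, ranges)
  rwct <- range_weight(ct, ranges)
  scores <- rwot - rwct
  bald <- ot - ct

  sel <- select_highly_endemic(rwct, normalize = elbow_normalize)
  thr <- score_thresholds(scores, normalize = elbow_normalize)
  category <- classify_branches(sel$selected, scores, thr)

  b <- tree$branch
  branch <- data.frame(
    branch_id = b$branch_id,
    parent_id = b$parent_id,
    is_terminal = b$is_terminal,
    observed_length = unname(ot),
    comparison_length = unname(ct),
    range_size = unname(ranges$size[b$branch_id]),
    rwot_length = unname(rwot),
    rwct_length = unname(rwct),
    rwibald = unname(scores),
    bald = unname(bald),
    highly_endemic = b$branch_id %in% sel$selected,
    category = unname(category[b$branch_id]),
    stringsAsFactors = FALSE
  )
  thresholds <- list(
    endemic_cutoff = sel$cutoff,
    neo_cutoff = thr$neo_cutoff,
    paleo_cutoff = thr$paleo_cutoff,
    elbow_indices = list(endemic = sel$elbow_index,
                         positive = thr$elbow_indices$positive,
                         negative = thr$elbow_indices$negative),
    degenerate = list(endemic = sel$degenerate,
                      positive = thr$degenerate$positive,
                      negative = thr$degenerate$negative)
  )
  structure(list(branch = branch, thresholds = thresholds, ranges = ranges,
                 tree = tree, dropped_terminals = ranges$dropped_terminals,
                 elbow_normalize = elbow_normalize,
                 call = match.call()),
            class = "rwibald")
}

#' Per-branch results table of a fitted RWiBaLD object
#'
#' @param fit an object returned by [rwibald()].
#' @return The per-branch data frame (see [rwibald()] for columns).
#' @export
branch_table <- function(fit) {
  stopifnot(inherits(fit, "rwibald"))
  fit$branch
}

#' Category counts of a fitted RWiBaLD object
#'
#' @param fit an object returned by [rwibald()].
#' @return Named integer vector with elements `highly_endemic`, `neo`,
#'   `meso`, `paleo`.
#' @export
category_counts <- function(fit) {
  b <- branch_table(fit)
  c(highly_endemic = sum(b$highly_endemic),
    neo = sum(b$category == "neo"),
    meso = sum(b$category == "meso"),
    paleo = sum(b$category == "paleo"))
}

#' @export
print.rwibald <- function(x, ...) {
  b <- x$branch
  cnt <- category_counts(x)
  cat("RWiBaLD classification of", nrow(b), "branches",
      sprintf("(%d terminals)\n", sum(b$is_terminal)))
  cat(sprintf("  highly endemic: %d (RWcT cutoff %s)\n",
              cnt[["highly_endemic"]], format(x$thresholds$endemic_cutoff)))
  cat(sprintf("  neo %d | meso %d | paleo %d\n",
              cnt[["neo"]], cnt[["meso"]], cnt[["paleo"]]))
  cat(sprintf("  score cutoffs: neo <= %s, paleo >= %s\n",
              format(x$thresholds$neo_cutoff),
              format(x$thresholds$paleo_cutoff)))
  if (length(x$dropped_terminals) > 0L) {
    cat("  dropped terminals without occurrences:",
        length(x$dropped_terminals), "\n")
  }
  invisible(x)
}

#' @export
summary.rwibald <- function(object, ...) {
  b <- object$branch
  by_cat <- lapply(split(b$rwibald, b$category), function(v) {
    c(n = length(v), min = min(v), median = stats::median(v), max = max(v))
  })
  out <- list(
    n_branches = nrow(b),
    n_terminals = sum(b$is_terminal),
    total_length = sum(b$observed_length),
    n_cells = length(unique(unlist(object$ranges$cells, use.names = FALSE))),
    counts = category_counts(object),
    thresholds = object$thresholds,
    score_by_category = by_cat,
    dropped_terminals = object$dropped_terminals,
    elbow_normalize = object$elbow_normalize
  )
  class(out) <- "summary.rwibald"
  out
}

#' @export
print.summary.rwibald <- function(x, ...) {
  cat("RWiBaLD fit:", x$n_branches, "branches,", x$n_terminals,
      "terminals,", x$n_cells, "occupied cells\n")
  cat("Total tree length:", format(x$total_length),
      "| comparison length per branch:",
      format(x$total_length / x$n_branches), "\n")
  cat("Elbow axis normalization:", x$elbow_normalize, "\n")
  cat(sprintf("Highly endemic: %d (RWcT cutoff %s)\n",
              x$counts[["highly_endemic"]],
              format(x$thresholds$endemic_cutoff)))
  cat(sprintf("Categories: neo %d, meso %d, paleo %d\n",
              x$counts[["neo"]], x$counts[["meso"]], x$counts[["paleo"]]))
  cat("RWiBaLD score range by category:\n")
  for (nm in names(x$score_by_category)) {
    s <- x$score_by_category[[nm]]
    cat(sprintf("  %-5s n=%4d  [%s, %s]\n", nm, s[["n"]],
                format(s[["min"]], digits = 4),
                format(s[["max"]], digits = 4)))
  }
  invisible(x)
}

#' Extract RWiBaLD scores as a continuous branch trait
#'
#' The signed score is defined for every branch (not only the endemic
#' set), so it can be used directly as a continuous measure of neo-
#' (negative) and paleo- (positive) endemism in phylogenetic comparative
#' methods.
#'
#' @param object an object returned by [rwibald()].
#' @param ... unused.
#' @return Named numeric vector of RWiBaLD scores.
#' @export
coef.rwibald <- function(object, ...) {
  setNames(object$branch$rwibald, object$branch$branch_id)
}

#' Ranked-curve diagnostic plots for a RWiBaLD fit
#'
#' Three panels: (A) branches ranked by RWcT length with the endemic
#' cutoff; (B) branches ranked by RWiBaLD score with the neo and paleo
#' cutoffs, endemic branches colored by category; (C) the same for the
#' unweighted BaLD scores.
#'
#' @param x an object returned by [rwibald()].
#' @param which subset of panels to draw (any of 1:3).
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.rwibald <- function(x, which = 1:3, ...) {
  b <- x$branch
  cols <- c(neo = "red", meso = "goldenrod", paleo = "blue", none = "grey60")
  op <- par(mfrow = c(1, length(which)), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  if (1 %in% which) {
    ord <- order(-b$rwct_length, b$branch_id, method = "radix")
    plot(seq_len(nrow(b)), b$rwct_length[ord], type = "l",
         xlab = "branches ranked by range restriction",
         ylab = "RWcT length", main = "A. endemic selection", ...)
    abline(h = x$thresholds$endemic_cutoff, col = "red", lty = 3)
  }
  if (2 %in% which) {
    ord <- order(b$rwibald, b$branch_id, method = "radix")
    plot(seq_len(nrow(b)), b$rwibald[ord], type = "p", pch = 16, cex = 0.5,
         col = cols[b$category[ord]],
         xlab = "branches ranked by RWiBaLD score",
         ylab = "RWiBaLD", main = "B. score thresholds", ...)
    abline(h = 0, col = "grey")
    abline(h = c(x$thresholds$neo_cutoff, x$thresholds$paleo_cutoff),
           col = "red", lty = 3)
  }
  if (3 %in% which) {
    ord <- order(b$bald, b$branch_id, method = "radix")
    plot(seq_len(nrow(b)), b$bald[ord], type = "p", pch = 16, cex = 0.5,
         col = cols[b$category[ord]],
         xlab = "branches ranked by BaLD score",
         ylab = "BaLD", main = "C. unweighted differences", ...)
    abline(h = 0, col = "grey")
  }
  invisible(x)
}
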