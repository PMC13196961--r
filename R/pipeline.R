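#' Write the per-branch results table as CSV
#'
#' Columns: branch_id, parent_id, is_terminal, observed_length,
#' comparison_length, range_size, rwot_length, rwct_length, rwibald,
#' bald, highly_endemic, category.  Output is byte-deterministic for
#' identical fits.
#'
#' @param fit an object returned by [rwibald()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_branch_table <- function(fit, file) {
  b <- branch_table(fit)
  b <- b[order(b$branch_id, method = "radix"), , drop = FALSE]
  b$observed_length <- format_num(b$observed_length)
  b$comparison_length <- format_num(b$comparison_length)
  b$rwot_length <- format_num(b$rwot_length)
  b$rwct_length <- format_num(b$rwct_length)
  b$rwibald <- format_num(b$rwibald)
  b$bald <- format_num(b$bald)
  write.csv(b, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write the per-cell composition table as CSV
#'
#' @param composition a [cell_composition()] data frame.
#' @param file output path.
#' @param detail_file optional path for the long-form per-(cell, branch)
#'   score export (for external histogram plotting).
#' @return The path, invisibly.
#' @export
write_cell_table <- function(composition, file, detail_file = NULL) {
  out <- as.data.frame(composition)
  out$pe <- format_num(out$pe)
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  if (!is.null(detail_file)) {
    d <- attr(composition, "detail")
    d$rwibald <- format_num(d$rwibald)
    write.csv(d, detail_file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

format_num <- function(x) {
  formatC(x, format = "g", digits = 15)
}

#' Write a Newick tree annotated with endemism categories
#'
#' Appends a `[&category=...]` comment to every classified branch
#' (categories other than `"none"`), in the style understood by common
#' tree-visualization tools, so categories can be displayed along the
#' phylogeny.  Written by a small dedicated serializer because standard
#' Newick writers do not emit node comments.
#'
#' @param fit an object returned by [rwibald()].
#' @param file output path; if `NULL`, the annotated Newick string is
#'   returned.
#' @param all_branches annotate every branch, including `category=none`
#'   (default `FALSE`).
#' @return The path (invisibly) or the Newick string.
#' @export
write_annotated_newick <- function(fit, file = NULL, all_branches = FALSE) {
  stopifnot(inherits(fit, "rwibald"))
  phy <- fit$tree$phylo
  b <- fit$tree$branch
  cat_by_node <- setNames(fit$branch$category, fit$branch$branch_id)
  node_cat <- rep(NA_character_, length(phy$tip.label) + phy$Nnode)
  node_cat[b$child_node] <- cat_by_node[b$branch_id]
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  elen <- setNames(phy$edge.length, phy$edge[, 2L])
  ntip <- length(phy$tip.label)

  annot <- function(node) {
    ct <- node_cat[node]
    if (is.na(ct) || (!all_branches && ct == "none")) "" else
      sprintf("[&category=%s]", ct)
  }
  render <- function(node) {
    inner <- if (node <= ntip) {
      phy$tip.label[node]
    } else {
      paste0("(", paste(vapply(kids[[as.character(node)]], render,
                               character(1L)), collapse = ","), ")")
    }
    len <- elen[as.character(node)]
    if (is.na(len)) inner else
      paste0(inner, annot(node), ":", format_num(len))
  }
  txt <- paste0(render(ntip + 1L), ";")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

#' Write thresholds and flags as JSON
#'
#' @param fit an object returned by [rwibald()].
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_thresholds <- function(fit, file) {
  thr <- fit$thresholds
  payload <- list(
    endemic_cutoff = thr$endemic_cutoff,
    neo_cutoff = thr$neo_cutoff,
    paleo_cutoff = thr$paleo_cutoff,
    elbow_indices = thr$elbow_indices,
    degenerate = thr$degenerate,
    elbow_normalize = fit$elbow_normalize,
    counts = as.list(category_counts(fit))
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(file)
}

#' Run the full RWiBaLD protocol with file output
#'
#' Reads a tree and occurrence data (or takes a synthetic instance),
#' fits [rwibald()], and writes the output bundle to a directory:
#' `branch_table.csv`, `thresholds.json`, `annotated.nwk`,
#' `cell_table.csv`, `cell_detail.csv`, and `run_log.txt` (configuration
#' echo plus category counts; no timestamps, so identical inputs produce
#' byte-identical bundles).
#'
#' @param tree path to a tree file, an `rwb_tree`, or an `rwibald_sim`
#'   (in which case `occurrences` is taken from the instance).
#' @param occurrences path to an occurrence file or an
#'   `occurrence_table`.
#' @param output_dir output directory (created if absent).
#' @param tree_format,tree_kind passed to [read_phylogeny()] for file
#'   input.
#' @param occ_layout,occ_delimiter passed to [read_occurrences()] for
#'   file input.
#' @param elbow_normalize,missing_policy passed to [rwibald()].
#' @param terminal_only_maps restrict per-cell rosters to terminal
#'   branches (default `FALSE`).
#' @param classify when `FALSE`, only scores are computed and written
#'   (no selection or categories) — the "scores-only" mode.
#' @return The fitted `rwibald` object (or, with `classify = FALSE`, the
#'   per-branch score data frame), invisibly.
#' @export
run_rwibald <- function(tree, occurrences = NULL, output_dir,
                        tree_format = c("newick", "nexus"),
                        tree_kind = c("unspecified", "phylogram",
                                      "chronogram"),
                        occ_layout = c("long", "matrix"),
                        occ_delimiter = ",",
                        elbow_normalize = TRUE,
                        missing_policy = c("error", "drop"),
                        terminal_only_maps = FALSE,
                        classify = TRUE) {
  tree_kind <- match.arg(tree_kind)
  if (inherits(tree, "rwibald_sim")) {
    occurrences <- tree$occurrences
    tree <- tree$tree
  }
  if (is.character(tree)) {
    tree <- read_phylogeny(tree, format = match.arg(tree_format),
                           tree_kind = tree_kind)
  }
  if (is.character(occurrences)) {
    occurrences <- read_occurrences(occurrences,
                                    layout = match.arg(occ_layout),
                                    delimiter = occ_delimiter)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  fit <- rwibald(tree, occurrences, elbow_normalize = elbow_normalize,
                 missing_policy = missing_policy)
  if (!classify) {
    scores <- branch_table(fit)[, c("branch_id", "parent_id", "is_terminal",
                                    "observed_length", "comparison_length",
                                    "range_size", "rwot_length",
                                    "rwct_length", "rwibald", "bald")]
    out <- scores
    out[] <- lapply(out, function(col) if (is.numeric(col) &&
                                           !is.integer(col))
      format_num(col) else col)
    write.csv(out[order(out$branch_id, method = "radix"), , drop = FALSE],
              file.path(output_dir, "branch_scores.csv"),
              row.names = FALSE, quote = FALSE)
    return(invisible(scores))
  }

  write_branch_table(fit, file.path(output_dir, "branch_table.csv"))
  write_thresholds(fit, file.path(output_dir, "thresholds.json"))
  write_annotated_newick(fit, file.path(output_dir, "annotated.nwk"))
  comp <- cell_composition(fit, terminal_only = terminal_only_maps)
  write_cell_table(comp, file.path(output_dir, "cell_table.csv"),
                   detail_file = file.path(output_dir, "cell_detail.csv"))

  cnt <- category_counts(fit)
  log_lines <- c(
    "rwibald run",
    sprintf("elbow_normalize=%s", elbow_normalize),
    sprintf("missing_policy=%s", match.arg(missing_policy)),
    sprintf("terminal_only_maps=%s", terminal_only_maps),
    sprintf("tree_kind=%s", fit$tree$tree_kind),
    sprintf("n_branches=%d", nrow(fit$branch)),
    sprintf("n_terminals=%d", sum(fit$branch$is_terminal)),
    sprintf("n_cells=%d", nrow(comp)),
    sprintf("dropped_terminals=%d", length(fit$dropped_terminals)),
    sprintf("highly_endemic=%d", cnt[["highly_endemic"]]),
    sprintf("neo=%d", cnt[["neo"]]),
    sprintf("meso=%d", cnt[["meso"]]),
    sprintf("paleo=%d", cnt[["paleo"]]),
    sprintf("degenerate_endemic=%s", fit$thresholds$degenerate$endemic),
    sprintf("degenerate_positive=%s", fit$thresholds$degenerate$positive),
    sprintf("degenerate_negative=%s", fit$thresholds$degenerate$negative)
  )
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(fit)
}
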