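# Independent oracles used across the suite.  They deliberately take
# different computational routes from the package internals.

# Elbow oracle: per-point perpendicular distance to the chord computed
# via the explicit projection foot (the package uses the cross-product
# form, vectorized).
oracle_elbow_index <- function(values, normalize = TRUE) {
  m <- length(values)
  x <- as.numeric(seq_len(m))
  y <- as.numeric(values)
  if (normalize) {
    x <- (x - 1) / (m - 1)
    r <- range(y)
    y <- if (diff(r) > 0) (y - r[1]) / diff(r) else rep(0, m)
  }
  vx <- x[m] - x[1]
  vy <- y[m] - y[1]
  tt <- ((x - x[1]) * vx + (y - y[1]) * vy) / (vx^2 + vy^2)
  footx <- x[1] + tt * vx
  footy <- y[1] + tt * vy
  d <- sqrt((x - footx)^2 + (y - footy)^2)
  which.max(d)
}

# hand-built instance mirroring the three-colored-tip illustration:
# eight widespread terminals plus three single-cell terminals that are
# long (Blue), short (Red) and near the equal share (Yellow)
toy_three_endemics <- function() {
  wide <- sprintf("W%d:%0.1f", 1:8, c(0.6, 0.8, 1.2, 1.4, 0.7, 1.3, 0.9, 1.1))
  nwk <- sprintf(paste0("((((%s,%s):0.7,(%s,%s):1.3):0.8,((%s,%s):1.2,",
                        "(%s,%s):0.9):1.1):1.0,",
                        "((Red:0.05,Yellow:1.16):1.0,Blue:5):1.0);"),
                 wide[1], wide[2], wide[3], wide[4],
                 wide[5], wide[6], wide[7], wide[8])
  cells <- paste0("c", 1:10)
  occ <- rbind(
    do.call(rbind, lapply(sprintf("W%d", 1:8), function(w)
      data.frame(terminal = w, cell = cells, stringsAsFactors = FALSE))),
    data.frame(terminal = c("Red", "Yellow", "Blue"),
               cell = c("c1", "c2", "c3"), stringsAsFactors = FALSE))
  list(tree = read_phylogeny(nwk), occ = occurrence_table(occ))
}

# Range oracle: for each branch, enumerate descendant tips with
# phangorn::Descendants and union their cells (the package accumulates
# unions in a single postorder pass instead).
oracle_branch_cells <- function(tree, occ) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  b <- tree$branch
  out <- vector("list", nrow(b))
  names(out) <- b$branch_id
  for (i in seq_len(nrow(b))) {
    node <- b$child_node[i]
    tips <- if (node <= ntip) node else
      phangorn::Descendants(phy, node, "tips")[[1L]]
    out[[i]] <- sort(unique(occ$cell[occ$terminal %in% phy$tip.label[tips]]))
  }
  out
}

# Random tree + occupancy instance, independent of simulate_endemism().
random_instance <- function(n_tips, n_cells = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(n_tips)
  cells <- paste0("c", seq_len(n_cells))
  rec <- do.call(rbind, lapply(phy$tip.label, function(tp) {
    data.frame(terminal = tp,
               cell = sample(cells, sample.int(n_cells, 1L)),
               stringsAsFactors = FALSE)
  }))
  list(tree = as_rwb_tree(phy), occ = occurrence_table(rec))
}

# Truth lookup for a simulated instance against a fitted object.
planted_vs_called <- function(sim, fit) {
  b <- branch_table(fit)
  truth <- sim$truth$class[match(b$branch_id, sim$truth$branch_id)]
  data.frame(branch_id = b$branch_id, truth = truth, called = b$category,
             stringsAsFactors = FALSE)
}
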