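#' Simulate a phylogeny and occurrence grid with planted endemic branches
#'
#' Generates a synthetic instance for validating the full pipeline: a
#' random rooted bifurcating tree with heterogeneous branch lengths, an
#' equal-area grid occupancy table with heavy-tailed background range
#' sizes, and a set of planted terminal branches that are simultaneously
#' range-restricted (exactly one cell) and short (neo), intermediate
#' (meso) or long (paleo) relative to the comparison length T/n of the
#' finished instance.  The generator returns full bookkeeping (a truth
#' table) so recovery can be checked exactly.
#'
#' Planted branch lengths are set as multiples `a * (T/n)` where the
#' multiplier satisfies `a <= eps` (neo), `a >= kappa` (paleo) or
#' `|a - 1| < delta` (meso).  Because T itself depends on the planted
#' lengths, the mean is solved in closed form:
#' `T/n = S_bg / (n - sum(a))` with `S_bg` the summed background
#' lengths.  Planted tips are chosen so that no two share a parent node,
#' keeping their signal from leaking into shared internal branches, and
#' each occupies its own private cell.  Background terminals occupy at
#' least `min_range_frac` of the grid, with range sizes drawn from a
#' truncated discrete power law, reproducing the empirically typical
#' sparse middle of the score distribution.  Optionally, whole small
#' clades can be confined to a single cell to exercise deep-branch
#' (internal) endemism.
#'
#' @param n_tips total number of terminals (default 100).
#' @param grid_dim integer vector of grid dimensions (default `c(10, 10)`).
#' @param n_neo,n_meso,n_paleo planted branches per class (default 3 each).
#' @param eps,kappa,delta separation multipliers for neo, paleo and meso
#'   planted lengths (defaults 0.05, 20, 0.1).
#' @param min_range_frac minimum fraction of grid cells occupied by each
#'   background terminal (default 0.02, i.e. a minimum range of 2 cells
#'   on the default grid: range-size distributions of real assemblages
#'   are strongly right-skewed, with many narrow-ranged taxa).
#' @param powerlaw_alpha exponent of the truncated power-law range-size
#'   distribution for background terminals (default 1.5).
#' @param n_confined_clades number of small (2-3 tip) background clades
#'   additionally confined to a single shared cell (default 0).
#' @param seed integer seed; the instance is a deterministic function of
#'   the seed (Mersenne-Twister).  The caller's RNG state is restored.
#' @return An object of class `rwibald_sim`: a list with `tree`
#'   (`rwb_tree`), `occurrences` (`occurrence_table`), `truth` (data
#'   frame `branch_id`, `class` over all branches, classes in
#'   neo/meso/paleo/background), `params`, and `rng` (the RNG algorithm
#'   name).
#' @examples
#' sim <- simulate_endemism(n_tips = 40, seed = 1)
#' fit <- rwibald(sim$tree, sim$occurrences)
#' table(truth = sim$truth$class[match(branch_table(fit)$branch_id,
#'                                     sim$truth$branch_id)],
#'       called = branch_table(fit)$category)
#' @export
simulate_endemism <- function(n_tips = 100, grid_dim = c(10, 10),
                              n_neo = 3, n_meso = 3, n_paleo = 3,
                              eps = 0.05, kappa = 20, delta = 0.1,
                              min_range_frac = 0.02, powerlaw_alpha = 1.5,
                              n_confined_clades = 0, seed = NULL) {
  n_planted <- n_neo + n_meso + n_paleo
  n_cells <- prod(grid_dim)
  if (n_tips < n_planted + 2L) {
    stop("infeasible: n_tips must be at least n_planted + 2", call. = FALSE)
  }
  if (n_cells < n_planted + 1L) {
    stop("infeasible: grid must have at least n_planted + 1 cells",
         call. = FALSE)
  }
  if (eps <= 0 || eps >= 1 || kappa <= 1 || delta <= 0 || delta >= 1) {
    stop("infeasible multipliers: need 0 < eps < 1 < kappa and 0 < delta < 1",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
      get(".Random.seed", envir = .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = .GlobalEnv))
    set.seed(seed)
  }

  phy <- ape::rtree(n_tips, br = NULL)
  phy$tip.label <- sprintf("t%03d", seq_len(n_tips))
  ntip <- n_tips
  n_edges <- nrow(phy$edge)

  # planted tips: no two share a parent, so no internal branch is forced
  # to range size <= n_planted by the planting itself
  tip_parent <- phy$edge[match(seq_len(ntip), phy$edge[, 2L]), 1L]
  cand <- sample.int(ntip)
  planted <- integer(0)
  used_parents <- integer(0)
  for (tp in cand) {
    if (length(planted) == n_planted) break
    if (!(tip_parent[tp] %in% used_parents)) {
      planted <- c(planted, tp)
      used_parents <- c(used_parents, tip_parent[tp])
    }
  }
  if (length(planted) < n_planted) {
    stop("infeasible: could not place ", n_planted,
         " planted tips on distinct parents", call. = FALSE)
  }
  classes <- rep(c("neo", "meso", "paleo"), times = c(n_neo, n_meso, n_paleo))
  a <- numeric(n_planted)
  # jitter keeps each class inside its envelope while the planted mass
  # stays a minority of total tree length, so background scores still
  # straddle zero and the meso scores sit inside the background tails
  a[classes == "neo"] <- eps * runif(n_neo, 0.5, 1)
  a[classes == "meso"] <- 1 + delta * runif(n_meso, -0.5, 0.5)
  a[classes == "paleo"] <- kappa * runif(n_paleo, 1, 1.1)
  if (sum(a) >= n_edges) {
    stop("infeasible: planted length multipliers exceed the branch count; ",
         "reduce kappa or the number of planted branches", call. = FALSE)
  }

  planted_edge <- match(planted, phy$edge[, 2L])
  len <- rexp(n_edges, rate = 1)
  s_bg <- sum(len[-planted_edge])
  mean_len <- s_bg / (n_edges - sum(a))  # solves mean = T/n exactly
  len[planted_edge] <- a * mean_len
  phy$edge.length <- len

  # occupancy: private single cells for planted tips, heavy-tailed
  # multi-cell ranges for background tips
  cells <- sprintf("c%03d", seq_len(n_cells))
  private <- sample(cells, n_planted)
  background <- setdiff(seq_len(ntip), planted)
  r_min <- max(2L, ceiling(min_range_frac * n_cells))
  sizes <- seq.int(r_min, n_cells)
  bg_range <- sample(sizes, length(background), replace = TRUE,
                     prob = sizes^(-powerlaw_alpha))
  rec <- vector("list", ntip)
  for (i in seq_along(planted)) {
    rec[[planted[i]]] <- data.frame(terminal = phy$tip.label[planted[i]],
                                    cell = private[i],
                                    stringsAsFactors = FALSE)
  }
  for (i in seq_along(background)) {
    tp <- background[i]
    rec[[tp]] <- data.frame(terminal = phy$tip.label[tp],
                            cell = sample(cells, bg_range[i]),
                            stringsAsFactors = FALSE)
  }

  confined <- character(0)
  if (n_confined_clades > 0) {
    tip_parent_tab <- table(tip_parent[background])
    cherries <- as.integer(names(tip_parent_tab)[tip_parent_tab >= 2L])
    cherries <- cherries[sample.int(length(cherries))]
    picked <- head(cherries, n_confined_clades)
    for (nd in picked) {
      clade_tips <- intersect(which(tip_parent == nd), background)
      cell <- sample(cells, 1L)
      for (tp in clade_tips) {
        rec[[tp]] <- data.frame(terminal = phy$tip.label[tp], cell = cell,
                                stringsAsFactors = FALSE)
      }
      confined <- c(confined, phy$tip.label[clade_tips])
    }
  }

  occ <- occurrence_table(do.call(rbind, rec))
  tree <- as_rwb_tree(phy)
  truth <- data.frame(branch_id = tree$branch$branch_id,
                      class = "background", stringsAsFactors = FALSE)
  truth$class[match(phy$tip.label[planted], truth$branch_id)] <- classes

  sim <- structure(list(tree = tree, occurrences = occ, truth = truth,
                        params = list(n_tips = n_tips, grid_dim = grid_dim,
                                      n_neo = n_neo, n_meso = n_meso,
                                      n_paleo = n_paleo, eps = eps,
                                      kappa = kappa, delta = delta,
                                      min_range_frac = min_range_frac,
                                      powerlaw_alpha = powerlaw_alpha,
                                      n_confined_clades = n_confined_clades,
                                      confined_terminals = confined,
                                      seed = seed),
                        rng = "Mersenne-Twister"),
                   class = "rwibald_sim")
  check_sim_invariants(sim)
  sim
}

# feasibility self-check: every emitted instance satisfies the planted
# invariants relative to the realized mean branch length
check_sim_invariants <- function(sim) {
  p <- sim$params
  b <- sim$tree$branch
  m <- sum(b$length) / nrow(b)
  occ_per_tip <- table(sim$occurrences$terminal)
  lab <- sim$truth$branch_id
  cls <- sim$truth$class
  for (i in which(cls != "background")) {
    stopifnot(occ_per_tip[[lab[i]]] == 1L)
    L <- b$length[b$branch_id == lab[i]]
    ok <- switch(cls[i],
                 neo = L <= m * p$eps + 1e-9 * m,
                 meso = abs(L - m) <= m * p$delta,
                 paleo = L >= m * p$kappa - 1e-9 * m)
    if (!ok) stop("internal error: planted ", cls[i],
                  " branch violates its length invariant", call. = FALSE)
  }
  r_min <- max(2L, ceiling(p$min_range_frac * prod(p$grid_dim)))
  bg_tips <- setdiff(lab[cls == "background" & lab %in%
                           terminal_labels(sim$tree)],
                     p$confined_terminals)
  stopifnot(all(occ_per_tip[bg_tips] >= r_min))
  invisible(TRUE)
}

#' @export
print.rwibald_sim <- function(x, ...) {
  p <- x$params
  cat("Synthetic endemism instance:", p$n_tips, "tips on a",
      paste(p$grid_dim, collapse = "x"), "grid\n")
  cat(sprintf("  planted: %d neo, %d meso, %d paleo (eps=%g, kappa=%g, delta=%g)\n",
              p$n_neo, p$n_meso, p$n_paleo, p$eps, p$kappa, p$delta))
  cat("  seed:", if (is.null(p$seed)) "none" else p$seed,
      "| RNG:", x$rng, "\n")
  invisible(x)
}

#' Write a synthetic instance to fixture files
#'
#' Serializes a [simulate_endemism()] instance as standard files so it
#' can round-trip through the file-based pipeline: a Newick tree, a
#' long-form occurrence CSV, and a truth CSV.
#'
#' @param sim an `rwibald_sim` object.
#' @param dir output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_instance <- function(sim, dir) {
  stopifnot(inherits(sim, "rwibald_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             occurrences = file.path(dir, "occurrences.csv"),
             truth = file.path(dir, "truth.csv"))
  write_phylogeny(sim$tree, paths[["tree"]])
  write.csv(as.data.frame(sim$occurrences)[, c("terminal", "cell")],
            paths[["occurrences"]], row.names = FALSE, quote = FALSE)
  write.csv(sim$truth, paths[["truth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
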