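# helper: fit on a hand-built tree/occupancy pair
fit_toy <- function(newick, records, ...) {
  suppressWarnings(rwibald(read_phylogeny(newick),
                           occurrence_table(as.data.frame(records)), ...))
}

test_that("score arithmetic: differences and the range-size identity", {
  fit <- fit_toy("((A:1,B:2):3,C:4);",
                 data.frame(terminal = c("A", "B", "B", "C"),
                            cell = c("c1", "c1", "c2", "c3")))
  b <- branch_table(fit)
  # T = 10, n = 4, CT = 2.5 everywhere; C has range 1 and length 4
  expect_equal(b$bald[order(b$observed_length)], c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(b$rwibald[b$branch_id == "C"], 4 / 1 - 2.5 / 1)
  expect_equal(b$rwibald, b$bald / b$range_size, tolerance = 1e-12)
  expect_equal(sum(b$bald), 0, tolerance = 1e-9)
})

test_that("equal-branch-length tree is a fixed point with empty categories", {
  phy <- ape::rtree(20)
  phy$edge.length[] <- 1.7
  occ <- do.call(rbind, lapply(seq_along(phy$tip.label), function(i) {
    data.frame(terminal = phy$tip.label[i],
               cell = paste0("c", seq_len((i %% 4) + 1)))
  }))
  fit <- suppressWarnings(rwibald(as_rwb_tree(phy), occurrence_table(occ)))
  b <- branch_table(fit)
  expect_true(all(b$rwibald == 0))
  expect_true(all(b$bald == 0))
  expect_equal(unname(category_counts(fit)[c("neo", "meso", "paleo")]),
               c(0L, 0L, 0L))
})

test_that("shrinkage: |score| is non-increasing in range size", {
  L <- c(b1 = 7, b2 = 0.01)
  ct <- c(b1 = 2, b2 = 2)
  prev <- c(b1 = Inf, b2 = Inf)
  for (r in 1:25) {
    rr <- c(b1 = r, b2 = r)
    s <- abs(range_weight(L, rr) - range_weight(ct, rr))
    expect_true(all(s <= prev + 1e-15))
    prev <- s
  }
})

test_that("symmetric score distributions give mirror-image cutoffs", {
  s <- c(-4, -3, -2, -0.2, -0.1, 0.1, 0.2, 2, 3, 4)
  names(s) <- paste0("b", seq_along(s))
  thr <- score_thresholds(s)
  expect_equal(thr$neo_cutoff, -thr$paleo_cutoff, tolerance = 1e-12)
  expect_true(thr$neo_cutoff <= 0 && thr$paleo_cutoff >= 0)
})

test_that("a half with too few scores leaves that category empty", {
  s <- c(a = 0.5, b = 1, c = 2, d = 9, e = 10, f = -1)
  expect_warning(score_thresholds(s), "negative")
  thr <- suppressWarnings(score_thresholds(s))
  expect_true(is.na(thr$neo_cutoff))
  expect_false(is.na(thr$paleo_cutoff))
  cats <- classify_branches(names(s), s, thr)
  expect_equal(unname(cats[["f"]]), "meso")  # would-be neo falls to meso
  expect_equal(sum(cats == "neo"), 0L)
})

test_that("classification respects inclusive cutoffs and zero goes to meso", {
  s <- c(n1 = -5, z = 0, m1 = 0.5, p1 = 5)
  thr <- list(neo_cutoff = -5, paleo_cutoff = 5)
  cats <- classify_branches(names(s), s, thr)
  expect_equal(unname(cats), c("neo", "meso", "meso", "paleo"))
  # outside the endemic set: none, regardless of score
  cats2 <- classify_branches(c("n1"), s, thr)
  expect_equal(unname(cats2[c("z", "m1", "p1")]), rep("none", 3))
})

test_that("selection keeps branches at or beyond the range-restriction elbow", {
  # three range-restricted branches stand out of a featureless background
  # whose ranked curve declines almost linearly
  rwct <- c(r1 = 1, r2 = 1, r3 = 1,
            setNames(seq(0.9, 0.01, length.out = 40), paste0("w", 1:40)))
  sel <- select_highly_endemic(rwct)
  expect_setequal(sel$selected, c("r1", "r2", "r3"))
  expect_equal(sel$cutoff, 1)
  # degenerate: all range sizes equal
  flat <- setNames(rep(0.5, 10), paste0("b", 1:10))
  sel2 <- expect_warning(select_highly_endemic(flat), "degenerate")
  expect_length(sel2$selected, 0L)
})

test_that("long/short/medium single-cell branches classify paleo/neo/meso", {
  # three highly range-restricted terminals on an otherwise widespread
  # tree: one much longer than the equal share (paleo), one much shorter
  # (neo), one about equal (meso)
  toy <- toy_three_endemics()
  fit <- suppressWarnings(rwibald(toy$tree, toy$occ))
  b <- branch_table(fit)
  expect_equal(b$category[b$branch_id == "Blue"], "paleo")
  expect_equal(b$category[b$branch_id == "Red"], "neo")
  expect_equal(b$category[b$branch_id == "Yellow"], "meso")
})
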