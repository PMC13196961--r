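test_that("comparison lengths share total length equally and conserve it", {
  tree <- read_phylogeny("((A:1,B:2):3,C:4);")
  ct <- comparison_lengths(tree)
  expect_equal(unname(ct), rep(2.5, 4))
  # equal-length tree is a fixed point
  eq <- read_phylogeny("((A:2,B:2):2,C:2);")
  expect_equal(unname(comparison_lengths(eq)), rep(2, 4))
  # conservation on random trees
  for (seed in 1:5) {
    phy <- ape::rtree(30)
    tr <- as_rwb_tree(phy)
    expect_equal(sum(comparison_lengths(tr)), sum(observed_lengths(tr)),
                 tolerance = 1e-9)
  }
  zero <- ape::rtree(4)
  zero$edge.length[] <- 0
  expect_error(comparison_lengths(as_rwb_tree(zero)), "degenerate")
})

test_that("range weighting divides by range size and is scale-equivariant", {
  L <- c(a = 4, b = 4, c = 3)
  r <- c(a = 1L, b = 8L, c = 1L)
  expect_equal(range_weight(L, r), c(a = 4, b = 0.5, c = 3))
  # all ranges 1: identity
  expect_equal(range_weight(L, c(a = 1L, b = 1L, c = 1L)), L)
  # scale equivariance
  expect_equal(range_weight(5 * L, r), 5 * range_weight(L, r))
  # invalid ranges rejected by name
  expect_error(range_weight(L, c(a = 1L, b = 0L, c = 1L)), "b")
  expect_error(range_weight(L, c(a = 1L, c = 1L)), "b")
})

test_that("per-branch PE contributions sum back to the unweighted length", {
  inst <- random_instance(n_tips = 10, n_cells = 8, seed = 42)
  rg <- branch_ranges(inst$tree, inst$occ)
  ot <- observed_lengths(rg$tree)
  rwot <- range_weight(ot, rg)
  for (b in names(rwot)) {
    expect_equal(rwot[[b]] * rg$size[[b]], ot[[b]], tolerance = 1e-9)
  }
})

test_that("cell PE equals the exhaustive branch-by-cell sum", {
  inst <- random_instance(n_tips = 10, n_cells = 6, seed = 7)
  rg <- branch_ranges(inst$tree, inst$occ)
  rwot <- range_weight(observed_lengths(rg$tree), rg)
  pe <- pe_scores(rwot, rg)
  for (cl in names(pe)) {
    manual <- 0
    for (b in names(rwot)) {
      if (cl %in% rg$cells[[b]]) manual <- manual + rwot[[b]]
    }
    expect_equal(pe[[cl]], manual, tolerance = 1e-12)
  }
  # a single terminal alone in a private cell contributes its full length
  tree <- read_phylogeny("((A:1,B:1):1,C:4);")
  occ <- occurrence_table(data.frame(terminal = c("A", "B", "C"),
                                     cell = c("c1", "c1", "c2")))
  rg2 <- branch_ranges(tree, occ)
  rwot2 <- range_weight(observed_lengths(rg2$tree), rg2)
  expect_equal(pe_scores(rwot2, rg2)[["c2"]], 4)
  expect_error(pe_scores(rwot2, rg2, cells = "nowhere"), "unknown")
})
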