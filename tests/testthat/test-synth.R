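test_that("identical seeds give byte-identical serialized instances", {
  s1 <- simulate_endemism(n_tips = 30, kappa = 8, seed = 5)
  s2 <- simulate_endemism(n_tips = 30, kappa = 8, seed = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_instance(s1, d1)
  p2 <- write_instance(s2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  s3 <- simulate_endemism(n_tips = 30, kappa = 8, seed = 6)
  expect_false(identical(write_phylogeny(s1$tree), write_phylogeny(s3$tree)))
})

test_that("generation does not clobber the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(simulate_endemism(n_tips = 20, kappa = 4, seed = 1))
  expect_identical(runif(1), a)
})

test_that("planted branches satisfy their length and range invariants", {
  sim <- simulate_endemism(n_tips = 80, grid_dim = c(8, 8), seed = 3)
  b <- sim$tree$branch
  m <- sum(b$length) / nrow(b)
  p <- sim$params
  occ_n <- table(sim$occurrences$terminal)
  for (i in seq_len(nrow(sim$truth))) {
    cls <- sim$truth$class[i]
    if (cls == "background") next
    id <- sim$truth$branch_id[i]
    L <- b$length[b$branch_id == id]
    expect_equal(occ_n[[id]], 1L)
    switch(cls,
           neo = expect_lte(L, m * p$eps),
           meso = expect_lt(abs(L - m), m * p$delta),
           paleo = expect_gte(L, m * p$kappa))
  }
  # background terminals occupy at least the stated fraction of cells
  bg <- setdiff(terminal_labels(sim$tree), sim$truth$branch_id[
    sim$truth$class != "background"])
  expect_true(all(occ_n[bg] >= ceiling(p$min_range_frac * 64)))
  expect_identical(sim$rng, "Mersenne-Twister")
})

test_that("infeasible parameters are rejected", {
  expect_error(simulate_endemism(n_tips = 8, n_neo = 3, n_meso = 3,
                                 n_paleo = 3, seed = 1), "n_tips")
  expect_error(simulate_endemism(n_tips = 30, grid_dim = c(3, 3),
                                 n_neo = 4, n_meso = 4, n_paleo = 4,
                                 seed = 1), "grid")
  expect_error(simulate_endemism(n_tips = 30, eps = 2, seed = 1),
               "multipliers")
  expect_error(simulate_endemism(n_tips = 20, kappa = 40,
                                 n_paleo = 1, n_neo = 0, n_meso = 0,
                                 seed = 1), "kappa|multipliers")
})

test_that("confined clades yield internal branches with range one", {
  sim <- simulate_endemism(n_tips = 60, n_confined_clades = 2, seed = 8)
  expect_gt(length(sim$params$confined_terminals), 0L)
  rg <- branch_ranges(sim$tree, sim$occurrences)
  b <- sim$tree$branch
  confined <- sim$params$confined_terminals
  # the parent branch of a confined cherry is internal with range 1
  internal_r1 <- names(rg$size)[rg$size == 1L &
                                  !b$is_terminal[match(names(rg$size),
                                                       b$branch_id)]]
  expect_gt(length(internal_r1), 0L)
  expect_true(all(rg$size[confined] == 1L))
})
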