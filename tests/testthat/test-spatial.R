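sim_fit <- local({
  sim <- simulate_endemism(n_tips = 50, grid_dim = c(5, 5),
                           n_neo = 2, n_meso = 2, n_paleo = 2, seed = 11)
  list(sim = sim, fit = rwibald(sim$tree, sim$occurrences))
})

test_that("cell rosters contain exactly the endemic branches present", {
  fit <- sim_fit$fit
  comp <- cell_composition(fit)
  b <- branch_table(fit)
  # every occupied cell is present, including empty-roster cells
  all_cells <- sort(unique(unlist(fit$ranges$cells, use.names = FALSE)))
  expect_identical(comp$cell_id, all_cells)
  detail <- attr(comp, "detail")
  endemic <- b$branch_id[b$highly_endemic]
  for (cl in comp$cell_id) {
    expected <- endemic[vapply(endemic, function(bb)
      cl %in% fit$ranges$cells[[bb]], logical(1L))]
    expect_setequal(detail$branch_id[detail$cell_id == cl], expected)
  }
  # counts equal roster tallies
  for (i in seq_len(nrow(comp))) {
    d <- detail[detail$cell_id == comp$cell_id[i], ]
    expect_equal(comp$n_neo[i], sum(d$category == "neo"))
    expect_equal(comp$n_meso[i], sum(d$category == "meso"))
    expect_equal(comp$n_paleo[i], sum(d$category == "paleo"))
  }
})

test_that("roster consistency: cell appearances sum to range size", {
  fit <- sim_fit$fit
  detail <- attr(cell_composition(fit), "detail")
  b <- branch_table(fit)
  for (bb in b$branch_id[b$highly_endemic]) {
    expect_equal(sum(detail$branch_id == bb), b$range_size[b$branch_id == bb])
  }
})

test_that("a planted singleton's private cell counts exactly one endemic", {
  sim <- sim_fit$sim
  fit <- sim_fit$fit
  comp <- cell_composition(fit)
  neo_tip <- sim$truth$branch_id[sim$truth$class == "neo"][1L]
  cell <- fit$ranges$cells[[neo_tip]]
  expect_length(cell, 1L)
  row <- comp[comp$cell_id == cell, ]
  expect_gte(row$n_neo, 1L)
  expect_true(grepl(paste0(neo_tip, ":neo"), row$roster))
  expect_gt(row$pe, 0)
})

test_that("category cell unions match the branch range records", {
  fit <- sim_fit$fit
  b <- branch_table(fit)
  for (cat in c("neo", "meso", "paleo")) {
    ids <- b$branch_id[b$category == cat & b$is_terminal]
    expected <- sort(unique(unlist(fit$ranges$cells[ids], use.names = FALSE)))
    expect_identical(category_cells(fit, cat), expected)
    # all-branch variant is a superset
    expect_true(all(expected %in%
                      category_cells(fit, cat, terminal_only = FALSE)))
  }
})

test_that("per-cell counts are invariant to branch iteration order", {
  fit <- sim_fit$fit
  fit2 <- fit
  perm <- rev(seq_len(nrow(fit$branch)))
  fit2$branch <- fit$branch[perm, ]
  fit2$ranges$cells <- fit$ranges$cells[rev(names(fit$ranges$cells))]
  fit2$ranges$size <- fit$ranges$size[rev(names(fit$ranges$size))]
  c1 <- cell_composition(fit)
  c2 <- cell_composition(fit2)
  # pe sums may differ by float addition order; everything else exactly
  expect_identical(c1$roster, c2$roster)
  expect_identical(c1[c("cell_id", "n_neo", "n_meso", "n_paleo")],
                   c2[c("cell_id", "n_neo", "n_meso", "n_paleo")])
  expect_equal(c1$pe, c2$pe, tolerance = 1e-12)
})
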