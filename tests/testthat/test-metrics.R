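test_that("grid PD applies the spanning-subtree and single-species rules", {
  tr <- tree_abc()
  occ <- occupancy_table(c("A", "B", "C", "C"), c("all", "all", "all", "lone"))
  pd <- suppressMessages(grid_pd(tr, occ))
  expect_equal(unname(pd["all"]), total_pd(tr))
  expect_equal(unname(pd["lone"]), 4)  # C alone: TBL only

  for (s in 1:5) {
    ds <- rand_instance(300 + s)
    expect_map_equal(grid_pd(ds$tree, ds$occupancy),
                     oracle_grid_pd(ds$tree, ds$occupancy))
  }
})

test_that("residual PD are OLS residuals of PD on richness", {
  # PD exactly linear in richness -> all residuals zero
  rich <- c(a = 1, b = 2, c = 3, d = 4)
  pd <- 2 + 3 * rich
  expect_equal(unname(residual_pd(pd, rich)), rep(0, 4), tolerance = 1e-12)

  # 5-cell toy vs closed-form normal equations
  x <- c(a = 1, b = 2, c = 3, d = 5, e = 9)
  y <- c(a = 2, b = 1, c = 7, d = 4, e = 11)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  expect_equal(residual_pd(y, x), y - (b0 + b1 * x), tolerance = 1e-12)
  expect_equal(sum(residual_pd(y, x)), 0, tolerance = 1e-12)

  expect_error(residual_pd(y, x[1:3]), "same cells")
  expect_error(residual_pd(c(a = 1, b = 2, c = 3),
                           c(a = 2, b = 2, c = 2)), "constant")
})

test_that("weighted endemism conserves one unit per species", {
  occ <- occupancy_table(c("solo"), c("c9"))
  expect_equal(weighted_endemism(occ), c(c9 = 1))
  ds <- rand_instance(42)
  we <- weighted_endemism(ds$occupancy)
  expect_equal(sum(we), length(unique(ds$occupancy$species)),
               tolerance = 1e-9)
  # double-loop oracle
  occ2 <- ds$occupancy
  ora <- sapply(sort(unique(occ2$cell)), function(cl) {
    sum(sapply(occ2$species[occ2$cell == cl], function(sp)
      1 / length(unique(occ2$cell[occ2$species == sp]))))
  })
  expect_map_equal(we, ora)
})

test_that("EDR shares each species' ED across its range and conserves PD", {
  tr <- tree_abc()
  occ1 <- occupancy_table(c("A", "B", "C"), rep("hub", 3))
  expect_equal(suppressMessages(edr(tr, occ1)), c(hub = total_pd(tr)))

  # toy: A in two cells, B and C in one -> hand-derived shares
  occ2 <- occupancy_table(c("A", "A", "B", "C"),
                          c("c1", "c2", "c1", "c2"))
  got <- suppressMessages(edr(tr, occ2))
  expect_equal(got, c(c1 = 2 / 2 + 2, c2 = 2 / 2 + 4), tolerance = 1e-12)
  expect_equal(sum(got), total_pd(tr), tolerance = 1e-9)
})

test_that("PE divides branch PD equally over occupied cells", {
  fx <- worked_example_fixture()
  p <- suppressMessages(pe(fx$forest, fx$occupancy))
  expect_equal(unname(p[fx$focal]), 10)      # 5 MY from each branch
  expect_equal(unname(p["quiet_a"]), 5)

  # a branch confined to one cell keeps its full length there
  tr <- tree_abc()
  occ <- occupancy_table(c("A", "B", "C"), c("c1", "c1", "c2"))
  got <- suppressMessages(pe(tr, occ))
  expect_equal(got, c(c1 = 1 + 1 + 2, c2 = 4), tolerance = 1e-12)

  for (s in 1:5) {
    ds <- rand_instance(500 + s)
    expect_map_equal(pe(ds$tree, ds$occupancy),
                     oracle_pe(ds$tree, ds$occupancy))
  }
})

test_that("HIPE apportions branch PD by HP weight and reduces to PE", {
  fx <- worked_example_fixture()
  h <- suppressMessages(hipe(fx$forest, fx$occupancy, fx$pressure))
  expect_equal(unname(h[fx$focal]), 10 * 0.2 / 1.2 + 10 * 0.2 / 0.4,
               tolerance = 1e-12)

  for (s in 1:5) {
    ds <- rand_instance(600 + s)
    expect_map_equal(hipe(ds$tree, ds$occupancy, ds$pressure),
                     oracle_hipe(ds$tree, ds$occupancy, ds$pressure))
    # constant pressure -> HIPE == PE cell by cell
    flat <- pressure_grid(ds$pressure$cell, rep(4, nrow(ds$pressure)))
    expect_map_equal(hipe(ds$tree, ds$occupancy, flat),
                     pe(ds$tree, ds$occupancy), tol = 1e-9)
  }
})

test_that("raising a cell's pressure never increases its HIPE", {
  ds <- rand_instance(77)
  h0 <- hipe(ds$tree, ds$occupancy, ds$pressure)
  grid2 <- ds$pressure
  set.seed(1)
  for (cl in sample(names(h0), 5)) {
    g <- pressure_grid(grid2$cell,
                       ifelse(grid2$cell == cl, 50, grid2$hf))
    h1 <- hipe(ds$tree, ds$occupancy, g)
    expect_lte(h1[[cl]], h0[[cl]] + 1e-12)
  }
})

test_that("HIPE/PE ratios respect the pressure-extreme bounds", {
  fx <- worked_example_fixture()
  p <- suppressMessages(pe(fx$forest, fx$occupancy))
  h <- suppressMessages(hipe(fx$forest, fx$occupancy, fx$pressure))
  vh <- hipe_pe_ratio(h, p, fx$pressure, "very_high")
  # branch B is wholly inside very-high cells: its second cell has ratio 1
  expect_equal(unname(vh["busy_b"]), 1, tolerance = 1e-12)
  # the focal cell mixes branch A (1.667/5) and branch B (5/5)
  expect_equal(unname(vh[fx$focal]), (10 * 0.2 / 1.2 + 5) / 10,
               tolerance = 1e-12)
  expect_true(all(vh <= 1 + 1e-12))
  no <- hipe_pe_ratio(h, p, fx$pressure, "none")
  expect_true(all(no >= 1 - 1e-12))
  # a zero-pressure cell sharing branch A with a very-high cell gains share
  expect_gt(unname(no["quiet_a"]), 1)

  # the worked example's branch A alone: focal ratio = (1.667/5) = 1/3
  fa <- list(fx$forest$A)
  occ_a <- occupancy_table(c("sp_A", "sp_A"), c("focal", "quiet_a"))
  ra <- hipe_pe_ratio(hipe(fa, occ_a, fx$pressure), pe(fa, occ_a),
                      fx$pressure, "very_high")
  expect_equal(unname(ra["focal"]), 1 / 3, tolerance = 1e-9)
})

test_that("clade contributions are per-cell proportions summing to one", {
  m <- clade_contribution(list(x = c(a = 2), y = c(a = 2, b = 3)))
  expect_equal(m$proportion[m$cell_id == "a" & m$clade == "x"], 0.5)
  expect_equal(m$proportion[m$cell_id == "b" & m$clade == "y"], 1)
  set.seed(8)
  maps <- list(r = c(a = runif(1), b = runif(1), c = runif(1)),
               s = c(b = runif(1), c = runif(1)),
               t = c(a = runif(1), c = runif(1)))
  got <- clade_contribution(maps)
  for (cl in c("a", "b", "c")) {
    tot <- sum(sapply(maps, function(m) if (cl %in% names(m)) m[[cl]] else 0))
    for (cd in names(maps)) {
      v <- got$proportion[got$cell_id == cl & got$clade == cd]
      exp_v <- (if (cl %in% names(maps[[cd]])) maps[[cd]][[cl]] else 0) / tot
      expect_equal(v, exp_v, tolerance = 1e-12)
    }
  }
})

test_that("cumulative capture bands follow the ranked prefix sums", {
  one <- cumulative_capture(c(a = 0, b = 5, c = 0))
  expect_equal(one$cell_id[1], "b")
  expect_equal(one$band[1], 0.1)

  uni <- cumulative_capture(stats::setNames(rep(1, 10), letters[1:10]))
  expect_equal(uni$band, seq(0.1, 1, by = 0.1))

  set.seed(3)
  m <- stats::setNames(runif(25), paste0("c", 1:25))
  got <- cumulative_capture(m)
  ord <- order(-m, names(m))
  cum <- cumsum(m[ord]) / sum(m)
  prev <- c(0, cum[-25])
  bands <- sapply(prev, function(pi) seq(0.1, 1, 0.1)[
    which(seq(0.1, 1, 0.1) - pi > 1e-12)[1]])
  expect_equal(got$band, unname(bands))
})

test_that("TE and HITE match their defining ratios and bounds", {
  fx <- worked_example_fixture()
  expect_equal(unname(te(fx$forest, fx$occupancy)["sp_H"]), 5)
  expect_equal(unname(hite(fx$forest, fx$occupancy, fx$pressure)["sp_H"]),
               10 / 1.2, tolerance = 1e-12)

  ds <- rand_instance(900)
  expect_equal(te(ds$tree, ds$occupancy),
               oracle_te(ds$tree, ds$occupancy), tolerance = 1e-9)
  h <- hite(ds$tree, ds$occupancy, ds$pressure)
  expect_equal(h, oracle_hite(ds$tree, ds$occupancy, ds$pressure),
               tolerance = 1e-9)
  ratio <- h / te(ds$tree, ds$occupancy)
  expect_true(all(ratio >= 1 - 1e-12 & ratio <= 5 + 1e-12))

  # all weights 1 -> HITE = TE; all weights 0.2 -> HITE = 5 TE
  cells <- sort(unique(ds$occupancy$cell))
  g1 <- pressure_grid(cells, rep(0, length(cells)))
  g5 <- pressure_grid(cells, rep(20, length(cells)))
  expect_equal(hite(ds$tree, ds$occupancy, g1), te(ds$tree, ds$occupancy),
               tolerance = 1e-12)
  expect_equal(hite(ds$tree, ds$occupancy, g5),
               5 * te(ds$tree, ds$occupancy), tolerance = 1e-12)
})

test_that("species score tables rank by HITE with deterministic ties", {
  fx <- worked_example_fixture()
  sc <- species_scores(fx$forest, fx$occupancy, fx$pressure)
  expect_equal(sc$species[sc$rank == 1], "sp_B")  # two 0.2 cells
  expect_equal(sc$hite[sc$rank == 1], 10 / 0.4, tolerance = 1e-12)
  expect_true(all(sc$hite >= sc$te - 1e-12))
  attrs <- data.frame(species = c("sp_A", "sp_B", "sp_H"),
                      iucn_category = c("LC", "DD", "CR"))
  sc2 <- species_scores(fx$forest, fx$occupancy, fx$pressure, attrs)
  expect_equal(sc2$iucn_category[sc2$species == "sp_B"], "DD")
})

test_that("tree-distribution aggregation uses midpoint medians and coverage", {
  tr <- tree_abc()
  single <- aggregate_over_trees(list(tr), function(t) fair_proportion(t))
  expect_equal(stats::setNames(single$median, single$key),
               fair_proportion(tr)[single$key])

  got <- aggregate_over_trees(list(tr, tr, tr), local({
    i <- 0
    vals <- list(c(x = 1), c(x = 2), c(x = 9))
    function(t) { i <<- i + 1; vals[[i]] }
  }))
  expect_equal(got$median, 2)
  got4 <- aggregate_over_trees(list(tr, tr, tr, tr), local({
    i <- 0
    vals <- list(c(x = 1), c(x = 2), c(x = 3), c(x = 4))
    function(t) { i <<- i + 1; vals[[i]] }
  }))
  expect_equal(got4$median, 2.5)
  expect_equal(got4$min, 1)
  expect_equal(got4$max, 4)

  # a key present in under half the trees is flagged, not reported
  sparse <- aggregate_over_trees(list(tr, tr, tr), local({
    i <- 0
    vals <- list(c(x = 1), c(x = 2, y = 5), c(x = 3))
    function(t) { i <<- i + 1; vals[[i]] }
  }))
  expect_equal(sparse$key, "x")
  expect_equal(attr(sparse, "flagged"), "y")
})
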