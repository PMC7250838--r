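# Small fixtures built in code.

tree_abc <- function() read_trees(text = "((A:1,B:1):2,C:4);")

# seeded random instance: tree + contiguous occupancy + pressure surface
rand_instance <- function(seed, n_tips = 15, nrow = 10, ncol = 10, ...) {
  simulate_dataset(n_species = n_tips, nrow = nrow, ncol = ncol,
                   seed = seed, ...)
}

# basal two-clade strata of a simulated tree (tips split at the root)
basal_strata <- function(tree) {
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  cl1 <- if (kids[1] <= length(tree$tip.label)) {
    tree$tip.label[kids[1]]
  } else {
    ape::extract.clade(tree, kids[1])$tip.label
  }
  stats::setNames(ifelse(tree$tip.label %in% cl1, "A", "B"),
                  tree$tip.label)
}

expect_map_equal <- function(map, oracle, tol = 1e-9) {
  expect_setequal(names(map), names(oracle))
  expect_equal(as.numeric(map[names(oracle)]), as.numeric(oracle),
               tolerance = tol)
}
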