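# Independent brute-force oracles: explicit per-tip root walks and double
# loops over branches and cells, sharing no traversal code with the package.

# edge indices on the root-to-tip path of one tip label
oracle_path_edges <- function(tree, sp) {
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  node <- match(sp, tree$tip.label)
  path <- integer(0)
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    path <- c(path, e)
    node <- tree$edge[e, 1]
  }
  path
}

oracle_tbl <- function(tree) {
  sapply(tree$tip.label, function(sp) {
    e <- which(tree$edge[, 2] == match(sp, tree$tip.label))
    tree$edge.length[e]
  })
}

oracle_subtree_pd <- function(tree, species) {
  if (length(species) == 1L) {
    e <- which(tree$edge[, 2] == match(species, tree$tip.label))
    return(tree$edge.length[e])
  }
  marked <- rep(FALSE, nrow(tree$edge))
  for (sp in species) marked[oracle_path_edges(tree, sp)] <- TRUE
  sum(tree$edge.length[marked])
}

# per edge: set of tip labels whose root walk passes through it
oracle_edge_tipsets <- function(tree) {
  sets <- vector("list", nrow(tree$edge))
  for (sp in tree$tip.label) {
    for (e in oracle_path_edges(tree, sp)) sets[[e]] <- c(sets[[e]], sp)
  }
  sets
}

oracle_fair_proportion <- function(tree) {
  sets <- oracle_edge_tipsets(tree)
  share <- tree$edge.length / lengths(sets)
  sapply(tree$tip.label, function(sp)
    sum(share[sapply(sets, function(s) sp %in% s)]))
}

oracle_pd_loss <- function(tree, drop) {
  keep <- setdiff(tree$tip.label, drop)
  marked <- rep(FALSE, nrow(tree$edge))
  for (sp in keep) marked[oracle_path_edges(tree, sp)] <- TRUE
  sum(tree$edge.length) - sum(tree$edge.length[marked])
}

# loop over FULL-tree edges; mapped species only; equal split across cells
oracle_pe <- function(forest, occ) {
  if (inherits(forest, "phylo")) forest <- list(forest)
  out <- numeric(0)
  for (tree in forest) {
    mapped <- intersect(tree$tip.label, occ$species)
    if (!length(mapped)) next
    sets <- oracle_edge_tipsets(tree)
    for (e in seq_along(sets)) {
      sp <- intersect(sets[[e]], mapped)
      if (!length(sp)) next
      cells <- unique(occ$cell[occ$species %in% sp])
      for (cl in cells) {
        v <- tree$edge.length[e] / length(cells)
        out[cl] <- if (is.na(out[cl])) v else out[cl] + v
      }
    }
  }
  out[order(names(out))]
}

oracle_hipe <- function(forest, occ, grid) {
  if (inherits(forest, "phylo")) forest <- list(forest)
  wt <- function(cl) {
    w <- grid$weight[match(cl, grid$cell)]
    w[is.na(w)] <- 1
    w
  }
  out <- numeric(0)
  for (tree in forest) {
    mapped <- intersect(tree$tip.label, occ$species)
    if (!length(mapped)) next
    sets <- oracle_edge_tipsets(tree)
    for (e in seq_along(sets)) {
      sp <- intersect(sets[[e]], mapped)
      if (!length(sp)) next
      cells <- unique(occ$cell[occ$species %in% sp])
      w <- wt(cells)
      for (i in seq_along(cells)) {
        v <- tree$edge.length[e] * w[i] / sum(w)
        cl <- cells[i]
        out[cl] <- if (is.na(out[cl])) v else out[cl] + v
      }
    }
  }
  out[order(names(out))]
}

oracle_grid_pd <- function(forest, occ) {
  if (inherits(forest, "phylo")) forest <- list(forest)
  out <- numeric(0)
  for (tree in forest) {
    for (cl in unique(occ$cell)) {
      sp <- intersect(occ$species[occ$cell == cl], tree$tip.label)
      if (!length(sp)) next
      v <- oracle_subtree_pd(tree, sp)
      out[cl] <- if (is.na(out[cl])) v else out[cl] + v
    }
  }
  out[order(names(out))]
}

oracle_te <- function(tree, occ) {
  tbl <- oracle_tbl(tree)
  mapped <- sort(intersect(names(tbl), occ$species))
  sapply(mapped, function(sp)
    tbl[[sp]] / length(unique(occ$cell[occ$species == sp])))
}

oracle_hite <- function(tree, occ, grid) {
  tbl <- oracle_tbl(tree)
  mapped <- sort(intersect(names(tbl), occ$species))
  sapply(mapped, function(sp) {
    cells <- unique(occ$cell[occ$species == sp])
    w <- grid$weight[match(cells, grid$cell)]
    w[is.na(w)] <- 1
    tbl[[sp]] / sum(w)
  })
}
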