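# Per-cell and per-species diversity metrics.
#
# Cell metric maps are named numeric vectors (cell id -> value, MY for
# PD/PE/HIPE, dimensionless for WE and ratios). All spatial metrics use only
# species present in BOTH the tree(s) and the occupancy table; species
# dropped at the namespace intersection are reported via message(). A forest
# (multiPhylo / list of trees, e.g. separate clade phylogenies) is handled
# by computing per tree and summing per cell; no cross-tree branches are
# fabricated.

# Namespace intersection (D6-style): forest + per-tree mapped species,
# reporting names dropped on either side.
.forest_occ <- function(trees, occ) {
  forest <- .as_forest(trees)
  sp_occ <- unique(occ$species)
  all_tips <- unlist(lapply(forest, `[[`, "tip.label"))
  only_occ <- setdiff(sp_occ, all_tips)
  if (length(only_occ))
    message(length(only_occ),
            " occupancy species absent from the tree(s) were dropped: ",
            paste(utils::head(only_occ, 5L), collapse = ", "),
            if (length(only_occ) > 5L) ", ..." else "")
  only_tree <- setdiff(all_tips, sp_occ)
  if (length(only_tree))
    message(length(only_tree),
            " tree species lack occupancy data and were dropped: ",
            paste(utils::head(only_tree, 5L), collapse = ", "),
            if (length(only_tree) > 5L) ", ..." else "")
  mapped <- lapply(forest, function(t) intersect(t$tip.label, sp_occ))
  if (!length(unlist(mapped)))
    stop("no species shared between tree(s) and occupancy")
  list(forest = forest, mapped = mapped)
}

# Prune a tree down to its mapped species (NULL if none are mapped).
.prune_to_mapped <- function(tree, mapped) {
  if (!length(mapped)) return(NULL)
  if (length(mapped) == length(tree$tip.label)) return(tree)
  prune_tree(tree, setdiff(tree$tip.label, mapped))
}

# Sum (cell, value) contributions into a sorted named vector.
.sum_by_cell <- function(cells, vals) {
  out <- tapply(vals, cells, sum)
  out <- stats::setNames(as.numeric(out), names(out))
  out[order(names(out))]
}

#' Convert a cell metric map to a data.frame
#'
#' @param map Named numeric vector (cell id -> value).
#' @param metric Metric name to record.
#' @return data.frame with columns `cell_id`, `metric`, `value`.
#' @export
cell_map_df <- function(map, metric = "value") {
  data.frame(cell_id = names(map), metric = metric, value = as.numeric(map),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Phylogenetic diversity per grid cell
#'
#' For each cell, the PD of the species present: the summed branch lengths
#' between root and tips of their spanning subtree when two or more species
#' are present, and the terminal branch length alone when a single species
#' is present. Cells whose species all lack tree data are omitted.
#'
#' @param trees A `phylo`, `multiPhylo`, or list of trees (forest metrics
#'   are summed per cell).
#' @param occ An `occupancy` table.
#' @return Named numeric vector of PD in MY per cell.
#' @export
grid_pd <- function(trees, occ) {
  ctx <- .forest_occ(trees, occ)
  cell_sp <- split(occ$species, occ$cell)
  out <- numeric(0)
  for (k in seq_along(ctx$forest)) {
    mapped <- ctx$mapped[[k]]
    if (!length(mapped)) next
    tree <- ctx$forest[[k]]
    for (cell in names(cell_sp)) {
      sp <- intersect(cell_sp[[cell]], mapped)
      if (!length(sp)) next
      v <- subtree_pd(tree, sp)
      out[cell] <- if (is.na(out[cell])) v else out[cell] + v
    }
  }
  out <- out[!is.na(out)]
  out[order(names(out))]
}

#' Residual PD given species richness
#'
#' Ordinary-least-squares residuals of per-cell PD regressed on per-cell
#' species richness. Positive residuals mark cells with more PD than
#' expected for their richness (disproportionately deep assemblages).
#'
#' @param pd Named numeric vector of per-cell PD.
#' @param richness Named numeric vector of per-cell richness on the same
#'   cell set.
#' @return Named numeric vector of residuals (MY); they sum to zero.
#' @export
residual_pd <- function(pd, richness) {
  if (!setequal(names(pd), names(richness)))
    stop("'pd' and 'richness' must cover the same cells")
  if (length(pd) < 3L) stop("need at least 3 cells for a regression")
  x <- as.numeric(richness[names(pd)])
  if (stats::var(x) == 0) stop("richness is constant; regression is singular")
  fit <- stats::lm(as.numeric(pd) ~ x)
  stats::setNames(stats::residuals(fit), names(pd))
}

#' Weighted endemism per grid cell
#'
#' Range-size-weighted species richness: each species contributes the
#' reciprocal of its range size to every cell it occupies, so summed over
#' all cells each species contributes exactly 1.
#'
#' @param occ An `occupancy` table.
#' @return Named numeric vector (dimensionless).
#' @export
weighted_endemism <- function(occ) {
  rs <- table(occ$species)
  .sum_by_cell(occ$cell, 1 / as.numeric(rs[occ$species]))
}

#' Evolutionary distinctiveness rarity per grid cell
#'
#' Fair-proportion ED of each mapped species (computed on the tree pruned to
#' mapped species) divided equally across the cells it occupies. Summed over
#' all cells, EDR equals the total mapped PD.
#'
#' @inheritParams grid_pd
#' @return Named numeric vector in MY.
#' @export
edr <- function(trees, occ) {
  ctx <- .forest_occ(trees, occ)
  sp_cells <- split(occ$cell, occ$species)
  cells <- character(0); vals <- numeric(0)
  for (k in seq_along(ctx$forest)) {
    pt <- .prune_to_mapped(ctx$forest[[k]], ctx$mapped[[k]])
    if (is.null(pt)) next
    ed <- fair_proportion(pt)
    for (sp in names(ed)) {
      cc <- sp_cells[[sp]]
      cells <- c(cells, cc)
      vals <- c(vals, rep(ed[[sp]] / length(cc), length(cc)))
    }
  }
  .sum_by_cell(cells, vals)
}

#' Phylogenetic endemism per grid cell
#'
#' Divides each branch's PD equally across all grid cells in which any of
#' its descendant species occur. Summed over all cells, PE equals the total
#' mapped PD (the spanning subtree of the mapped species, root path
#' included).
#'
#' @inheritParams grid_pd
#' @return Named numeric vector in MY.
#' @export
pe <- function(trees, occ) {
  ctx <- .forest_occ(trees, occ)
  sp_cells <- split(occ$cell, occ$species)
  cells <- character(0); vals <- numeric(0)
  for (k in seq_along(ctx$forest)) {
    pt <- .prune_to_mapped(ctx$forest[[k]], ctx$mapped[[k]])
    if (is.null(pt)) next
    bt <- branch_table(pt)
    for (i in seq_len(nrow(bt))) {
      cc <- unique(unlist(sp_cells[bt$tips[[i]]], use.names = FALSE))
      cells <- c(cells, cc)
      vals <- c(vals, rep(bt$length[i] / length(cc), length(cc)))
    }
  }
  .sum_by_cell(cells, vals)
}

#' Human-impacted phylogenetic endemism per grid cell
#'
#' Apportions each branch's PD across the cells in which its descendants
#' occur in proportion to each cell's HP weight, i.e. cell c receives
#' length(b) * w(c) / sum of w over the branch's cells. Cells under lower
#' human pressure (higher weight) receive a larger share; when all weights
#' are equal HIPE coincides with PE. Conservation holds: summed over cells,
#' HIPE equals total mapped PD.
#'
#' @inheritParams grid_pd
#' @param grid A `pressure_grid`. Cells absent from it get HP weight 1 with
#'   a warning.
#' @return Named numeric vector in MY.
#' @export
hipe <- function(trees, occ, grid) {
  ctx <- .forest_occ(trees, occ)
  sp_cells <- split(occ$cell, occ$species)
  wts <- .cell_weights(sort(unique(occ$cell)), grid)
  cells <- character(0); vals <- numeric(0)
  for (k in seq_along(ctx$forest)) {
    pt <- .prune_to_mapped(ctx$forest[[k]], ctx$mapped[[k]])
    if (is.null(pt)) next
    bt <- branch_table(pt)
    for (i in seq_len(nrow(bt))) {
      cc <- unique(unlist(sp_cells[bt$tips[[i]]], use.names = FALSE))
      w <- wts[cc]
      cells <- c(cells, cc)
      vals <- c(vals, bt$length[i] * w / sum(w))
    }
  }
  .sum_by_cell(cells, vals)
}

#' HIPE/PE ratio at a pressure extreme
#'
#' The ratio of HIPE to PE restricted to cells in one of the two extreme
#' pressure categories. For very-high-pressure cells the ratio is at most 1
#' (they can only lose PD share to less impacted cells); a ratio near 1
#' marks PD overwhelmingly confined to very high pressure. For no-pressure
#' cells the ratio is at least 1.
#'
#' @param hipe_map,pe_map Named numeric vectors from [hipe()] and [pe()] on
#'   the same inputs.
#' @param grid A `pressure_grid`.
#' @param extreme `"very_high"` or `"none"`.
#' @return Named numeric vector of ratios over the selected cells; cells
#'   with zero PE are omitted with a warning.
#' @export
hipe_pe_ratio <- function(hipe_map, pe_map, grid,
                          extreme = c("very_high", "none")) {
  extreme <- match.arg(extreme)
  sel <- intersect(grid$cell[as.character(grid$category) == extreme],
                   names(pe_map))
  zero <- sel[pe_map[sel] == 0]
  if (length(zero)) {
    warning("omitting ", length(zero), " cell(s) with zero PE")
    sel <- setdiff(sel, zero)
  }
  h <- hipe_map[sel]
  h[is.na(h)] <- 0
  stats::setNames(as.numeric(h) / as.numeric(pe_map[sel]), sel)
}

#' Per-clade contributions to a combined metric
#'
#' Given per-clade cell maps of the same metric (e.g. HIPE per tetrapod
#' clade), returns each clade's proportional contribution per cell.
#' Proportions sum to 1 in every cell with a positive total.
#'
#' @param maps Named list of cell metric maps.
#' @return Long data.frame with columns `cell_id`, `clade`, `proportion`.
#' @export
clade_contribution <- function(maps) {
  if (is.null(names(maps)) || any(names(maps) == ""))
    stop("'maps' must be a named list of cell maps")
  cells <- sort(unique(unlist(lapply(maps, names))))
  m <- sapply(maps, function(x) {
    v <- x[cells]
    v[is.na(v)] <- 0
    as.numeric(v)
  })
  m <- matrix(m, nrow = length(cells),
              dimnames = list(cells, names(maps)))
  tot <- rowSums(m)
  keep <- tot > 0
  m <- m[keep, , drop = FALSE] / tot[keep]
  data.frame(
    cell_id = rep(rownames(m), times = ncol(m)),
    clade = rep(colnames(m), each = nrow(m)),
    proportion = as.numeric(m),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Cumulative-capture bands of a cell metric map
#'
#' Sorts cells by decreasing value (ties broken by ascending cell id) and
#' assigns each cell the smallest cumulative-share band whose running total
#' first covers it; e.g. with 10% bands, the top cells jointly capturing
#' 10% of the global total fall in band 0.1.
#'
#' @param map Named numeric vector of non-negative values.
#' @param fractions Increasing band boundaries in (0, 1], ending at 1.
#' @return data.frame with columns `cell_id`, `value`, `cumulative`, `band`,
#'   in ranked order.
#' @export
cumulative_capture <- function(map, fractions = seq(0.1, 1, by = 0.1)) {
  if (!length(map)) stop("empty map")
  if (is.unsorted(fractions, strictly = TRUE) || any(fractions <= 0) ||
      any(fractions > 1))
    stop("'fractions' must be strictly increasing in (0, 1]")
  fractions <- unique(c(fractions, 1))
  ord <- order(-map, names(map))
  v <- as.numeric(map[ord])
  cum <- cumsum(v) / sum(v)
  # a cell belongs to the first band it is needed for: the smallest
  # fraction still uncovered before the cell is added
  prev <- c(0, cum[-length(cum)])
  band <- vapply(prev, function(pi)
    fractions[which(fractions - pi > 1e-12)[1]], numeric(1))
  data.frame(cell_id = names(map)[ord], value = v, cumulative = cum,
             band = band, stringsAsFactors = FALSE, row.names = NULL)
}

#' Terminal endemism per species
#'
#' TBL multiplied by the reciprocal of range size: the species-level
#' component common to PE and EDR. Terminal branch lengths are taken from
#' the full tree(s) as supplied, before any intersection with occupancy.
#'
#' @inheritParams grid_pd
#' @return Named numeric vector (MY per cell) over mapped species.
#' @export
te <- function(trees, occ) {
  tbl <- terminal_branch_lengths(trees)
  mapped <- sort(intersect(names(tbl), unique(occ$species)))
  if (!length(mapped)) stop("no species shared between tree(s) and occupancy")
  tbl[mapped] / range_size(mapped, occ)
}

#' Human-impacted terminal endemism per species
#'
#' TBL multiplied by the reciprocal of the species' HP-weighted distribution
#' score. Because HP weights are at most 1, HITE is always at least TE, and
#' at most 5 times TE (weights are at least 0.2): species confined to
#' heavily impacted cells score highest.
#'
#' @inheritParams hipe
#' @return Named numeric vector (MY per weighted cell) over mapped species.
#' @export
hite <- function(trees, occ, grid) {
  tbl <- terminal_branch_lengths(trees)
  mapped <- sort(intersect(names(tbl), unique(occ$species)))
  if (!length(mapped)) stop("no species shared between tree(s) and occupancy")
  sp_cells <- split(occ$cell, occ$species)
  hpw <- vapply(mapped, function(sp)
    hp_weighted_distribution(sp_cells[[sp]], grid), numeric(1))
  tbl[mapped] / hpw
}

#' Species score table
#'
#' Per-species TBL, range size, HP-weighted range, TE and HITE, ranked by
#' HITE (descending, ties broken by species label). Optional attribute data
#' (e.g. IUCN category, clade) are merged by species.
#'
#' @inheritParams hipe
#' @param attributes Optional data.frame with a `species` column plus
#'   attribute columns to carry along.
#' @return data.frame ordered by rank.
#' @export
species_scores <- function(trees, occ, grid, attributes = NULL) {
  tbl <- terminal_branch_lengths(trees)
  mapped <- sort(intersect(names(tbl), unique(occ$species)))
  if (!length(mapped)) stop("no species shared between tree(s) and occupancy")
  sp_cells <- split(occ$cell, occ$species)
  hpw <- vapply(mapped, function(sp)
    hp_weighted_distribution(sp_cells[[sp]], grid), numeric(1))
  rng <- range_size(mapped, occ)
  out <- data.frame(
    species = mapped,
    tbl = as.numeric(tbl[mapped]),
    range = as.integer(rng),
    hp_weighted_range = as.numeric(hpw),
    te = as.numeric(tbl[mapped] / rng),
    hite = as.numeric(tbl[mapped] / hpw),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(attributes)) {
    if (!("species" %in% names(attributes)))
      stop("'attributes' must have a 'species' column")
    out <- merge(out, attributes, by = "species", all.x = TRUE, sort = FALSE)
  }
  out <- out[order(-out$hite, out$species), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Aggregate a metric over a tree distribution
#'
#' Applies a per-tree metric across a distribution of phylogenies (e.g. 100
#' posterior trees) and summarises per key (cell or species) by median, min
#' and max. The even-count median is the midpoint of the central pair. Keys
#' present in fewer than `min_prop` of the trees are dropped and recorded in
#' the `"flagged"` attribute.
#'
#' @param trees A `multiPhylo` or list of `phylo`.
#' @param metric_fun Function taking a tree as first argument and returning
#'   a named numeric vector.
#' @param ... Further fixed arguments to `metric_fun`.
#' @param min_prop Minimum proportion of trees a key must appear in.
#' @return data.frame with columns `key`, `n`, `median`, `min`, `max`.
#' @export
aggregate_over_trees <- function(trees, metric_fun, ..., min_prop = 0.5) {
  forest <- .as_forest(trees)
  vals <- lapply(forest, function(t) metric_fun(t, ...))
  keys <- sort(unique(unlist(lapply(vals, names))))
  per <- lapply(keys, function(k)
    unlist(lapply(vals, function(v) unname(v[k])), use.names = FALSE))
  per <- lapply(per, function(v) v[!is.na(v)])
  n <- lengths(per)
  keep <- n >= min_prop * length(forest)
  out <- data.frame(
    key = keys[keep],
    n = as.integer(n[keep]),
    median = vapply(per[keep], stats::median, numeric(1)),
    min = vapply(per[keep], min, numeric(1)),
    max = vapply(per[keep], max, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "flagged") <- keys[!keep]
  out
}
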