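# Randomization tests and extinction-scenario PD loss.

#' Top-fraction cells of a metric map
#'
#' The `ceiling(fraction * n)` highest-valued cells, with ties broken by
#' ascending cell id for reproducibility.
#'
#' @param map Named numeric vector (cell id -> value).
#' @param fraction Fraction of cells to select, in (0, 1).
#' @return Character vector of cell ids.
#' @export
top_cells <- function(map, fraction) {
  if (!length(map)) stop("empty map")
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  n <- ceiling(fraction * length(map))
  ord <- order(-map, names(map))
  names(map)[ord][seq_len(n)]
}

#' Human-pressure overlap of a cell set
#'
#' Proportions of the given cells falling under high-or-very-high pressure
#' (HF >= 6), under low-or-no pressure (HF < 3), and in each of the five
#' pressure categories.
#'
#' @param cells Character vector of cell ids, all present in `grid`.
#' @param grid A `pressure_grid`.
#' @return List with elements `hf_ge6`, `hf_lt3` (scalars in \[0, 1\]) and
#'   `by_category` (named proportions summing to 1).
#' @export
pressure_overlap <- function(cells, grid) {
  cells <- unique(as.character(cells))
  idx <- match(cells, grid$cell)
  if (anyNA(idx))
    stop("cells absent from pressure grid: ",
         paste(cells[is.na(idx)], collapse = ", "))
  hf <- grid$hf[idx]
  cat <- factor(as.character(grid$category[idx]),
                levels = c("none", "low", "moderate", "high", "very_high"))
  list(
    hf_ge6 = mean(hf >= 6),
    hf_lt3 = mean(hf < 3),
    by_category = prop.table(table(cat))
  )
}

.null_dist <- function(replicates, observed, reps, seed) {
  structure(list(replicates = replicates, observed = observed,
                 reps = reps, seed = seed),
            class = "hipe_null")
}

#' @export
print.hipe_null <- function(x, ...) {
  cat("Null distribution:", x$reps, "replicates (seed", x$seed, ")\n")
  cat("  observed:", format(x$observed), "\n")
  cat("  null mean:", format(mean(x$replicates)),
      " 2.5/97.5%:", paste(format(stats::quantile(
        x$replicates, c(0.025, 0.975))), collapse = " / "), "\n")
  invisible(x)
}

#' Pressure-randomization null for top-cell overlap
#'
#' Tests whether the top-valued cells of a metric map coincide with high
#' human pressure more than expected if pressure were randomly placed.
#' Observed Human Footprint values are permuted (sampled without
#' replacement) across the cells of the grid -- the occupied-cell universe
#' the grid should be restricted to -- and the proportion of top cells
#' with HF >= 6 is recomputed per replicate.
#'
#' @param map Named numeric vector; its cells must all be in `grid`.
#' @param grid A `pressure_grid` over the occupied-cell universe.
#' @param fraction Top fraction of cells, in (0, 1).
#' @param reps Number of permutations.
#' @param seed Integer seed.
#' @return A `hipe_null` with the observed HF >= 6 overlap attached.
#' @export
randomize_pressure_null <- function(map, grid, fraction = 0.1,
                                    reps = 1000L, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (reps < 1L) stop("'reps' must be >= 1")
  top <- top_cells(map, fraction)
  observed <- pressure_overlap(top, grid)$hf_ge6
  idx_top <- match(top, grid$cell)
  if (anyNA(idx_top)) stop("top cells absent from pressure grid")
  set.seed(seed)
  repl <- vapply(seq_len(reps), function(i) {
    hf <- sample(grid$hf)
    mean(hf[idx_top] >= 6)
  }, numeric(1))
  .null_dist(repl, observed, as.integer(reps), seed)
}

#' PD lost by dropping a species set
#'
#' The reduction in total PD when the given species are removed from the
#' tree (or forest): `total_pd(trees) - total_pd(prune(trees, drop))`. At
#' least the summed TBLs of the dropped species, at most the total PD.
#'
#' @param trees A `phylo`, `multiPhylo`, or list of trees.
#' @param drop Character vector of species; must not exhaust any tree.
#' @return Lost PD in MY.
#' @export
pd_loss <- function(trees, drop) {
  forest <- .as_forest(trees)
  drop <- unique(as.character(drop))
  all_tips <- unlist(lapply(forest, `[[`, "tip.label"))
  unknown <- setdiff(drop, all_tips)
  if (length(unknown))
    stop("species not in tree(s): ", paste(unknown, collapse = ", "))
  loss <- 0
  for (tree in forest) {
    d <- intersect(drop, tree$tip.label)
    if (!length(d)) next
    if (length(d) == length(tree$tip.label))
      stop("cannot drop every tip of a tree")
    keep_idx <- match(setdiff(tree$tip.label, d), tree$tip.label)
    cnt <- .edge_tip_counts(tree, keep_idx)
    loss <- loss + sum(tree$edge.length[cnt == 0])
  }
  loss
}

#' Stratified random-extinction null for PD loss
#'
#' Compares the PD lost under an observed extinction set (e.g. all
#' threatened species) with losses under random extinction sets of the same
#' size drawn within strata (e.g. taxonomic orders): each replicate drops,
#' within every stratum, a uniform random species set matching the observed
#' count there.
#'
#' @inheritParams pd_loss
#' @param observed_drop Character vector of observed species to drop.
#' @param strata Named character vector mapping species to stratum labels;
#'   the sampling pool is `names(strata)`. Defaults to a single stratum of
#'   all tips.
#' @param reps Number of replicate extinction sets.
#' @param seed Integer seed.
#' @return A `hipe_null` with the observed PD loss attached.
#' @export
random_extinction_null <- function(trees, observed_drop, strata = NULL,
                                   reps = 100L, seed) {
  if (missing(seed)) stop("'seed' is required")
  forest <- .as_forest(trees)
  all_tips <- unlist(lapply(forest, `[[`, "tip.label"))
  observed_drop <- unique(as.character(observed_drop))
  if (length(setdiff(observed_drop, all_tips)))
    stop("observed species not in tree(s)")
  if (is.null(strata))
    strata <- stats::setNames(rep("all", length(all_tips)), all_tips)
  if (is.null(names(strata))) stop("'strata' must be named by species")
  if (length(setdiff(names(strata), all_tips)))
    stop("strata contain species not in the tree(s)")
  if (length(setdiff(observed_drop, names(strata))))
    stop("observed species missing from 'strata'")
  pool <- split(names(strata), as.character(strata))
  need <- table(as.character(strata[observed_drop]))
  over <- names(need)[as.integer(need) > lengths(pool)[names(need)]]
  if (length(over))
    stop("observed count exceeds stratum size in: ",
         paste(over, collapse = ", "))
  observed <- pd_loss(forest, observed_drop)
  set.seed(seed)
  repl <- vapply(seq_len(reps), function(r) {
    d <- unlist(lapply(names(need), function(s)
      sample(pool[[s]], need[[s]])), use.names = FALSE)
    pd_loss(forest, d)
  }, numeric(1))
  .null_dist(repl, observed, as.integer(reps), seed)
}

#' PD-loss range under data-deficiency extinction scenarios
#'
#' Summarises PD loss across a tree distribution when unassessed or
#' data-deficient candidate species go extinct under one of three scenarios:
#' `single_min` (per tree, the smallest loss over single-candidate
#' extinctions -- the best case), `random_subset` (per replicate, a uniform
#' random subset size then a uniform subset), or `all` (every candidate
#' lost -- the worst case).
#'
#' @param trees A `multiPhylo`, list of trees, or single `phylo`.
#' @param candidates Character vector of candidate species; intersected with
#'   each tree's tips (missing names are reported).
#' @param mode One of `"single_min"`, `"random_subset"`, `"all"`.
#' @param reps Replicates per tree for `random_subset`.
#' @param seed Integer seed (required for `random_subset`).
#' @return List with `mode`, `min`, `median`, `max`, and the raw `values`.
#' @export
scenario_loss_range <- function(trees, candidates,
                                mode = c("single_min", "random_subset", "all"),
                                reps = 100L, seed = NULL) {
  mode <- match.arg(mode)
  forest <- .as_forest(trees)
  candidates <- unique(as.character(candidates))
  if (!length(candidates)) stop("'candidates' must be non-empty")
  if (mode == "random_subset") {
    if (is.null(seed)) stop("'seed' is required for mode 'random_subset'")
    set.seed(seed)
  }
  values <- numeric(0)
  any_present <- FALSE
  for (tree in forest) {
    cand <- intersect(candidates, tree$tip.label)
    if (length(cand) < length(candidates))
      message(length(candidates) - length(cand),
              " candidate(s) absent from a tree were skipped there")
    if (!length(cand)) next
    any_present <- TRUE
    values <- c(values, switch(mode,
      single_min = min(vapply(cand, function(s) pd_loss(tree, s),
                              numeric(1))),
      all = pd_loss(tree, cand),
      random_subset = vapply(seq_len(reps), function(r) {
        k <- sample.int(length(cand), 1L)
        pd_loss(tree, sample(cand, k))
      }, numeric(1))
    ))
  }
  if (!any_present) stop("no candidate occurs in any tree")
  list(mode = mode, min = min(values), median = stats::median(values),
       max = max(values), values = values)
}
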