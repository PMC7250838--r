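# Tree primitives for phylogenetic-diversity accounting.
#
# Trees are ape "phylo" objects (rooted, branch lengths in millions of years).
# Pruned trees may contain a singleton root node (a root with a single child)
# because the stem above the retained species' most recent common ancestor is
# part of their spanning-subtree PD; all traversals here tolerate singletons,
# unlike some of ape's C-level routines.

#' Read rooted phylogenies from Newick or NEXUS input
#'
#' Parses a single tree or a multi-tree file (one Newick string per line, or
#' a NEXUS trees block). Every edge must carry a branch length; trees without
#' complete branch lengths, with duplicated tip labels, or that are unrooted
#' are rejected. An explicit root edge (e.g. a trailing `:0` before the
#' semicolon) is retained on the object but excluded from [total_pd()] and
#' all downstream metrics, which operate on the ingroup tree.
#'
#' @param file Path to a Newick or NEXUS file. Exactly one of `file`/`text`.
#' @param text A Newick string (possibly several, newline-separated).
#' @return A `phylo` object, or a `multiPhylo` list when the input contains
#'   more than one tree.
#' @examples
#' tr <- read_trees(text = "((A:1,B:1):1,C:2);")
#' total_pd(tr)
#' @export
read_trees <- function(file = NULL, text = NULL) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' or 'text'")
  if (!is.null(file)) {
    if (!file.exists(file)) stop("no such file: ", file)
    first <- readLines(file, n = 1L, warn = FALSE)
    tr <- if (grepl("^\\s*#NEXUS", first, ignore.case = TRUE)) {
      ape::read.nexus(file)
    } else {
      ape::read.tree(file)
    }
  } else {
    tr <- ape::read.tree(text = text)
  }
  if (is.null(tr)) stop("could not parse tree input")
  if (inherits(tr, "multiPhylo")) {
    lapply(tr, .validate_phylo)
  } else {
    .validate_phylo(tr)
  }
  tr
}

.validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; all edges must carry a length")
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths on some edges")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  roots <- unique(tree$edge[!(tree$edge[, 1] %in% tree$edge[, 2]), 1])
  if (length(roots) != 1L) stop("tree must have exactly one root")
  invisible(tree)
}

# root node id (singleton-safe; does not assume ntip+1 ordering)
.root_node <- function(tree) {
  unique(tree$edge[!(tree$edge[, 1] %in% tree$edge[, 2]), 1])
}

# Edge indices ordered so that every edge appears after all edges below it
# (children before parents). Works on trees with singleton nodes.
.postorder_edges <- function(tree) {
  E <- tree$edge
  nmax <- max(E)
  kids <- split(seq_len(nrow(E)), factor(E[, 1], levels = seq_len(nmax)))
  root <- .root_node(tree)
  pre <- integer(nrow(E))
  top <- 0L
  stack <- kids[[root]]
  while (length(stack)) {
    e <- stack[length(stack)]
    stack <- stack[-length(stack)]
    top <- top + 1L
    pre[top] <- e
    stack <- c(stack, kids[[E[e, 2]]])
  }
  rev(pre)
}

# Per-edge count of marked tips descending from the edge.
.edge_tip_counts <- function(tree, tip_idx) {
  E <- tree$edge
  cnt <- numeric(max(E))
  cnt[tip_idx] <- 1
  for (e in .postorder_edges(tree))
    cnt[E[e, 1]] <- cnt[E[e, 1]] + cnt[E[e, 2]]
  cnt[E[, 2]]
}

#' Total phylogenetic diversity of a tree or forest
#'
#' Faith's PD of the whole tree: the sum of all branch lengths (any explicit
#' root edge excluded). For a forest (a `multiPhylo` or list of trees, e.g.
#' separate clade phylogenies analysed jointly) the per-tree totals are
#' summed; no connecting branches between trees are fabricated, so forest
#' totals are conservative.
#'
#' @param trees A `phylo`, `multiPhylo`, or list of `phylo`.
#' @return Total branch length in MY.
#' @export
total_pd <- function(trees) {
  sum(vapply(.as_forest(trees), function(t) sum(t$edge.length), numeric(1)))
}

#' Terminal branch lengths
#'
#' Length of each species' pendant edge: its unique, unshared contribution to
#' PD. Computed on the tree as supplied; for species-level scores TBLs should
#' be taken from the full tree before any intersection with occupancy data,
#' so that spatial data gaps do not distort branch lengths.
#'
#' @inheritParams total_pd
#' @return Named numeric vector, one entry per tip, in MY.
#' @export
terminal_branch_lengths <- function(trees) {
  out <- lapply(.as_forest(trees), function(tree) {
    ntip <- length(tree$tip.label)
    pend <- tree$edge[, 2] <= ntip
    tbl <- stats::setNames(tree$edge.length[pend],
                           tree$tip.label[tree$edge[pend, 2]])
    tbl[tree$tip.label]
  })
  res <- unlist(unname(out))
  if (anyDuplicated(names(res)))
    stop("duplicate tip labels across forest trees")
  res
}

#' Phylogenetic diversity of a species subset
#'
#' For two or more species, the sum of branch lengths on the union of
#' root-to-tip paths of the species (the root path is included). For a single
#' species the terminal branch length alone is returned; this is the
#' convention used when mapping PD onto grid cells occupied by one species,
#' and it is deliberately discontinuous with the two-species case (see the
#' package vignette).
#'
#' @param tree A `phylo`.
#' @param species Character vector of tip labels (non-empty).
#' @return PD in MY.
#' @export
subtree_pd <- function(tree, species) {
  species <- unique(as.character(species))
  if (!length(species)) stop("'species' must be non-empty")
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (length(species) == 1L)
    return(unname(terminal_branch_lengths(tree)[species]))
  cnt <- .edge_tip_counts(tree, match(species, tree$tip.label))
  sum(tree$edge.length[cnt > 0])
}

#' Branch table of a tree
#'
#' One row per edge with its length and the set of descendant tips; the
#' object that phylogenetic endemism and its variants apportion over grid
#' cells. Lengths sum to [total_pd()].
#'
#' @param tree A `phylo`.
#' @return A data.frame with columns `branch_id`, `length`, and a list column
#'   `tips` (character vectors of descendant tip labels).
#' @export
branch_table <- function(tree) {
  .validate_phylo(tree)
  E <- tree$edge
  desc <- vector("list", max(E))
  ntip <- length(tree$tip.label)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in .postorder_edges(tree))
    desc[[E[e, 1]]] <- c(desc[[E[e, 1]]], desc[[E[e, 2]]])
  out <- data.frame(
    branch_id = sprintf("b%d_%d", E[, 1], E[, 2]),
    length = tree$edge.length,
    stringsAsFactors = FALSE
  )
  out$tips <- lapply(E[, 2], function(ch) tree$tip.label[sort(desc[[ch]])])
  out
}

#' Fair-proportion evolutionary distinctiveness
#'
#' Divides each branch's length equally among its descendant tips and sums
#' per tip. ED scores sum to the total PD of the tree.
#'
#' @param tree A `phylo`.
#' @return Named numeric vector of ED scores in MY.
#' @export
fair_proportion <- function(tree) {
  .validate_phylo(tree)
  E <- tree$edge
  ntip <- length(tree$tip.label)
  nd <- .edge_tip_counts(tree, seq_len(ntip))
  po <- .postorder_edges(tree)
  val <- numeric(max(E))
  for (e in rev(po))  # preorder: parents before children
    val[E[e, 2]] <- val[E[e, 1]] + tree$edge.length[e] / nd[e]
  stats::setNames(val[seq_len(ntip)], tree$tip.label)
}

#' Prune species from a tree, preserving spanning-subtree PD
#'
#' Drops the given tips and merges the resulting unbranched chains
#' additively, so that `total_pd(prune_tree(tree, drop))` equals the PD of
#' the spanning subtree of the retained tips, root path included. The stem
#' above the retained species' MRCA is therefore kept (as an edge below a
#' singleton root) rather than discarded; dropping one tip of a cherry
#' reduces total PD by exactly that tip's terminal branch length. Pruning to
#' a single survivor yields a one-tip tree whose sole edge is the survivor's
#' full root-to-tip path.
#'
#' @param tree A `phylo`.
#' @param drop Character vector of tip labels to remove (a proper subset of
#'   the tips; dropping everything is an error).
#' @return A `phylo`.
#' @export
prune_tree <- function(tree, drop) {
  .validate_phylo(tree)
  drop <- unique(as.character(drop))
  tips <- tree$tip.label
  unknown <- setdiff(drop, tips)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (length(drop) == length(tips))
    stop("cannot drop every tip of the tree")
  if (!length(drop)) return(tree)
  keep <- setdiff(tips, drop)
  keep_idx <- sort(match(keep, tips))

  E <- tree$edge
  L <- tree$edge.length
  root <- .root_node(tree)
  cnt <- .edge_tip_counts(tree, keep_idx)
  ke <- which(cnt > 0)

  parent_of <- integer(max(E))
  elen_of <- numeric(max(E))
  parent_of[E[ke, 2]] <- E[ke, 1]
  elen_of[E[ke, 2]] <- L[ke]

  if (length(keep_idx) == 1L) {
    len <- 0
    u <- keep_idx
    while (u != root) {
      len <- len + elen_of[u]
      u <- parent_of[u]
    }
    return(structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = len,
      tip.label = tips[keep_idx],
      Nnode = 1L
    ), class = "phylo"))
  }

  nkids <- tabulate(E[ke, 1], nbins = max(E))
  branching <- setdiff(which(nkids >= 2L), keep_idx)
  internal <- unique(c(root, sort(branching)))
  retained <- c(keep_idx, internal)
  is_retained <- logical(max(E))
  is_retained[retained] <- TRUE

  new_id <- integer(max(E))
  new_id[keep_idx] <- seq_along(keep_idx)
  new_id[internal] <- length(keep_idx) + seq_along(internal)

  heads <- setdiff(retained, root)
  new_edge <- matrix(0L, length(heads), 2L)
  new_len <- numeric(length(heads))
  for (i in seq_along(heads)) {
    v <- heads[i]
    len <- elen_of[v]
    p <- parent_of[v]
    while (!is_retained[p]) {
      len <- len + elen_of[p]
      p <- parent_of[p]
    }
    new_edge[i, ] <- c(new_id[p], new_id[v])
    new_len[i] <- len
  }
  structure(list(
    edge = new_edge,
    edge.length = new_len,
    tip.label = tips[keep_idx],
    Nnode = length(internal)
  ), class = "phylo")
}

#' Rarefy a tree to a fixed taxonomic completeness
#'
#' Randomly retains `round(f * ntip)` tips, repeated `reps` times, producing
#' a tree distribution; used to equalize sampling completeness across clades
#' before comparing PD-based metrics.
#'
#' @param tree A `phylo`.
#' @param target_fraction Fraction of tips to retain, in (0, 1].
#' @param reps Number of rarefied trees.
#' @param seed Integer seed; results are reproducible.
#' @return A `multiPhylo` of length `reps`.
#' @export
rarefy_tree <- function(tree, target_fraction, reps = 100L, seed) {
  .validate_phylo(tree)
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction > 1)
    stop("'target_fraction' must be in (0, 1]")
  if (reps < 1L) stop("'reps' must be >= 1")
  if (missing(seed)) stop("'seed' is required")
  n <- length(tree$tip.label)
  m <- round(target_fraction * n)
  if (m < 1L)
    stop("'target_fraction' retains no tips at this tree size")
  set.seed(seed)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    keep <- sample(tree$tip.label, m)
    out[[r]] <- prune_tree(tree, setdiff(tree$tip.label, keep))
  }
  class(out) <- "multiPhylo"
  out
}

# Coerce a phylo / multiPhylo / list of phylo into a plain list of phylo.
.as_forest <- function(trees) {
  if (inherits(trees, "phylo")) return(list(trees))
  if (inherits(trees, "multiPhylo")) return(unclass(trees))
  if (is.list(trees) && length(trees) &&
      all(vapply(trees, inherits, logical(1), "phylo")))
    return(trees)
  stop("expected a 'phylo', 'multiPhylo', or list of 'phylo' objects")
}
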