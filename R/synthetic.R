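# Synthetic-data generators.
#
# These emulate the statistical structure the metrics are designed around:
# ultrametric trees whose terminal branch lengths are heavy-tailed,
# spatially contiguous geographic ranges with a heavy-tailed (log-normal)
# range-size distribution and optional phylogenetic signal in range size,
# and spatially autocorrelated Human Footprint surfaces. All generators are
# deterministic under their seed.

#' Simulate an ultrametric pure-birth tree
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per MY.
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (n_tips < 2L) stop("'n_tips' must be >= 2")
  set.seed(seed)
  ape::rphylo(n_tips, birth = birth_rate, death = 0)
}

# grid cell ids laid out row-major on an nrow x ncol lattice
.grid_cells <- function(nrow, ncol) {
  as.vector(t(outer(seq_len(nrow), seq_len(ncol),
                    function(r, c) paste0("c", r, "_", c))))
}

# 4-neighbourhood of a row-major linear index
.neighbors <- function(idx, nrow, ncol) {
  r <- (idx - 1L) %/% ncol + 1L
  c <- (idx - 1L) %% ncol + 1L
  out <- integer(0)
  if (r > 1L) out <- c(out, idx - ncol)
  if (r < nrow) out <- c(out, idx + ncol)
  if (c > 1L) out <- c(out, idx - 1L)
  if (c < ncol) out <- c(out, idx + 1L)
  out
}

# contiguous region of `size` cells grown by uniform frontier sampling
.grow_region <- function(nrow, ncol, size, start) {
  inreg <- logical(nrow * ncol)
  region <- integer(size)
  region[1L] <- start
  inreg[start] <- TRUE
  frontier <- .neighbors(start, nrow, ncol)
  i <- 1L
  while (i < size && length(frontier)) {
    nxt <- frontier[sample.int(length(frontier), 1L)]
    i <- i + 1L
    region[i] <- nxt
    inreg[nxt] <- TRUE
    frontier <- unique(c(frontier, .neighbors(nxt, nrow, ncol)))
    frontier <- frontier[!inreg[frontier]]
  }
  region[seq_len(i)]
}

#' Simulate species occupancy on a grid
#'
#' Every species receives a contiguous block of cells (grown by random
#' frontier expansion) or, optionally, a scattered random cell set. Log
#' range sizes are a convex mixture of a Brownian-motion trait evolved
#' along the tree and independent noise, so `signal` interpolates between
#' phylogenetically independent (0) and fully heritable (1) range sizes:
#' `z = sqrt(signal) * z_phylo + sqrt(1 - signal) * z_indep`, and range size
#' is `round(exp(meanlog + sdlog * z))` clamped to the grid.
#'
#' @param tree A `phylo` providing the species and their relatedness.
#' @param nrow,ncol Grid dimensions.
#' @param meanlog,sdlog Log-normal range-size parameters (cells). Defaults
#'   give a heavy-tailed distribution with median 4 cells.
#' @param signal Phylogenetic-signal strength for log range size in
#'   \[0, 1\].
#' @param contiguous Grow contiguous ranges (default) or scatter cells.
#' @param seed Integer seed.
#' @return An `occupancy` table covering all tips.
#' @export
simulate_occupancy <- function(tree, nrow, ncol, meanlog = log(4),
                               sdlog = 1, signal = 0.4, contiguous = TRUE,
                               seed) {
  if (missing(seed)) stop("'seed' is required")
  if (signal < 0 || signal > 1) stop("'signal' must be in [0, 1]")
  if (nrow < 1L || ncol < 1L) stop("grid dimensions must be positive")
  set.seed(seed)
  n <- length(tree$tip.label)
  ncell <- nrow * ncol
  zp <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  zp <- if (stats::sd(zp) > 0) (zp - mean(zp)) / stats::sd(zp) else zp * 0
  zi <- stats::rnorm(n)
  zi <- (zi - mean(zi)) / stats::sd(zi)
  z <- sqrt(signal) * zp + sqrt(1 - signal) * zi
  sizes <- pmin(ncell, pmax(1L, round(exp(meanlog + sdlog * z))))
  cells <- .grid_cells(nrow, ncol)
  sp <- character(0); cc <- character(0)
  for (i in seq_len(n)) {
    reg <- if (contiguous) {
      .grow_region(nrow, ncol, sizes[i], sample.int(ncell, 1L))
    } else {
      sample.int(ncell, sizes[i])
    }
    sp <- c(sp, rep(tree$tip.label[i], length(reg)))
    cc <- c(cc, cells[reg])
  }
  occupancy_table(sp, cc)
}

# row-normalised Gaussian smoothing matrix for one grid axis
.smooth_matrix <- function(n, len) {
  if (len <= 0) return(diag(n))
  if (!is.finite(len)) return(matrix(1 / n, n, n))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-(d^2) / (2 * len^2))
  k / rowSums(k)
}

#' Simulate a spatially autocorrelated Human Footprint surface
#'
#' A Gaussian white-noise field smoothed with a separable Gaussian kernel of
#' the requested correlation length (in cells), rescaled to mean
#' `base_mean`, spread `base_sd`, and clipped to the HF range \[0, 50\];
#' clipping at zero produces genuinely pristine cells. `autocorr_length = 0`
#' yields independent cells; `Inf` yields a constant surface at
#' `base_mean`.
#'
#' @param nrow,ncol Grid dimensions.
#' @param autocorr_length Smoothing length in cells (>= 0, may be `Inf`).
#' @param base_mean,base_sd Location and spread of the HF field before
#'   clipping.
#' @param seed Integer seed.
#' @return A `pressure_grid` covering every grid cell.
#' @export
simulate_hf <- function(nrow, ncol, autocorr_length = 2, base_mean = 8,
                        base_sd = 10, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (autocorr_length < 0) stop("'autocorr_length' must be >= 0")
  set.seed(seed)
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  f <- .smooth_matrix(nrow, autocorr_length) %*% z %*%
    t(.smooth_matrix(ncol, autocorr_length))
  s <- stats::sd(as.vector(f))
  f <- if (s > 1e-12) (f - mean(f)) / s else f * 0
  hf <- pmin(50, pmax(0, base_mean + base_sd * f))
  pressure_grid(.grid_cells(nrow, ncol), as.vector(t(hf)))
}

#' Simulate a complete analysis dataset
#'
#' Bundles a pure-birth tree, contiguous occupancy and an autocorrelated
#' pressure surface under one seed (component seeds are derived as
#' `seed`, `seed + 1`, `seed + 2`).
#'
#' @param n_species Number of species.
#' @param nrow,ncol Grid dimensions.
#' @param birth_rate Speciation rate.
#' @param meanlog,sdlog,signal,contiguous Passed to [simulate_occupancy()].
#' @param autocorr_length,base_mean,base_sd Passed to [simulate_hf()].
#' @param seed Integer seed.
#' @return List with `tree`, `occupancy`, `pressure`, and the `config` used.
#' @export
simulate_dataset <- function(n_species = 40L, nrow = 15L, ncol = 15L,
                             birth_rate = 1, meanlog = log(4), sdlog = 1,
                             signal = 0.4, contiguous = TRUE,
                             autocorr_length = 2, base_mean = 8,
                             base_sd = 10, seed) {
  if (missing(seed)) stop("'seed' is required")
  cfg <- list(n_species = n_species, nrow = nrow, ncol = ncol,
              birth_rate = birth_rate, meanlog = meanlog, sdlog = sdlog,
              signal = signal, contiguous = contiguous,
              autocorr_length = autocorr_length, base_mean = base_mean,
              base_sd = base_sd, seed = seed)
  tree <- simulate_tree(n_species, birth_rate, seed = seed)
  occ <- simulate_occupancy(tree, nrow, ncol, meanlog, sdlog, signal,
                            contiguous, seed = seed + 1L)
  grid <- simulate_hf(nrow, ncol, autocorr_length, base_mean, base_sd,
                      seed = seed + 2L)
  list(tree = tree, occupancy = occ, pressure = grid, config = cfg)
}

#' Simulate threat status with phylogenetic signal
#'
#' Marks roughly `fraction` of the species as threatened, with `signal`
#' controlling how phylogenetically clumped threat is. A Brownian-motion
#' trait is evolved along the tree; for `signal` in (0, 1) species whose
#' mixed trait (`sqrt(signal)` phylogenetic + `sqrt(1 - signal)`
#' independent) exceeds the `1 - fraction` quantile are threatened, for
#' `signal = 0` a uniform random species set is drawn, and for `signal = 1`
#' threat is perfectly clumped: a union of whole clades, chosen in
#' decreasing order of clade-mean trait until the target count is reached
#' (so every threatened group is monophyletic).
#'
#' @param tree A `phylo`.
#' @param fraction Target threatened fraction of species.
#' @param signal Phylogenetic-signal strength in \[0, 1\].
#' @param seed Integer seed.
#' @return Character vector of threatened tip labels.
#' @export
simulate_threat <- function(tree, fraction = 0.3, signal = 1, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (fraction <= 0 || fraction >= 1) stop("'fraction' must be in (0, 1)")
  if (signal < 0 || signal > 1) stop("'signal' must be in [0, 1]")
  set.seed(seed)
  n <- length(tree$tip.label)
  k <- max(1L, round(fraction * n))
  if (signal == 0) return(sample(tree$tip.label, k))
  trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  if (signal < 1) {
    zp <- (trait - mean(trait)) / stats::sd(trait)
    zi <- stats::rnorm(n)
    zi <- (zi - mean(zi)) / stats::sd(zi)
    z <- sqrt(signal) * zp + sqrt(1 - signal) * zi
    return(tree$tip.label[order(-z)][seq_len(k)])
  }
  bt <- branch_table(tree)
  clades <- bt$tips[lengths(bt$tips) >= 2L & lengths(bt$tips) <= k]
  if (!length(clades)) return(tree$tip.label[order(-trait)][seq_len(k)])
  means <- vapply(clades, function(x) mean(trait[x]), numeric(1))
  thr <- character(0)
  for (i in order(-means)) {
    cand <- union(thr, clades[[i]])
    if (length(cand) <= k) thr <- cand
    if (length(thr) >= k - 1L) break
  }
  if (!length(thr)) thr <- clades[[which.max(means)]]
  thr
}

.single_tip_tree <- function(label, length) {
  structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                 edge.length = length,
                 tip.label = label,
                 Nnode = 1L), class = "phylo")
}

#' Two-branch worked-example fixture
#'
#' The canonical small instance for HP-weighted branch apportionment: a
#' focal grid cell under very high pressure (HP weight 0.2) holds two
#' branches of 10 MY each. Branch A also occurs in a pristine cell (weight
#' 1), branch B in a second very-high-pressure cell (weight 0.2). Under PE
#' the focal cell receives 5 MY from each branch; under HIPE it receives
#' 10 * 0.2/1.2 = 1.667 MY from A but still 5 MY from B. A third species
#' with TBL 10 MY occupying one weight-0.2 and one weight-1 cell
#' illustrates the species scores: TE = 5, HITE = 10/1.2 = 8.33.
#' Branches are modelled as single-tip trees so that branch and species
#' coincide exactly.
#'
#' @return List with `forest` (three single-tip trees), `occupancy`,
#'   `pressure`, and `focal` (the focal cell id).
#' @export
worked_example_fixture <- function() {
  forest <- list(
    A = .single_tip_tree("sp_A", 10),
    B = .single_tip_tree("sp_B", 10),
    H = .single_tip_tree("sp_H", 10)
  )
  occ <- occupancy_table(
    species = c("sp_A", "sp_A", "sp_B", "sp_B", "sp_H", "sp_H"),
    cell = c("focal", "quiet_a", "focal", "busy_b", "busy_h", "quiet_h")
  )
  grid <- pressure_grid(
    cell = c("focal", "quiet_a", "busy_b", "busy_h", "quiet_h"),
    hf = c(12, 0, 12, 12, 0)
  )
  list(forest = forest, occupancy = occ, pressure = grid, focal = "focal")
}
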