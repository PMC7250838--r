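# Gridded occupancy and Human Footprint handling.
#
# Grid cells are opaque keys (character); species occupancy is a long-format
# binary incidence table. The Human Footprint (HF) index is a 0-50 composite
# of human pressures per cell; it is categorised into five pressure classes
# and linearly scored with HP weights {1, 0.8, 0.6, 0.4, 0.2}.

#' Build an occupancy table
#'
#' A sparse binary species-by-cell incidence in long format. Duplicate
#' (species, cell) pairs are collapsed; every species must occupy at least
#' one cell.
#'
#' @param species Character vector of species labels.
#' @param cell Character vector of grid-cell ids, same length as `species`.
#' @return A data.frame of class `occupancy` with columns `species`, `cell`.
#' @examples
#' occ <- occupancy_table(c("A", "A", "B"), c("c1", "c2", "c2"))
#' range_size(c("A", "B"), occ)
#' @export
occupancy_table <- function(species, cell) {
  species <- as.character(species)
  cell <- as.character(cell)
  if (length(species) != length(cell))
    stop("'species' and 'cell' must have the same length")
  if (!length(species)) stop("occupancy table must be non-empty")
  if (anyNA(species) || anyNA(cell)) stop("missing values in occupancy")
  df <- unique(data.frame(species = species, cell = cell,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  class(df) <- c("occupancy", "data.frame")
  df
}

#' Read occupancy from CSV
#'
#' Accepts either a long table with two columns (species, cell id) or a wide
#' 0/1 presence-absence matrix whose first column holds species labels and
#' whose remaining column names are cell ids.
#'
#' @param path CSV file path.
#' @param format `"auto"` (two columns means long), `"long"`, or `"wide"`.
#' @return An `occupancy` table.
#' @export
read_occupancy <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "auto") format <- if (ncol(df) == 2L) "long" else "wide"
  if (format == "long") {
    if (ncol(df) < 2L) stop("long occupancy needs two columns")
    occupancy_table(df[[1]], df[[2]])
  } else {
    sp <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    idx <- which(mat != 0, arr.ind = TRUE)
    if (!nrow(idx)) stop("wide occupancy matrix has no presences")
    occupancy_table(sp[idx[, 1]], colnames(mat)[idx[, 2]])
  }
}

#' Species range size in grid cells
#'
#' @param species Character vector of species to look up.
#' @param occ An `occupancy` table.
#' @return Named integer vector of occupied-cell counts.
#' @export
range_size <- function(species, occ) {
  species <- as.character(species)
  tab <- table(occ$species)
  unknown <- setdiff(species, names(tab))
  if (length(unknown))
    stop("species not in occupancy: ", paste(unknown, collapse = ", "))
  stats::setNames(as.integer(tab[species]), species)
}

#' Species richness per grid cell
#'
#' @param occ An `occupancy` table.
#' @return Named integer vector, cell id to species count.
#' @export
grid_richness <- function(occ) {
  tab <- table(occ$cell)
  stats::setNames(as.integer(tab), names(tab))
}

#' Human-pressure category and HP weight for HF values
#'
#' Maps Human Footprint values to the five pressure categories and their
#' linear weights: no pressure (HF = 0) -> 1, low (HF 1-2) -> 0.8, moderate
#' (HF 3-5) -> 0.6, high (HF 6-11) -> 0.4, very high (HF 12-50) -> 0.2.
#' Fractional values (which arise after block-mean upscaling) fall in
#' half-open intervals anchored at the published integer cutoffs: none iff
#' hf = 0 exactly, low iff 0 < hf < 3, moderate iff 3 <= hf < 6, high iff
#' 6 <= hf < 12, very high iff hf >= 12.
#'
#' @param hf Numeric vector of Human Footprint values in [0, 50].
#' @return A data.frame with columns `hf`, `category` (ordered factor
#'   none < low < moderate < high < very_high) and `weight`.
#' @examples
#' hp_weight(c(0, 4, 20))
#' @export
hp_weight <- function(hf) {
  if (anyNA(hf) || any(!is.finite(hf)))
    stop("HF values must be finite and non-missing")
  if (any(hf < 0 | hf > 50)) stop("HF values must lie in [0, 50]")
  lv <- c("none", "low", "moderate", "high", "very_high")
  cat <- ifelse(hf == 0, "none",
         ifelse(hf < 3, "low",
         ifelse(hf < 6, "moderate",
         ifelse(hf < 12, "high", "very_high"))))
  cat <- factor(cat, levels = lv, ordered = TRUE)
  w <- c(none = 1, low = 0.8, moderate = 0.6, high = 0.4, very_high = 0.2)
  data.frame(hf = hf, category = cat, weight = unname(w[as.character(cat)]))
}

#' Build a pressure grid
#'
#' Per-cell Human Footprint values with their pressure category and HP
#' weight.
#'
#' @param cell Character vector of cell ids (unique).
#' @param hf Numeric HF values in [0, 50], same length.
#' @return A data.frame of class `pressure_grid` with columns `cell`, `hf`,
#'   `category`, `weight`.
#' @export
pressure_grid <- function(cell, hf) {
  cell <- as.character(cell)
  if (length(cell) != length(hf))
    stop("'cell' and 'hf' must have the same length")
  if (anyDuplicated(cell)) stop("duplicate cell ids in pressure grid")
  hw <- hp_weight(hf)
  df <- data.frame(cell = cell, hf = hw$hf, category = hw$category,
                   weight = hw$weight, stringsAsFactors = FALSE)
  class(df) <- c("pressure_grid", "data.frame")
  df
}

#' Read a pressure grid from CSV
#'
#' Expects columns `cell_id` (or `cell`) and `hf`.
#'
#' @param path CSV file path.
#' @return A `pressure_grid`.
#' @export
read_pressure <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cell_col <- intersect(c("cell_id", "cell"), names(df))[1]
  if (is.na(cell_col) || !("hf" %in% names(df)))
    stop("pressure CSV needs columns cell_id (or cell) and hf")
  pressure_grid(df[[cell_col]], df$hf)
}

#' Upscale a fine Human Footprint raster by block means
#'
#' Aggregates a fine-resolution HF matrix onto a coarser grid by taking the
#' arithmetic mean of all non-missing fine cells within each block (e.g.
#' 1 km cells onto an analysis grid). Blocks containing only missing values
#' (e.g. marine areas) are absent from the output rather than zero-filled,
#' which would fabricate "no pressure".
#'
#' @param fine Numeric matrix of HF values; `NA` marks missing cells.
#' @param block Integer aggregation factor (>= 1); trailing partial blocks
#'   are averaged over the cells they contain.
#' @param prefix Prefix for generated coarse cell ids (`"<prefix><row>_<col>"`).
#' @return A `pressure_grid` over the non-empty coarse cells.
#' @export
upscale_hf <- function(fine, block, prefix = "c") {
  if (!is.matrix(fine) || !length(fine)) stop("'fine' must be a non-empty matrix")
  if (block < 1L || block != round(block)) stop("'block' must be a positive integer")
  block <- as.integer(block)
  nr <- ceiling(nrow(fine) / block)
  nc <- ceiling(ncol(fine) / block)
  cells <- character(0)
  vals <- numeric(0)
  for (i in seq_len(nr)) {
    rows <- ((i - 1L) * block + 1L):min(i * block, nrow(fine))
    for (j in seq_len(nc)) {
      cols <- ((j - 1L) * block + 1L):min(j * block, ncol(fine))
      v <- fine[rows, cols]
      if (all(is.na(v))) next
      cells <- c(cells, paste0(prefix, i, "_", j))
      vals <- c(vals, mean(v, na.rm = TRUE))
    }
  }
  if (!length(cells)) stop("raster is entirely missing")
  pressure_grid(cells, vals)
}

# HP weights for a set of cells; cells absent from the grid default to
# weight 1 (unimpacted) with a warning, biasing toward PE-equivalence
# rather than inventing threat.
.cell_weights <- function(cells, grid, missing = c("warn", "error")) {
  missing <- match.arg(missing)
  w <- grid$weight[match(cells, grid$cell)]
  if (anyNA(w)) {
    absent <- cells[is.na(w)]
    if (missing == "error")
      stop("cells absent from pressure grid: ", paste(absent, collapse = ", "))
    warning("assigning HP weight 1 to ", length(absent),
            " cell(s) absent from the pressure grid: ",
            paste(utils::head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ..." else "")
    w[is.na(w)] <- 1
  }
  stats::setNames(w, cells)
}

#' Human-pressure-weighted distribution score
#'
#' The sum of HP weights over a set of occupied cells: the "HP-weighted
#' distribution" of a species or branch. Bounded between 0.2 and 1 times the
#' number of cells.
#'
#' @param cells Character vector of cell ids (non-empty; duplicates removed).
#' @param grid A `pressure_grid`.
#' @param missing How to treat cells absent from the grid: `"warn"` assigns
#'   weight 1 with a warning, `"error"` aborts.
#' @return The weighted-cell score (scalar).
#' @examples
#' g <- pressure_grid(c("a", "b"), c(12, 0))
#' hp_weighted_distribution(c("a", "b"), g)  # 0.2 + 1.0
#' @export
hp_weighted_distribution <- function(cells, grid, missing = c("warn", "error")) {
  cells <- unique(as.character(cells))
  if (!length(cells)) stop("'cells' must be non-empty")
  sum(.cell_weights(cells, grid, match.arg(missing)))
}
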