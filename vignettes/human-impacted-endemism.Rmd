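---
title: "Human-impacted phylogenetic endemism: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Human-impacted phylogenetic endemism: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipe)
```

## The problem

Phylogenetic diversity (PD) — the summed branch lengths connecting a species
set across its phylogeny, in millions of years (MY) — is a currency for
conservation value: it measures how much unique evolutionary history a region
or a species embodies. Range-weighted PD metrics such as phylogenetic
endemism (PE) and evolutionary distinctiveness rarity (EDR) identify regions
holding PD that is restricted to small areas. They quantify
*irreplaceability*, but they are blind to *vulnerability*: a pristine
wilderness cell and a megacity cell holding the same endemic branches score
identically.

`hipe` implements a family of metrics that weight branch apportionment by
human pressure, using the Human Footprint index (HF), a 0–50 composite of
built environments, cropland, pasture, population density, night lights,
railways, roads and navigable waterways:

* **HIPE** (human-impacted phylogenetic endemism) — a spatial metric that
  apportions each branch's PD across the grid cells its descendants occupy
  in proportion to each cell's human-pressure (HP) weight;
* **TE** (terminal endemism) — a species score: terminal branch length (TBL)
  divided by range size;
* **HITE** (human-impacted terminal endemism) — TBL divided by the species'
  HP-weighted distribution.

Alongside these the package provides the reference metrics they extend
(per-cell PD, residual PD, weighted endemism, EDR, PE), randomization nulls,
and extinction-scenario PD-loss machinery.

## The model

### Pressure categories and HP weights

HF values are categorised into five pressure classes and scored linearly:

| category  | HF        | HP weight |
|-----------|-----------|-----------|
| none      | 0         | 1.0       |
| low       | 1–2       | 0.8       |
| moderate  | 3–5       | 0.6       |
| high      | 6–11      | 0.4       |
| very high | 12–50     | 0.2       |

The relationship between HF and biological impact is non-linear (HF 4 is
already pasture-equivalent), so a small number of biologically anchored
categories is preferred to the raw 51 levels. Because block-mean upscaling
produces fractional HF values, `hp_weight()` uses half-open intervals that
preserve the published integer anchors: *none* iff hf = 0 exactly, *low* iff
0 < hf < 3, *moderate* iff 3 ≤ hf < 6, *high* iff 6 ≤ hf < 12, *very high*
iff hf ≥ 12. Ties exactly at 3, 6 or 12 are a convention of this package;
the three published cutoffs fall on these boundaries.

When a fine HF raster is upscaled to the analysis grid (`upscale_hf()`),
coarse values are arithmetic means of the non-missing fine cells; blocks
that are entirely missing (sea) are dropped rather than zero-filled, since
zero-filling would fabricate "no pressure". Occupied cells missing from the
pressure grid are assigned weight 1 with a warning: treating the unknown as
unimpacted biases HIPE toward PE rather than inventing threat.

### Branch apportionment

Let branch $b$ have length $\ell_b$ and cell set $C_b$ (the union of cells
occupied by its descendant species). PE gives cell $c \in C_b$ the share
$\ell_b / |C_b|$. HIPE replaces the uniform share with the HP-weighted one:

$$\mathrm{HIPE}(c) \;=\; \sum_{b\,:\,c \in C_b} \ell_b\,
  \frac{w(c)}{\sum_{c' \in C_b} w(c')},$$

where $w$ is the HP weight. Cells under lower pressure receive a larger
share of each shared branch, under the assumption that they are more
favourable for persistence. Three consequences are load-bearing and are
enforced by tests:

* **Conservation** — summed over cells, PE, HIPE and EDR each equal the
  total mapped PD; pressure redistributes value, never creates it.
* **Reduction** — with constant pressure, HIPE ≡ PE cell by cell.
* **Bounded ratios** — for very-high-pressure cells HIPE/PE ≤ 1 and for
  zero-pressure cells HIPE/PE ≥ 1; a very-high-pressure cell with ratio
  near 1 holds PD that is essentially confined to very high pressure.

The canonical two-branch example: a focal cell of weight 0.2 holds two
10 MY branches. Branch A also occurs in a weight-1.0 cell, branch B in a
second weight-0.2 cell. PE gives the focal cell 5 MY from each. HIPE gives
it $10 \times 0.2/1.2 = 1.667$ MY from A but still 5 MY from B:

```{r worked}
fx <- worked_example_fixture()
pe(fx$forest, fx$occupancy)["focal"]
hipe(fx$forest, fx$occupancy, fx$pressure)["focal"]
```

### Species scores

$\mathrm{TE}(s) = \mathrm{TBL}(s)/\mathrm{range}(s)$ and
$\mathrm{HITE}(s) = \mathrm{TBL}(s)/\sum_{c \in \mathrm{cells}(s)} w(c)$.
Since weights lie in $[0.2, 1]$, $\mathrm{HITE}/\mathrm{TE} \in [1, 5]$ for
every species. TBLs are extracted from the full input tree *before*
intersecting with occupancy data, so that missing spatial data do not
lengthen terminal branches artificially. The example species (TBL 10 MY,
cells of weight 0.2 and 1.0) scores TE = 5 and HITE = 10/1.2 ≈ 8.33.

A note on units: the per-cell and per-species scores are constructed as MY
per (weighted) cell and are reported that way; the command-line interface
accepts an optional cell-area factor (e.g. a 96.5 × 96.5 km cell) for users
who want per-km² values.

### PD accounting conventions

Several small conventions matter and were genuinely open choices:

* **Root edge** — an explicit length on the root of an input Newick string
  is recorded but excluded from `total_pd()` and all metrics; the metrics
  operate on the ingroup tree.
* **Single-species cells** — a cell occupied by one species contributes that
  species' TBL, not its root-to-tip path. This published rule is
  deliberately discontinuous with the two-species case (which includes the
  root path): we follow it verbatim rather than smoothing it, and flag it
  here.
* **Pruning** — `prune_tree()` merges unsampled chains additively so that
  the pruned tree's total PD equals the retained species' spanning-subtree
  PD, root path included. The stem above the survivors' MRCA is kept as an
  edge below a singleton root node (ape's `drop.tip()` would move it into
  the excluded root edge); pruning to one survivor yields its full
  root-to-tip path, so "reduction in total PD" is always well defined, and
  dropping one tip of a cherry costs exactly its TBL.
* **Forests** — clades supplied as separate trees (e.g. turtles and
  crocodilians alongside squamates) are analysed per tree and summed per
  cell; no connecting branches are fabricated, so forest PD is
  conservative.
* **Namespace intersection** — spatial metrics use species present in both
  tree and occupancy; dropped names are reported. Branches with no mapped
  descendant contribute nothing.
* **Ties** — rankings, top-cell selection and cumulative bands order by
  descending value then ascending label, so runs are reproducible.
* **Medians over tree distributions** — midpoint of the central pair for
  even counts; a key must appear in at least half the trees to be
  summarised (others are flagged).
* **Zero-length edges and polytomies** are permitted and propagate
  naturally.

## Randomization machinery

`randomize_pressure_null()` permutes the observed HF values (sampling
without replacement, i.e. a permutation of the empirical distribution —
"redistributing" values implies keeping their multiset) across the
occupied-cell universe and recomputes how many of the top-fraction metric
cells fall at HF ≥ 6. Permuting raw values and re-deriving categories is
equivalent to permuting categories, since the category map is deterministic
in the value. Under the null the expected overlap is the global HF ≥ 6
share, which the acceptance suite verifies to within Monte-Carlo error.

`random_extinction_null()` draws, within every stratum (e.g. taxonomic
order), uniform random extinction sets matching the observed per-stratum
counts, and compares PD losses. `scenario_loss_range()` brackets losses for
unassessed/data-deficient candidates under best-case (`single_min`),
random-subset and worst-case (`all`) scenarios across a tree distribution;
the random-subset size is uniform on 1…n candidates, a documented choice
where no law is published.

## The synthetic-data generator

Because the global datasets behind real analyses (range polygons, published
posteriors, the HF raster) are large and licensed, the package ships
generators that emulate their statistical structure, and all tests run on
them:

* `simulate_tree()` — pure-birth ultrametric trees (via `ape::rphylo`),
  whose TBL distribution is right-skewed as in real timetrees.
* `simulate_occupancy()` — contiguous ranges grown by random frontier
  expansion on the grid (PE/HIPE behaviour depends on range overlap, which
  scattered cells would not emulate), with log-normal range sizes
  (`meanlog = log(4)`, `sdlog = 1`: heavy-tailed, median 4 cells) and a
  tunable phylogenetic signal in log range size
  (`signal` default 0.4, the magnitude reported for squamate range sizes);
  the signal mixes a Brownian trait with independent noise as
  $z = \sqrt{s}\,z_{\mathrm{phylo}} + \sqrt{1-s}\,z_{\mathrm{indep}}$.
* `simulate_hf()` — Gaussian noise smoothed at a chosen correlation length
  (default 2 cells), rescaled to mean 8, sd 10 and clipped to [0, 50], so
  that genuinely pristine (HF = 0) and very-high-pressure cells both occur
  at realistic frequencies.
* `simulate_threat()` — threat status with tunable phylogenetic signal:
  0 is uniform random, intermediate values threshold a mixed Brownian
  trait, and 1 is the fully clumped limit in which threat is a union of
  whole clades chosen by clade-mean trait.

What passing tests on these fixtures shows — and what it does not: the
generators reproduce heavy-tailed ranges, spatial contiguity, autocorrelated
pressure and clumped threat, so they exercise every code path and every
conservation law at realistic parameter shapes. They do not reproduce real
biogeography (coastlines, latitudinal gradients, range cohesion across
biomes), real HF spatial structure, or the empirical global numbers
reported for reptiles; those depend on external datasets and are out of
scope here.

Problem sizes used by the test batteries (up to ~50 tips and 400 cells for
the conservation sweeps; 100-tip trees for the extinction-direction runs;
1000-replicate permutation nulls) were chosen so the whole suite settles in
well under a minute while keeping Monte-Carlo error small relative to the
margins tested.

### The clumped-extinction direction

When threat is phylogenetically clumped, the loss from observed extinctions
exceeds the stratified-random expectation, because whole clades disappear
and their shared internal branches are lost outright, while scattered
extinction sets mostly lose terminal branches only. The property test runs
this comparison on 100-tip trees with fully clumped threat (signal 1,
threatened fraction 0.4, strata = the two basal subclades) and requires the
direction to hold in at least 95% of 50 seeded runs. With *partial*
clumping (thresholding a Brownian trait, signal < 1) the direction still
dominates but holds in only roughly 80–95% of runs at these sizes — the
threshold cuts across clades, so fewer internal branches are fully
subtended by threatened tips. The acceptance property therefore tests the
strong-signal limit; users exploring weaker signal should expect a noisier
direction at small tree sizes.

## Numerical choices

Conservation identities are asserted to 1e-9 relative tolerance; all
arithmetic is double precision with no special accumulation. Degenerate
inputs error early with messages naming the offending species or cells:
trees without branch lengths, duplicate tips, empty species sets, dropping
every tip, constant richness in the residual regression, HF outside
[0, 50], cells absent from grids (where the fallback is not wanted). Zero-PE
cells are omitted from HIPE/PE ratios with a warning rather than producing
infinities.

## Known limitations

* Raster input is limited to numeric matrices and CSV; reading GeoTIFF and
  reprojection belong to dedicated geospatial packages, and this package
  deliberately consumes pre-gridded occupancy keyed by opaque cell ids.
* The HP weighting is the published linear five-category scheme;
  `hp_weight()` is a single choke point, so alternative weightings are a
  one-function change, but none are shipped.
* Forest totals omit the connecting branches between separately supplied
  clade trees and are therefore conservative.
* No spatial-autocorrelation-corrected correlation statistics, map
  rendering, or complementarity-based site prioritisation are included.
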