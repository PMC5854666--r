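---
title: "Models and methods behind refugia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind refugia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`refugia` estimates how a warming climate could reshape the biodiversity held
by a network of protected areas: per-reserve species gain, loss, turnover and
richness, representativity at nested spatial scales, and the change in
protected land overlapping each species' range. This vignette is the
package's own account of the models, the parameters that matter, the
synthetic study system, and the numerical choices — including the ones that
were genuinely open.

## The data model

All layers live on a regular square grid (`make_grid()`). Cells are
axis-aligned squares with half-open `[min, max)` boundaries, so a point on a
shared edge belongs to exactly one cell; cell ids are 0-based and row-major,
and the row index increases southward (row 0 is the northernmost band). The
nominal unit is the kilometre on a planar frame — no geodesy, no CRS. The
statistics computed here depend only on cell adjacency, cell areas and
polygon/cell intersections, all of which are exact on a planar grid, so
projections would add dependency weight without changing any result.

Climate is a long table (`cell_id`, `variable`, `period`, `value`) for two
periods, *reference* and *future*. Species occurrences are per-cell
presence/absence. Protected areas are axis-aligned rectangles (id, extent,
exact geometric area, management category). The region hierarchy maps each
cell to one natural region nested inside one natural province.

## The synthetic study system

`simulate_landscape()` generates the complete system from one master seed.
It emulates the *structure* a northern protected-area analysis assumes, not
any particular geography:

- **Climate.** Each variable is linear in row index plus iid Gaussian noise;
  the future layer is the reference layer plus a spatially uniform offset
  (default +3 °C on mean temperature over a ~17 °C latitudinal span on the
  30×20 default grid). Noise levels are set so that mean and minimum
  temperature and growing degree-days are strongly collinear (|r| ≈ 0.95)
  while precipitation is nearly independent — the collinearity screen then
  has real work to do.
- **Species.** Sixty virtual species by default (20 birds, 8 amphibians,
  12 trees, 20 other vascular plants). Each has a known niche response to
  mean temperature — Gaussian by default (optimum, breadth ~ U(1.5, 3.5) °C),
  logistic and step shapes available — and trees are additionally modulated
  by a preferred surface-deposit class (suitability ×0.4 off-class; deposits
  have 7 classes, drainage 3). Occurrences are independent Bernoulli draws
  per cell with probability suitability × sampling rate (rate 1 by default:
  a census). Niche optima are drawn with linearly increasing density toward
  the warm edge (`optimum_power = 2`) and up to 25% of the temperature span
  beyond it. Both choices encode the two structural facts the analysis rests
  on: species richness declines with latitude, and the continental pool
  holds species whose suitable climate lies just south of the study area
  (immigrants under warming). With uniform optima neither holds, the
  latitudinal gain contrast disappears, and the system no longer behaves
  like a northern network.
- **Protected areas.** Axis-aligned rectangles with log-normal areas
  (meanlog 1.66, sdlog 1.2, i.e. median ≈ 5 km² and ≈ 97% of areas below
  the 50 km² small-reserve cap), uniform placement, free mutual overlap.
  Most reserves are therefore much smaller than a 400 km² cell — the
  small-reserve-in-one-cell situation that drives the aggregation rules
  below.
- **Regions.** Contiguous latitudinal bands: by default 3 provinces × 2
  regions each. Band partitioning guarantees the nesting invariant by
  construction; a seeded growth partition was considered and dropped as it
  adds randomness without changing any downstream property.

What the generator does **not** emulate: spatial autocorrelation in
detection, dispersal limitation, biotic interactions, observer effort
gradients, and non-uniform (GCM-style) climate anomalies. Passing tests
therefore demonstrate that the statistical machinery is correct and that the
qualitative northern-refuge pattern follows from the encoded structure —
they do not validate forecasts for any real landscape.

## Ensemble niche modelling

Per species (`model_species()`):

1. **Training sets.** Species with real absences (trees) use the full
   labelled table; otherwise pseudo-absences are drawn uniformly, without
   replacement, from cells strictly farther than `buffer_cells` (default 2)
   cell widths — centre to centre — from every presence, exactly as many as
   there are presences (prevalence exactly 0.5). Ten repetitions by default;
   for real-absence species the repetitions are ten stratified splits of the
   one training set. Species with fewer than `min_presences` (15) presences,
   or for which the buffer leaves too few eligible cells (wide-ranging
   species on a small grid), are skipped with a logged status rather than
   aborting the run.
2. **Committee.** Four families spanning linear, tree, ensemble-of-trees and
   instance-based learners: ridge logistic regression on linear + squared
   terms (λ = 0.01 — the quadratic terms let a linear model express a
   unimodal niche), a CART tree (minbucket 5, cp 0.005), bagged trees
   (100 trees, mtry = number of predictors, i.e. bagging rather than a
   random subspace forest), and kNN (k = 7, standardized design). The
   registry is pluggable.
3. **Evaluation and consensus.** Each member is scored by AUC (rank/
   Mann–Whitney form, ties = ½) on the 30% held-out rows of its repetition.
   Members below the AUC floor (0.7) are excluded and the exclusion
   recorded; the rest are combined as an AUC-weighted mean, weights
   normalized to 1. If no member clears the floor the species is flagged
   unmodellable.
4. **Binarization.** One threshold per species, chosen to maximize TSS
   (sensitivity + specificity − 1) over the consensus scores of the pooled
   unique training cells, smallest maximizer on ties, presence where
   score ≥ threshold — applied identically to both periods so that gain and
   loss are never artefacts of period-specific thresholds.

Every stochastic step draws its seed from one master seed through a fixed
integer-mixing stream, so a run is reproducible bit for bit and species can
be recomputed independently.

Collinearity screening (`correlation_filter()`) is a greedy scan in a
documented priority order: a variable is retained iff |Pearson r| with every
already-retained variable is strictly below 0.6. Greedy retention is
deterministic and order-transparent; it does not maximize the retained-set
size, which the tests assert explicitly (feasibility, not optimality).
Categorical soil covariates bypass the Pearson screen and are appended for
tree-type species only.

## Overlay and conservation metrics

A reserve's *covering cells* are the cells its footprint intersects with
positive area (edge-touching does not count; the half-open cells make the
assignment unambiguous). Metric values for a multi-cell reserve are computed
on the pooled species sets of its covering cells — the minimal cell-aligned
region containing the footprint — which for a single-cell reserve reduces
exactly to that cell's values. Pooling was chosen over a bounding-box
reading because values are defined per cell, and the two coincide for the
dominant single-cell case.

Protected land per cell is the area of the geometric union of all reserve
footprints clipped to the cell (coordinate-compression sweep; exact for
rectangles), so overlapping reserves are never double-counted in land-area
statistics, while per-reserve distributions deliberately keep every reserve
as its own sampling unit.

Gain, loss and turnover follow the standard community-turnover definitions
(`rG = 100·G/refSR`, `rL = 100·L/refSR`, `T = 100·(G+L)/(refSR+G)`); they
carry full floating precision internally and are undefined (flagged and
excluded from summaries, counted in the run report) when `refSR = 0`.
Representativity divides the reserve's pooled richness by the regional pool
at three nested scales; a reserve is assigned to the region holding the
majority of its covering cells, its province is that region's province (so
the scale chain stays nested and representativity is non-increasing as the
reference pool coarsens), and ties are excluded and counted. A reserve
straddling a region boundary can exceed 1 at the finest scale — its cells
can hold species the assigned region lacks; values are reported as computed.
Protected-range change uses `ΔPR = 100·(futurePR − refPR)/refPR`, excluding
(with recorded reason) species whose reference range overlaps no protected
land. Periods are compared with the classic paired Wilcoxon signed-rank test
(zero differences dropped, V = positive-rank sum, exact/approximate switch
as in `stats::wilcox.test`); an all-zero comparison returns an explicit
"no change" outcome instead of a p-value. Summaries always carry both
mean ± SD and median ± MAD, with MAD reported raw (constant 1), matching the
robust-reporting convention for heavy-tailed percentage distributions.

## Verification strategy and problem sizes

The test suite pairs every non-trivial computation with an independent
oracle: AUC against brute-force pair enumeration (and pROC), covering cells
against an exhaustive per-cell intersection scan, the rectangle-union sweep
against 10⁵-point Monte-Carlo hit-or-miss (3 SD band), the greedy screen
against exhaustive subset search (≤ 6 candidates), and the signed-rank V
against hand-ranked examples.

Two property suites exercise the whole chain. *Niche recovery*: 20
real-absence species with purely climatic Gaussian niches on the 600-cell
default grid, census sampling, default committee — median Spearman ρ between
consensus and true suitability ≥ 0.8 and median Jaccard between the
binarized and true range (true suitability ≥ 0.5) ≥ 0.7. Real-absence
species are the right recovery instrument: the pseudo-absence buffer
deliberately removes mid-suitability absences from training, which inflates
the binarized range margin (rank recovery stays excellent, ρ ≈ 0.99, but
Jaccard drops to ≈ 0.56), and soil-modulated tree truth fragments the true
range; both effects are properties of those designs, not of the estimator.
*Northern-refuge pattern*: the default demo configuration (30×20 grid, 60
species, 150 reserves, one CPU, well under a minute) must show higher mean
relative gain in the northern than the southern third of reserves, a
significant positive Wilcoxon richness shift, and scale-monotone
representativity for every reserve.

These sizes were chosen as the smallest at which the distributional claims
are stable across seeds; everything scales up by editing the configuration.

## Known limitations

- Geometry is restricted to axis-aligned rectangles for reserves; arbitrary
  polygons would require a planar-geometry dependency.
- Pseudo-absence selection can be infeasible for species occupying most of a
  small grid (skipped and logged); on landscape-sized grids this does not
  arise.
- The binarized range of pseudo-absence species is systematically generous
  (see above); analyses based on the continuous consensus are unaffected.
- Independent Bernoulli sampling understates the spatial clumping of real
  occurrence data, so AUCs here are optimistic relative to field data.
- No dispersal constraint: projected "gains" are potential, conditional on
  species tracking their climate.
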