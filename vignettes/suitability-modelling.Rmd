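---
title: "Ensemble suitability modelling for podoconiosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble suitability modelling for podoconiosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podomapr)
```

podomapr estimates where the environment permits podoconiosis to occur —
not where it does occur, and not its prevalence. The modelled quantity is
an environmental suitability in [0, 1] per 5-km grid cell, learned from
the contrast between communities with confirmed cases and communities (or
whole regions) where the disease is absent or considered unlikely. This
vignette explains the model, the knobs that matter, what the synthetic
scenarios do and do not emulate, and the design choices made where the
method left room.

## The training table

Survey communities are deduplicated on exact coordinates (a confirmed
presence beats a co-located absence; no tolerance merging, so upstream
coordinate rounding is the user's responsibility) and labelled endemic
iff they reported confirmed cases. Because the nationwide surveys behind
such databases examine whole communities, unreporting communities are
treated as *true* absences with the same unit weight as presences.

Coverage beyond surveyed regions comes from pseudo-absences: random cell
centres in countries whose evidence score is negative (evidence of
absence). Their count equals the number of survey records — balancing the
survey table — and their weight is a min–max rescaling of |score| onto
[floor, 1] over eligible countries, most negative score → 1, with a
configurable floor (default 0.25) so no eligible country is weightless.
The direction (stronger evidence of absence → larger weight) makes
confident absences count more; the floor keeps weakly attested countries
in play. Points sit at cell centres because covariates are constant
within a cell. Weights enter every learner as observation weights; no
additional class weighting is applied.

## Learners

Six algorithms sit behind one fit/predict contract (probabilities of
presence, observation weights honoured, seeded reproducibility):

* **GLM** — weighted logistic regression (`stats::glm`).
* **GAM** — penalised regression splines (`mgcv::gam`, REML), `k = 8`
  basis functions per covariate by default: close to mgcv's own default
  while bounded sensibly for frames of a few hundred rows.
* **GBM** — gradient-boosted trees (xgboost) with learning rate 0.005 and
  tree depth 5 (up to five-way interactions), 1,000 trees and 0.5-row
  subsampling by default. The slow learning rate is the tuning that lets
  boosting converge without overfitting presence records.
* **ANN** — one hidden layer (`nnet`, 5 units, decay 0.01), inputs
  standardised internally.
* **MARS** — forward selection of hinge pairs `max(x − t, 0)`,
  `max(t − x, 0)` at quantile knots, followed by one weighted logistic
  fit; deterministic, at most 14 terms by default.
* **RF** — probability forest (`ranger`, 500 trees, case weights).

Stochastic learners draw their seed from (global seed, algorithm,
replicate index), so the replicate loop is reproducible and
order-independent.

## Replicates, gates, ensemble

`run_replicates()` draws, per algorithm, `n_reps` (default 50)
stratified 80/20 splits — stratification keeps both classes in every test
set, without which the AUC is undefined — fits on the 80% and scores the
20% with weighted AUC, TSS and PCC. The TSS/PCC of a run are taken at the
threshold that maximises TSS on the *evaluation* predictions, the
convention of the standard ensemble frameworks. That maximisation is
optimistically biased on small test sets (its null expectation is
positive, roughly +0.3 at 40 test points), which is why the unbiased,
rank-based AUC is gated alongside it, and why the package's null-data
tests assert centrality of the AUC and of TSS at a fixed threshold rather
than of the maximised TSS.

Runs with AUC < 0.8 or TSS < 0.7 are discarded. Survivors predict over
all stack-valid cells and are combined as an AUC-weighted mean; the
per-cell uncertainty band is the 2.5%/97.5% empirical quantile of the
member predictions — distribution-free, and each bound is an actual
member value rather than a parametric extrapolation. Member surfaces are
retained because the population-at-risk interval downstream needs
per-replicate map totals, not cellwise bounds.

## Spatial block cross-validation

Random splits flatter spatially autocorrelated data. `make_spatial_blocks()`
tiles the extent with square blocks (2,000 km at continental scale;
desk-scale scenarios use 200 km so that several blocks exist) anchored at
the grid origin, assigns blocks to k = 5 fold labels balanced in count
and shuffled by the seed, and `block_cv()` trains on four folds and tests
on the fifth. Reading "five folds" as five *labels* rather than five
blocks is deliberate: a fixed 2,000-km tiling of a large extent yields
more than five blocks, and balanced labels keep the folds comparable.
The block-CV comparison ensemble combines **all** fold models
AUC-weighted: each fold contributes a single model per algorithm, so
skill-gating here would routinely leave the comparison undefined at desk
scale; the regular ensemble keeps the published gates. Agreement between
the two ensemble means is summarised by Pearson correlation over jointly
valid cells.

## Threshold and aggregation

`optimal_threshold()` scans every distinct score plus the midpoints
between consecutive distinct scores and maximises sensitivity +
specificity (equivalently TSS); ties break towards higher accuracy, then
the lower threshold — the permissive side, consistent with a mapping
policy that would rather flag too much than miss endemic areas.
Classification at the threshold is presence-inclusive (`score ≥ t`).

`binarize()` + `population_at_risk()` overlay the binary map on the
population raster: the per-zone point estimate is the population in
suitable cells, and the 95% interval comes from recomputing the total
under each ensemble member's binary map (2.5%/97.5% quantiles of map
totals). Zone totals sum exactly to the overall total on integer
populations. `overlap_binary()` partitions population into
neither/one/other/both classes against a second binary layer.
`classify_ius()` calls an IU suitable iff its suitable-cell fraction
exceeds `min_fraction` (default 0: any suitable cell — again the
permissive rule), intersecting IU zones with cells by cell centre;
needs-mapping is suitable-and-unmapped. IUs with no valid cells are
flagged indeterminate and excluded from share denominators. Reported
shares are rounded half-up to one decimal at the reporting layer only.

## The synthetic scenario generator

`make_scenario()` builds a 120 × 120 grid of 5-km cells (600 × 600 km)
with 400 survey sites by default — small enough for minutes-scale test
runs, large enough for non-degenerate block CV. Covariates are
Gaussian-filtered noise fields rescaled to realistic ranges
(precipitation 0–3,000 mm; elevation 0–3,000 masl; LST 10–40 °C; EVI
0–0.8; soil pH 4–9; clay/silt 0–60%), plus a distance-to-water surface
computed from a synthetic river mask with the exact Euclidean transform.

The truth surface is a logistic combination of the documented
marginal-effect shapes: a precipitation plateau peaking inside
1,000–1,800 mm, an elevation window elevated between 1,000 and
2,500 masl, risk decreasing in soil pH through 7, and increasing in clay
and silt. Two calibrations are built in and recorded with the scenario:
the combined logit surface is standardised to `signal_sd = 4`, which
gives the generating (Bayes) surface a held-out AUC of ≈ 0.95 against
Bernoulli survey outcomes — slightly above the 0.88–0.92 a fitted model
achieves, as it should be, since fitted models cannot beat the generating
truth — and the intercept is solved so mean suitability equals the
prevalence target (default 0.45, mirroring the ~46% presence fraction of
real compiled survey databases). Country evidence scores are *ordered by
mean true suitability* (least suitable → most negative): evidence maps
encode observed absence, so pseudo-absence countries must actually be
unsuitable, and breaking that link floods the absence class with label
noise no real evidence map would produce. Survey-site sampling is uniform
by default; a bias dial exists to emulate survey effort concentrated on
suspected endemic areas, off by default.

What the scenarios do **not** emulate: real coastline/nodata geometry,
geographic-degree coordinates (everything is planar km), covariate
cross-correlations of real remote-sensing products, imperfect diagnosis,
and geocoding error. Passing recovery tests therefore demonstrates the
pipeline's correctness and statistical behaviour under known truth, not
predictive validity on real data.

## Numerical and I/O choices

* Grid cells own half-open intervals (right/top edge ownership), so point
  extraction and block assignment are deterministic on boundaries; row 1
  is the northernmost row.
* Bilinear resampling interpolates the four surrounding source cell
  centres and masks any output cell touching a masked or out-of-extent
  neighbour with positive weight — conservative at coastlines; zero-weight
  neighbours are ignored, making same-grid resampling an exact identity.
* Distances are centre-to-centre, matching the source resolution; no
  sub-cell geometry is claimed.
* The threshold sweep and the AUC are computed by cumulative sums over
  sorted unique scores; tie-break comparisons are rounded at 1e-12 so
  float noise cannot reorder exact ties. The AUC counts tied scores as
  one half.
* Rasters are single-band float32 GeoTIFFs (uncompressed, little-endian,
  ModelPixelScale/ModelTiepoint georeferencing, GDAL-style ASCII nodata
  tag, CRS label in the citation key) written and parsed by the package;
  round trips are exact for float32-representable values. Anything the
  reader does not understand — multi-band, compressed, BigTIFF — is an
  explicit error naming the file, never a silent misread.
* Test problem sizes: module tests run on 60 × 60 scenarios with 200
  sites and 5 replicates; the recovery suite uses the full default
  scenario with 10 replicates each of GLM, GBM and RF. These sizes are
  the package's choice of desk scale: large enough that gate survival,
  recovery correlation and block CV are all exercised non-degenerately.

## Known limitations

Learner internals are the installed implementations (mgcv, xgboost,
ranger, nnet) with documented settings — no claim is made of bit-level
equivalence with any other framework's defaults, only of the same
algorithmic roles. MARS is a deliberately simple hinge-basis
approximation. The gates (AUC ≥ 0.8, TSS ≥ 0.7) are strict at desk
scale: with few replicates it is possible for very few members — at times
one — to survive, which widens the uncertainty band and is reported
honestly in the member count. Geographic-degree inputs must be projected
upstream; the package is planar throughout.
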