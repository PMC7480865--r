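# podomapr

Ensemble environmental-suitability mapping and population-at-risk
estimation for **podoconiosis** — a non-infectious tropical lymphedema
caused by barefoot exposure to irritant red-clay soils in genetically
susceptible people. The package is aimed at NTD epidemiologists and
modellers who need a tested, reproducible implementation of the
species-distribution-modelling workflow used to delineate the ecological
limits of the disease and to prioritise WHO implementation units (IUs,
typically districts) for community-level mapping.

## The method

Training data are endemicity-labelled survey communities (endemic `1` iff
confirmed cases were reported, else a *true absence*, both with weight 1),
augmented with **pseudo-absences** sampled uniformly over countries whose
evidence score is below 0; pseudo-absence weights are a min–max rescaling
of the absolute evidence score onto `[0.25, 1]`, so confident absences
count more. Each of six learners — GLM, GAM, GBM (lr = 0.005, up to
five-way interactions), ANN, MARS, RF — is calibrated on an 80% stratified
random sample and evaluated on the held-out 20%, repeated 50 times per
algorithm. Replicates with held-out AUC < 0.8 or TSS < 0.7 are discarded;
the survivors form the ensemble surface

```
suitability(cell) = Σᵢ AUCᵢ · pᵢ(cell) / Σᵢ AUCᵢ
```

with per-cell 2.5%/97.5% member quantiles as uncertainty bounds. The
model is validated by **spatial block cross-validation** (square blocks
assigned to k = 5 folds; train/test spatially disjoint at block
granularity) and the two ensemble means compared by Pearson correlation.
A presence threshold is chosen to maximise sensitivity + specificity
(the true skill statistic, TSS), the suitability surface is binarised
(presence-inclusive at the cut-off), and the binary map is overlaid on a
gridded population surface to produce per-zone population-at-risk totals
with member-derived 95% intervals, four-class overlap maps against a
second binary risk layer (lymphatic filariasis, whose lymphedema is
clinically confused with podoconiosis), and an IU table flagging suitable
IUs that still need mapping.

A seeded synthetic-scenario generator supplies complete desk-scale inputs
(spatially autocorrelated covariates, a known truth surface built from
the documented marginal-effect shapes, Bernoulli surveys, evidence
scores, population, country/IU zones, an LF layer), so the entire
pipeline is testable offline; rasters travel as single-band float32
GeoTIFFs read and written by the package itself.

## Worked example

```r
library(podomapr)

scen_dir <- tempfile("scenario"); run_dir <- tempfile("run")
config <- pipeline_config(algorithms = c("GLM", "GBM", "RF"), n_reps = 10,
                          block_km = 200, seed = 42)
res <- run_pipeline(scen_dir, run_dir, config,
                    scenario = scenario_spec(rng_seed = 42))

res$fit$ensemble
#> <ensemble_prediction> 15 members over 14400 valid cells; mean in [0.007, 0.980]
```

Fifteen of the 30 replicate runs survived the AUC/TSS gates; their
held-out scores (and the AUC weights they contribute) are in
`tidy(res$fit$ensemble)`. The threshold stage reports the optimal
trade-off and the agreement between regular and spatial-block ensembles:

```r
res$threshold$threshold
#> # A tibble: 1 × 6
#>   threshold sensitivity specificity accuracy   tss   auc
#>       <dbl>       <dbl>       <dbl>    <dbl> <dbl> <dbl>
#> 1     0.267       0.977       0.889    0.914 0.866 0.978
res$threshold$agreement
#> [1] 0.9975358
```

so occurrence is assumed possible wherever suitability ≥ 0.267, which
classifies 97.7% of presences and 88.9% of absences correctly on the
training table. Aggregation converts the binary map into decisions:

```r
glance(res$aggregate$risk)     # overall population at risk, 95% interval
#> # A tibble: 1 × 3
#>   population_at_risk   lower   upper
#>                <dbl>   <dbl>   <dbl>
#> 1             774040 669435. 807808.
tidy(res$aggregate$risk)       # the same, per country
res$aggregate$shares
#>  suitable_ius_pct needs_mapping_pct
#>              79.2              57.9
```

Here 79.2% of the scenario's 48 implementation units are environmentally
suitable and 57.9% of those still need community-level mapping.
`autoplot(res$fit$ensemble)` maps the suitability surface;
`plot_partial_dependence()` draws marginal-effect curves.

A thin command-line wrapper over the same functions lives at
`inst/cli/podomapr.R` (`simulate` and `run` subcommands).

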