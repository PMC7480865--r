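#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with the published analysis'
#' settings as defaults: six algorithms, 50 replicates of stratified 80/20
#' splits, AUC/TSS gates of 0.8/0.7, 2,000-km spatial blocks in five
#' folds, threshold optimisation (or a fixed override), and the permissive
#' implementation-unit rule. Any override is echoed into the run log and
#' the config hash is written with every output.
#'
#' @param algorithms Character vector of learner algorithms.
#' @param n_reps Replicates per algorithm (default 50).
#' @param train_fraction Calibration fraction (default 0.8).
#' @param auc_min,tss_min Ensemble gates (defaults 0.8, 0.7).
#' @param block_km Spatial block side in km (default 2000).
#' @param k_folds Number of CV folds (default 5).
#' @param threshold `"optimise"` (default) or a fixed numeric threshold.
#' @param min_fraction IU suitability rule (default 0: any suitable cell).
#' @param evidence_floor Pseudo-absence weight floor (default 0.25).
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(algorithms = c("GLM", "GAM", "GBM", "ANN", "MARS", "RF"),
                            n_reps = 50, train_fraction = 0.8,
                            auc_min = 0.8, tss_min = 0.7,
                            block_km = 2000, k_folds = 5,
                            threshold = "optimise", min_fraction = 0,
                            evidence_floor = 0.25, seed = 1) {
  cfg <- list(algorithms = toupper(algorithms), n_reps = n_reps,
              train_fraction = train_fraction, auc_min = auc_min,
              tss_min = tss_min, block_km = block_km, k_folds = k_folds,
              threshold = threshold, min_fraction = min_fraction,
              evidence_floor = evidence_floor, seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) rlang::hash(unclass(cfg))

provenance <- function(cfg) {
  list(config_hash = config_hash(cfg), seed = cfg$seed,
       package_version = as.character(utils::packageVersion("podomapr")))
}

#' Simulate a scenario directory (pipeline stage 1)
#'
#' @param scenario A [scenario_spec()].
#' @param dir Output directory.
#' @return The in-memory scenario, invisibly.
#' @export
pipeline_simulate <- function(scenario = scenario_spec(), dir) {
  simulate_scenario(scenario, dir)
}

read_scenario_inputs <- function(scenario_dir) {
  req <- function(f) {
    p <- file.path(scenario_dir, f)
    if (!file.exists(p)) stop(sprintf("scenario input missing: %s", p), call. = FALSE)
    p
  }
  list(
    stack = read_stack(req("scenario.yaml")),
    surveys = req("surveys.csv"),
    evidence = req("evidence.csv"),
    countries = read_raster(req("countries.tif")),
    country_lookup = tibble::as_tibble(utils::read.csv(req("countries_lookup.csv"))),
    ius = read_raster(req("ius.tif")),
    iu_lookup = tibble::as_tibble(utils::read.csv(req("ius_lookup.csv"))),
    mapped_flags = tibble::as_tibble(utils::read.csv(req("mapped_flags.csv"))),
    population = read_raster(req("population.tif")),
    lf_binary = if (file.exists(file.path(scenario_dir, "lf_binary.tif"))) {
      read_raster(file.path(scenario_dir, "lf_binary.tif"))
    } else NULL)
}

# weighted presence/absence/pseudo-absence frame per the published recipe:
# pseudo-absence count equals the presence + true-absence count
assemble_frame <- function(inp, cfg) {
  labelled <- label_endemicity(load_and_dedupe(inp$surveys))
  weights <- rescale_evidence(inp$evidence, floor = cfg$evidence_floor)
  weights$country_index <- inp$country_lookup$country_index[
    match(weights$country, inp$country_lookup$country)]
  eligible <- inp$countries
  eligible$mask <- eligible$mask | !stack_valid_mask(inp$stack) |
    !(eligible$values %in% weights$country_index)
  eligible$values[eligible$mask] <- NA_real_
  pseudo <- sample_pseudo_absences(eligible, weights, n = nrow(labelled),
                                   rng_seed = cfg$seed * 1000L + 7)
  build_model_frame(labelled, pseudo, inp$stack)
}

#' Fit the gated ensemble and write suitability rasters (stage 2)
#'
#' Builds the weighted training frame from the scenario directory, runs
#' the replicate engine, gates on AUC/TSS, assembles the AUC-weighted
#' ensemble, and writes `suitability_mean/lower/upper.tif`, `runs.json`
#' and `provenance.json` into `run_dir`.
#'
#' @param scenario_dir Directory written by [pipeline_simulate()] (or
#'   user-supplied with the same layout).
#' @param run_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @return List with `frame`, `runs`, `selected`, `ensemble`, invisibly.
#' @export
pipeline_fit <- function(scenario_dir, run_dir, config = pipeline_config()) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_scenario_inputs(scenario_dir)
  frame <- assemble_frame(inp, config)
  specs <- purrr::map(config$algorithms, learner_spec, rng_seed = config$seed)
  runs <- run_replicates(frame, specs, n_reps = config$n_reps,
                         train_fraction = config$train_fraction,
                         rng_seed = config$seed)
  selected <- select_runs(runs, config$auc_min, config$tss_min)
  ens <- ensemble_predict(selected, inp$stack)
  write_raster(ens$mean, file.path(run_dir, "suitability_mean.tif"))
  write_raster(ens$lower, file.path(run_dir, "suitability_lower.tif"))
  write_raster(ens$upper, file.path(run_dir, "suitability_upper.tif"))
  jsonlite::write_json(dplyr::select(tibble::as_tibble(runs), -"fitted"),
                       file.path(run_dir, "runs.json"), digits = NA)
  jsonlite::write_json(provenance(config), file.path(run_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(list(frame = frame, runs = runs, selected = selected,
                 ensemble = ens, inputs = inp))
}

#' Optimise the threshold and run spatial-block CV (stage 3)
#'
#' Computes the optimal presence threshold from the ensemble-mean
#' suitability at the training points (unless the config fixes one), runs
#' spatial-block cross-validation with the configured block size and fold
#' count, builds the block-CV ensemble with the same specs and gates, and
#' reports the Pearson agreement between the two ensemble means. Writes
#' `threshold.json` and `blockcv.json`.
#'
#' @param fit Result of [pipeline_fit()].
#' @param run_dir Output directory.
#' @param config A [pipeline_config()].
#' @return List with `threshold` (tibble), `blockcv_runs`, `agreement`,
#'   invisibly.
#' @export
pipeline_threshold <- function(fit, run_dir, config = pipeline_config()) {
  frame <- fit$frame
  scores <- predict_ensemble_at(fit$ensemble, frame)
  thr <- if (identical(config$threshold, "optimise")) {
    optimal_threshold(frame$label, scores, frame$weight)
  } else {
    cf <- confusion_at(frame$label, scores, frame$weight, config$threshold)
    tibble::tibble(threshold = config$threshold, sensitivity = cf$sensitivity,
                   specificity = cf$specificity, accuracy = cf$pcc, tss = cf$tss,
                   auc = roc_auc(frame$label, scores, frame$weight))
  }
  specs <- purrr::map(config$algorithms, learner_spec, rng_seed = config$seed)
  folds <- make_spatial_blocks(fit$ensemble$spec, frame,
                               block_km = config$block_km, k = config$k_folds,
                               rng_seed = config$seed)
  bcv <- block_cv(frame, specs, folds, stack = fit$inputs$stack)
  agreement <- compare_predictions_pearson(fit$ensemble$mean, bcv$ensemble$mean)
  jsonlite::write_json(thr, file.path(run_dir, "threshold.json"), digits = NA)
  jsonlite::write_json(
    list(per_fold = dplyr::select(tibble::as_tibble(bcv$runs), -"fitted"),
         agreement_pearson = agreement),
    file.path(run_dir, "blockcv.json"), digits = NA, auto_unbox = TRUE)
  invisible(list(threshold = thr, blockcv_runs = bcv$runs,
                 blockcv_ensemble = bcv$ensemble, agreement = agreement))
}

# ensemble-mean suitability at point locations (cell-of-point lookup)
predict_ensemble_at <- function(ens, points) {
  rc <- point_to_cell(ens$spec, points$x, points$y)
  ens$mean$values[cbind(rc$row, rc$col)]
}

#' Aggregate risk: binary map, population at risk, overlap, IUs (stage 4)
#'
#' Binarises the ensemble mean (and every member) at the chosen threshold,
#' sums population at risk per country with the member-derived 95%
#' interval, overlays the second-disease binary layer when present, and
#' classifies implementation units. Writes `risk_summary.json`,
#' `risk_zones.csv`, `iu_table.csv`, `overlap.csv` and `occurrence.tif`.
#'
#' @param fit Result of [pipeline_fit()].
#' @param threshold Numeric threshold (e.g. from [pipeline_threshold()]).
#' @param run_dir Output directory.
#' @param config A [pipeline_config()].
#' @return List with `binary`, `risk`, `overlap` (or NULL), `ius`,
#'   `shares`, invisibly.
#' @export
pipeline_aggregate <- function(fit, threshold, run_dir,
                               config = pipeline_config()) {
  inp <- fit$inputs
  binary <- binarize(fit$ensemble$mean, threshold)
  members <- purrr::map(seq_len(ncol(fit$ensemble$members)), function(i) {
    binarize(member_raster(fit$ensemble, i), threshold)
  })
  zone_names <- dplyr::rename(inp$country_lookup, zone_index = "country_index",
                              zone = "country")
  risk <- population_at_risk(binary, inp$population, members, inp$countries,
                             zone_names)
  ov <- if (!is.null(inp$lf_binary)) {
    overlap_binary(binary, inp$lf_binary, inp$population)
  } else NULL
  ius <- classify_ius(binary, inp$ius, inp$mapped_flags,
                      min_fraction = config$min_fraction)
  n_elig <- sum(!ius$indeterminate)
  n_suit <- sum(ius$suitable)
  shares <- c(
    suitable_ius_pct = unname(share_percentages(n_suit, max(n_elig, 1))),
    needs_mapping_pct = if (n_suit > 0) {
      unname(share_percentages(sum(ius$needs_mapping), n_suit))
    } else NA_real_)
  write_raster(binary, file.path(run_dir, "occurrence.tif"))
  utils::write.csv(risk$zones, file.path(run_dir, "risk_zones.csv"),
                   row.names = FALSE)
  utils::write.csv(ius, file.path(run_dir, "iu_table.csv"), row.names = FALSE)
  if (!is.null(ov)) {
    utils::write.csv(ov$table, file.path(run_dir, "overlap.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(overall = risk$overall, threshold = threshold, shares = as.list(shares),
         n_suitable_ius = n_suit, n_ius = n_elig,
         provenance = provenance(config)),
    file.path(run_dir, "risk_summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(list(binary = binary, risk = risk, overlap = ov, ius = ius,
                 shares = shares))
}

#' Run the full pipeline on a scenario directory
#'
#' simulate (optional) -> fit -> threshold & block CV -> aggregate, all
#' seeded from the config. Every stage writes its artifacts under
#' `run_dir`.
#'
#' @param scenario_dir Scenario input directory; if it lacks a
#'   `scenario.yaml` and `scenario` is given, the scenario is simulated
#'   there first.
#' @param run_dir Output directory.
#' @param config A [pipeline_config()].
#' @param scenario Optional [scenario_spec()] to simulate.
#' @return List with all stage results, invisibly.
#' @export
run_pipeline <- function(scenario_dir, run_dir, config = pipeline_config(),
                         scenario = NULL) {
  if (!file.exists(file.path(scenario_dir, "scenario.yaml"))) {
    if (is.null(scenario)) stop("no scenario found and none supplied", call. = FALSE)
    pipeline_simulate(scenario, scenario_dir)
  }
  fit <- pipeline_fit(scenario_dir, run_dir, config)
  thr <- pipeline_threshold(fit, run_dir, config)
  agg <- pipeline_aggregate(fit, thr$threshold$threshold, run_dir, config)
  invisible(list(fit = fit, threshold = thr, aggregate = agg))
}
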