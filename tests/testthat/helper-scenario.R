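# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# desk-scale scenario used by most module tests (60 x 60 cells, 200 sites)
small_scenario <- function() {
  cached("small_scenario", function() {
    make_scenario(scenario_spec(n_rows = 60, n_cols = 60, n_survey_sites = 200,
                                n_ius = 24, rng_seed = 11))
  })
}

# weighted training frame for the small scenario
small_frame <- function() {
  cached("small_frame", function() {
    sc <- small_scenario()
    build_frame_from_scenario(sc, seed = 11)
  })
}

build_frame_from_scenario <- function(sc, seed) {
  labelled <- label_endemicity(suppressMessages(load_and_dedupe(sc$surveys)))
  w <- rescale_evidence(sc$evidence)
  w$country_index <- sc$country_lookup$country_index[
    match(w$country, sc$country_lookup$country)]
  elig <- sc$countries
  elig$mask <- elig$mask | !stack_valid_mask(sc$stack) |
    !(elig$values %in% w$country_index)
  elig$values[elig$mask] <- NA
  pseudo <- sample_pseudo_absences(elig, w, n = nrow(labelled),
                                   rng_seed = seed * 1000 + 7)
  suppressMessages(build_model_frame(labelled, pseudo, sc$stack))
}

# frame built directly from supplied columns (for learner/CV unit tests)
direct_frame <- function(df, covariates) {
  df <- tibble::as_tibble(df)
  if (!"weight" %in% names(df)) df$weight <- 1
  if (!"origin" %in% names(df)) df$origin <- "survey"
  attr(df, "covariates") <- covariates
  class(df) <- c("model_frame", class(df))
  df
}

# linearly separable toy frame on one covariate
separable_frame <- function(n = 20) {
  direct_frame(
    tibble::tibble(label = rep(c(1L, 0L), each = n / 2),
                   weight = 1,
                   x = seq_len(n), y = 1,
                   z = c(stats::rnorm(n / 2, 5, 0.3), stats::rnorm(n / 2, -5, 0.3))),
    covariates = "z")
}

# iid-covariate frame with labels unrelated to the covariates
null_frame <- function(n = 200, seed = 42) {
  withr::with_seed(seed, direct_frame(
    tibble::tibble(label = rep(c(0L, 1L), length.out = n),
                   weight = 1,
                   x = stats::runif(n, 0, 300), y = stats::runif(n, 0, 300),
                   a = stats::rnorm(n), b = stats::rnorm(n)),
    covariates = c("a", "b")))
}

# small gated run table for ensemble tests (GLM + RF on the small frame)
small_runs <- function() {
  cached("small_runs", function() {
    specs <- list(learner_spec("GLM", rng_seed = 5), learner_spec("RF", rng_seed = 5))
    suppressWarnings(suppressMessages(
      run_replicates(small_frame(), specs, n_reps = 5, rng_seed = 5)))
  })
}
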