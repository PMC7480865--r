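# Evaluate one fitted learner on its held-out split. Following the
# standard ensemble-framework convention, the run's TSS and PCC are taken
# at the threshold that maximises TSS on the evaluation predictions; on
# small evaluation sets this maximisation is optimistically biased (its
# null expectation is positive), which is why the rank-based, unbiased AUC
# is gated alongside it.
evaluate_fit <- function(fit, train, test, algorithm, replicate, split_seed) {
  p_test <- predict_prob(fit, test)
  opt <- optimal_threshold(test$label, p_test, test$weight)
  tibble::tibble(
    algorithm = algorithm, replicate = as.integer(replicate),
    split_seed = as.integer(split_seed),
    auc = opt$auc, tss = opt$tss, pcc = opt$accuracy, threshold = opt$threshold,
    fitted = list(fit))
}

stratified_split <- function(frame, train_fraction, seed, max_retries = 10) {
  n <- nrow(frame)
  for (attempt in 0:max_retries) {
    idx <- withr_seed(seed + attempt * 331, {
      unlist(purrr::map(split(seq_len(n), frame$label), function(ix) {
        sample(ix, max(1, round(train_fraction * length(ix))))
      }), use.names = FALSE)
    })
    test <- setdiff(seq_len(n), idx)
    if (length(unique(frame$label[idx])) == 2 &&
        length(unique(frame$label[test])) == 2) {
      if (attempt > 0) {
        message(sprintf("split reseeded %d time(s) to keep both classes in the test set",
                        attempt))
      }
      return(list(train = idx, test = test))
    }
  }
  stop("could not obtain a two-class train/test split", call. = FALSE)
}

#' Run the replicate-and-evaluate engine
#'
#' For each learner spec and each of `n_reps` replicates: draw a stratified
#' random `train_fraction` / `1 - train_fraction` split of the frame
#' (default 80/20), fit the learner on the training part, and score AUC,
#' TSS and PCC on the held-out part with observation weights. Splits with
#' a single-class test set are re-drawn from a derived seed (bounded
#' retries, logged). Fully deterministic given `rng_seed`.
#'
#' @param frame A `model_frame`.
#' @param specs List of [learner_spec()] objects.
#' @param n_reps Replicates per algorithm (default 50).
#' @param train_fraction Fraction of rows used for calibration (default 0.8).
#' @param rng_seed Integer master seed; per-run seeds are derived from
#'   (seed, algorithm, replicate).
#' @return A `model_runs` tibble: one row per run with `algorithm`,
#'   `replicate`, `split_seed`, `auc`, `tss`, `pcc`, `threshold` and the
#'   fitted learner in the `fitted` list-column.
#' @export
run_replicates <- function(frame, specs, n_reps = 50, train_fraction = 0.8,
                           rng_seed = 1) {
  stopifnot(n_reps >= 1, train_fraction > 0, train_fraction < 1)
  if (inherits(specs, "learner_spec")) specs <- list(specs)
  runs <- purrr::map_dfr(specs, function(sp) {
    purrr::map_dfr(seq_len(n_reps), function(rep_i) {
      sp_run <- derive_spec_seed(sp, rep_i + rng_seed * 131)
      split_seed <- sp_run$rng_seed
      sp_idx <- stratified_split(frame, train_fraction, split_seed)
      train <- frame[sp_idx$train, , drop = FALSE]
      test <- frame[sp_idx$test, , drop = FALSE]
      fit <- fit_learner(sp_run, train)
      evaluate_fit(fit, train, test, algorithm = sp$algorithm,
                   replicate = rep_i, split_seed = split_seed)
    })
  })
  class(runs) <- c("model_runs", class(runs))
  runs
}

#' Gate replicate runs on held-out skill
#'
#' Keeps exactly the runs with `auc >= auc_min` and `tss >= tss_min`
#' (boundary values are kept), preserving order. The defaults are the
#' gates of the published analysis: runs with AUC below 0.8 or TSS below
#' 0.7 are disregarded when assembling the final model.
#'
#' @param runs A `model_runs` tibble.
#' @param auc_min,tss_min Gate thresholds.
#' @return The selected subset, same class.
#' @export
select_runs <- function(runs, auc_min = 0.8, tss_min = 0.7) {
  stopifnot(nrow(runs) > 0)
  sel <- dplyr::filter(runs, .data$auc >= auc_min, .data$tss >= tss_min)
  if (nrow(sel) == 0) {
    stop(sprintf(paste0("no runs pass the gates (AUC >= %.2f and TSS >= %.2f); ",
                        "best run had AUC %.3f, TSS %.3f -- consider relaxing the gates"),
                 auc_min, tss_min, max(runs$auc), max(runs$tss)), call. = FALSE)
  }
  sel
}

# AUC-weighted mean of member predictions (rows = cells, cols = members)
# with equal-tail empirical quantile bounds across members.
combine_weighted <- function(pred, weights, probs = c(0.025, 0.975)) {
  stopifnot(ncol(pred) == length(weights), all(weights > 0))
  mean <- as.numeric(pred %*% weights) / sum(weights)
  qs <- t(apply(pred, 1, stats::quantile, probs = probs, names = FALSE))
  list(mean = mean, lower = qs[, 1], upper = qs[, 2])
}

#' Build the gated, AUC-weighted ensemble prediction
#'
#' Every selected run predicts presence probability over all stack-valid
#' cells; the ensemble surface is the weighted mean with the run's held-out
#' AUC as its weight, and the per-cell lower/upper bounds are the 2.5% and
#' 97.5% empirical quantiles of the member predictions. Cells invalid in
#' any stack layer stay masked.
#'
#' @param runs A (gated) `model_runs` tibble.
#' @param stack A `covariate_stack` carrying all training covariates.
#' @return An `ensemble_prediction`: list with `mean`, `lower`, `upper`
#'   (`grid_raster`s), `members` (cells-by-runs matrix over valid cells),
#'   `runs` (metadata tibble with `weight`), `cells` (row/col of the valid
#'   cells) and `spec`.
#' @export
ensemble_predict <- function(runs, stack) {
  stopifnot(nrow(runs) >= 1)
  cells <- stack_cell_table(stack)
  missing_cov <- setdiff(
    unique(unlist(purrr::map(runs$fitted, "covariates"))), stack$names)
  if (length(missing_cov) > 0) {
    stop(sprintf("stack lacks covariate(s) used in training: %s",
                 paste(missing_cov, collapse = ", ")), call. = FALSE)
  }
  pred <- do.call(cbind, purrr::map(runs$fitted, predict_prob, features = cells))
  cmb <- combine_weighted(pred, runs$auc)
  as_raster <- function(v) {
    m <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
    m[cbind(cells$row, cells$col)] <- v
    grid_raster(stack$spec, m)
  }
  meta <- dplyr::mutate(dplyr::select(tibble::as_tibble(runs), -"fitted"),
                        run_id = dplyr::row_number(), weight = .data$auc)
  structure(list(mean = as_raster(cmb$mean), lower = as_raster(cmb$lower),
                 upper = as_raster(cmb$upper), members = pred, runs = meta,
                 cells = cells[c("row", "col", "x", "y")], spec = stack$spec),
            class = "ensemble_prediction")
}

#' Raster of one ensemble member's predictions
#'
#' @param ens An `ensemble_prediction`.
#' @param run_id Member index (row of `ens$runs`).
#' @return A `grid_raster`.
#' @export
member_raster <- function(ens, run_id) {
  stopifnot(run_id >= 1, run_id <= ncol(ens$members))
  m <- matrix(NA_real_, ens$spec$n_rows, ens$spec$n_cols)
  m[cbind(ens$cells$row, ens$cells$col)] <- ens$members[, run_id]
  grid_raster(ens$spec, m)
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> %d members over %d valid cells; mean in [%.3f, %.3f]\n",
              ncol(x$members), nrow(x$members),
              min(raster_values(x$mean)), max(raster_values(x$mean))))
  invisible(x)
}

#' Tidy the member table of an ensemble
#'
#' @param x An `ensemble_prediction`.
#' @param ... Unused.
#' @return Tibble of member metadata (algorithm, replicate, scores, weight).
#' @method tidy ensemble_prediction
#' @export
tidy.ensemble_prediction <- function(x, ...) x$runs

#' One-row ensemble summary
#'
#' @param x An `ensemble_prediction`.
#' @param ... Unused.
#' @return Tibble: member count, AUC/TSS ranges, mean suitability.
#' @method glance ensemble_prediction
#' @export
glance.ensemble_prediction <- function(x, ...) {
  tibble::tibble(n_members = ncol(x$members),
                 n_algorithms = dplyr::n_distinct(x$runs$algorithm),
                 auc_min = min(x$runs$auc), auc_max = max(x$runs$auc),
                 tss_min = min(x$runs$tss), tss_max = max(x$runs$tss),
                 mean_suitability = mean(raster_values(x$mean)))
}
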