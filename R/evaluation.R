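#' Weighted area under the ROC curve
#'
#' The AUC is computed as the weighted probability that a randomly drawn
#' presence receives a higher score than a randomly drawn absence, with
#' ties counted one half -- the Mann-Whitney formulation. Observation
#' weights enter as sampling weights on both classes.
#'
#' @param labels 0/1 vector (1 = presence).
#' @param scores Numeric scores (higher = more presence-like).
#' @param weights Optional positive observation weights (default 1).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))  # 3 of 4 pairs concordant
roc_auc <- function(labels, scores, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(labels))
  stopifnot(length(labels) == length(scores), length(weights) == length(scores),
            all(weights > 0))
  labels <- as.numeric(labels)
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  d <- dplyr::arrange(tibble::tibble(s = scores, l = labels, w = weights), .data$s)
  grp <- dplyr::summarise(dplyr::group_by(d, .data$s),
                          wp = sum(.data$w[.data$l == 1]),
                          wa = sum(.data$w[.data$l == 0]), .groups = "drop")
  wa_below <- cumsum(dplyr::lag(grp$wa, default = 0))
  conc <- sum(grp$wp * (wa_below + 0.5 * grp$wa))
  conc / (sum(grp$wp) * sum(grp$wa))
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`; a prevalence-insensitive skill
#' score in `[-1, 1]` (0 = no skill).
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return The TSS.
#' @export
tss <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}

#' Weighted confusion summary at a threshold
#'
#' A score is classified presence iff `score >= threshold`
#' (presence-inclusive at the cut-off). Counts are weighted.
#'
#' @inheritParams roc_auc
#' @param threshold Classification threshold.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `pcc` (proportion correctly classified) and `tss`.
#' @export
confusion_at <- function(labels, scores, weights = NULL, threshold) {
  if (is.null(weights)) weights <- rep(1, length(labels))
  labels <- as.numeric(labels)
  pred <- scores >= threshold
  tp <- sum(weights[labels == 1 & pred]); fn <- sum(weights[labels == 1 & !pred])
  tn <- sum(weights[labels == 0 & !pred]); fp <- sum(weights[labels == 0 & pred])
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 pcc = (tp + tn) / (tp + tn + fp + fn),
                 tss = sens + spec - 1)
}

threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  sort(unique(c(s, (s[-1] + s[-length(s)]) / 2)))
}

#' Optimal presence threshold
#'
#' Scans all distinct scores plus the midpoints between consecutive
#' distinct scores and returns the threshold maximising
#' `sensitivity + specificity` (equivalently the TSS) -- the best trade-off
#' point between the two error rates. Ties are broken by higher accuracy,
#' then by the lower threshold.
#'
#' @inheritParams roc_auc
#' @return One-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `tss`, `auc`.
#' @export
optimal_threshold <- function(labels, scores, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(labels))
  labels <- as.numeric(labels)
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("threshold optimisation requires both classes present", call. = FALSE)
  }
  # vectorised sweep: per unique score, cumulative class weights below it
  d <- dplyr::arrange(tibble::tibble(s = scores, l = labels, w = weights), .data$s)
  grp <- dplyr::summarise(dplyr::group_by(d, .data$s),
                          w1 = sum(.data$w[.data$l == 1]),
                          w0 = sum(.data$w[.data$l == 0]), .groups = "drop")
  m <- nrow(grp)
  cum1 <- c(0, cumsum(grp$w1)); cum0 <- c(0, cumsum(grp$w0))
  W1 <- cum1[m + 1]; W0 <- cum0[m + 1]
  # candidates in ascending order: s1, m1, s2, m2, ..., sm; for candidate t,
  # i = count of unique scores strictly below t (a score at t counts presence)
  if (m > 1) {
    mids <- (grp$s[-1] + grp$s[-m]) / 2
    cand <- c(rbind(grp$s[-m], mids), grp$s[m])
    i <- c(rbind(seq_len(m - 1) - 1L, seq_len(m - 1)), m - 1L)
  } else {
    cand <- grp$s; i <- 0L
  }
  sens <- (W1 - cum1[i + 1]) / W1
  spec <- cum0[i + 1] / W0
  acc <- (W1 - cum1[i + 1] + cum0[i + 1]) / (W1 + W0)
  tss_v <- sens + spec - 1
  # round before ranking so float noise cannot override the tie-break order
  ord <- order(-round(tss_v, 12), -round(acc, 12), cand)[1]
  tibble::tibble(threshold = cand[ord], sensitivity = sens[ord],
                 specificity = spec[ord], accuracy = acc[ord], tss = tss_v[ord],
                 auc = roc_auc(labels, scores, weights))
}

#' Assign spatial blocks to cross-validation folds
#'
#' Tiles the grid extent with square blocks of side `block_km` anchored at
#' `(x_min, y_min)` (half-open ownership, as for cells), assigns the blocks
#' fold labels `1..k` balanced in count and shuffled by `rng_seed`, and
#' gives every point its block's fold. The continental analysis this
#' mirrors used 2,000-km blocks and five folds; on desk-scale scenarios a
#' smaller `block_km` keeps all folds populated.
#'
#' @param spec A `grid_spec` describing the modelling extent.
#' @param points Data frame with `x`, `y` columns.
#' @param block_km Block side length in coordinate units (default 2000).
#' @param k Number of folds (default 5).
#' @param rng_seed Integer seed for the fold shuffle.
#' @return A `fold_assignment`: list with `block_size_km`, `blocks`
#'   (tibble: `block_id`, `bx`, `by`, `fold`) and `points` (input plus
#'   `block_id`, `fold`).
#' @export
make_spatial_blocks <- function(spec, points, block_km = 2000, k = 5, rng_seed = 1) {
  stopifnot(block_km > 0, k >= 2)
  points <- tibble::as_tibble(points)
  nbx <- ceiling((spec_x_max(spec) - spec$x_min) / block_km)
  nby <- ceiling((spec_y_max(spec) - spec$y_min) / block_km)
  blocks <- tidyr::expand_grid(bx = seq_len(nbx) - 1L, by = seq_len(nby) - 1L)
  blocks$block_id <- seq_len(nrow(blocks))
  folds <- rep(seq_len(k), length.out = nrow(blocks))
  blocks$fold <- withr_seed(rng_seed, sample(folds))
  bx <- floor((points$x - spec$x_min) / block_km)
  by <- floor((points$y - spec$y_min) / block_km)
  pt_block <- match(paste(bx, by), paste(blocks$bx, blocks$by))
  if (anyNA(pt_block)) stop("points fall outside the block tiling extent", call. = FALSE)
  points$block_id <- blocks$block_id[pt_block]
  points$fold <- blocks$fold[pt_block]
  empty <- setdiff(seq_len(k), unique(points$fold))
  if (length(empty) > 0) {
    stop(sprintf("fold(s) %s contain no points; use a smaller block_km or smaller k",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  structure(list(block_size_km = block_km, blocks = blocks, points = points, k = k),
            class = "fold_assignment")
}

# evaluate with a local RNG state, leaving the global stream untouched
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Spatial block cross-validation
#'
#' For each fold, fits every learner spec on the points of all other folds
#' and evaluates AUC, TSS and PCC on the held-out fold -- test data are
#' spatially separated from training data at block granularity, so the
#' evaluation is less flattered by spatial autocorrelation than random
#' splits. Folds whose test set has a single class are skipped with a
#' warning. When a stack is given, an AUC-weighted ensemble of the fold
#' models is built for comparison with the regular-CV ensemble; by default
#' it combines all fold models (each fold contributes only one model per
#' algorithm, so skill-gating here would routinely leave the spatial
#' comparison undefined at desk scale) -- pass `auc_min`/`tss_min` to gate.
#'
#' @param frame A `model_frame`.
#' @param specs List of [learner_spec()] objects.
#' @param folds A `fold_assignment` whose points match `frame` rows (by
#'   position).
#' @param stack Optional `covariate_stack` on which to predict the
#'   block-CV ensemble.
#' @param auc_min,tss_min Optional gates applied to the fold models before
#'   ensembling (default NULL: keep all).
#' @return List with `runs` (a `model_runs` tibble, `replicate` = fold) and
#'   `ensemble` (an `ensemble_prediction` or NULL).
#' @export
block_cv <- function(frame, specs, folds, stack = NULL,
                     auc_min = NULL, tss_min = NULL) {
  stopifnot(inherits(folds, "fold_assignment"))
  fold_of <- folds$points$fold
  stopifnot(length(fold_of) == nrow(frame))
  runs <- purrr::map_dfr(sort(unique(fold_of)), function(f) {
    test <- frame[fold_of == f, , drop = FALSE]
    train <- frame[fold_of != f, , drop = FALSE]
    if (length(unique(test$label)) < 2 || length(unique(train$label)) < 2) {
      warning(sprintf("fold %d skipped: single-class train or test set", f),
              call. = FALSE)
      return(NULL)
    }
    purrr::map_dfr(specs, function(sp) {
      fit <- fit_learner(derive_spec_seed(sp, f), train)
      evaluate_fit(fit, train, test, algorithm = sp$algorithm, replicate = f,
                   split_seed = sp$rng_seed)
    })
  })
  if (nrow(runs) == 0) stop("all folds unusable for block CV", call. = FALSE)
  class(runs) <- c("model_runs", class(runs))
  ens <- NULL
  if (!is.null(stack)) {
    sel <- if (is.null(auc_min) && is.null(tss_min)) runs else {
      select_runs(runs, auc_min = auc_min %||% 0, tss_min = tss_min %||% -1)
    }
    ens <- ensemble_predict(sel, stack)
  }
  list(runs = runs, ensemble = ens)
}

#' Pearson agreement between two prediction rasters
#'
#' Correlation over the jointly valid cells; the statistic used to compare
#' ensembles built under regular and spatial-block cross-validation.
#'
#' @param a,b Aligned `grid_raster` objects.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
compare_predictions_pearson <- function(a, b) {
  stop_if_misaligned(a, b)
  ok <- !a$mask & !b$mask
  if (sum(ok) < 2) stop("fewer than 2 jointly valid cells", call. = FALSE)
  x <- a$values[ok]; y <- b$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the prediction rasters", call. = FALSE)
  }
  stats::cor(x, y)
}
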