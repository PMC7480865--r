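ALGORITHMS <- c("GLM", "GAM", "GBM", "ANN", "MARS", "RF")

#' Specify a suitability learner
#'
#' One spec per algorithm; the six algorithms of the ensemble are GLM
#' (logistic regression), GAM (penalised regression splines via mgcv), GBM
#' (gradient-boosted trees via xgboost, tuned with a slow learning rate of
#' 0.005 and trees deep enough for five-way interactions), ANN (single
#' hidden layer, nnet), MARS (forward hinge-basis selection with a weighted
#' logistic fit) and RF (probability random forest via ranger). All
#' algorithms accept observation weights and fit presence probability.
#'
#' @param algorithm One of `"GLM"`, `"GAM"`, `"GBM"`, `"ANN"`, `"MARS"`,
#'   `"RF"`.
#' @param hyper Named list of hyperparameter overrides. GBM defaults:
#'   `learning_rate = 0.005`, `interaction_depth = 5`, `n_trees = 1000`,
#'   `subsample = 0.5`. RF: `n_trees = 500`. GAM: `k = 8` basis functions
#'   per smooth. ANN: `size = 5`, `decay = 0.01`, `maxit = 200`. MARS:
#'   `max_terms = 14`, `n_knots = 7`.
#' @param rng_seed Integer seed for stochastic algorithms (GBM, RF, ANN).
#' @param drop_zero_variance Drop constant covariates (with a warning)
#'   instead of retaining them (default FALSE: retain, warn).
#' @return A `learner_spec`.
#' @export
learner_spec <- function(algorithm, hyper = list(), rng_seed = 1,
                         drop_zero_variance = FALSE) {
  algorithm <- match.arg(toupper(algorithm), ALGORITHMS)
  defaults <- switch(algorithm,
    GBM = list(learning_rate = 0.005, interaction_depth = 5,
               n_trees = 1000, subsample = 0.5),
    RF = list(n_trees = 500),
    GAM = list(k = 8),
    ANN = list(size = 5, decay = 0.01, maxit = 200),
    MARS = list(max_terms = 14, n_knots = 7),
    list())
  hyper <- utils::modifyList(defaults, hyper)
  structure(list(algorithm = algorithm, hyper = hyper,
                 rng_seed = as.integer(rng_seed),
                 drop_zero_variance = isTRUE(drop_zero_variance)),
            class = "learner_spec")
}

# per-run seed derived from (spec seed, replicate index) so the replicate
# loop is reproducible and order-independent
derive_spec_seed <- function(spec, replicate) {
  idx <- match(spec$algorithm, ALGORITHMS)
  spec$rng_seed <- as.integer((spec$rng_seed * 48271 + idx * 7919 + replicate * 104729) %%
                                2147483647L)
  spec
}

frame_covariates <- function(frame) {
  cov <- attr(frame, "covariates")
  if (is.null(cov)) {
    cov <- setdiff(names(frame), c("site_id", "label", "weight", "x", "y",
                                   "origin", "valid", "country", "cases", "source"))
  }
  cov
}

#' Fit one suitability learner
#'
#' Fits `spec` to a weighted model frame, honouring observation weights in
#' every algorithm, and returns an object whose [predict_prob()] output is
#' a presence probability. Stochastic algorithms (GBM, RF, ANN) are seeded
#' from `spec$rng_seed`, so repeated fits are identical.
#'
#' @param spec A [learner_spec()].
#' @param frame A `model_frame` (see [build_model_frame()]): tibble with
#'   `label` (0/1), `weight` and covariate columns.
#' @return A `fitted_learner`.
#' @export
fit_learner <- function(spec, frame) {
  stopifnot(inherits(spec, "learner_spec"))
  cov <- frame_covariates(frame)
  if (length(unique(frame$label)) < 2) {
    stop("model frame contains a single class; models untrainable", call. = FALSE)
  }
  if (is.null(frame$weight)) frame$weight <- rep(1, nrow(frame))
  stopifnot(all(frame$weight > 0))
  sds <- vapply(cov, function(nm) stats::sd(frame[[nm]]), 0)
  if (any(sds == 0)) {
    flat <- cov[sds == 0]
    warning(sprintf("covariate(s) with zero variance: %s%s",
                    paste(flat, collapse = ", "),
                    if (spec$drop_zero_variance) " (dropped)" else " (retained)"),
            call. = FALSE)
    if (spec$drop_zero_variance) cov <- setdiff(cov, flat)
  }
  X <- as.matrix(frame[cov])
  y <- as.numeric(frame$label)
  w <- frame$weight
  h <- spec$hyper
  fit <- switch(spec$algorithm,
    GLM = {
      dat <- data.frame(.y = y, X, check.names = FALSE)
      fml <- stats::reformulate(sprintf("`%s`", cov), response = ".y")
      suppressWarnings(stats::glm(fml, data = dat, family = stats::quasibinomial(),
                                  weights = w))
    },
    GAM = {
      dat <- data.frame(.y = y, X, check.names = FALSE)
      k <- min(h$k, nrow(frame) - 1)
      terms <- vapply(cov, function(nm) {
        if (length(unique(frame[[nm]])) > k) sprintf("s(`%s`, k = %d)", nm, k)
        else sprintf("`%s`", nm)
      }, "")
      fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      suppressWarnings(mgcv::gam(fml, data = dat, family = stats::quasibinomial(),
                                 weights = w, method = "REML"))
    },
    GBM = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w)
      withr_seed(spec$rng_seed,
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = h$learning_rate,
                        max_depth = h$interaction_depth, subsample = h$subsample,
                        nthread = 1, seed = spec$rng_seed),
          data = dtrain, nrounds = h$n_trees, verbose = 0))
    },
    RF = {
      dat <- data.frame(.y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = dat,
                     probability = TRUE, num.trees = h$n_trees,
                     case.weights = w, seed = spec$rng_seed, num.threads = 1)
    },
    ANN = {
      sc_center <- colMeans(X); sc_scale <- pmax(apply(X, 2, stats::sd), 1e-12)
      Xs <- scale(X, sc_center, sc_scale)
      nn <- withr_seed(spec$rng_seed,
        nnet::nnet(Xs, y, weights = w, size = h$size, decay = h$decay,
                   maxit = h$maxit, entropy = TRUE, trace = FALSE))
      list(net = nn, center = sc_center, scale = sc_scale)
    },
    MARS = fit_mars_hinge(X, y, w, max_terms = h$max_terms, n_knots = h$n_knots)
  )
  structure(list(spec = spec, fit = fit, covariates = cov),
            class = "fitted_learner")
}

#' @export
print.fitted_learner <- function(x, ...) {
  cat(sprintf("<fitted_learner> %s on %d covariates\n",
              x$spec$algorithm, length(x$covariates)))
  invisible(x)
}

#' Predict presence probability
#'
#' @param model A `fitted_learner`.
#' @param features Data frame holding the training covariate columns by
#'   name; extra columns are ignored, but a missing covariate is an error
#'   (names are matched strictly, never positionally). Rows with missing
#'   covariate values yield `NA`.
#' @return Numeric vector of probabilities in `[0, 1]` (NA for masked rows).
#' @export
predict_prob <- function(model, features) {
  stopifnot(inherits(model, "fitted_learner"))
  missing_cov <- setdiff(model$covariates, names(features))
  if (length(missing_cov) > 0) {
    stop(sprintf("covariate(s) absent from prediction features: %s",
                 paste(missing_cov, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(as.data.frame(features)[model$covariates])
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (!any(ok)) return(out)
  Xok <- X[ok, , drop = FALSE]
  fit <- model$fit
  p <- switch(model$spec$algorithm,
    GLM = stats::predict(fit, newdata = as.data.frame(Xok), type = "response"),
    GAM = as.numeric(stats::predict(fit, newdata = as.data.frame(Xok),
                                    type = "response")),
    GBM = stats::predict(fit, xgboost::xgb.DMatrix(Xok)),
    RF = stats::predict(fit, data = as.data.frame(Xok),
                        num.threads = 1)$predictions[, "1"],
    ANN = as.numeric(stats::predict(fit$net,
                                    scale(Xok, fit$center, fit$scale))),
    MARS = predict_mars_hinge(fit, Xok)
  )
  out[ok] <- pmin(pmax(as.numeric(p), 0), 1)
  out
}

#' Partial-dependence curve of a fitted learner
#'
#' The marginal effect of one covariate on the predicted presence
#' probability after averaging over the effects of all others: for each
#' grid value `v`, the covariate column of every frame row is set to `v`
#' and the mean prediction recorded.
#'
#' @param model A `fitted_learner`.
#' @param frame The model frame over which to average.
#' @param covariate Covariate name.
#' @param grid Numeric vector of values at which to evaluate the curve.
#' @return Tibble with columns `covariate`, `value`, `yhat`.
#' @export
partial_dependence <- function(model, frame, covariate, grid) {
  stopifnot(covariate %in% frame_covariates(frame))
  if (length(grid) == 0) stop("empty partial-dependence grid", call. = FALSE)
  yhat <- vapply(grid, function(v) {
    mod <- frame
    mod[[covariate]] <- v
    mean(predict_prob(model, mod))
  }, 0)
  tibble::tibble(covariate = covariate, value = as.numeric(grid), yhat = yhat)
}

# --- MARS: forward hinge-basis selection + weighted logistic fit ---------
# Candidate basis: hinge pairs max(x - t, 0), max(t - x, 0) at interior
# quantile knots of each covariate. Greedy forward selection by binomial
# deviance, then one logistic fit on the selected basis. Deterministic.

mars_basis <- function(X, knots) {
  cols <- list(); info <- list()
  for (j in seq_len(ncol(X))) {
    for (t in knots[[j]]) {
      cols[[length(cols) + 1]] <- pmax(X[, j] - t, 0)
      info[[length(info) + 1]] <- list(j = j, t = t, dir = 1)
      cols[[length(cols) + 1]] <- pmax(t - X[, j], 0)
      info[[length(info) + 1]] <- list(j = j, t = t, dir = -1)
    }
  }
  list(B = do.call(cbind, cols), info = info)
}

fit_mars_hinge <- function(X, y, w, max_terms = 14, n_knots = 7) {
  probs <- seq(0.1, 0.9, length.out = n_knots)
  knots <- purrr::map(seq_len(ncol(X)), function(j)
    unique(stats::quantile(X[, j], probs, names = FALSE)))
  cand <- mars_basis(X, knots)
  chosen <- integer(0)
  dev_of <- function(cols) {
    B <- cbind(1, cand$B[, cols, drop = FALSE])
    f <- suppressWarnings(stats::glm.fit(B, y, weights = w,
                                         family = stats::binomial()))
    f$deviance
  }
  current <- dev_of(chosen)
  repeat {
    if (length(chosen) >= max_terms) break
    remaining <- setdiff(seq_along(cand$info), chosen)
    devs <- vapply(remaining, function(k) dev_of(c(chosen, k)), 0)
    best <- which.min(devs)
    if (devs[best] >= current - 1e-8) break
    chosen <- c(chosen, remaining[best])
    current <- devs[best]
  }
  B <- cbind(1, cand$B[, chosen, drop = FALSE])
  f <- suppressWarnings(stats::glm.fit(B, y, weights = w,
                                       family = stats::binomial()))
  list(coef = f$coefficients, terms = cand$info[chosen])
}

predict_mars_hinge <- function(fit, X) {
  B <- cbind(1, do.call(cbind, c(list(matrix(0, nrow(X), 0)),
    purrr::map(fit$terms, function(tm) {
      if (tm$dir == 1) pmax(X[, tm$j] - tm$t, 0) else pmax(tm$t - X[, tm$j], 0)
    }))))
  coef <- fit$coef
  coef[is.na(coef)] <- 0
  stats::plogis(as.numeric(B %*% coef))
}
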