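# Independent oracles, deliberately naive: brute-force pair counting for
# the AUC, exhaustive candidate enumeration for the threshold, all-pairs
# search for the distance transform, dense-matrix Moran's I.

brute_auc <- function(labels, scores, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(labels))
  p <- which(labels == 1); a <- which(labels == 0)
  num <- 0; den <- 0
  for (i in p) for (j in a) {
    w <- weights[i] * weights[j]
    num <- num + w * ((scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j]))
    den <- den + w
  }
  num / den
}

brute_optimal_threshold <- function(labels, scores, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(labels))
  s <- sort(unique(scores))
  cand <- sort(unique(c(s, (s[-1] + s[-length(s)]) / 2)))
  best <- NULL
  for (t in cand) {
    cf <- confusion_at(labels, scores, weights, t)
    key <- c(cf$tss, cf$pcc, -t)
    if (is.null(best) || key[1] > best$key[1] + 1e-12 ||
        (abs(key[1] - best$key[1]) <= 1e-12 &&
         (key[2] > best$key[2] + 1e-12 ||
          (abs(key[2] - best$key[2]) <= 1e-12 && key[3] > best$key[3])))) {
      best <- list(threshold = t, tss = cf$tss, acc = cf$pcc, key = key)
    }
  }
  best
}

brute_distance <- function(feature_mask) {
  spec <- feature_mask$spec
  cc <- cell_centres(spec)
  feat <- which(as.vector(t(feature_mask$values)) == 1)
  d <- vapply(seq_len(nrow(cc)), function(i) {
    min(sqrt((cc$x[i] - cc$x[feat])^2 + (cc$y[i] - cc$y[feat])^2))
  }, 0)
  matrix(d, spec$n_rows, spec$n_cols, byrow = TRUE)
}

# Moran's I with rook adjacency on a full grid
morans_i <- function(m) {
  x <- m - mean(m)
  num <- sum(x[-1, ] * x[-nrow(m), ]) + sum(x[, -1] * x[, -ncol(m)])
  w_tot <- (nrow(m) - 1) * ncol(m) + nrow(m) * (ncol(m) - 1)
  (length(m) / (2 * w_tot)) * (2 * num) / sum(x^2)
}
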