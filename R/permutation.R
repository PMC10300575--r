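## Permutation-based significance: a label-shuffling null for the selected
## model's AUC, and a Welch-t null for individual features averaged across
## prevalence thresholds with Bonferroni correction.

#' Welch's t statistic
#'
#' `(mean_x - mean_y) / sqrt(s2_x/n_x + s2_y/n_y)` with n-1 variance
#' denominators; cross-checked against [stats::t.test()] in the test suite.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return The t statistic.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

## Column-wise Welch t for a matrix against binary labels; vectorized so the
## permutation null can be computed by matrix products.
welch_t_cols <- function(X, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  v1 <- (colSums(X[y == 1, , drop = FALSE]^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(X[y == 0, , drop = FALSE]^2) - n0 * m0^2) / (n0 - 1)
  (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
}

#' Permutation test of the selected model's AUC
#'
#' The final model's features undergo SMOTE once; each permutation shuffles
#' the decline labels, splits the data into stratified train/test sets
#' (default 80/20), trains a linear SVC on the training part and computes
#' the AUC on the test part. The p-value is the add-one-corrected fraction
#' of permutation AUCs at or above the observed AUC.
#'
#' @param x matrix restricted to the final support, or a `decline_model`
#'   (its chosen support and LOO AUC are used).
#' @param labels binary labels (ignored for a `decline_model`).
#' @param observed the observed AUC (ignored for a `decline_model`).
#' @param n_perm number of permutations (the reference protocol uses 10000).
#' @param train_frac training fraction of the stratified split.
#' @param cost SVC regularization constant.
#' @param smote_k SMOTE neighbour count.
#' @param seed RNG seed.
#' @return A `permutation_test`: `observed_stat`, `null_stats`, `n_perm`,
#'   `p_value` in (0, 1].
#' @export
model_permutation_test <- function(x, labels = NULL, observed = NULL,
                                   n_perm = 10000, train_frac = 0.8,
                                   cost = 1, smote_k = 5, seed = 1) {
  if (inherits(x, "decline_model")) {
    m <- x
    if (is.null(m$final)) stop("model has no final support to test")
    div <- m$final$div
    xs <- sweep(m$x, 2, div, "/")
    x <- xs[, m$final$support, drop = FALSE]
    labels <- m$y
    observed <- observed %||% m$auc
    cost <- m$cost
  }
  stopifnot(!is.null(labels), !is.null(observed))
  y <- as.integer(labels)
  set.seed(seed)
  b <- smote(as.matrix(x), y, smote_k)
  xb <- b$x; yb <- b$y
  n <- length(yb)
  i1 <- which(yb == 1); i0 <- which(yb == 0)
  n1tr <- max(1L, round(train_frac * length(i1)))
  n0tr <- max(1L, round(train_frac * length(i0)))
  null_stats <- numeric(n_perm)
  for (bb in seq_len(n_perm)) {
    yp <- sample(yb)
    repeat {
      j1 <- which(yp == 1); j0 <- which(yp == 0)
      tr <- c(sample(j1, min(n1tr, length(j1) - 1L)),
              sample(j0, min(n0tr, length(j0) - 1L)))
      te <- setdiff(seq_len(n), tr)
      if (length(unique(yp[tr])) == 2L && length(unique(yp[te])) == 2L) break
      yp <- sample(yb)  # degenerate split: resample
    }
    m <- svc_fit(xb[tr, , drop = FALSE], yp[tr], cost)
    null_stats[bb] <- auc_score(svc_decision(m, xb[te, , drop = FALSE]), yp[te])
  }
  p <- (1 + sum(null_stats >= observed, na.rm = TRUE)) / (n_perm + 1)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 n_perm = n_perm, p_value = p), class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test: observed = %.4f, null mean = %.4f, p = %.4g (%d permutations)\n",
              x$observed_stat, mean(x$null_stats, na.rm = TRUE), x$p_value,
              x$n_perm))
  invisible(x)
}

#' Per-feature permutation test (Welch-t null)
#'
#' For each feature and prevalence threshold, the observed Welch t between
#' decliners and non-decliners is compared with a null built by shuffling
#' the labels jointly across features (preserving inter-feature
#' correlation); per-threshold p-values count |t_null| >= |t_obs| with the
#' add-one correction, are averaged across thresholds, and Bonferroni
#' multiplied by the number of features (capped at 1).
#'
#' @param xlist list of feature matrices (one per threshold) sharing
#'   columns, or a single matrix.
#' @param labels binary labels.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return Data frame: feature, observed t per first threshold, mean
#'   permutation p across thresholds, Bonferroni-corrected p.
#' @export
feature_permutation_test <- function(xlist, labels, n_perm = 10000, seed = 1) {
  if (is.matrix(xlist)) xlist <- list(xlist)
  xlist <- lapply(xlist, function(m) if (inherits(m, "feature_matrix")) m$x else m)
  y <- as.integer(labels)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) stop("both groups need >= 2 patients")
  p_feats <- ncol(xlist[[1]])
  set.seed(seed)
  perms <- replicate(n_perm, sample(y))
  pmat <- matrix(NA_real_, p_feats, length(xlist))
  t_obs_first <- NULL
  for (t in seq_along(xlist)) {
    X <- xlist[[t]]
    t_obs <- welch_t_cols(X, y)
    zerovar <- !is.finite(t_obs)
    if (any(zerovar)) {
      warning(sum(zerovar), " feature(s) with zero variance in both groups; p = 1")
      t_obs[zerovar] <- 0
    }
    if (t == 1) t_obs_first <- t_obs
    exceed <- numeric(p_feats)
    for (bb in seq_len(n_perm)) {
      t_null <- welch_t_cols(X, perms[, bb])
      exceed <- exceed + (abs(t_null) >= abs(t_obs) | !is.finite(t_null))
    }
    pmat[, t] <- (1 + exceed) / (n_perm + 1)
    pmat[zerovar, t] <- 1
  }
  mean_p <- rowMeans(pmat)
  data.frame(feature = colnames(xlist[[1]]) %||% paste0("f", seq_len(p_feats)),
             t_observed = t_obs_first, mean_p = mean_p,
             p_bonferroni = pmin(1, mean_p * p_feats),
             stringsAsFactors = FALSE)
}
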