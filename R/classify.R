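## SMOTE-balanced linear SVC inside leave-one-out cross-validation over the
## SCAD candidate supports, model selection by pooled AUC, weighted feature
## importance, and the main decline_model() fitting interface.

#' Synthetic minority over-sampling (SMOTE)
#'
#' Balances a binary training set by interpolating new minority samples
#' between each drawn minority point and one of its k nearest minority
#' neighbours: `x_i + u (x_nn - x_i)` with u ~ Uniform(0, 1). Classes are
#' returned at equal counts. Uses the current RNG state (seed it for
#' determinism).
#'
#' @param x numeric matrix of training rows.
#' @param y 0/1 labels.
#' @param k neighbour count (reduced if the minority class is small).
#' @return List with augmented `x` and `y`.
#' @export
smote <- function(x, y, k = 5) {
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  if (tab[1] == tab[2]) return(list(x = x, y = y))
  minority <- as.integer(names(which.min(tab)))
  need <- abs(tab[1] - tab[2])
  xm <- x[y == minority, , drop = FALSE]
  nm <- nrow(xm)
  if (nm < 2) stop("SMOTE requires at least 2 minority samples")
  k <- min(k, nm - 1)
  dmat <- as.matrix(dist(xm))
  diag(dmat) <- Inf
  ord <- apply(dmat, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1) matrix(ord, ncol = 1) else t(ord)
  base <- sample(nm, need, replace = TRUE)
  pick <- nn[cbind(base, sample(k, need, replace = TRUE))]
  u <- runif(need)
  synth <- xm[base, , drop = FALSE] +
    u * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  list(x = rbind(x, synth), y = c(y, rep(minority, need)))
}

## Linear SVC wrappers around e1071. Decision values are oriented so that
## positive favours class "1" regardless of e1071's internal label order.
svc_fit <- function(x, y, cost = 1, class_weights = NULL) {
  f <- factor(y, levels = c(0, 1))
  e1071::svm(x, f, kernel = "linear", cost = cost, scale = FALSE,
             class.weights = class_weights)
}

svc_decision <- function(model, newx) {
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1)
  d <- attr(predict(model, newx, decision.values = TRUE), "decision.values")
  if (colnames(d)[1] == "0/1") -d[, 1] else d[, 1]
}

svc_weights <- function(model) {
  drop(t(model$coefs) %*% model$SV)
}

balance_training <- function(x, y, balance, smote_k, cost) {
  if (balance == "smote") {
    b <- smote(x, y, smote_k)
    list(x = b$x, y = b$y, class_weights = NULL)
  } else if (balance == "weights") {
    tab <- table(factor(y, levels = c(0, 1)))
    cw <- sum(tab) / (2 * pmax(tab, 1))
    names(cw) <- c("0", "1")
    list(x = x, y = y, class_weights = cw)
  } else list(x = x, y = y, class_weights = NULL)
}

#' Confusion-count classification metrics
#'
#' @param tp,fn,tn,fp nonnegative confusion counts.
#' @return List: sensitivity (= recall), specificity, accuracy, precision,
#'   f1. Metrics with zero denominators are NA, except F1 which is 0 when
#'   there are positives but none were recovered.
#' @export
evaluate_counts <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  if (total <= 0) stop("empty confusion table")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (tp == 0 && (fn > 0 || fp > 0)) 0
        else if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / total, precision = prec, recall = sens,
       f1 = f1)
}

#' Label-count weighted AUC
#'
#' Combines per-label AUCs with weights equal to the number of true
#' instances of each label.
#'
#' @param aucs per-label AUC values.
#' @param counts per-label true-instance counts (> 0 in total).
#' @return The weighted mean AUC.
#' @export
weighted_auc <- function(aucs, counts) {
  if (sum(counts) <= 0) stop("true-instance counts must sum to > 0")
  sum(aucs * counts) / sum(counts)
}

#' Select the best candidate model
#'
#' Maximum AUC; ties broken toward parsimony (smaller support), then larger
#' lambda, then smaller a.
#'
#' @param results list of model records, each with `auc`, `support_size`,
#'   `lambda`, `a`.
#' @return The winning record.
#' @export
select_best_model <- function(results) {
  if (length(results) == 0L) stop("no candidate models")
  auc <- vapply(results, function(r) r$auc, numeric(1))
  sz <- vapply(results, function(r) r$support_size %||% NA_real_, numeric(1))
  lam <- vapply(results, function(r) r$lambda %||% NA_real_, numeric(1))
  a <- vapply(results, function(r) r$a %||% NA_real_, numeric(1))
  ord <- order(-auc, sz, -lam, a)
  results[[ord[1]]]
}

#' Weighted feature importance
#'
#' For each feature: the mean absolute classifier coefficient over the
#' iterations (leave-one-out folds x thresholds) in which the feature was
#' selected, multiplied by the percentage of iterations including it.
#' Features never selected score 0.
#'
#' @param iterations list; each element has `support` (feature names or
#'   indices) and `coef` (absolute SVC coefficients, aligned with support).
#' @param features the full feature-name vector.
#' @return Named numeric vector of importances.
#' @export
weighted_feature_importance <- function(iterations, features) {
  total <- length(iterations)
  if (total == 0L) stop("no iterations")
  sums <- stats::setNames(numeric(length(features)), features)
  incl <- sums
  for (it in iterations) {
    f <- if (is.numeric(it$support)) features[it$support] else it$support
    sums[f] <- sums[f] + abs(it$coef)
    incl[f] <- incl[f] + 1
  }
  ifelse(incl > 0, (sums / pmax(incl, 1)) * (100 * incl / total), 0)
}

## Nested leave-one-out over one feature matrix: per fold, scale by the
## training-fold SD, run the SCAD path on the training rows, train one SVC
## per admissible unique support, and score the held-out patient at every
## grid point. Returns per-grid decisions and per-fold model caches.
nested_loo <- function(X, y, cfg, cost, balance, smote_k, seed) {
  n <- nrow(X)
  G <- cfg$a_count * cfg$lambda_count
  dec <- matrix(NA_real_, n, G)
  ssz <- matrix(NA_real_, n, G)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2L) {
      warning("fold ", i, " skipped: single class after exclusion")
      next
    }
    s <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    div <- ifelse(is.na(s) | s <= 0, 1, s)
    Xs <- sweep(X, 2, div, "/")
    path <- scad_path(Xs[tr, , drop = FALSE], ytr, cfg)
    sizes <- vapply(path$supports, length, integer(1))
    admissible <- which(sizes >= 1L & sizes <= cfg$max_support)
    if (!length(admissible)) next
    set.seed(fan_seed(seed, 20) + i)
    cache_dec <- numeric(length(path$supports))
    cache_w <- vector("list", length(path$supports))
    for (id in admissible) {
      sup <- path$supports[[id]]
      bt <- balance_training(Xs[tr, sup, drop = FALSE], ytr, balance,
                             smote_k, cost)
      m <- svc_fit(bt$x, bt$y, cost, bt$class_weights)
      cache_dec[id] <- svc_decision(m, Xs[i, sup, drop = FALSE])
      cache_w[[id]] <- abs(svc_weights(m))
    }
    gid <- path$grid$support_id
    ok <- gid %in% admissible
    dec[i, ok] <- cache_dec[gid[ok]]
    ssz[i, ok] <- sizes[gid[ok]]
    folds[[i]] <- list(grid_sid = gid, supports = path$supports,
                       w = cache_w, admissible = admissible, div = div)
  }
  aucs <- apply(dec, 2, auc_score, labels = y)
  ## a grid point is only a candidate model if every evaluable fold produced
  ## an admissible support for it: AUCs on lucky patient subsets are not
  ## comparable with full-coverage ones
  n_valid <- sum(!vapply(folds, is.null, logical(1)))
  covered <- colSums(!is.na(dec)) == n_valid & n_valid > 0
  aucs[!covered] <- NA_real_
  list(dec = dec, ssz = ssz, folds = folds, aucs = aucs,
       mean_size = colMeans(ssz, na.rm = TRUE))
}

#' Fit the naming-decline classification model
#'
#' The full two-step procedure: for every patient left out, the remaining
#' patients are scaled, run through the SCAD path over the (a, lambda) grid,
#' and each admissible support (size < 20 by default) trains a
#' class-balanced linear SVC that scores the held-out patient. Pooled
#' held-out decision values give one AUC per grid point (and per prevalence
#' threshold when a per-threshold feature list is supplied); the maximum AUC
#' picks the reported model. Feature importance is the mean absolute SVC
#' coefficient weighted by the percentage of leave-one-out x threshold
#' iterations including the feature.
#'
#' @param features a `feature_matrix`, list of them (one per threshold), or
#'   a plain numeric matrix.
#' @param labels binary outcome (0/1 or logical); NA labels drop the patient.
#' @param scad a `scad_config`.
#' @param cost SVC regularization constant C.
#' @param balance class rebalancing on the training fold: `"smote"`
#'   (default), `"weights"` (inverse-frequency class weights), or `"none"`.
#' @param smote_k SMOTE neighbour count.
#' @param seed master seed for SMOTE and any stochastic step.
#' @return A `decline_model` with pooled LOO predictions, AUC/F1/sensitivity/
#'   specificity/accuracy, the chosen (a, lambda ratio, threshold), weighted
#'   feature importances, and a full-data refit used by [predict()].
#' @export
decline_model <- function(features, labels, scad = scad_config(), cost = 1,
                          balance = c("smote", "weights", "none"),
                          smote_k = 5, seed = 1) {
  balance <- match.arg(balance)
  cl <- match.call()
  xlist <- as_matrix_list(features)
  y <- as.integer(labels)
  keep <- !is.na(y)
  y <- y[keep]
  xlist <- lapply(xlist, function(m) m[keep, , drop = FALSE])
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  n <- length(y)
  feats <- colnames(xlist[[1]])

  runs <- lapply(seq_along(xlist), function(t)
    nested_loo(xlist[[t]], y, scad, cost, balance, smote_k,
               fan_seed(seed, t)))

  ## best (threshold, grid point): max AUC, ties toward parsimony then
  ## larger lambda (earlier grid index) then smaller a
  auc_mat <- vapply(runs, `[[`, numeric(scad$a_count * scad$lambda_count), "aucs")
  auc_mat <- matrix(auc_mat, ncol = length(runs))
  size_mat <- vapply(runs, `[[`, numeric(scad$a_count * scad$lambda_count), "mean_size")
  size_mat <- matrix(size_mat, ncol = length(runs))
  G <- nrow(auc_mat)
  lam_idx <- rep(seq_len(scad$lambda_count), times = scad$a_count)
  a_idx <- rep(seq_len(scad$a_count), each = scad$lambda_count)
  cand <- which(!is.na(auc_mat))
  if (!length(cand)) stop("no admissible model on the grid")
  gi <- (cand - 1) %% G + 1
  ti <- (cand - 1) %/% G + 1
  ord <- order(-auc_mat[cand], size_mat[cand], lam_idx[gi], a_idx[gi])
  best <- ord[1]
  g_star <- gi[best]
  t_star <- ti[best]
  run <- runs[[t_star]]

  a_grid <- seq(scad$a_min, scad$a_max, length.out = scad$a_count)
  lam_ratio <- exp(seq(log(1), log(scad$lambda_min_ratio),
                       length.out = scad$lambda_count))
  chosen <- list(a = a_grid[a_idx[g_star]],
                 lambda_ratio = lam_ratio[lam_idx[g_star]],
                 threshold = names(xlist)[t_star] %||% t_star)

  dec <- run$dec[, g_star]
  predicted <- as.integer(dec > 0)
  ok <- !is.na(dec)
  tp <- sum(ok & y == 1 & predicted == 1)
  fn <- sum(ok & y == 1 & predicted == 0)
  tn <- sum(ok & y == 0 & predicted == 0)
  fp <- sum(ok & y == 0 & predicted == 1)
  metrics <- evaluate_counts(tp, fn, tn, fp)

  ## iterations for weighted importance: every fold x threshold at the
  ## chosen grid point
  iterations <- list()
  for (t in seq_along(runs)) {
    for (f in runs[[t]]$folds) {
      if (is.null(f)) next
      id <- f$grid_sid[g_star]
      if (!(id %in% f$admissible)) next
      iterations[[length(iterations) + 1L]] <-
        list(support = feats[f$supports[[id]]], coef = f$w[[id]])
    }
  }
  wfi <- if (length(iterations))
    weighted_feature_importance(iterations, feats)
  else stats::setNames(numeric(length(feats)), feats)

  ## full-data refit at the chosen grid point, for predict()
  Xb <- xlist[[t_star]]
  s <- apply(Xb, 2, stats::sd)
  div <- ifelse(is.na(s) | s <= 0, 1, s)
  Xs <- sweep(Xb, 2, div, "/")
  full_path <- scad_path(Xs, y, scad)
  fid <- full_path$grid$support_id[g_star]
  fsup <- full_path$supports[[fid]]
  final <- NULL
  if (length(fsup) >= 1L && length(fsup) <= scad$max_support) {
    set.seed(fan_seed(seed, 99))
    bt <- balance_training(Xs[, fsup, drop = FALSE], y, balance, smote_k, cost)
    final <- list(support = fsup, features = feats[fsup], div = div,
                  model = svc_fit(bt$x, bt$y, cost, bt$class_weights))
  }

  fold_results <- data.frame(
    patient = rownames(Xb) %||% seq_len(n), actual = y,
    predicted = predicted, decision = dec,
    support_size = run$ssz[, g_star])

  structure(list(call = cl, auc = auc_mat[cand[best]], f1 = metrics$f1,
                 sensitivity = metrics$sensitivity,
                 specificity = metrics$specificity,
                 accuracy = metrics$accuracy, precision = metrics$precision,
                 counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 chosen = chosen, weighted_importance = wfi,
                 iterations = iterations,
                 fold_results = fold_results, final = final,
                 feature_names = feats, n = n, balance = balance,
                 cost = cost, scad = scad, seed = seed,
                 x = Xb, y = y), class = "decline_model")
}

as_matrix_list <- function(features) {
  if (inherits(features, "feature_matrix")) {
    out <- list(features$x)
    names(out) <- features$threshold
    out
  } else if (is.matrix(features)) {
    list(features)
  } else if (is.list(features)) {
    lapply(features, function(f) if (inherits(f, "feature_matrix")) f$x else f)
  } else stop("unsupported features object")
}

#' @export
print.decline_model <- function(x, ...) {
  cat("Naming-decline classifier (SCAD selection + nested LOO linear SVC)\n")
  cat(sprintf("  n = %d patients, %d features, balance = %s, C = %g\n",
              x$n, length(x$feature_names), x$balance, x$cost))
  cat(sprintf("  chosen: a = %.3f, lambda/lambda_max = %.3f, threshold = %s\n",
              x$chosen$a, x$chosen$lambda_ratio, as.character(x$chosen$threshold)))
  cat(sprintf("  LOO AUC = %.3f, F1 = %.3f, sens = %.1f%%, spec = %.1f%%, acc = %.1f%%\n",
              x$auc, x$f1, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy))
  invisible(x)
}

#' @export
summary.decline_model <- function(object, n_top = 15, ...) {
  wfi <- sort(object$weighted_importance, decreasing = TRUE)
  wfi <- wfi[wfi > 0]
  structure(list(model = object,
                 top_features = head(wfi, n_top)), class = "summary.decline_model")
}

#' @export
print.summary.decline_model <- function(x, ...) {
  print(x$model)
  cat("\nTop features by weighted importance:\n")
  tf <- x$top_features
  if (!length(tf)) cat("  (none selected)\n")
  else print(round(tf, 2))
  invisible(x)
}

#' @export
coef.decline_model <- function(object, ...) {
  if (is.null(object$final)) return(NULL)
  w <- svc_weights(object$final$model)
  stats::setNames(w, object$final$features)
}

#' Predict decline for new patients
#'
#' Uses the full-data refit at the chosen grid point: new feature rows are
#' scaled with the training divisors and scored by the final linear SVC.
#'
#' @param object a `decline_model`.
#' @param newdata numeric matrix or `feature_matrix` with the same columns.
#' @param type `"class"` (0/1) or `"decision"` (signed SVC values).
#' @param ... unused.
#' @export
predict.decline_model <- function(object, newdata,
                                  type = c("class", "decision"), ...) {
  type <- match.arg(type)
  if (is.null(object$final)) stop("model has no admissible final support")
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else as.matrix(newdata)
  x <- x[, object$feature_names, drop = FALSE]
  xs <- sweep(x, 2, object$final$div, "/")
  d <- svc_decision(object$final$model, xs[, object$final$support, drop = FALSE])
  if (type == "decision") d else as.integer(d > 0)
}

#' @export
plot.decline_model <- function(x, n_top = 15, ...) {
  wfi <- sort(x$weighted_importance, decreasing = TRUE)
  wfi <- head(wfi[wfi > 0], n_top)
  if (!length(wfi)) {
    warning("no selected features to plot")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(wfi), horiz = TRUE, las = 1,
                    xlab = "weighted importance",
                    main = "Feature importance", cex.names = 0.7)
  invisible(x)
}
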