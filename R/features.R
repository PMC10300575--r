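## Feature assembly, outcome dichotomization, scanner harmonization and
## scaling.

#' Feature matrix container
#'
#' Patients x features values with per-column metadata (kind, region, metric)
#' and a per-row scanner batch label.
#'
#' @param x numeric matrix, rownames = patient ids.
#' @param meta data frame with columns `name`, `kind` ("graph"/"clinical"),
#'   `region`, `metric`; one row per column of `x`.
#' @param batch factor/character of scanner labels, one per row.
#' @param threshold prevalence threshold the graph features were computed at,
#'   or `"averaged"`.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(x, meta, batch, threshold = "averaged") {
  stopifnot(is.matrix(x), nrow(meta) == ncol(x), length(batch) == nrow(x))
  if (anyNA(x)) stop("feature matrix must not contain missing values")
  colnames(x) <- meta$name
  structure(list(x = x, meta = meta, batch = as.character(batch),
                 patient_ids = rownames(x), threshold = threshold),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "patients x", ncol(x$x), "features (",
      sum(x$meta$kind == "graph"), "graph,", sum(x$meta$kind == "clinical"),
      "clinical ), threshold:", x$threshold, "\n")
  invisible(x)
}

#' Dichotomize naming change at the reliable-change threshold
#'
#' A pre-minus-post drop of at least `threshold` points (default 4) counts
#' as clinically significant decline. Missing post-operative scores yield a
#' missing label, excluding the patient from that timepoint's analysis.
#'
#' @param pre,post nonnegative naming scores (vectorized).
#' @param threshold decline threshold in score points.
#' @return Logical vector (NA where post is missing).
#' @export
rci_dichotomize <- function(pre, post, threshold = 4) {
  if (any(pre < 0, na.rm = TRUE) || any(post < 0, na.rm = TRUE))
    stop("naming scores must be nonnegative")
  (pre - post) >= threshold
}

#' Outcome labels for a cohort table
#'
#' @param patients data frame with `naming_pre`, `naming_3mo`, `naming_12mo`.
#' @param threshold reliable-change threshold.
#' @return List with integer vectors `decline_3mo` and `decline_12mo`
#'   (NA where 12-month follow-up is missing).
#' @export
outcome_labels <- function(patients, threshold = 4) {
  list(decline_3mo = as.integer(rci_dichotomize(patients$naming_pre,
                                                patients$naming_3mo, threshold)),
       decline_12mo = as.integer(rci_dichotomize(patients$naming_pre,
                                                 patients$naming_12mo, threshold)))
}

#' Assemble the classification feature matrix
#'
#' Combines per-region metric-change features with the four clinical
#' covariates (age of onset, age at surgery, pre-operative naming score,
#' fMRI laterality index). In `"averaged"` mode changes are averaged across
#' prevalence thresholds, giving regions x 3 metrics + 4 clinical columns
#' (286 for a 94-region atlas). In `"per_threshold"` mode one matrix per
#' threshold is returned, clinical columns repeated in each.
#'
#' @param changes tidy change table from [compute_metric_changes()].
#' @param clinical data frame with `patient_id`, `age_of_onset`, `age`,
#'   `preop_naming`, `fmri_li`, and `batch`.
#' @param mode `"per_threshold"` (default) or `"averaged"`.
#' @return A `feature_matrix` (averaged) or list of them (per threshold).
#' @export
assemble_features <- function(changes, clinical,
                              mode = c("per_threshold", "averaged")) {
  mode <- match.arg(mode)
  pids <- clinical$patient_id
  if (!all(pids %in% changes$patient_id))
    stop("patient missing from the metric-change table")
  metrics <- sort(unique(changes$metric))
  regions <- unique(changes$region)
  gnames <- as.vector(t(outer(regions, metrics, paste, sep = ".")))
  cnames <- c("age_of_onset", "age", "preop_naming", "fmri_li")
  meta <- rbind(
    data.frame(name = gnames, kind = "graph",
               region = rep(regions, each = length(metrics)),
               metric = rep(metrics, times = length(regions)),
               stringsAsFactors = FALSE),
    data.frame(name = cnames, kind = "clinical", region = NA, metric = NA,
               stringsAsFactors = FALSE))
  clin <- as.matrix(clinical[, cnames])
  rownames(clin) <- pids

  one_matrix <- function(ch, threshold) {
    key <- paste(ch$region, ch$metric, sep = ".")
    g <- matrix(NA_real_, length(pids), length(gnames),
                dimnames = list(pids, gnames))
    g[cbind(match(ch$patient_id, pids), match(key, gnames))] <- ch$change
    if (anyNA(g)) stop("patient missing a metric value")
    feature_matrix(cbind(g, clin), meta, clinical$batch, threshold)
  }

  if (mode == "averaged") {
    agg <- stats::aggregate(change ~ patient_id + region + metric, changes, mean)
    one_matrix(agg, "averaged")
  } else {
    ths <- sort(unique(changes$threshold))
    out <- lapply(ths, function(t) one_matrix(changes[changes$threshold == t, ], t))
    names(out) <- as.character(ths)
    out
  }
}

#' Apply planted batch effects to a feature matrix
#'
#' Feature f of a patient in batch b becomes `scale_b * f + shift_b`. Used by
#' the synthetic generator to emulate the two-scanner acquisition; labels are
#' untouched. By default only graph-derived columns are perturbed (clinical
#' covariates are scanner-independent).
#'
#' @param fm a `feature_matrix` or list of them.
#' @param shift,scale named per-batch offset/factor; defaults from `truth`.
#' @param truth optional `ground_truth` carrying `batch_params`.
#' @param kinds which feature kinds to perturb.
#' @return The perturbed object.
#' @export
apply_batch_effects <- function(fm, shift = NULL, scale = NULL, truth = NULL,
                                kinds = "graph") {
  if (is.list(fm) && !inherits(fm, "feature_matrix"))
    return(lapply(fm, apply_batch_effects, shift = shift, scale = scale,
                  truth = truth, kinds = kinds))
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is.null(truth)) {
    shift <- shift %||% truth$batch_params$shift
    scale <- scale %||% truth$batch_params$scale
  }
  if (is.null(shift) || is.null(scale)) stop("shift and scale are required")
  if (!all(fm$batch %in% names(shift)) || !all(fm$batch %in% names(scale)))
    stop("unknown batch label: ", paste(setdiff(fm$batch, names(shift)), collapse = ", "))
  cols <- fm$meta$kind %in% kinds
  x <- fm$x
  for (b in unique(fm$batch)) {
    r <- fm$batch == b
    x[r, cols] <- x[r, cols, drop = FALSE] * scale[[b]] + shift[[b]]
  }
  fm$x <- x
  fm
}

#' Empirical-Bayes scanner harmonization
#'
#' Location/scale harmonization across acquisition batches with parametric
#' empirical-Bayes shrinkage (normal prior on batch locations, inverse-gamma
#' on batch scales), performed feature-wise; outcome labels are never used.
#' A single batch is returned unchanged. Constant features cannot be
#' harmonized and are left unchanged with a warning.
#'
#' @param fm a `feature_matrix` or list of them.
#' @return The harmonized object.
#' @export
combat_harmonize <- function(fm) {
  if (is.list(fm) && !inherits(fm, "feature_matrix"))
    return(lapply(fm, combat_harmonize))
  stopifnot(inherits(fm, "feature_matrix"))
  batches <- unique(fm$batch)
  if (length(batches) < 2L) return(fm)
  if (any(table(fm$batch) < 2L)) stop("each batch needs at least 2 patients")
  v <- apply(fm$x, 2, stats::var)
  const <- v <= .Machine$double.eps
  if (any(const))
    warning(sum(const), " constant feature(s) left unharmonized")
  if (all(const)) return(fm)
  dat <- t(fm$x[, !const, drop = FALSE])
  adj <- sva::ComBat(dat = dat, batch = fm$batch, par.prior = TRUE,
                     prior.plots = FALSE)
  x <- fm$x
  x[, !const] <- t(adj)
  bad <- !is.finite(colSums(x))
  if (any(bad)) {
    warning(sum(bad), " feature(s) restored after degenerate harmonization")
    x[, bad] <- fm$x[, bad]
  }
  fm$x <- x
  fm
}

#' Scale features to unit standard deviation
#'
#' Each column is divided by its standard deviation computed on `fit_rows`
#' only (the training fold), then the same divisors are applied to all rows,
#' so held-out patients never influence the scaling. Columns with zero SD
#' are left unchanged. No mean-centering is performed; the unpenalized
#' intercept of the selection model absorbs the mean (set `center = TRUE`
#' to subtract the fit-row means as well).
#'
#' @param x numeric matrix or `feature_matrix`.
#' @param fit_rows row indices used to estimate the scaling.
#' @param center subtract fit-row means first.
#' @return Object of the same type, scaled.
#' @export
scale_sd1 <- function(x, fit_rows = seq_len(nrow(if (is.matrix(x)) x else x$x)),
                      center = FALSE) {
  if (inherits(x, "feature_matrix")) {
    x$x <- scale_sd1(x$x, fit_rows, center)
    return(x)
  }
  if (length(fit_rows) == 0L) stop("fit_rows must be nonempty")
  if (center) {
    mu <- colMeans(x[fit_rows, , drop = FALSE])
    x <- sweep(x, 2, mu, "-")
  }
  s <- apply(x[fit_rows, , drop = FALSE], 2, stats::sd)
  div <- ifelse(is.na(s) | s <= 0, 1, s)
  sweep(x, 2, div, "/")
}
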