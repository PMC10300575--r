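## Synthetic cohort generator. Emulates the statistical structure the
## analysis assumes: per-patient streamline tables over a hemisphere-tagged
## parcellation, a left-temporal virtual resection, clinical covariates,
## pre/3-month/12-month naming scores consistent with the decline labels,
## two scanner batches, and a planted group difference in the metric-change
## features of a configurable set of signal regions.

#' Cohort specification
#'
#' Defaults mirror the study conditions: 44 patients, a 94-region
#' parcellation, decline prevalences 17/44 at 3 months and 11/37 at
#' 12 months, 7 patients missing 12-month follow-up, and 27/44 patients on
#' the first scanner.
#'
#' @param n_patients number of patients.
#' @param n_regions number of atlas regions (>= 4).
#' @param decline_rate_3mo,decline_rate_12mo decline prevalence at each
#'   timepoint (the 12-month rate applies to patients with follow-up).
#' @param n_missing_12mo number of patients without 12-month scores.
#' @param batch_assignment proportion of patients in batch A.
#' @param effect_size standardized mean difference d planted between
#'   decliners and non-decliners in the signal features. By the Gaussian
#'   location-shift construction this equals the logistic regression
#'   coefficient of the label on each standardized signal feature.
#' @param n_signal_regions number of regions carrying the planted effect.
#' @param batch_shift,batch_scale additive offset and multiplicative factor
#'   per batch, applied later by [apply_batch_effects()].
#' @param seed integer; fully determines the cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 44, n_regions = 94,
                        decline_rate_3mo = 17 / 44,
                        decline_rate_12mo = 11 / 37,
                        n_missing_12mo = 7,
                        batch_assignment = 27 / 44,
                        effect_size = 1, n_signal_regions = NULL,
                        batch_shift = c(A = 0, B = 0.5),
                        batch_scale = c(A = 1, B = 1.2),
                        seed = 1) {
  n_signal_regions <- n_signal_regions %||% min(5, max(1, n_regions - 1))
  stopifnot(n_patients >= 1, n_regions >= 1, n_missing_12mo >= 0,
            n_missing_12mo < n_patients, effect_size >= 0,
            n_signal_regions >= 1, n_signal_regions <= n_regions)
  for (r in c(decline_rate_3mo, decline_rate_12mo, batch_assignment))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  structure(list(n_patients = n_patients, n_regions = n_regions,
                 decline_rate_3mo = decline_rate_3mo,
                 decline_rate_12mo = decline_rate_12mo,
                 n_missing_12mo = n_missing_12mo,
                 batch_assignment = batch_assignment,
                 effect_size = effect_size,
                 n_signal_regions = n_signal_regions,
                 batch_shift = batch_shift, batch_scale = batch_scale,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

region_label_set <- function(n_regions) {
  n_left <- ceiling(n_regions / 2)
  c(paste0("L", sprintf("%02d", seq_len(n_left))),
    paste0("R", sprintf("%02d", seq_len(n_regions - n_left))))
}

#' Generate the template connectome
#'
#' A distance-penalized random geometric graph over points on a sphere split
#' into two hemispheres, with an inter-hemispheric backbone guaranteeing
#' connectedness. A contiguous left-hemisphere subset ("left temporal") is
#' designated as the resection target, and each region pair carries a base
#' probability that its streamlines pass through the resection mask.
#'
#' @param spec a `cohort_spec` (n_regions >= 4).
#' @return A `template_connectome` (also a `connectome`): integer weights,
#'   region labels, spatial coordinates, resection and signal region indices,
#'   and the per-pair resection probability matrix.
#' @export
generate_template_connectome <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_regions < 4) stop("invalid spec: n_regions must be at least 4")
  n <- spec$n_regions
  set.seed(fan_seed(spec$seed, 1))
  ## points on the unit sphere, mirrored into hemispheres (x < 0 is left)
  z <- runif(n, -1, 1)
  th <- runif(n, 0, 2 * pi)
  pts <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  n_left <- ceiling(n / 2)
  pts[seq_len(n_left), 1] <- -abs(pts[seq_len(n_left), 1])
  pts[-seq_len(n_left), 1] <- abs(pts[-seq_len(n_left), 1])
  labels <- region_label_set(n)

  ## resection target: left regions nearest an anterior-temporal anchor
  anchor <- c(-0.6, -0.7, -0.4)
  anchor <- anchor / sqrt(sum(anchor^2))
  d_anchor <- sqrt(colSums((t(pts) - anchor)^2))
  n_res <- max(1L, round(0.08 * n))
  resection <- order(d_anchor)[seq_len(min(n_res, n_left))]
  resection <- resection[resection <= n_left]
  if (!length(resection)) resection <- which.min(d_anchor[seq_len(n_left)])

  ## signal regions: spread apart (greedy max-min distance) among
  ## non-resected regions, so each planted feature carries its own signal
  ## rather than sharing it with spatial neighbours
  cand <- setdiff(seq_len(n), resection)
  centroid <- colMeans(pts[resection, , drop = FALSE])
  d_cent <- sqrt(colSums((t(pts[cand, , drop = FALSE]) - centroid)^2))
  dmat_cand <- as.matrix(dist(pts))[cand, cand, drop = FALSE]
  sel <- which.max(d_cent)
  while (length(sel) < min(spec$n_signal_regions, length(cand))) {
    dmin <- apply(dmat_cand[, sel, drop = FALSE], 1, min)
    dmin[sel] <- -Inf
    sel <- c(sel, which.max(dmin))
  }
  signal <- cand[sel]

  ## distance-penalized weights
  d <- as.matrix(dist(pts))
  p_edge <- plogis(2.5 - 3 * d)
  mu <- 80 * exp(-1.5 * d)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  present <- runif(sum(ut)) < p_edge[ut]
  counts <- 1 + rnbinom(sum(ut), mu = mu[ut], size = 4)
  w[ut] <- ifelse(present, counts, 0)
  w <- w + t(w)
  diag(w) <- 0
  ## backbone: ring-free path keeps the graph connected
  for (i in seq_len(n - 1)) {
    w[i, i + 1] <- max(w[i, i + 1], 3)
    w[i + 1, i] <- w[i, i + 1]
  }

  ## base probability a streamline on edge (i, j) crosses the resection mask
  d_res <- apply(d[, resection, drop = FALSE], 1, min)
  rho <- matrix(0, n, n)
  in_res <- seq_len(n) %in% resection
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (in_res[i] && in_res[j]) rho[i, j] <- 0.95
    else if (in_res[i] || in_res[j]) rho[i, j] <- 0.7
    else rho[i, j] <- 0.3 * exp(-3 * (d_res[i] + d_res[j]))
  }

  out <- connectome(w, labels)
  out$points <- pts
  out$resection_regions <- sort(resection)
  out$signal_regions <- sort(signal)
  out$resect_prob <- rho
  class(out) <- c("template_connectome", "connectome")
  out
}

## Solve the 12-month logistic intercept so the marginal rate among patients
## with follow-up matches the configured rate, given the realized 3-month labels.
solve_12mo_intercept <- function(y3_observed, rate12, b = 2) {
  if (rate12 <= 0) return(-Inf)
  if (rate12 >= 1) return(Inf)
  f <- function(a) mean(plogis(a + b * y3_observed)) - rate12
  uniroot(f, c(-20, 20))$root
}

#' Generate one synthetic patient
#'
#' Streamline counts per region pair are drawn as overdispersed negative
#' binomial noise around the template weights. Each streamline is flagged as
#' resected with the template's pass-through probability, except streamlines
#' touching a signal region, whose resection probability is the patient's
#' severity: `0.25 + 0.08 * (d * decline_3mo + noise)`. The label enters the
#' severity as a Gaussian location shift, so the conditional law of the label
#' given the standardized signal feature is logistic with coefficient d.
#' Naming scores are generated backwards from the labels so that
#' dichotomizing the pre-minus-post drop at the reliable-change threshold of
#' 4 points reproduces the labels exactly.
#'
#' @param template a `template_connectome`.
#' @param spec the `cohort_spec`.
#' @param patient_index integer index (seeds the patient's draws).
#' @param decline_3mo,decline_12mo optional fixed labels (12-month may be
#'   NA); drawn from the configured rates when missing.
#' @param batch scanner batch label, `"A"` or `"B"`.
#' @return A `synthetic_patient`: streamline table, clinical record, naming
#'   scores, batch, true labels, and severity.
#' @export
generate_patient <- function(template, spec, patient_index,
                             decline_3mo = NULL, decline_12mo = NULL,
                             batch = NULL) {
  stopifnot(inherits(template, "template_connectome"))
  set.seed(fan_seed(spec$seed, 2) + 7L * as.integer(patient_index))
  n <- nrow(template$weights)
  d_eff <- spec$effect_size

  y3 <- decline_3mo %||% rbinom(1, 1, spec$decline_rate_3mo)
  if (is.null(decline_12mo)) {
    a12 <- qlogis(min(max(spec$decline_rate_12mo, 1e-6), 1 - 1e-6))
    y12 <- rbinom(1, 1, plogis(a12 + 2 * y3 - 2 * spec$decline_rate_3mo))
  } else y12 <- decline_12mo
  if (is.null(batch)) batch <- if (runif(1) < spec$batch_assignment) "A" else "B"

  ## one independent severity draw per signal region: each planted feature
  ## carries the effect with its own within-class noise, so decliners differ
  ## by d pooled SDs on every signal feature separately
  n_sig <- length(template$signal_regions)
  severity <- pmin(pmax(0.25 + 0.08 * (d_eff * y3 + rnorm(n_sig)), 0.02), 0.9)
  names(severity) <- template$region_labels[template$signal_regions]

  ## streamline counts around template weights
  w <- template$weights
  ut <- which(upper.tri(w) & w > 0)
  counts <- rnbinom(length(ut), mu = w[ut], size = 10)
  keep <- counts > 0
  ut <- ut[keep]; counts <- counts[keep]
  ii <- ((ut - 1L) %% n) + 1L
  jj <- ((ut - 1L) %/% n) + 1L
  ri <- rep(ii, counts)
  rj <- rep(jj, counts)
  p_res <- rep(template$resect_prob[ut], counts)
  sig <- template$signal_regions
  sev_i <- match(ri, sig)
  sev_j <- match(rj, sig)
  sev_idx <- ifelse(is.na(sev_i), sev_j, sev_i)
  touches_signal <- !is.na(sev_idx)
  p_res[touches_signal] <- severity[sev_idx[touches_signal]]
  resected <- runif(length(ri)) < p_res
  streamlines <- data.frame(region_i = ri, region_j = rj, resected = resected)

  ## clinical covariates, shifted by label to emulate the cohort's
  ## decliner/non-decliner contrasts
  y12n <- if (is.na(y12)) 0 else y12
  age_of_onset <- min(max(rnorm(1, 18 - 6 * y3, 10), 1), 55)
  age <- min(max(rnorm(1, 38 + 8 * y12n, 11), 18), 70)
  fmri_li <- min(max(rnorm(1, 0.72 + 0.07 * y3, 0.15), 0.05), 1)

  ## naming scores generated backwards from the labels (threshold 4)
  drop3 <- if (y3 == 1) 4 + rbinom(1, 8, 0.25) else sample(-3:3, 1)
  drop12 <- if (is.na(y12)) NA_integer_
            else if (y12 == 1) 4 + rbinom(1, 8, 0.25) else sample(-3:3, 1)
  pre_raw <- round(rnorm(1, 14 + 3 * y12n, 5.5))
  pre <- min(30, max(pre_raw, drop3, if (is.na(drop12)) 0L else drop12, 0))
  score_3mo <- pre - drop3
  score_12mo <- if (is.na(drop12)) NA_integer_ else pre - drop12

  structure(list(
    patient_id = sprintf("P%03d", patient_index),
    streamlines = streamlines,
    clinical = list(age_of_onset = age_of_onset, age = age,
                    preop_naming = pre, fmri_li = fmri_li),
    naming_scores = list(pre = pre, score_3mo = score_3mo,
                         score_12mo = score_12mo),
    batch = batch,
    decline_truth = list(decline_3mo = y3, decline_12mo = y12),
    severity = severity), class = "synthetic_patient")
}

#' Simulate a full synthetic cohort
#'
#' Draws 3-month labels at the configured prevalence, selects exactly
#' `n_missing_12mo` patients to lack 12-month follow-up, draws 12-month
#' labels from a logistic model tied to the 3-month label (calibrated so the
#' marginal 12-month rate among followed-up patients matches the configured rate),
#' assigns scanner batches, and generates every patient.
#'
#' @param spec a `cohort_spec`.
#' @return A `synthetic_cohort`: patients data frame, named list of
#'   streamline tables, the template, region labels, and a `ground_truth`
#'   record (signal features, batch parameters, generating coefficients,
#'   per-patient severity).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  template <- generate_template_connectome(spec)
  n <- spec$n_patients
  set.seed(fan_seed(spec$seed, 3))
  y3 <- rbinom(n, 1, spec$decline_rate_3mo)
  missing12 <- sample(n, spec$n_missing_12mo)
  observed <- setdiff(seq_len(n), missing12)
  y12 <- rep(NA_integer_, n)
  if (length(observed)) {
    a12 <- solve_12mo_intercept(y3[observed], spec$decline_rate_12mo)
    y12[observed] <- rbinom(length(observed), 1, plogis(a12 + 2 * y3[observed]))
  }
  n_a <- round(spec$batch_assignment * n)
  batch <- rep("B", n)
  batch[sample(n, n_a)] <- "A"

  patients <- vector("list", n)
  for (i in seq_len(n))
    patients[[i]] <- generate_patient(template, spec, i, decline_3mo = y3[i],
                                      decline_12mo = y12[i], batch = batch[i])

  pdf <- do.call(rbind, lapply(patients, function(p) data.frame(
    patient_id = p$patient_id,
    age_of_onset = p$clinical$age_of_onset, age = p$clinical$age,
    preop_naming = p$clinical$preop_naming, fmri_li = p$clinical$fmri_li,
    naming_pre = p$naming_scores$pre,
    naming_3mo = p$naming_scores$score_3mo,
    naming_12mo = p$naming_scores$score_12mo,
    batch = p$batch,
    decline_3mo = p$decline_truth$decline_3mo,
    decline_12mo = p$decline_truth$decline_12mo,
    stringsAsFactors = FALSE)))
  streamlines <- lapply(patients, `[[`, "streamlines")
  names(streamlines) <- pdf$patient_id

  labels <- template$region_labels
  truth <- structure(list(
    signal_features = data.frame(
      region = labels[template$signal_regions], metric = "strength",
      stringsAsFactors = FALSE),
    batch_params = list(shift = spec$batch_shift, scale = spec$batch_scale),
    generating_coefficients = c(
      stats::setNames(rep(spec$effect_size, length(template$signal_regions)),
                      paste0(labels[template$signal_regions], ".strength"))),
    severity = structure(do.call(rbind, lapply(patients, `[[`, "severity")),
                         dimnames = list(pdf$patient_id,
                                         labels[template$signal_regions]))),
    class = "ground_truth")

  structure(list(spec = spec, template = template, patients = pdf,
                 streamlines = streamlines, region_labels = labels,
                 truth = truth), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$patients
  cat("Synthetic cohort:", nrow(p), "patients,", x$spec$n_regions, "regions\n")
  cat("  3-month decline:", sum(p$decline_3mo), "/", nrow(p), "\n")
  cat("  12-month decline:", sum(p$decline_12mo, na.rm = TRUE), "/",
      sum(!is.na(p$decline_12mo)), " (", sum(is.na(p$decline_12mo)),
      "missing )\n")
  cat("  batches:", paste(names(table(p$batch)), table(p$batch),
                          sep = "=", collapse = ", "), "\n")
  cat("  planted effect d =", x$spec$effect_size, "in",
      nrow(x$truth$signal_features), "regions\n")
  invisible(x)
}

#' Write / read a cohort directory
#'
#' Writes `patients.csv`, `streamlines/<id>.tsv` (region_i, region_j,
#' resected as 0/1) and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "streamlines"), recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  for (pid in names(cohort$streamlines)) {
    s <- cohort$streamlines[[pid]]
    s$resected <- as.integer(s$resected)
    write.table(s, file.path(dir, "streamlines", paste0(pid, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  truth <- cohort$truth
  jsonlite::write_json(list(
    signal_features = truth$signal_features,
    batch_shift = as.list(truth$batch_params$shift),
    batch_scale = as.list(truth$batch_params$scale),
    generating_coefficients = as.list(truth$generating_coefficients),
    severity = as.data.frame(truth$severity),
    region_labels = cohort$region_labels,
    n_regions = cohort$spec$n_regions),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  patients <- read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  files <- list.files(file.path(dir, "streamlines"), full.names = TRUE)
  streamlines <- lapply(files, function(f) {
    s <- read.table(f, header = TRUE, sep = "\t")
    s$resected <- as.logical(s$resected)
    s
  })
  names(streamlines) <- sub("\\.tsv$", "", basename(files))
  streamlines <- streamlines[patients$patient_id]
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  structure(list(spec = NULL, template = NULL, patients = patients,
                 streamlines = streamlines,
                 region_labels = truth$region_labels,
                 truth = truth), class = "synthetic_cohort")
}
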