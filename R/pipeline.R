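## End-to-end orchestration: simulate -> build networks -> metrics ->
## features -> fit -> permutation test, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param ... named overrides for any section (`cohort`, `build`,
#'   `features`, `classifier`, `scad`, `permutation`, `timepoints`).
#' @return A nested configuration list that round-trips through YAML.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    cohort = list(n_patients = 44, n_regions = 94, effect_size = 1,
                  n_signal_regions = 5),
    build = list(thresholds = seq(75, 100, by = 5), log_offset = 1),
    features = list(mode = "per_threshold", rci_threshold = 4),
    scad = list(),
    classifier = list(cost = 1, balance = "smote", smote_k = 5),
    permutation = list(n_perm = 1000, train_frac = 0.8),
    timepoints = c("3mo", "12mo", "chain"))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic cohort: simulation, network
#' construction with virtual resection, metric-change computation, feature
#' assembly with planted batch effects, scanner harmonization, model fitting
#' per requested timepoint, and the model permutation test. All outputs and
#' a manifest (configuration, derived seeds, file checksums) are written to
#' `out_dir`; re-running with the same configuration reproduces identical
#' results.
#'
#' @param config configuration list from [default_config()] or the path of
#'   a YAML file with the same structure.
#' @param out_dir output directory.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the fitted models, the permutation test,
#'   and the output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[connectoclass] ", ...)
  seed <- config$seed %||% 1
  t0 <- Sys.time()

  say("stage 1/5: simulate cohort")
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = fan_seed(seed, 1))))
  cohort <- simulate_cohort(spec)
  write_cohort(cohort, file.path(out_dir, "cohort"))

  say("stage 2/5: build networks")
  networks <- build_cohort_networks(cohort,
                                    thresholds = config$build$thresholds,
                                    log_offset = config$build$log_offset %||% 1)

  say("stage 3/5: metric changes")
  changes <- compute_metric_changes(networks)
  write.csv(changes, file.path(out_dir, "metric_changes.csv"), row.names = FALSE)

  say("stage 4/5: features (assembly, batch effects, harmonization)")
  fm <- assemble_features(changes, cohort$patients,
                          mode = config$features$mode %||% "per_threshold")
  fm <- apply_batch_effects(fm, truth = cohort$truth)
  fm <- suppressWarnings(combat_harmonize(fm))
  labels <- outcome_labels(cohort$patients,
                           threshold = config$features$rci_threshold %||% 4)

  say("stage 5/5: classification")
  cc <- config$classifier
  scad_cfg <- do.call(scad_config, config$scad %||% list())
  models <- list()
  if ("3mo" %in% config$timepoints)
    models$`3mo` <- decline_model(fm, labels$decline_3mo, scad = scad_cfg,
                                  cost = cc$cost %||% 1,
                                  balance = cc$balance %||% "smote",
                                  smote_k = cc$smote_k %||% 5,
                                  seed = fan_seed(seed, 5))
  if ("12mo" %in% config$timepoints)
    models$`12mo` <- decline_model(fm, labels$decline_12mo, scad = scad_cfg,
                                   cost = cc$cost %||% 1,
                                   balance = cc$balance %||% "smote",
                                   smote_k = cc$smote_k %||% 5,
                                   seed = fan_seed(seed, 6))
  if ("chain" %in% config$timepoints)
    models$chain <- decline_chain(fm, labels$decline_3mo, labels$decline_12mo,
                                  scad = scad_cfg, cost = cc$cost %||% 1,
                                  seed = fan_seed(seed, 7))

  perm <- NULL
  n_perm <- config$permutation$n_perm %||% 0
  if (n_perm > 0 && !is.null(models$`3mo`) && !is.null(models$`3mo`$final)) {
    say("permutation test (", n_perm, " permutations)")
    perm <- model_permutation_test(models$`3mo`, n_perm = n_perm,
                                   train_frac = config$permutation$train_frac %||% 0.8,
                                   seed = fan_seed(seed, 8))
  }

  ## outputs
  res <- lapply(models, function(m) {
    if (inherits(m, "decline_chain"))
      list(kind = "chain", weighted_auc = m$weighted_auc,
           auc_3mo = m$step1$auc, auc_12mo = m$step2$auc,
           sens_3mo = m$step1$sensitivity, spec_3mo = m$step1$specificity,
           sens_12mo = m$step2$sensitivity, spec_12mo = m$step2$specificity)
    else
      list(kind = "single", auc = m$auc, f1 = m$f1,
           sensitivity = m$sensitivity, specificity = m$specificity,
           accuracy = m$accuracy, chosen = m$chosen,
           counts = as.list(m$counts))
  })
  if (!is.null(perm))
    res$permutation <- list(observed = perm$observed_stat, p = perm$p_value,
                            n_perm = perm$n_perm)
  jsonlite::write_json(res, file.path(out_dir, "model_result.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(models$`3mo`)) {
    wfi <- sort(models$`3mo`$weighted_importance, decreasing = TRUE)
    write.csv(data.frame(feature = names(wfi), wfi = unname(wfi)),
              file.path(out_dir, "importance.csv"), row.names = FALSE)
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = config,
    seeds = list(cohort = fan_seed(seed, 1), fit_3mo = fan_seed(seed, 5),
                 fit_12mo = fan_seed(seed, 6), chain = fan_seed(seed, 7),
                 permutation = fan_seed(seed, 8)),
    skipped = if (n_perm > 0) character(0) else "permutation",
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    checksums = as.list(tools::md5sum(files)))
  names(manifest$checksums) <- substring(files, nchar(out_dir) + 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(models = models, permutation = perm, cohort = cohort,
                 features = fm, labels = labels, dir = out_dir))
}

#' Verify a run directory against its manifest
#'
#' Recomputes the checksum of every declared output file; a mismatch (e.g. a
#' tampered intermediate) raises an error.
#'
#' @param dir run directory containing `manifest.json`.
#' @return Invisibly TRUE.
#' @export
verify_run <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  for (f in names(manifest$checksums)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing output file: ", f)
    h <- unname(tools::md5sum(path))
    if (!identical(h, unname(manifest$checksums[[f]])))
      stop("checksum mismatch for ", f)
  }
  invisible(TRUE)
}

#' Summarize a completed run
#'
#' Prints the per-timepoint classification metrics, the top features by
#' weighted importance, and the permutation p-value.
#'
#' @param dir run directory written by [run_pipeline()].
#' @param n_top number of top features to show.
#' @return Invisibly, the parsed results list.
#' @export
pipeline_report <- function(dir, n_top = 15) {
  res_path <- file.path(dir, "model_result.json")
  if (!file.exists(res_path)) {
    warning("incomplete run: no model_result.json")
    return(invisible(NULL))
  }
  res <- jsonlite::read_json(res_path, simplifyVector = TRUE)
  cat("Pipeline report:", dir, "\n\n")
  for (nm in setdiff(names(res), "permutation")) {
    r <- res[[nm]]
    if (identical(r$kind, "chain"))
      cat(sprintf("%-6s weighted AUC = %.3f (3mo %.3f, 12mo %.3f)\n", nm,
                  r$weighted_auc, r$auc_3mo, r$auc_12mo))
    else
      cat(sprintf("%-6s AUC = %.3f  F1 = %.3f  sens = %.1f%%  spec = %.1f%%  acc = %.1f%%\n",
                  nm, r$auc, r$f1, 100 * r$sensitivity, 100 * r$specificity,
                  100 * r$accuracy))
  }
  if (!is.null(res$permutation))
    cat(sprintf("\nPermutation test: observed AUC = %.3f, p = %.4g (%d permutations)\n",
                res$permutation$observed, res$permutation$p,
                res$permutation$n_perm))
  imp_path <- file.path(dir, "importance.csv")
  if (file.exists(imp_path)) {
    imp <- read.csv(imp_path)
    imp <- imp[imp$wfi > 0, ]
    cat("\nTop features (weighted importance):\n")
    print(head(imp, min(n_top, nrow(imp))), row.names = FALSE)
  }
  invisible(res)
}
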