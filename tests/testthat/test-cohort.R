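test_that("template connectome is symmetric, connected and deterministic", {
  spec <- cohort_spec(n_patients = 8, n_regions = 4, seed = 1)
  t1 <- generate_template_connectome(spec)
  expect_equal(dim(t1$weights), c(4, 4))
  expect_equal(t1$weights, t(t1$weights))
  expect_equal(diag(t1$weights), rep(0, 4), ignore_attr = TRUE)
  expect_identical(t1$weights, generate_template_connectome(spec)$weights)

  big <- generate_template_connectome(cohort_spec(n_regions = 94, seed = 7))
  g <- igraph::graph_from_adjacency_matrix(big$weights, mode = "undirected",
                                           weighted = TRUE)
  expect_gte(igraph::ecount(g), 93)
  expect_true(igraph::is_connected(g))
  expect_true(all(big$resection_regions <= ceiling(94 / 2)))  # left hemisphere
})

test_that("small-region templates are rejected", {
  spec <- cohort_spec(n_regions = 4, seed = 1)
  spec$n_regions <- 3
  expect_error(generate_template_connectome(spec), "at least 4")
})

test_that("cohorts are byte-identical under the same spec", {
  spec <- cohort_spec(n_patients = 6, n_regions = 8, n_missing_12mo = 1, seed = 123)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$streamlines, c2$streamlines)
  c3 <- simulate_cohort(cohort_spec(n_patients = 6, n_regions = 8, n_missing_12mo = 1, seed = 124))
  expect_false(identical(c1$patients, c3$patients))
})

test_that("exactly the configured number of patients miss 12-month scores", {
  spec <- cohort_spec(n_patients = 44, n_regions = 8, n_missing_12mo = 7,
                      seed = 2)
  cohort <- simulate_cohort(spec)
  expect_equal(sum(is.na(cohort$patients$naming_12mo)), 7)
  expect_equal(sum(!is.na(cohort$patients$naming_12mo)), 37)
  expect_equal(is.na(cohort$patients$naming_12mo),
               is.na(cohort$patients$decline_12mo))
})

test_that("dichotomizing generated scores reproduces the true labels", {
  fx <- fixture_cohort()
  p <- fx$cohort$patients
  lab <- outcome_labels(p)
  expect_equal(lab$decline_3mo, p$decline_3mo)
  expect_equal(lab$decline_12mo, p$decline_12mo)
})

test_that("label prevalence converges to the configured rates", {
  spec <- cohort_spec(n_patients = 600, n_regions = 4, seed = 31,
                      decline_rate_3mo = 17 / 44, n_missing_12mo = 0)
  cohort <- simulate_cohort(spec)
  rate <- mean(cohort$patients$decline_3mo)
  ## binomial 3-sigma band around 0.386 at n = 600
  expect_lt(abs(rate - 17 / 44), 3 * sqrt(17 / 44 * 27 / 44 / 600))
})

test_that("planted effect size appears in the signal strength features", {
  spec <- cohort_spec(n_patients = 200, n_regions = 94, effect_size = 2,
                      seed = 9)
  cohort <- simulate_cohort(spec)
  networks <- build_cohort_networks(cohort)
  changes <- compute_metric_changes(networks, metrics = "strength")
  fm <- assemble_features(changes, cohort$patients, mode = "averaged")
  y <- cohort$patients$decline_3mo
  sig <- paste0(cohort$truth$signal_features$region, ".strength")
  d_hat <- vapply(sig, function(s) {
    v <- fm$x[, s]
    sp <- sqrt(((sum(y == 1) - 1) * var(v[y == 1]) +
                (sum(y == 0) - 1) * var(v[y == 0])) / (length(y) - 2))
    (mean(v[y == 1]) - mean(v[y == 0])) / sp
  }, numeric(1))
  ## decliners lose more signal-region streamlines: ratio drops by ~2 SD
  expect_true(all(abs(d_hat) > 1.5))
  expect_true(all(abs(d_hat) < 2.5))
  expect_equal(mean(abs(d_hat)), 2, tolerance = 0.15)
})

test_that("batch effects shift and scale the configured columns", {
  fx <- fixture_cohort()
  fm <- fx$features
  ## identity parameters leave the matrix untouched
  id <- apply_batch_effects(fm, shift = c(A = 0, B = 0),
                            scale = c(A = 1, B = 1))
  expect_equal(id$x, fm$x)
  shifted <- apply_batch_effects(fm, shift = c(A = 0, B = 5),
                                 scale = c(A = 1, B = 1))
  g <- fm$meta$kind == "graph"
  dm <- colMeans(shifted$x[shifted$batch == "B", g, drop = FALSE]) -
    colMeans(shifted$x[shifted$batch == "A", g, drop = FALSE])
  dm0 <- colMeans(fm$x[fm$batch == "B", g, drop = FALSE]) -
    colMeans(fm$x[fm$batch == "A", g, drop = FALSE])
  expect_equal(dm, dm0 + 5)
  scaled <- apply_batch_effects(fm, shift = c(A = 0, B = 0),
                                scale = c(A = 1, B = 2))
  sB <- apply(scaled$x[scaled$batch == "B", g, drop = FALSE], 2, sd)
  s0 <- apply(fm$x[fm$batch == "B", g, drop = FALSE], 2, sd)
  nz <- s0 > 1e-12
  expect_equal(sB[nz] / s0[nz], rep(2, sum(nz)), ignore_attr = TRUE)
  ## labels and clinical columns untouched
  expect_equal(shifted$x[, !g], fm$x[, !g])
  expect_error(apply_batch_effects(fm, shift = c(A = 0), scale = c(A = 1)),
               "unknown batch")
})
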