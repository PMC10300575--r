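## Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

## Small synthetic cohort with features, cached by argument signature.
fixture_cohort <- function(n_patients = 16, n_regions = 16, effect_size = 0,
                           seed = 42, mode = "averaged",
                           metrics = c("strength", "betweenness", "clustering")) {
  key <- paste(n_patients, n_regions, effect_size, seed, mode,
               paste(metrics, collapse = "+"), sep = "_")
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  spec <- cohort_spec(n_patients = n_patients, n_regions = n_regions,
                      effect_size = effect_size,
                      n_missing_12mo = min(3, n_patients - 2), seed = seed)
  cohort <- simulate_cohort(spec)
  networks <- build_cohort_networks(cohort)
  changes <- compute_metric_changes(networks, metrics = metrics)
  features <- assemble_features(changes, cohort$patients, mode = mode)
  out <- list(spec = spec, cohort = cohort, networks = networks,
              changes = changes, features = features)
  .fixture_env[[key]] <- out
  out
}

## Random streamline table over n regions.
random_streamlines <- function(n_records, n_regions, p_resect = 0.3) {
  data.frame(region_i = sample(n_regions, n_records, replace = TRUE),
             region_j = sample(n_regions, n_records, replace = TRUE),
             resected = runif(n_records) < p_resect)
}

## Random connected-ish weighted graph as a connectome.
random_connectome <- function(n, p_edge = 0.6, max_w = 5) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < p_edge, sample(max_w, sum(ut), replace = TRUE), 0)
  w[ut] <- vals
  w <- w + t(w)
  connectome(w)
}

## Exhaustive betweenness oracle: enumerate all simple paths per unordered
## pair, edge length 1/weight, fractional credit over shortest-path ties.
brute_betweenness <- function(c) {
  w <- c$weights
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  score <- numeric(n)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(v, visited, d) {
      if (v == t) {
        out[[length(out) + 1L]] <<- list(d = d, interior = setdiff(visited, c(s, t)))
        return()
      }
      for (u in which(len[v, ] < Inf)) {
        if (!(u %in% visited)) walk(u, c(visited, u), d + len[v, u])
      }
    }
    walk(s, c(s), 0)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (!length(ps)) next
    ds <- vapply(ps, `[[`, numeric(1), "d")
    best <- min(ds)
    hit <- which(abs(ds - best) < 1e-9)
    for (h in hit) {
      for (v in ps[[h]]$interior) score[v] <- score[v] + 1 / length(hit)
    }
  }
  score
}

## Brute-force SCAD fit: cyclic coordinate minimization where each 1-D
## problem is solved by dense grid search over the exact objective, fully
## independent of the closed-form update used by the package.
brute_scad <- function(X, y, a, lam, grid_lim = 5, step = 1e-4, sweeps = 200) {
  n <- nrow(X); p <- ncol(X)
  beta <- numeric(p)
  b0 <- mean(y)
  obj <- function(beta, b0) {
    sum((y - b0 - X %*% beta)^2) / (2 * n) + sum(scad_penalty(beta, a, lam))
  }
  grid <- seq(-grid_lim, grid_lim, by = step)
  for (s in seq_len(sweeps)) {
    old <- c(b0, beta)
    for (j in seq_len(p)) {
      r <- y - b0 - X[, -j, drop = FALSE] %*% beta[-j]
      vals <- colSums((as.vector(r) - outer(as.vector(X[, j]), grid))^2) / (2 * n) +
        scad_penalty(grid, a, lam)
      beta[j] <- grid[which.min(vals)]
    }
    b0 <- mean(y - X %*% beta)
    if (max(abs(c(b0, beta) - old)) < step / 2) break
  }
  list(beta = beta, intercept = b0, objective = obj(beta, b0))
}

## Direct Gaussian feature matrix with planted group shift, for classifier
## tests that do not need the full connectome pipeline.
gaussian_features <- function(n, p, d = 0, n_signal = 0, rate = 0.4) {
  y <- rbinom(n, 1, rate)
  while (length(unique(y)) < 2) y <- rbinom(n, 1, rate)
  x <- matrix(rnorm(n * p), n, p)
  if (n_signal > 0) x[, seq_len(n_signal)] <- x[, seq_len(n_signal)] + d * y
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}
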