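## Weighted, undirected graph metrics per region and their pre -> post change
## encodings. Strength and the Onnela-form weighted clustering coefficient are
## computed directly; betweenness centrality delegates to igraph with the
## inverse-weight edge-length convention.

#' Node strength
#'
#' The sum of connection weights to/from each region.
#'
#' @param c a `connectome`.
#' @return A named numeric vector, one value per region.
#' @export
node_strength <- function(c) {
  check_connectome(c)
  rowSums(c$weights)
}

#' Node betweenness centrality
#'
#' The number of shortest paths between other region pairs passing through
#' each region, with edge length 1/weight (stronger connections are shorter),
#' each unordered pair counted once and ties split fractionally. Disconnected
#' regions score 0.
#'
#' @param c a `connectome`.
#' @return A named numeric vector, one value per region.
#' @export
node_betweenness <- function(c) {
  check_connectome(c)
  w <- c$weights
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L) {
    out <- numeric(nrow(w))
  } else {
    out <- igraph::betweenness(g, directed = FALSE,
                               weights = 1 / igraph::E(g)$weight)
  }
  names(out) <- c$region_labels
  out
}

#' Node clustering coefficient (weighted, geometric-mean form)
#'
#' Weights are first normalized by the matrix maximum; each region's
#' coefficient is the sum over neighbour pairs of the geometric mean of the
#' three triangle weights, divided by k(k-1) where k is the binary degree.
#' Regions with fewer than two neighbours score 0. On a binary graph this
#' reduces to the unweighted per-node transitivity.
#'
#' @param c a `connectome`.
#' @return A named numeric vector in [0, 1], one value per region.
#' @export
node_clustering <- function(c) {
  check_connectome(c)
  w <- c$weights
  k <- rowSums(w > 0)
  mx <- max(w)
  out <- numeric(nrow(w))
  if (mx > 0) {
    w3 <- (w / mx)^(1 / 3)
    cyc3 <- diag(w3 %*% w3 %*% w3)
    denom <- k * (k - 1)
    out <- ifelse(denom > 0, cyc3 / denom, 0)
  }
  names(out) <- c$region_labels
  out
}

#' Pre to post metric change
#'
#' Strength uses the ratio post/pre (post-operative strength can only
#' decrease, so the ratio lies in [0, 1]); 0/0 is defined as 1 for regions
#' untouched because they were already disconnected. Betweenness and
#' clustering can move in either direction after resection and use the
#' difference post - pre.
#'
#' @param pre,post numeric metric vectors at the same threshold.
#' @param metric one of `"strength"`, `"betweenness"`, `"clustering"`.
#' @return A numeric change vector.
#' @export
metric_change <- function(pre, post, metric = c("strength", "betweenness", "clustering")) {
  metric <- match.arg(metric)
  if (length(pre) != length(post)) stop("pre/post length mismatch")
  if (metric == "strength") {
    out <- numeric(length(pre))
    zz <- pre == 0 & post == 0
    if (any(pre == 0 & post > 0))
      stop("post-operative strength exceeds zero pre-operative strength")
    out[zz] <- 1
    out[!zz] <- post[!zz] / pre[!zz]
  } else {
    out <- post - pre
  }
  names(out) <- names(pre)
  out
}

#' Average change vectors across prevalence thresholds
#'
#' @param per_threshold list of change vectors of one metric, one per
#'   threshold.
#' @return The elementwise arithmetic mean.
#' @export
average_over_thresholds <- function(per_threshold) {
  if (length(per_threshold) == 0L) stop("empty list of change vectors")
  Reduce(`+`, per_threshold) / length(per_threshold)
}

#' Metric-change table for a cohort of networks
#'
#' For every patient, threshold and metric: applies the cohort prevalence
#' mask to the raw pre- and post-operative connectomes, log-transforms both,
#' computes the metric at each stage, and encodes the change (ratio for
#' strength, difference otherwise).
#'
#' @param networks a `cohort_networks` object from [build_cohort_networks()].
#' @param metrics metrics to compute.
#' @return A tidy data frame: patient_id, region, metric, threshold, change.
#' @export
compute_metric_changes <- function(networks,
                                   metrics = c("strength", "betweenness", "clustering")) {
  stopifnot(inherits(networks, "cohort_networks"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  funs <- list(strength = node_strength, betweenness = node_betweenness,
               clustering = node_clustering)
  rows <- list()
  for (pid in names(networks$pre)) {
    for (m in networks$masks) {
      pre <- log_transform(apply_mask(networks$pre[[pid]], m),
                           offset = networks$log_offset)
      post <- log_transform(apply_mask(networks$post[[pid]], m),
                            offset = networks$log_offset)
      for (met in metrics) {
        ch <- metric_change(funs[[met]](pre), funs[[met]](post), met)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, region = names(ch), metric = met,
          threshold = m$threshold, change = unname(ch),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build pre/post connectomes and prevalence masks for a cohort
#'
#' @param streamlines named list of streamline tables (one per patient), or a
#'   `synthetic_cohort`.
#' @param n_regions number of atlas regions (taken from the cohort if given).
#' @param region_labels optional region names.
#' @param thresholds prevalence thresholds in percent.
#' @param log_offset offset used later by the log transform.
#' @return A `cohort_networks` object: raw pre/post connectomes per patient,
#'   shared prevalence masks computed on the pre-operative matrices, and the
#'   threshold/log settings.
#' @export
build_cohort_networks <- function(streamlines, n_regions = NULL,
                                  region_labels = NULL,
                                  thresholds = seq(75, 100, by = 5),
                                  log_offset = 1) {
  if (inherits(streamlines, "synthetic_cohort")) {
    cohort <- streamlines
    streamlines <- cohort$streamlines
    region_labels <- region_labels %||% cohort$region_labels
    n_regions <- n_regions %||% cohort$spec$n_regions %||% length(region_labels)
  }
  if (is.null(n_regions)) stop("n_regions is required")
  pre <- lapply(streamlines, build_connectome, n_regions = n_regions,
                use = "all", region_labels = region_labels)
  post <- lapply(streamlines, build_connectome, n_regions = n_regions,
                 use = "surviving", region_labels = region_labels)
  masks <- prevalence_masks(pre, thresholds)
  structure(list(pre = pre, post = post, masks = masks,
                 thresholds = thresholds, log_offset = log_offset,
                 region_labels = region_labels %||% pre[[1]]$region_labels),
            class = "cohort_networks")
}
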