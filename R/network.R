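## Connectome construction: streamline tables -> weighted adjacency matrices,
## virtual resection, log transform, and cross-patient prevalence thresholding.

#' Construct a connectome object
#'
#' A connectome is a symmetric, nonnegative weighted adjacency matrix over
#' atlas regions with a zero diagonal (self-connections removed).
#'
#' @param weights symmetric numeric matrix of nonnegative edge weights.
#' @param region_labels character vector of region names (hemisphere-tagged),
#'   one per row/column. Defaults to existing dimnames or `R1..Rn`.
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, region_labels = NULL) {
  if (!is_square_symmetric(weights)) stop("weights must be a symmetric square matrix")
  if (any(weights < 0)) stop("weights must be nonnegative")
  diag(weights) <- 0
  n <- nrow(weights)
  if (is.null(region_labels)) region_labels <- rownames(weights) %||% paste0("R", seq_len(n))
  if (length(region_labels) != n) stop("region_labels length must match matrix dimension")
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, region_labels = region_labels),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  w <- x$weights
  cat("Connectome:", nrow(w), "regions,", sum(w[upper.tri(w)] > 0), "edges,",
      "total weight", format(sum(w) / 2, digits = 6), "\n")
  invisible(x)
}

#' Build a connectome from a streamline table
#'
#' Counts streamlines per unordered region pair. Self-connections (both
#' endpoints in the same region) are removed. With `use = "surviving"` only
#' streamlines not flagged as resected contribute, yielding the estimated
#' post-operative connectome.
#'
#' @param streamlines data frame with integer columns `region_i`, `region_j`
#'   and logical/0-1 column `resected`.
#' @param n_regions number of atlas regions.
#' @param use `"all"` (pre-operative) or `"surviving"` (post-operative).
#' @param region_labels optional region names.
#' @return A `connectome` with integer streamline-count weights.
#' @export
build_connectome <- function(streamlines, n_regions,
                             use = c("all", "surviving"),
                             region_labels = NULL) {
  use <- match.arg(use)
  ri <- as.integer(streamlines$region_i)
  rj <- as.integer(streamlines$region_j)
  res <- as.logical(streamlines$resected)
  if (length(ri) && (min(ri, rj) < 1L || max(ri, rj) > n_regions))
    stop("streamline region id out of atlas range [1, ", n_regions, "]")
  if (use == "surviving") {
    keep <- !res
    ri <- ri[keep]; rj <- rj[keep]
  }
  w <- matrix(0, n_regions, n_regions)
  if (length(ri)) {
    off <- ri != rj  # self-connections removed
    lo <- pmin(ri[off], rj[off])
    hi <- pmax(ri[off], rj[off])
    if (length(lo)) {
      tab <- table(lo + n_regions * (hi - 1L))
      idx <- as.integer(names(tab))
      w[idx] <- as.numeric(tab)
      w <- w + t(w)
    }
  }
  connectome(w, region_labels)
}

#' Virtual resection of a streamline table
#'
#' Removes every streamline flagged as passing through the resection mask,
#' returning the surviving records only.
#'
#' @param streamlines streamline data frame with a `resected` column.
#' @return The subset of rows with `resected == FALSE`.
#' @export
virtual_resection <- function(streamlines) {
  streamlines[!as.logical(streamlines$resected), , drop = FALSE]
}

#' Log-transform connectome weights
#'
#' Applies `log10(offset + w)` elementwise, mapping zeros to zero when
#' `offset = 1` and preserving the weight order. Streamline-count
#' distributions are heavily right-skewed, which motivates the transform.
#'
#' @param c a `connectome`.
#' @param offset added before the log; the default 1 keeps zero edges at zero
#'   (a bare log10 would annihilate weight-1 edges).
#' @return A transformed `connectome`.
#' @export
log_transform <- function(c, offset = 1) {
  check_connectome(c)
  if (any(c$weights < 0)) stop("negative weights")
  w <- log10(offset + c$weights)
  if (offset == 1) w[c$weights == 0] <- 0
  diag(w) <- 0
  connectome(w, c$region_labels)
}

#' Cross-patient prevalence masks
#'
#' For each threshold t, an edge is kept iff it has strictly positive
#' pre-operative weight in at least t% of patients. Masks are nested: the
#' 100% mask is contained in every lower-threshold mask.
#'
#' @param preop_cohort list of pre-operative `connectome`s (>= 2 patients).
#' @param thresholds percent thresholds, default 75 to 100 in steps of 5.
#' @return A list of `prevalence_mask` objects (fields `threshold`, `keep`).
#' @export
prevalence_masks <- function(preop_cohort, thresholds = seq(75, 100, by = 5)) {
  if (length(preop_cohort) < 2L) stop("need at least 2 patients")
  dims <- vapply(preop_cohort, function(c) nrow(c$weights), integer(1))
  if (length(unique(dims)) != 1L) stop("connectome dimension mismatch")
  pres <- Reduce(`+`, lapply(preop_cohort, function(c) (c$weights > 0) * 1))
  frac <- pres / length(preop_cohort)
  lapply(thresholds, function(t) {
    keep <- frac >= (t / 100 - 1e-9)
    diag(keep) <- FALSE
    structure(list(threshold = t, keep = keep), class = "prevalence_mask")
  })
}

#' Apply a prevalence mask to a connectome
#'
#' Zeroes edges not kept by the mask. The same cohort-level mask is applied
#' to the pre- and post-operative matrix of every patient so that change
#' metrics compare like-for-like.
#'
#' @param c a `connectome`.
#' @param m a `prevalence_mask` of matching dimension.
#' @return The masked `connectome`.
#' @export
apply_mask <- function(c, m) {
  check_connectome(c)
  if (!identical(dim(c$weights), dim(m$keep))) stop("mask dimension mismatch")
  w <- c$weights * (m$keep * 1)
  connectome(w, c$region_labels)
}

#' Write / read a connectome as dense CSV
#'
#' @param c a `connectome`.
#' @param path CSV path; header row carries region labels.
#' @export
write_connectome <- function(c, path) {
  check_connectome(c)
  write.csv(as.data.frame(c$weights), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  connectome(as.matrix(d), colnames(d))
}
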