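## Internal helpers shared across modules.

#' @useDynLib connectoclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rnbinom sd var dist uniroot plogis
#'   qlogis predict coef t.test
#' @importFrom utils write.csv read.csv head
NULL

col_sd <- function(x) {
  apply(x, 2, stats::sd)
}

## Rank-based AUC for binary labels (probability a positive scores above a
## negative; ties count 1/2). Decision values with NA are dropped pairwise.
## Cross-checked against pROC in the test suite.
auc_score <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Deterministic seed fan-out: one sub-seed per named stage, stable under
## stage insertion because each stage has a fixed slot.
fan_seed <- function(master, slot) {
  stopifnot(is.numeric(master), length(master) == 1L, slot >= 0, slot < 1000)
  (abs(as.integer(master)) %% 1000000L) * 1000L + as.integer(slot)
}

is_square_symmetric <- function(w, tol = 1e-8) {
  is.matrix(w) && nrow(w) == ncol(w) && max(abs(w - t(w))) <= tol
}

check_connectome <- function(c) {
  stopifnot(inherits(c, "connectome"))
  w <- c$weights
  if (!is_square_symmetric(w)) stop("connectome weights must be a symmetric matrix")
  if (any(w < 0)) stop("connectome weights must be nonnegative")
  if (any(diag(w) != 0)) stop("connectome must have a zero diagonal")
  invisible(c)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
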