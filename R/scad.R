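## SCAD-penalized least squares: penalty, closed-form coordinate update,
## lambda path top, (a, lambda) grid, coordinate-descent solver (compiled)
## and candidate-support extraction.

#' SCAD configuration
#'
#' Defaults follow the selection protocol: the concavity parameter a takes
#' 50 evenly spaced values between 2 and 10, lambda takes 100 values from
#' lambda_max (the smallest penalty producing an all-zero fit) down to half
#' of it, giving 5000 grid points, and only supports with fewer than 20
#' variables are carried forward to classification.
#'
#' @param a_count,a_min,a_max concavity grid.
#' @param lambda_count,lambda_min_ratio lambda grid (log-spaced).
#' @param max_support largest admissible support size (19 = "under 20").
#' @param tolerance coordinate-descent convergence tolerance (max
#'   coefficient change per sweep).
#' @param max_iter maximum sweeps per grid point.
#' @return A `scad_config`.
#' @export
scad_config <- function(a_count = 50, a_min = 2, a_max = 10,
                        lambda_count = 100, lambda_min_ratio = 0.5,
                        max_support = 19, tolerance = 1e-6, max_iter = 500) {
  stopifnot(a_min > 1, a_max >= a_min, lambda_min_ratio > 0,
            lambda_min_ratio < 1, max_support >= 1, tolerance > 0)
  structure(list(a_count = a_count, a_min = a_min, a_max = a_max,
                 lambda_count = lambda_count,
                 lambda_min_ratio = lambda_min_ratio,
                 max_support = max_support, tolerance = tolerance,
                 max_iter = max_iter), class = "scad_config")
}

#' SCAD penalty function
#'
#' Piecewise in the coefficient magnitude: linear (lasso-like) below lambda,
#' quadratically clipped between lambda and a*lambda, and constant at
#' lambda^2 (a + 1) / 2 beyond, so large coefficients are not shrunk.
#' Continuous and even in beta.
#'
#' @param beta coefficient value(s).
#' @param a concavity parameter (> 1).
#' @param lam penalty scale (>= 0).
#' @return Penalty value(s).
#' @export
scad_penalty <- function(beta, a, lam) {
  if (a <= 1) stop("SCAD requires a > 1")
  if (any(lam < 0)) stop("lambda must be nonnegative")
  b <- abs(beta)
  ifelse(b <= lam, lam * b,
         ifelse(b <= a * lam,
                (2 * a * lam * b - b^2 - lam^2) / (2 * (a - 1)),
                lam^2 * (a + 1) / 2))
}

#' Univariate SCAD update
#'
#' Closed-form minimizer of `0.5 * (z - beta)^2 + scad_penalty(beta, a, lam)`
#' (the coordinate-descent kernel for a standardized design): soft threshold
#' below 2*lambda, a rescaled shrink up to a*lambda, identity beyond.
#'
#' @param z unpenalized univariate solution.
#' @param a concavity parameter (> 2 for this closed form).
#' @param lam penalty scale.
#' @return The penalized minimizer.
#' @export
scad_threshold <- function(z, a, lam) {
  if (a <= 2) stop("closed-form SCAD update requires a > 2")
  az <- abs(z)
  s <- sign(z)
  ifelse(az <= 2 * lam, s * pmax(0, az - lam),
         ifelse(az <= a * lam, ((a - 1) * z - s * a * lam) / (a - 2), z))
}

#' Top of the lambda path
#'
#' The smallest penalty scale at which the penalized least-squares fit is
#' entirely zero: `max_j |x_j' (y - mean(y))| / n`.
#'
#' @param X design matrix (features standardized on the training rows).
#' @param y response (binary labels as 0/1 reals).
#' @return lambda_max.
#' @export
lambda_max <- function(X, y) {
  n <- nrow(X)
  g <- abs(crossprod(X, y - mean(y))) / n
  out <- max(g)
  if (out <= 0) stop("design is constant; lambda_max undefined")
  out
}

#' Build the (a, lambda) grid
#'
#' @param cfg a `scad_config`.
#' @param lam_max top of the lambda path.
#' @return Data frame of `a` and `lambda` (a-major, lambda descending and
#'   log-spaced down to `lambda_min_ratio * lam_max`); 5000 rows at the
#'   defaults.
#' @export
build_grid <- function(cfg = scad_config(), lam_max) {
  stopifnot(lam_max > 0)
  a <- seq(cfg$a_min, cfg$a_max, length.out = cfg$a_count)
  lam <- exp(seq(log(lam_max), log(cfg$lambda_min_ratio * lam_max),
                 length.out = cfg$lambda_count))
  data.frame(a = rep(a, each = cfg$lambda_count),
             lambda = rep(lam, times = cfg$a_count))
}

scad_objective <- function(X, y, beta, intercept, a, lam) {
  r <- y - intercept - drop(X %*% beta)
  sum(r^2) / (2 * nrow(X)) + sum(scad_penalty(beta, a, lam))
}

#' Fit SCAD-penalized least squares at one (a, lambda)
#'
#' Cyclic coordinate descent with the exact univariate SCAD minimizer and an
#' unpenalized intercept (handled by centering). The objective
#' `|y - b0 - X beta|^2 / (2n) + sum_j p(beta_j; a, lambda)` is non-increasing
#' across sweeps; convergence is declared when the largest coefficient
#' change in a sweep falls below the tolerance.
#'
#' @param X design matrix.
#' @param y response.
#' @param a,lam SCAD parameters.
#' @param warm_start optional initial coefficients.
#' @param tolerance,max_iter solver controls.
#' @return List: `beta`, `intercept`, `converged`, `iterations`,
#'   `objective`, `support` (1-based nonzero indices). Non-convergence is
#'   flagged, not an error.
#' @export
fit_scad <- function(X, y, a, lam, warm_start = NULL, tolerance = 1e-8,
                     max_iter = 1000) {
  stopifnot(a > 1, lam >= 0, nrow(X) >= 2)
  n <- nrow(X); p <- ncol(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar, "-")
  yc <- y - mean(y)
  beta0 <- warm_start %||% numeric(p)
  fit <- scad_fit_cpp(crossprod(Xc), drop(crossprod(Xc, yc)), n, a, lam,
                      tolerance, max_iter, beta0)
  beta <- drop(fit$beta)
  names(beta) <- colnames(X)
  intercept <- mean(y) - sum(xbar * beta)
  list(beta = beta, intercept = intercept, converged = fit$converged,
       iterations = fit$iterations,
       objective = scad_objective(X, y, beta, intercept, a, lam),
       support = which(beta != 0))
}

#' Compute the full SCAD path over the (a, lambda) grid
#'
#' Warm-started along each a-row with lambda descending from lambda_max.
#' Supports are deduplicated across the grid.
#'
#' @param X design matrix (training rows, scaled).
#' @param y 0/1 response.
#' @param cfg a `scad_config`.
#' @param coefficients keep per-grid-point coefficient vectors (memory-heavy
#'   for large p; supports are always returned).
#' @return A `scad_path`: `grid` (data frame with a, lambda, support_id,
#'   support_size, converged), `supports` (list of 1-based index vectors),
#'   `lam_max`, and optionally `beta` (p x grid matrix).
#' @export
scad_path <- function(X, y, cfg = scad_config(), coefficients = FALSE) {
  n <- nrow(X)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar, "-")
  yc <- y - mean(y)
  lm <- lambda_max(X, y)
  grid <- build_grid(cfg, lm)
  avals <- seq(cfg$a_min, cfg$a_max, length.out = cfg$a_count)
  lamvals <- exp(seq(log(lm), log(cfg$lambda_min_ratio * lm),
                     length.out = cfg$lambda_count))
  res <- scad_path_cpp(crossprod(Xc), drop(crossprod(Xc, yc)), n, avals,
                       lamvals, cfg$tolerance, cfg$max_iter, coefficients)
  sizes <- vapply(res$supports, length, integer(1))
  grid$support_id <- res$support_id
  grid$support_size <- sizes[res$support_id]
  grid$converged <- res$converged
  out <- list(grid = grid, supports = res$supports, lam_max = lm,
              config = cfg)
  if (coefficients) out$beta <- res$beta
  structure(out, class = "scad_path")
}

#' Candidate supports from a SCAD path
#'
#' Unique nonzero index sets with size between 1 and `max_support`
#' (inclusive), each tagged with one (a, lambda) pair that produced it.
#'
#' @param path a `scad_path`.
#' @param max_support inclusion cap (default from the path's config).
#' @return Data-frame-free list: each element has `support`, `a`, `lambda`.
#' @export
select_candidate_supports <- function(path, max_support = path$config$max_support) {
  sizes <- vapply(path$supports, length, integer(1))
  ok <- which(sizes >= 1L & sizes <= max_support)
  lapply(ok, function(id) {
    hit <- which(path$grid$support_id == id)[1]
    list(support = path$supports[[id]], a = path$grid$a[hit],
         lambda = path$grid$lambda[hit])
  })
}
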