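test_that("the SCAD penalty matches its piecewise branches and is continuous", {
  expect_equal(scad_penalty(0, 3, 1), 0)
  expect_equal(scad_penalty(0.5, 3, 1), 0.5)          # linear branch
  expect_equal(scad_penalty(2, 3, 1), 1.75)           # (12 - 4 - 1) / 4
  expect_equal(scad_penalty(10, 3, 1), 2)             # plateau (a + 1) / 2
  expect_equal(scad_penalty(-2, 3, 1), scad_penalty(2, 3, 1))  # even
  ## continuity at |beta| = lambda and a * lambda
  for (a in c(2.3, 3.7, 8)) for (lam in c(0.4, 1, 2.5)) {
    eps <- 1e-9
    expect_equal(scad_penalty(lam - eps, a, lam), scad_penalty(lam + eps, a, lam),
                 tolerance = 1e-6)
    expect_equal(scad_penalty(a * lam - eps, a, lam),
                 scad_penalty(a * lam + eps, a, lam), tolerance = 1e-6)
    expect_equal(scad_penalty(lam, a, lam), lam^2)
    expect_equal(scad_penalty(a * lam, a, lam), lam^2 * (a + 1) / 2)
  }
  expect_error(scad_penalty(1, 0.9, 1), "a > 1")
})

test_that("the univariate update solves the scalar penalized problem", {
  expect_equal(scad_threshold(0.5, 3.7, 1), 0)   # below threshold
  expect_equal(scad_threshold(10, 3.7, 1), 10)   # unpenalized region
  expect_error(scad_threshold(1, 2, 1), "a > 2")
  set.seed(14)
  grid <- seq(-8, 8, by = 1e-4)
  for (i in 1:25) {
    z <- runif(1, -5, 5); a <- runif(1, 2.05, 9); lam <- runif(1, 0.05, 2)
    brute <- grid[which.min(0.5 * (z - grid)^2 + scad_penalty(grid, a, lam))]
    expect_equal(scad_threshold(z, a, lam), brute, tolerance = 1e-3)
  }
})

test_that("lambda_max tops the path and matches the gradient formula", {
  set.seed(21)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rbinom(40, 1, 0.4)
  lm_ <- lambda_max(X, y)
  expect_equal(lm_, max(abs(crossprod(X, y - mean(y)))) / 40)
  f <- fit_scad(X, y, a = 3.7, lam = lm_)
  expect_length(f$support, 0)
  f2 <- fit_scad(X, y, a = 3.7, lam = 1.01 * lm_)
  expect_length(f2$support, 0)
  ## orthonormal columns: direct formula check
  Q <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  expect_equal(lambda_max(Q, y[1:30]),
               max(abs(t(Q) %*% (y[1:30] - mean(y[1:30])))) / 30)
  expect_error(lambda_max(matrix(1, 10, 2), rep(0.5, 10)), "constant")
})

test_that("the (a, lambda) grid has 5000 points with the stated endpoints", {
  g <- build_grid(scad_config(), lam_max = 3)
  expect_equal(nrow(g), 5000)
  expect_equal(length(unique(g$a)), 50)
  expect_equal(range(g$a), c(2, 10))
  expect_equal(max(g$lambda), 3)
  expect_equal(min(g$lambda), 1.5)  # lambda_min_ratio 0.5
})

test_that("fit_scad recovers least squares at lambda = 0", {
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  y <- rnorm(5)
  f <- fit_scad(X, y, a = 3.7, lam = 0)
  ols <- unname(coef(lm(y ~ X)))
  expect_equal(unname(f$beta), ols[-1], tolerance = 1e-6)
  expect_equal(f$intercept, ols[1], tolerance = 1e-6)
})

test_that("orthonormal-design coordinates equal the univariate update", {
  set.seed(33)
  n <- 40
  Q <- qr.Q(qr(matrix(rnorm(n * 5), n, 5))) * sqrt(n)  # columns with x'x = n
  Q <- sweep(Q, 2, colMeans(Q))  # centered, nearly orthonormal
  Q <- qr.Q(qr(Q)) * sqrt(n)
  y <- rnorm(n)
  ols <- drop(crossprod(Q, y - mean(y))) / n
  for (lam in c(0.05, 0.1, 0.2)) {
    f <- fit_scad(Q, y, a = 3.7, lam = lam)
    expect_equal(unname(f$beta), unname(scad_threshold(ols, 3.7, lam)),
                 tolerance = 1e-5)
  }
})

test_that("solutions match brute-force coordinate search on tiny problems", {
  set.seed(55)
  for (i in 1:6) {
    n <- sample(5:8, 1); p <- sample(2:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    a <- runif(1, 2.1, 6); lam <- runif(1, 0.05, 0.5)
    f <- fit_scad(X, y, a = a, lam = lam)
    b <- brute_scad(X, y, a, lam)
    expect_lte(f$objective, b$objective + 1e-6)
  }
})

test_that("the objective never increases from warm starts or perturbations", {
  set.seed(77)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rbinom(30, 1, 0.5)
  obj <- function(beta, b0, a, lam)
    sum((y - b0 - X %*% beta)^2) / (2 * 30) + sum(scad_penalty(beta, a, lam))
  for (i in 1:10) {
    a <- runif(1, 2.1, 9); lam <- runif(1, 0.02, 0.3)
    start <- rnorm(8, sd = 0.5)
    f <- fit_scad(X, y, a = a, lam = lam, warm_start = start)
    b0_start <- mean(y) - sum(colMeans(X) * start)
    expect_lte(f$objective, obj(start, b0_start, a, lam) + 1e-10)
    expect_lte(f$objective, obj(numeric(8), mean(y), a, lam) + 1e-10)
  }
})

test_that("the path dedupes supports and applies the size cap", {
  set.seed(91)
  x <- gaussian_features(30, 12, d = 2, n_signal = 3)
  Xs <- scale_sd1(x$x)
  path <- scad_path(Xs, x$y, scad_config(a_count = 5, lambda_count = 20))
  expect_equal(nrow(path$grid), 100)
  ## lambda_max row is the all-zero support
  expect_equal(path$grid$support_size[1], 0)
  cands <- select_candidate_supports(path)
  sizes <- vapply(cands, function(c) length(c$support), integer(1))
  expect_true(all(sizes >= 1 & sizes <= 19))
  ## dedup: no two candidates share a support
  keys <- vapply(cands, function(c) paste(c$support, collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0L)
  cap <- select_candidate_supports(path, max_support = 2)
  expect_true(all(vapply(cap, function(c) length(c$support), integer(1)) <= 2))
})

test_that("support just below lambda_max is the top-correlation feature", {
  set.seed(101)
  n <- 60
  Q <- qr.Q(qr(matrix(rnorm(n * 6), n, 6))) * sqrt(n)
  beta <- c(2, 0, 0, 0, 0, 0)
  y <- drop(Q %*% beta) + rnorm(n, sd = 0.3)
  lm_ <- lambda_max(Q, y)
  f <- fit_scad(Q, y, a = 3.7, lam = 0.995 * lm_)
  j_star <- which.max(abs(crossprod(Q, y - mean(y))))
  expect_equal(f$support, j_star, ignore_attr = TRUE)
})
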