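test_that("build_connectome counts unordered streamline pairs and drops self-loops", {
  s <- data.frame(region_i = c(1, 2, 3), region_j = c(2, 1, 3),
                  resected = c(FALSE, FALSE, FALSE))
  c <- build_connectome(s, 4)
  expect_equal(c$weights[1, 2], 2)
  expect_equal(c$weights[2, 1], 2)
  expect_equal(c$weights[3, 3], 0)  # self-connection removed
  expect_equal(sum(c$weights), 4)

  mix <- data.frame(region_i = c(1, 1), region_j = c(2, 2),
                    resected = c(TRUE, FALSE))
  expect_equal(build_connectome(mix, 3, use = "surviving")$weights[1, 2], 1)
  expect_equal(build_connectome(mix, 3, use = "all")$weights[1, 2], 2)

  bad <- data.frame(region_i = 5, region_j = 1, resected = FALSE)
  expect_error(build_connectome(bad, 4), "out of atlas range")
})

test_that("virtual resection removes flagged records only", {
  set.seed(1)
  s <- random_streamlines(10, 5)
  s$resected <- c(rep(TRUE, 3), rep(FALSE, 7))
  expect_equal(nrow(virtual_resection(s)), 7)
  s$resected <- FALSE
  expect_identical(virtual_resection(s), s)
  s$resected <- TRUE
  expect_equal(nrow(virtual_resection(s)), 0)
})

test_that("building from a resected table equals the surviving selector", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_streamlines(sample(5:60, 1), 6)
    a <- build_connectome(virtual_resection(s), 6)
    b <- build_connectome(s, 6, use = "surviving")
    expect_equal(a$weights, b$weights)
  }
})

test_that("log transform maps counts as log10(1 + w) and rejects negatives", {
  c <- connectome(rbind(c(0, 9, 0), c(9, 0, 99), c(0, 99, 0)))
  lt <- log_transform(c)
  expect_equal(lt$weights[1, 2], 1)    # log10(10)
  expect_equal(lt$weights[2, 3], 2)    # log10(100)
  expect_equal(lt$weights[1, 3], 0)    # zero stays zero
  ## monotone order preserved
  set.seed(3)
  r <- random_connectome(6)
  lr <- log_transform(r)
  ut <- upper.tri(r$weights)
  expect_equal(order(r$weights[ut]), order(lr$weights[ut]))
  expect_error(connectome(rbind(c(0, -1), c(-1, 0))), "nonnegative")
})

test_that("prevalence masks follow the cross-patient presence fraction", {
  mk <- function(w12, w13) {
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- w12
    w[1, 3] <- w[3, 1] <- w13
    connectome(w)
  }
  ## edge (1,2) present in 3/4 patients, edge (1,3) in 4/4
  cohort <- list(mk(1, 1), mk(2, 3), mk(5, 2), mk(0, 4))
  masks <- prevalence_masks(cohort)
  expect_length(masks, 6)
  m75 <- masks[[1]]; m80 <- masks[[2]]; m100 <- masks[[6]]
  expect_true(m75$keep[1, 2])    # 3/4 = 75%
  expect_false(m80$keep[1, 2])
  expect_true(all(vapply(masks, function(m) m$keep[1, 3], logical(1))))
  expect_false(any(vapply(masks, function(m) m$keep[2, 3], logical(1))))
  ## nesting: higher threshold is a subset
  for (k in 2:6) expect_true(all(masks[[k]]$keep <= masks[[k - 1]]$keep))
  ## 100% mask equals the cohort-wide edge intersection
  inter <- Reduce(`&`, lapply(cohort, function(c) c$weights > 0))
  diag(inter) <- FALSE
  expect_equal(m100$keep, inter)
  expect_error(prevalence_masks(cohort[1]), "at least 2")
})

test_that("apply_mask zeroes removed edges and nothing else", {
  set.seed(11)
  c <- random_connectome(5)
  all_true <- structure(list(threshold = 75,
                             keep = matrix(TRUE, 5, 5) & !diag(5) > 0),
                        class = "prevalence_mask")
  expect_equal(apply_mask(c, all_true)$weights, c$weights)
  none <- all_true; none$keep[] <- FALSE
  expect_true(all(apply_mask(c, none)$weights == 0))
  one <- all_true; one$keep[1, 2] <- one$keep[2, 1] <- FALSE
  masked <- apply_mask(c, one)$weights
  expect_equal(masked[1, 2], 0)
  masked[1, 2] <- masked[2, 1] <- c$weights[1, 2]
  expect_equal(masked, c$weights)
})

test_that("post-operative weights never exceed pre-operative ones", {
  fx <- fixture_cohort()
  net <- fx$networks
  for (pid in names(net$pre)) {
    for (m in net$masks) {
      pre <- apply_mask(net$pre[[pid]], m)$weights
      post <- apply_mask(net$post[[pid]], m)$weights
      expect_true(all(post <= pre))
    }
  }
})

test_that("connectome CSV round-trips", {
  set.seed(2)
  c <- random_connectome(4)
  f <- tempfile(fileext = ".csv")
  write_connectome(c, f)
  expect_equal(read_connectome(f)$weights, c$weights)
})
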