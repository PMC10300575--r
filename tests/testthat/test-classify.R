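test_that("SMOTE balances classes by segment interpolation", {
  set.seed(1)
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0, 1), 5)
  bal <- smote(x, y)                 # already balanced: identity
  expect_identical(bal$x, x)
  ## minority on the diagonal: synthetic points stay on the segment
  xm <- rbind(c(0, 0), c(1, 1))
  xmaj <- matrix(rnorm(20, 5), 10, 2)
  x2 <- rbind(xm, xmaj)
  y2 <- c(1, 1, rep(0, 10))
  bal2 <- smote(x2, y2, k = 1)
  expect_equal(sum(bal2$y == 1), 10)
  synth <- bal2$x[bal2$y == 1, ][-(1:2), ]
  expect_equal(synth[, 1], synth[, 2])
  ## study imbalance 17 vs 27 becomes 27 vs 27
  x3 <- matrix(rnorm(44 * 3), 44, 3)
  y3 <- c(rep(1, 17), rep(0, 27))
  bal3 <- smote(x3, y3)
  expect_equal(as.integer(table(bal3$y)), c(27L, 27L))
  expect_error(smote(matrix(rnorm(10), 5), c(1, 0, 0, 0, 0)),
               "at least 2 minority")
})

test_that("confusion-count metrics match hand arithmetic", {
  m <- evaluate_counts(tp = 14, fn = 3, tn = 23, fp = 4)
  expect_equal(round(100 * m$specificity, 1), 85.2)
  expect_equal(round(100 * m$accuracy, 1), 84.1)
  m2 <- evaluate_counts(tp = 10, fn = 1, tn = 21, fp = 5)
  expect_equal(round(100 * m2$specificity, 2), 80.77)
  expect_equal(round(100 * m2$accuracy, 2), 83.78)
  perfect <- evaluate_counts(tp = 5, fn = 0, tn = 5, fp = 0)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "precision", "f1")]),
               rep(1, 5), ignore_attr = TRUE)
  ## all-majority predictions: zero F1 for the minority
  maj <- evaluate_counts(tp = 0, fn = 7, tn = 20, fp = 0)
  expect_equal(maj$f1, 0)
  expect_true(is.na(maj$precision))
  expect_error(evaluate_counts(0, 0, 0, 0), "empty")
})

test_that("accuracy decomposes into prevalence-weighted sens and spec", {
  set.seed(9)
  for (i in 1:20) {
    tp <- sample(0:20, 1); fn <- sample(0:20, 1)
    tn <- sample(0:20, 1); fp <- sample(0:20, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    m <- evaluate_counts(tp, fn, tn, fp)
    P <- tp + fn; N <- tn + fp
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
  }
})

test_that("model selection maximizes AUC with parsimony tie-breaks", {
  r <- function(auc, sz, lam = 1, a = 3) list(auc = auc, support_size = sz,
                                              lambda = lam, a = a)
  expect_equal(select_best_model(list(r(0.7, 3)))$auc, 0.7)
  expect_equal(select_best_model(list(r(0.7, 3), r(0.9, 8), r(0.8, 2)))$auc, 0.9)
  tie <- select_best_model(list(r(0.9, 12), r(0.9, 5)))
  expect_equal(tie$support_size, 5)
  lam_tie <- select_best_model(list(r(0.9, 5, lam = 0.5), r(0.9, 5, lam = 0.8)))
  expect_equal(lam_tie$lambda, 0.8)
  expect_error(select_best_model(list()), "no candidate")
})

test_that("weighted AUC combines timepoints by true-instance counts", {
  expect_equal(weighted_auc(c(0.8, 0.6), c(1, 1)), 0.7)
  expect_equal(weighted_auc(c(0.8, 0.6), c(3, 1)), 0.75)
  expect_equal(weighted_auc(0.66, 5), 0.66)
  expect_error(weighted_auc(c(0.5), 0), "sum")
})

test_that("weighted feature importance multiplies mean |coef| by inclusion", {
  feats <- c("a", "b", "c")
  its <- list(list(support = "a", coef = 1),
              list(support = c("a", "b"), coef = c(1, 0.5)))
  wfi <- weighted_feature_importance(its, feats)
  expect_equal(unname(wfi["a"]), 1 * 100)       # every iteration, |coef| 1
  expect_equal(unname(wfi["b"]), 0.5 * 50)      # half of iterations
  expect_equal(unname(wfi["c"]), 0)             # never selected
})

test_that("rank AUC agrees with pROC and is monotone-transform invariant", {
  set.seed(12)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  a1 <- connectoclass:::auc_score(s, y)
  expect_equal(a1, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                  direction = "<"))))
  expect_equal(connectoclass:::auc_score(exp(3 * s) + 2, y), a1)
  expect_equal(connectoclass:::auc_score(rank(s), y), a1)
})

test_that("separable planted data achieves a perfect pooled LOO AUC", {
  set.seed(3)
  g <- gaussian_features(36, 10, d = 4, n_signal = 2)
  m <- decline_model(g$x, g$y, scad = scad_config(a_count = 10, lambda_count = 25),
                     seed = 5)
  expect_gte(m$auc, 0.97)
  expect_s3_class(m, "decline_model")
  ## the fitted object supports the standard methods
  expect_no_error(print(m))
  expect_no_error(summary(m))
  expect_type(coef(m), "double")
  pred <- predict(m, g$x)
  expect_true(all(pred %in% 0:1))
  expect_gt(mean(pred == g$y), 0.85)
})

test_that("fitting is deterministic under a fixed seed", {
  set.seed(8)
  g <- gaussian_features(24, 8, d = 1.5, n_signal = 2)
  m1 <- decline_model(g$x, g$y, scad = scad_config(a_count = 4, lambda_count = 10),
                      seed = 7)
  m2 <- decline_model(g$x, g$y, scad = scad_config(a_count = 4, lambda_count = 10),
                      seed = 7)
  expect_identical(m1$auc, m2$auc)
  expect_identical(m1$weighted_importance, m2$weighted_importance)
  expect_identical(m1$fold_results, m2$fold_results)
})

test_that("held-out patients never influence selection, scaling or SMOTE", {
  ## move one patient far outside the training distribution: its own fold
  ## prediction must come from a model fitted without it, so the extreme
  ## row cannot make its own fold collapse
  set.seed(15)
  g <- gaussian_features(20, 6, d = 2, n_signal = 2)
  g$x[1, ] <- g$x[1, ] + 50
  expect_no_error(m <- decline_model(g$x, g$y,
                                     scad = scad_config(a_count = 3,
                                                        lambda_count = 8),
                                     seed = 2))
  expect_equal(nrow(m$fold_results), 20)
})
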