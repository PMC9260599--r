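test_that("slide vectors are weighted occupancy fractions", {
  fm <- tiny_feature_model(W = c(1, 1, 1.2, 1))
  a <- data.frame(slide_id = rep("sA", 10), cluster = rep(3L, 10))
  v <- build_slide_vectors(a, fm)
  expect_equal(unname(v["sA", ]), c(0, 0, 1.2, 0))

  # fraction-based: patch counts cancel
  a2 <- data.frame(slide_id = c(rep("s1", 4), rep("s2", 8)),
                   cluster = c(1L, 1L, 2L, 3L, rep(c(1L, 1L, 2L, 3L), 2)))
  v2 <- build_slide_vectors(a2, fm)
  expect_equal(unname(v2["s1", ]), unname(v2["s2", ]))

  # uniform occupancy with unit weights gives 1/k everywhere
  fm1 <- tiny_feature_model(W = rep(1, 4))
  a3 <- data.frame(slide_id = "u", cluster = 1:4)
  expect_equal(unname(build_slide_vectors(a3, fm1)["u", ]), rep(0.25, 4))

  # dividing by W recovers fractions summing to one
  expect_equal(sum(v["sA", ] / fm$scores$W), 1)
  expect_error(build_slide_vectors(a, fm, slide_ids = c("sA", "ghost")),
               "zero QC-passed")
})

test_that("cross-validation achieves near-perfect accuracy on separable data", {
  g <- sep_gaussians()
  for (fam in c("logistic", "svm")) {
    cv <- crossvalidate(g$x, g$y, family = fam, folds = 10, seed = 2)
    expect_gte(cv$mean_accuracy, 0.95)
    expect_gte(cv$auc, 0.95)
    expect_equal(length(cv$fold_accuracy), 10)
    expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  }
})

test_that("cross-validation is deterministic given the seed", {
  g <- sep_gaussians()
  cv1 <- crossvalidate(g$x, g$y, family = "logistic", folds = 10, seed = 9)
  cv2 <- crossvalidate(g$x, g$y, family = "logistic", folds = 10, seed = 9)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  expect_identical(cv1$auc, cv2$auc)
})

test_that("permuted labels drive accuracy to chance", {
  g <- sep_gaussians()
  set.seed(55)
  accs <- vapply(1:20, function(i) {
    crossvalidate(g$x, sample(g$y), family = "logistic", folds = 10,
                  seed = i)$mean_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("folds are disjoint, exhaustive and label-stratified", {
  g <- sep_gaussians(n = 50, seed = 43)
  cv <- crossvalidate(g$x, g$y, family = "logistic", folds = 10, seed = 3)
  expect_setequal(unique(cv$fold), 1:10)
  expect_equal(length(cv$fold), 50)
  # stratification: each fold's class count within 1 of n/folds per class
  for (j in 1:10) {
    tab <- table(factor(g$y[cv$fold == j],
                        levels = c("ineffective", "effective")))
    expect_true(all(abs(tab - 2.5) <= 0.5 + 1))
  }
})

test_that("AUC from continuous scores is invariant to monotone transforms", {
  set.seed(44)
  y <- factor(rep(c("ineffective", "effective"), each = 20),
              levels = c("ineffective", "effective"))
  s <- c(rnorm(20, 0), rnorm(20, 1))
  a1 <- olpfeat:::roc_auc(y, s)
  a2 <- olpfeat:::roc_auc(y, exp(3 * s))
  expect_equal(a1, a2)
})

test_that("unit weights reproduce raw-occupancy predictions", {
  fm1 <- tiny_feature_model(W = rep(1, 4))
  set.seed(45)
  a <- data.frame(
    slide_id = rep(sprintf("s%02d", 1:20), each = 9),
    cluster = sample.int(4, 180, replace = TRUE))
  v <- build_slide_vectors(a, fm1)
  frac <- t(vapply(sprintf("s%02d", 1:20), function(s)
    tabulate(a$cluster[a$slide_id == s], 4) / 9, numeric(4)))
  expect_equal(unname(v), unname(frac), ignore_attr = TRUE)
})

test_that("holdout evaluation behaves at both extremes", {
  g <- sep_gaussians()
  clf <- fit_classifier(g$x, g$y, family = "logistic")
  hold <- evaluate_holdout(clf, g$x, g$y)
  expect_equal(hold$auc, 1)
  expect_gte(hold$accuracy, 0.95)
  # re-evaluating the training set matches training accuracy closely
  cv <- crossvalidate(g$x, g$y, family = "logistic", folds = 10, seed = 1)
  expect_lt(abs(hold$accuracy - cv$mean_accuracy), 0.05 + 1e-9)
  # flipping the labels reverses the ranking
  flipped <- ifelse(g$y == "effective", "ineffective", "effective")
  expect_lte(evaluate_holdout(clf, g$x, flipped)$auc, 0.5)
  expect_error(evaluate_holdout(clf, g$x[0, , drop = FALSE], character(0)),
               "empty")
})

test_that("single-class inputs are rejected", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(fit_classifier(x, rep("effective", 10)), "both classes")
  expect_error(crossvalidate(x, rep("effective", 10)), "both classes")
})
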