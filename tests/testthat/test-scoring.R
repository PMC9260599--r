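toy_assignments <- function() {
  # n+ = 4, n- = 2; cluster 1 holds 3 positives + 1 negative,
  # cluster 2 holds 1 positive + 1 negative
  data.frame(
    slide_id = c("e1", "e1", "e1", "i1", "e1", "i1"),
    cluster = c(1L, 1L, 1L, 1L, 2L, 2L),
    label = c("effective", "effective", "effective", "ineffective",
              "effective", "ineffective"))
}

test_that("labels propagate from manifest and missing entries error", {
  a <- data.frame(slide_id = c("s1", "s1", "s2"), cluster = c(1L, 2L, 1L))
  m <- data.frame(slide_id = c("s1", "s2"),
                  label = c("effective", "ineffective"))
  la <- label_assignments(a, m)
  expect_equal(la$label, c("effective", "effective", "ineffective"))
  expect_error(label_assignments(a, m[1, , drop = FALSE]), "missing.*s2")
  m$label[2] <- NA
  expect_error(label_assignments(a, m), "without a response label")
})

test_that("the worked toy set reproduces the hand-computed scores", {
  s <- compute_feature_scores(toy_assignments(), k = 2)
  expect_equal(s$r_plus, c(0.75, 0.25))
  expect_equal(s$r_minus, c(0.5, 0.5))
  expect_equal(s$I, c(0.6, 1 / 3))
  expect_equal(s$W, c(1.1, 1 + abs(0.5 - 1 / 3)))
  expect_equal(s$W[2], 1.1667, tolerance = 1e-4)
  expect_equal(s$polarity, c("positive", "negative"))
})

test_that("scores match the hand-count oracle on random small sets", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    k <- sample(2:5, 1)
    a <- data.frame(slide_id = "s",
                    cluster = sample.int(k, n, replace = TRUE),
                    label = sample(c("effective", "ineffective"), n,
                                   replace = TRUE, prob = c(0.6, 0.4)))
    if (length(unique(a$label)) < 2) next
    s <- compute_feature_scores(a, k)
    o <- oracle_scores(a$cluster, a$label, k)
    expect_equal(s$r_plus, o$r_plus)
    expect_equal(s$r_minus, o$r_minus)
    expect_equal(s$I, o$I)
    expect_equal(s$W, o$W)
  }
})

test_that("labeled patches are conserved and weights bounded", {
  set.seed(22)
  for (rep in 1:5) {
    a <- data.frame(slide_id = "s",
                    cluster = sample.int(6, 80, replace = TRUE),
                    label = rep(c("effective", "ineffective"), c(50, 30)))
    s <- compute_feature_scores(a, 6)
    expect_equal(sum(s$r_plus), 1)
    expect_equal(sum(s$r_minus), 1)
    expect_true(all(s$W >= 1 & s$W <= 1.5))
    expect_true(all(s$I >= 0 & s$I <= 1))
    expect_equal(sum(s$size), 80)
  }
})

test_that("impact scores are rate-based: duplicating every patch changes nothing", {
  a <- toy_assignments()
  s1 <- compute_feature_scores(a, 2)
  s2 <- compute_feature_scores(rbind(a, a), 2)
  expect_equal(s1$I, s2$I)
  expect_equal(s1$W, s2$W)
})

test_that("moving a positive patch into a cluster never lowers its impact", {
  a <- toy_assignments()
  before <- compute_feature_scores(a, 2)$I[2]
  a$cluster[1] <- 2L   # one positive moves from cluster 1 to cluster 2
  after <- compute_feature_scores(a, 2)$I[2]
  expect_gte(after, before)
})

test_that("empty clusters are neutral and flagged; one-label inputs error", {
  a <- toy_assignments()
  s <- compute_feature_scores(a, 3)  # cluster 3 has no members
  expect_equal(s$I[3], 0.5)
  expect_equal(s$W[3], 1)
  expect_true(s$empty[3])
  expect_equal(s$polarity[3], "neutral")

  a$label <- "effective"
  expect_error(compute_feature_scores(a, 2), "both labels")
})

test_that("key-feature selection applies the threshold and shape exclusion", {
  s <- data.frame(cluster = 1:4, I = c(0.85, 0.62, 0.5, 0.15))
  morph <- data.frame(cluster = 1:4,
                      morphology = c("histology", "histology", "histology",
                                     "shape"))
  keyed <- select_key_features(s, 1.1, morph)
  # W = 1.35, 1.12, 1.0, 1.35; cluster 4 excluded as shape
  expect_equal(keyed$is_key, c(TRUE, TRUE, FALSE, FALSE))

  # W never exceeds 1.5, so a 1.5 threshold admits nothing
  expect_false(any(select_key_features(s, 1.5, morph)$is_key))
  # at 1.0 every non-neutral non-shape cluster is key
  expect_equal(select_key_features(s, 1.0, morph)$is_key,
               c(TRUE, TRUE, FALSE, FALSE))

  expect_error(select_key_features(s, 1.1,
                                   data.frame(cluster = 9,
                                              morphology = "shape")),
               "unknown cluster")
  expect_error(select_key_features(s, 1.1,
                                   data.frame(cluster = 1,
                                              morphology = "weird")),
               "shape.*histology")
})

test_that("the blank-area heuristic separates shape from histology clusters", {
  half_blank <- new_patch("s", 0L, 0L, {
    px <- textured_patch(31, 1)$pixels
    px[1:64, , ] <- 255L
    px
  })
  expect_equal(classify_shape_heuristic(rep(list(half_blank), 3)), "shape")
  expect_equal(classify_shape_heuristic(lapply(1:3, textured_patch)),
               "histology")
  expect_warning(out <- classify_shape_heuristic(list()), "histology")
  expect_equal(out, "histology")
})
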