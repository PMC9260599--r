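test_that("blank-pixel rule requires all three channels at threshold", {
  expect_true(is_blank_pixel(c(255, 255, 255), 240))
  expect_false(is_blank_pixel(c(0, 0, 0), 240))
  expect_false(is_blank_pixel(c(245, 239, 250), 240))  # G below threshold
  expect_true(is_blank_pixel(c(240, 240, 240), 240))
})

test_that("degenerate patches fail their expected first-cause criterion", {
  expect_equal(qc_patch(uniform_patch(255)), "blank")     # all white
  expect_equal(qc_patch(uniform_patch(180)), "variance")  # constant gray
  edge <- new_patch("s1", 0L, 0L, array(180L, dim = c(128, 100, 3)))
  expect_equal(qc_patch(edge), "size")                    # 100 px wide
  dark <- uniform_patch(50)
  expect_equal(qc_patch(dark), "brightness")              # mean 50 < 120
  expect_equal(qc_patch(textured_patch()), "accept")
})

test_that("size is checked before the pixel criteria", {
  # a blank *and* undersized patch must report size, the first criterion
  p <- new_patch("s1", 0L, 0L, array(255L, dim = c(100, 128, 3)))
  expect_equal(qc_patch(p), "size")
})

test_that("brightness and variance use pooled channel statistics", {
  px <- array(0L, dim = c(128, 128, 3))
  px[, , 1] <- 255L  # pure red: mean 85, pooled population variance 14450
  p <- new_patch("s1", 0L, 0L, px)
  v <- as.numeric(px)
  expect_equal(mean(v), 85)
  expect_equal(mean((v - mean(v))^2), 14450)
  expect_equal(qc_patch(p), "brightness")  # 85 < 120
})

test_that("filtering preserves order, counts first causes, and is idempotent", {
  patches <- list(textured_patch(1, 1), uniform_patch(255),
                  textured_patch(2, 2), uniform_patch(180),
                  new_patch("s1", 0L, 0L, array(180L, dim = c(100, 128, 3))),
                  textured_patch(3, 3))
  res <- qc_filter(patches)
  expect_equal(res$report$n_input, 6)
  expect_equal(res$report$n_passed, 3)
  expect_equal(res$report$n_rejected_by_criterion[["blank"]], 1)
  expect_equal(res$report$n_rejected_by_criterion[["variance"]], 1)
  expect_equal(res$report$n_rejected_by_criterion[["size"]], 1)
  expect_equal(res$report$n_passed +
                 sum(res$report$n_rejected_by_criterion),
               res$report$n_input)
  # survivors keep input order
  expect_identical(res$passed, patches[c(1, 3, 6)])
  # idempotent
  res2 <- qc_filter(res$passed)
  expect_identical(res2$passed, res$passed)
  expect_equal(res2$report$n_passed, res2$report$n_input)
})

test_that("empty input and uniform-reject sets produce consistent reports", {
  res <- qc_filter(list())
  expect_equal(res$report$n_input, 0)
  expect_equal(res$report$n_passed, 0)
  expect_equal(sum(res$report$n_rejected_by_criterion), 0)

  res <- qc_filter(rep(list(uniform_patch(255)), 10))
  expect_equal(res$report$n_rejected_by_criterion[["blank"]], 10)
  expect_length(res$passed, 0)
})

test_that("the 300x300 tiling passes 4 interior patches and rejects 5 by size", {
  r <- array(0L, dim = c(300, 300, 3))
  tex <- textured_patch(4, 1)$pixels
  for (ox in c(0, 128)) for (oy in c(0, 128))
    r[oy + 1:128, ox + 1:128, ] <- tex
  res <- qc_filter(tile_slide(r, "s1", 128))
  expect_equal(res$report$n_passed, 4)
  expect_equal(res$report$n_rejected_by_criterion[["size"]], 5)
})

test_that("raising the blank threshold never increases blank rejections", {
  set.seed(4)
  patches <- c(lapply(1:5, function(i) textured_patch(i, (i %% 4) + 1)),
               lapply(1:5, function(i)
                 uniform_patch(sample(235:255, 1))))
  counts <- vapply(c(200, 220, 240, 250, 256), function(th) {
    qc_filter(patches, qc_params(blank_threshold = th)
    )$report$n_rejected_by_criterion[["blank"]]
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("permuting the input permutes the pass set identically", {
  patches <- c(lapply(1:6, function(i) textured_patch(i, (i %% 4) + 1)),
               list(uniform_patch(255), uniform_patch(180)))
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  res_fwd <- qc_filter(patches)
  res_perm <- qc_filter(patches[perm])
  ids <- function(ps) vapply(ps, function(p) paste(p$slide_id, p$x, p$y,
                                                   sum(p$pixels)),
                             character(1))
  expect_setequal(ids(res_fwd$passed), ids(res_perm$passed))
  expect_equal(res_fwd$report$n_passed, res_perm$report$n_passed)
})
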