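test_that("analytic conv/tconv gradients match finite differences", {
  ns <- asNamespace("olpfeat")
  set.seed(42)
  num_grad <- function(arr, f, eps = 1e-5) {
    out <- arr
    for (i in seq_along(arr)) {
      a1 <- arr; a1[i] <- a1[i] + eps
      a2 <- arr; a2[i] <- a2[i] - eps
      out[i] <- (f(a1) - f(a2)) / (2 * eps)
    }
    out
  }
  h <- 8L; cin <- 2L; cout <- 3L; k <- 4L
  x <- array(rnorm(h * h * cin * 2), dim = c(h, h, cin, 2))
  w <- array(rnorm(k * k * cin * cout, sd = 0.3), dim = c(k, k, cin, cout))
  b <- rnorm(cout)
  f <- function(x, w, b) sum(ns$cpp_conv_forward(x, w, b, 2L, 1L)^2)
  g <- ns$cpp_conv_backward(x, w, 2 * ns$cpp_conv_forward(x, w, b, 2L, 1L),
                            2L, 1L)
  expect_lt(max(abs(num_grad(w, function(a) f(x, a, b)) - g$dw)), 1e-6)
  expect_lt(max(abs(num_grad(x, function(a) f(a, w, b)) - g$dx)), 1e-6)
  expect_lt(max(abs(num_grad(b, function(a) f(x, w, a)) - g$db)), 1e-6)

  v <- array(rnorm(k * k * cout * cin, sd = 0.3), dim = c(k, k, cout, cin))
  ft <- function(x, v, b) sum(ns$cpp_tconv_forward(x, v, b, 2L, 1L)^2)
  yt <- ns$cpp_tconv_forward(x, v, b, 2L, 1L)
  expect_equal(dim(yt), c(16L, 16L, cout, 2L))  # stride-2 upsampling
  gt <- ns$cpp_tconv_backward(x, v, 2 * yt, 2L, 1L)
  expect_lt(max(abs(num_grad(v, function(a) ft(x, a, b)) - gt$dw)), 1e-6)
  expect_lt(max(abs(num_grad(x, function(a) ft(a, v, b)) - gt$dx)), 1e-6)
  expect_lt(max(abs(num_grad(b, function(a) ft(x, v, a)) - gt$db)), 1e-6)
})

test_that("training reduces reconstruction loss and is seed-reproducible", {
  patches <- lapply(1:16, function(i) textured_patch(i, (i %% 4) + 1))
  ae1 <- train_autoencoder(patches, latent_dim = 64, epochs = 3,
                           batch_size = 4, seed = 5)
  expect_length(ae1$loss, 3)
  expect_true(all(is.finite(ae1$loss)))
  expect_lte(ae1$loss[3], ae1$loss[1])
  ae2 <- train_autoencoder(patches, latent_dim = 64, epochs = 3,
                           batch_size = 4, seed = 5)
  expect_identical(ae1$loss, ae2$loss)
  expect_identical(encode_patches(ae1, patches[1:3]),
                   encode_patches(ae2, patches[1:3]))
})

test_that("input validation rejects empty, non-uniform and misshapen input", {
  expect_error(train_autoencoder(list()), "at least one")
  p1 <- textured_patch(1)
  small <- new_patch("s", 0L, 0L, array(100L, dim = c(64, 64, 3)))
  expect_error(train_autoencoder(list(p1, small)), "identical dimensions")
  expect_error(train_autoencoder(list(small), latent_dim = 64), "128x128")
  expect_error(train_autoencoder(list(p1), latent_dim = 50), "multiple of 64")

  ae <- train_autoencoder(list(p1), latent_dim = 64, epochs = 1,
                          batch_size = 1, seed = 1)
  expect_error(encode_patches(ae, small), "does not match")
  expect_error(decode_latent(ae, numeric(32)), "latent length")
})

test_that("a single repeated patch is memorized to near-zero loss", {
  p <- textured_patch(5, 2)
  ae <- train_autoencoder(list(p), latent_dim = 256, epochs = 250,
                          batch_size = 1, seed = 3)
  base <- mean((p$pixels / 255 - mean(p$pixels / 255))^2)
  expect_lt(ae$loss[250], 10 * base)
  rec <- decode_latent(ae, encode_patches(ae, p)[1, ])
  expect_lt(mean(abs(as.numeric(rec) - as.numeric(p$pixels))), 10)
})

test_that("encoding is deterministic, context-free, and decoding in range", {
  patches <- lapply(1:6, function(i) textured_patch(i, (i %% 4) + 1))
  ae <- train_autoencoder(patches, latent_dim = 64, epochs = 1,
                          batch_size = 4, seed = 2)
  l1 <- encode_patches(ae, patches[[1]])
  expect_equal(dim(l1), c(1L, 64L))
  expect_true(all(is.finite(l1)))
  # same patch encoded twice, and alongside others, gives identical rows
  expect_identical(l1, encode_patches(ae, patches[[1]]))
  expect_equal(unname(encode_patches(ae, patches)[1, ]), unname(l1[1, ]))
  # provenance travels with the matrix
  expect_equal(attr(encode_patches(ae, patches), "provenance")$slide_id,
               rep("s1", 6))

  d <- decode_latent(ae, l1[1, ])
  expect_equal(dim(d), c(128L, 128L, 3L))
  expect_true(all(d >= 0 & d <= 255))
  d0 <- decode_latent(ae, numeric(64))  # all-zero latent is valid input
  expect_true(all(d0 >= 0 & d0 <= 255))
})

test_that("checkpoints reload to bit-identical encodings", {
  patches <- lapply(1:4, function(i) textured_patch(i, i))
  ae <- train_autoencoder(patches, latent_dim = 64, epochs = 1,
                          batch_size = 2, seed = 8)
  f <- tempfile(fileext = ".rds")
  save_autoencoder(ae, f)
  expect_true(file.exists(paste0(f, ".json")))
  ae2 <- load_autoencoder(f)
  expect_identical(encode_patches(ae2, patches),
                   encode_patches(ae, patches))
})

test_that("latents separate texture classes better than within-class noise", {
  set.seed(6)
  pa <- lapply(1:25, function(i) textured_patch(100 + i, 1))
  pb <- lapply(1:25, function(i) textured_patch(200 + i, 3))
  ae <- train_autoencoder(c(pa, pb), latent_dim = 64, epochs = 4,
                          batch_size = 8, seed = 6)
  la <- encode_patches(ae, pa)
  lb <- encode_patches(ae, pb)
  pair_d <- function(a, b) {
    mean(vapply(1:50, function(i) {
      sqrt(sum((a[sample(nrow(a), 1), ] - b[sample(nrow(b), 1), ])^2))
    }, numeric(1)))
  }
  within <- (pair_d(la, la) + pair_d(lb, lb)) / 2
  between <- pair_d(la, lb)
  expect_gt(between, within)
})

test_that("the default architecture encodes into 2048 numbers", {
  p <- textured_patch(9, 2)
  ae <- train_autoencoder(list(p, textured_patch(10, 3)), latent_dim = 2048,
                          epochs = 1, batch_size = 2, seed = 1)
  expect_equal(ncol(encode_patches(ae, p)), 2048L)
})
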