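#' Convolutional patch autoencoder
#'
#' Unsupervised encoder-decoder trained to reconstruct 128x128 RGB patches.
#' The encoder is four stride-2 convolution blocks (kernel 4, padding 1)
#' taking the spatial grid 128 -> 64 -> 32 -> 16 -> 8, with a linear
#' bottleneck of `latent_dim` units (the flattened 8 x 8 x C final feature
#' map, so `latent_dim` must be a multiple of 64; the default 2048 uses
#' C = 32 channels). The decoder mirrors it with transposed convolutions
#' and a sigmoid output; the loss is mean squared error on pixels scaled
#' to [0, 1], optimized with Adam. Training is fully seeded (parameter
#' initialization and batch shuffling) and single-threaded, so a given
#' config + seed + input order reproduces the same fit on the same machine.
#'
#' @param patches list of `olp_patch` objects, all 128x128 RGB (the
#'   QC-passed set).
#' @param latent_dim bottleneck width; multiple of 64, default 2048.
#' @param epochs training epochs, default 50.
#' @param batch_size minibatch size, default 64.
#' @param learning_rate Adam step size, default 1e-3.
#' @param seed integer seed controlling initialization and shuffling.
#' @param verbose print per-epoch reconstruction loss.
#' @return object of class `patch_autoencoder` with elements `layers`
#'   (parameters), `config` and `loss` (per-epoch mean reconstruction MSE).
#' @seealso [encode_patches()], [decode_latent()]
#' @export
train_autoencoder <- function(patches, latent_dim = 2048L, epochs = 50L,
                              batch_size = 64L, learning_rate = 1e-3,
                              seed = 1L, verbose = FALSE) {
  if (length(patches) < 1L) stop("need at least one patch", call. = FALSE)
  latent_dim <- as.integer(latent_dim)
  if (latent_dim < 64L || latent_dim %% 64L != 0L)
    stop("latent_dim must be a positive multiple of 64", call. = FALSE)
  x <- patches_to_array(patches)              # errors on non-uniform shapes
  d <- dim(x)
  if (d[1] != 128L || d[2] != 128L || d[3] != 3L)
    stop("patches must be 128x128 RGB", call. = FALSE)
  n <- d[4]

  model <- with_seed(seed, {
    layers <- ae_init_layers(latent_dim)
    opt <- adam_init(layers)
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      tot <- 0
      for (start in seq.int(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        fw <- ae_forward(layers, xb)
        err <- fw$out - xb
        tot <- tot + mean(err^2) * length(idx)
        grads <- ae_backward(layers, fw, 2 * err / length(err))
        upd <- adam_update(layers, grads, opt, learning_rate)
        layers <- upd$layers
        opt <- upd$opt
      }
      losses[ep] <- tot / n
      if (!is.finite(losses[ep]))
        stop("training diverged at epoch ", ep, call. = FALSE)
      if (verbose)
        message(sprintf("epoch %d/%d  reconstruction MSE %.6f", ep, epochs, losses[ep]))
    }
    list(layers = layers, loss = losses)
  })
  structure(list(layers = model$layers, loss = model$loss,
                 config = list(latent_dim = latent_dim, epochs = epochs,
                               batch_size = batch_size,
                               learning_rate = learning_rate, seed = seed,
                               input_dim = c(128L, 128L, 3L))),
            class = "patch_autoencoder")
}

# Encoder: conv(3->8)+relu, conv(8->16)+relu, conv(16->32)+relu,
# conv(32->C) linear bottleneck. Decoder mirrored with tconv, sigmoid out.
ae_init_layers <- function(latent_dim) {
  clat <- latent_dim %/% 64L
  enc_ch <- c(3L, 8L, 16L, 32L, clat)
  dec_ch <- rev(enc_ch)
  layers <- list()
  k <- 4L
  for (i in 1:4) {
    cin <- enc_ch[i]; cout <- enc_ch[i + 1]
    w <- array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
               dim = c(k, k, cin, cout))
    layers[[i]] <- list(type = "conv", w = w, b = numeric(cout),
                        act = if (i == 4) "linear" else "relu")
  }
  for (i in 1:4) {
    cin <- dec_ch[i]; cout <- dec_ch[i + 1]
    w <- array(rnorm(k * k * cout * cin, sd = sqrt(2 / (k * k * cin))),
               dim = c(k, k, cout, cin))
    layers[[4 + i]] <- list(type = "tconv", w = w, b = numeric(cout),
                            act = if (i == 4) "sigmoid" else "relu")
  }
  layers
}

ae_activate <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         linear = z,
         sigmoid = 1 / (1 + exp(-z)))
}

ae_activate_grad <- function(z, a, act) {
  switch(act,
         relu = (z > 0) * 1,
         linear = array(1, dim = dim(z)),
         sigmoid = a * (1 - a))
}

ae_forward <- function(layers, x, upto = length(layers)) {
  cache <- vector("list", upto)
  a <- x
  for (i in seq_len(upto)) {
    ly <- layers[[i]]
    z <- if (ly$type == "conv")
      cpp_conv_forward(a, ly$w, ly$b, 2L, 1L)
    else
      cpp_tconv_forward(a, ly$w, ly$b, 2L, 1L)
    out <- ae_activate(z, ly$act)
    cache[[i]] <- list(input = a, z = z, a = out)
    a <- out
  }
  list(out = a, cache = cache)
}

ae_backward <- function(layers, fw, dout) {
  grads <- vector("list", length(layers))
  da <- dout
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- fw$cache[[i]]
    dz <- da * ae_activate_grad(cc$z, cc$a, ly$act)
    res <- if (ly$type == "conv")
      cpp_conv_backward(cc$input, ly$w, dz, 2L, 1L)
    else
      cpp_tconv_backward(cc$input, ly$w, dz, 2L, 1L)
    grads[[i]] <- list(dw = res$dw, db = res$db)
    da <- res$dx
  }
  grads
}

adam_init <- function(layers) {
  state <- lapply(layers, function(ly)
    list(mw = array(0, dim = dim(ly$w)), vw = array(0, dim = dim(ly$w)),
         mb = numeric(length(ly$b)), vb = numeric(length(ly$b))))
  list(state = state, t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_update <- function(layers, grads, opt, lr) {
  b1 <- opt$beta1; b2 <- opt$beta2
  opt$t <- opt$t + 1L
  corr <- sqrt(1 - b2^opt$t) / (1 - b1^opt$t)  # bias correction
  for (i in seq_along(layers)) {
    st <- opt$state[[i]]
    g <- grads[[i]]
    st$mw <- b1 * st$mw + (1 - b1) * g$dw
    st$vw <- b2 * st$vw + (1 - b2) * g$dw^2
    st$mb <- b1 * st$mb + (1 - b1) * g$db
    st$vb <- b2 * st$vb + (1 - b2) * g$db^2
    layers[[i]]$w <- layers[[i]]$w - lr * corr * st$mw / (sqrt(st$vw) + opt$eps)
    layers[[i]]$b <- layers[[i]]$b - lr * corr * st$mb / (sqrt(st$vb) + opt$eps)
    opt$state[[i]] <- st
  }
  list(layers = layers, opt = opt)
}

#' Encode patches into latent vectors
#'
#' Runs the trained encoder half of a [train_autoencoder()] fit. Encoding
#' is deterministic for a fixed model and independent of which other
#' patches are encoded in the same call.
#'
#' @param model a `patch_autoencoder`.
#' @param patches one `olp_patch` or a list of them; shapes must match the
#'   training shape (128x128 RGB).
#' @return numeric matrix, one row per patch, `latent_dim` columns, with
#'   `slide_id`/`x`/`y` provenance attached as a data.frame attribute
#'   `"provenance"`.
#' @export
encode_patches <- function(model, patches) {
  stopifnot(inherits(model, "patch_autoencoder"))
  if (inherits(patches, "olp_patch")) patches <- list(patches)
  x <- patches_to_array(patches)
  d <- dim(x)
  if (!identical(d[1:3], model$config$input_dim))
    stop("patch shape ", paste(d[1:3], collapse = "x"),
         " does not match the training shape ",
         paste(model$config$input_dim, collapse = "x"), call. = FALSE)
  out <- ae_forward(model$layers, x, upto = 4L)$out
  # out is (8, 8, C, n); flatten each image column-major into one row
  lat <- t(matrix(out, nrow = prod(dim(out)[1:3]), ncol = d[4]))
  if (!all(is.finite(lat))) stop("non-finite latent values", call. = FALSE)
  attr(lat, "provenance") <- data.frame(
    slide_id = vapply(patches, `[[`, character(1), "slide_id"),
    x = vapply(patches, `[[`, integer(1), "x"),
    y = vapply(patches, `[[`, integer(1), "y"),
    stringsAsFactors = FALSE)
  lat
}

#' Decode a latent vector into a patch-shaped raster
#'
#' @param model a `patch_autoencoder`.
#' @param latent numeric vector of length `latent_dim`.
#' @return integer raster `c(128, 128, 3)` with values in 0-255.
#' @export
decode_latent <- function(model, latent) {
  stopifnot(inherits(model, "patch_autoencoder"))
  if (length(latent) != model$config$latent_dim)
    stop("latent length ", length(latent), " does not match latent_dim ",
         model$config$latent_dim, call. = FALSE)
  clat <- model$config$latent_dim %/% 64L
  a <- array(as.numeric(latent), dim = c(8L, 8L, clat, 1L))
  for (i in 5:8) {
    ly <- model$layers[[i]]
    z <- cpp_tconv_forward(a, ly$w, ly$b, 2L, 1L)
    a <- ae_activate(z, ly$act)
  }
  clamp_raster(array(a, dim = dim(a)[1:3]))
}

#' @export
#' @describeIn train_autoencoder `predict` returns the latent matrix for
#'   new patches (equivalent to [encode_patches()]).
predict.patch_autoencoder <- function(object, newdata, ...) {
  encode_patches(object, newdata)
}

#' @export
print.patch_autoencoder <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Convolutional patch autoencoder\n",
                     "  latent_dim %d, %d epoch(s), batch %d, lr %g, seed %d\n",
                     "  reconstruction MSE: first %.5f, final %.5f\n"),
              cfg$latent_dim, cfg$epochs, cfg$batch_size, cfg$learning_rate,
              cfg$seed, x$loss[1], x$loss[length(x$loss)]))
  invisible(x)
}

#' Save / load an autoencoder checkpoint
#'
#' The checkpoint is an RDS file holding the full parameter set, with a
#' JSON sidecar (`<path>.json`) carrying the config and the per-epoch loss
#' log. Reloading reproduces encodings bit-identically.
#'
#' @param model a `patch_autoencoder`.
#' @param path checkpoint file path.
#' @return `save_autoencoder` returns `path` invisibly; `load_autoencoder`
#'   returns the restored `patch_autoencoder`.
#' @export
save_autoencoder <- function(model, path) {
  stopifnot(inherits(model, "patch_autoencoder"))
  saveRDS(model, path)
  jsonlite::write_json(list(config = model$config, loss = model$loss),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_autoencoder
#' @export
load_autoencoder <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "patch_autoencoder"))
  model
}
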