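# Independent, deliberately naive reference implementations used to check
# the package's vectorized paths on small inputs.

# Hand-count scoring: loops over patches, counts per cluster, applies the
# rate/impact/weight definitions one value at a time.
oracle_scores <- function(cluster, label, k) {
  n_plus <- sum(label == "effective")
  n_minus <- sum(label == "ineffective")
  out <- data.frame(cluster = seq_len(k), r_plus = 0, r_minus = 0,
                    I = 0.5, W = 1)
  for (kk in seq_len(k)) {
    pos <- 0; neg <- 0
    for (i in seq_along(cluster)) {
      if (cluster[i] == kk) {
        if (label[i] == "effective") pos <- pos + 1 else neg <- neg + 1
      }
    }
    rp <- pos / n_plus
    rm_ <- neg / n_minus
    out$r_plus[kk] <- rp
    out$r_minus[kk] <- rm_
    if (rp + rm_ > 0) out$I[kk] <- rp / (rp + rm_)
    out$W[kk] <- 1 + abs(0.5 - out$I[kk])
  }
  out
}

# Exhaustive nearest-centroid scan.
oracle_assign <- function(latents, centroids) {
  n <- nrow(latents)
  cl <- integer(n); dist <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf; bestk <- NA_integer_
    for (j in seq_len(nrow(centroids))) {
      d <- sqrt(sum((latents[i, ] - centroids[j, ])^2))
      if (d < best) { best <- d; bestk <- j }
    }
    cl[i] <- bestk; dist[i] <- best
  }
  list(cluster = cl, distance = dist)
}

# A QC-passing textured test patch.
textured_patch <- function(seed = 1, class_idx = 1, slide_id = "s1",
                           x = 0L, y = 0L) {
  make_patch(default_texture_classes()[[class_idx]], seed = seed,
             slide_id = slide_id, x = x, y = y)
}

# A uniform-color patch (degenerate QC cases).
uniform_patch <- function(value, h = 128L, w = 128L, slide_id = "s1") {
  new_patch(slide_id, 0L, 0L, array(as.integer(value), dim = c(h, w, 3L)))
}

# A feature model built on trivially separable 2-D latents, used where a
# fitted model object is required.
tiny_feature_model <- function(W = NULL, k = 4) {
  set.seed(31)
  lat <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 30), 10, 2),
               matrix(rnorm(20, 60), 10, 2), matrix(rnorm(20, 90), 10, 2))
  sid <- rep(c("e1", "i1"), 20)
  man <- data.frame(slide_id = c("e1", "i1"),
                    label = c("effective", "ineffective"))
  fm <- feature_model(lat, man, k = k, slide_ids = sid, seed = 1)
  if (!is.null(W)) fm$scores$W <- W
  fm
}

sep_gaussians <- function(n = 60, seed = 41) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * 4, mean = 0, sd = 0.5), n / 2, 4),
             matrix(rnorm(n / 2 * 4, mean = 4, sd = 0.5), n / 2, 4))
  y <- rep(c("ineffective", "effective"), each = n / 2)
  list(x = x, y = y)
}
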