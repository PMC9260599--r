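#' Fit the image-based feature model
#'
#' The central estimator of the package: clusters patch latent vectors
#' into k features with K-means ([fit_kmeans()]), labels every patch with
#' its slide's treatment-response label ([label_assignments()]), scores
#' each cluster's association with response ([compute_feature_scores()])
#' and selects the key features ([select_key_features()]). The fitted
#' object carries the centroids and the per-cluster impact scores I,
#' weights W, polarity, morphology class and key flag.
#'
#' @param latents numeric matrix of patch latent vectors with a
#'   `"provenance"` attribute (from [encode_patches()]), or a bare matrix
#'   plus `slide_ids`.
#' @param manifest slide manifest with `slide_id` and `label` columns.
#' @param k number of clusters; defaults to the number of distinct slides
#'   among the supplied patches (the original design used one cluster per
#'   training slide).
#' @param slide_ids character vector, one per latent row; overrides the
#'   provenance attribute.
#' @param key_threshold weight threshold for key features (default 1.1).
#' @param morphology optional annotation data.frame (`cluster`,
#'   `morphology`); when `NULL` and `patches` is supplied, the blank-area
#'   heuristic [classify_shape_heuristic()] stands in; otherwise clusters
#'   are `"unknown"`.
#' @param patches optional list of the `olp_patch` objects behind
#'   `latents` (same order), used only by the morphology heuristic.
#' @param seed integer seed for the clustering initialization.
#' @param ... passed to [fit_kmeans()].
#' @return object of class `feature_model`: list with `centroids` (a
#'   `centroid_set`), `scores` (a `feature_scores` data.frame with
#'   morphology and key flags), `k`, `key_threshold`, `seed` and the
#'   labeled training `assignments`.
#' @examples
#' \donttest{
#' cohort <- make_cohort(n_slides = 8, grid = c(3, 3), seed = 1)
#' pp <- prepare_cohort_patches(cohort)
#' ae <- train_autoencoder(pp$patches, latent_dim = 64, epochs = 2,
#'                         seed = 1)
#' fm <- feature_model(encode_patches(ae, pp$patches), cohort$manifest,
#'                     k = 4, seed = 1)
#' summary(fm)
#' }
#' @export
feature_model <- function(latents, manifest, k = NULL, slide_ids = NULL,
                          key_threshold = 1.1, morphology = NULL,
                          patches = NULL, seed = 1L, ...) {
  prov <- attr(latents, "provenance")
  if (!is.null(slide_ids)) {
    prov <- data.frame(slide_id = slide_ids, stringsAsFactors = FALSE)
    if (!is.null(attr(latents, "provenance")))
      prov <- cbind(prov, attr(latents, "provenance")[c("x", "y")])
  }
  if (is.null(prov))
    stop("latents carry no provenance; supply slide_ids", call. = FALSE)
  k <- as.integer(k %||% length(unique(prov$slide_id)))
  cents <- fit_kmeans(latents, k = k, seed = seed, ...)
  assignments <- assign_latents(latents, cents, provenance = prov)
  assignments <- label_assignments(assignments, manifest)
  scores <- compute_feature_scores(assignments, k)
  if (is.null(morphology) && !is.null(patches)) {
    morphology <- data.frame(
      cluster = seq_len(k),
      morphology = vapply(seq_len(k), function(j)
        classify_shape_heuristic(patches[assignments$cluster == j]),
        character(1)),
      stringsAsFactors = FALSE)
  }
  scores <- select_key_features(scores, key_threshold, morphology)
  structure(list(centroids = cents, scores = scores, k = k,
                 key_threshold = key_threshold, seed = seed,
                 assignments = assignments),
            class = "feature_model")
}

#' @export
print.feature_model <- function(x, ...) {
  s <- x$scores
  cat(sprintf(paste0("Image-based feature model\n",
                     "  %d clusters over %d labeled patches ",
                     "(n+ = %d, n- = %d)\n",
                     "  %d positive, %d negative, %d neutral; ",
                     "%d key feature(s) at W > %g\n"),
              x$k, sum(s$size), sum(s$n_pos), sum(s$n_neg),
              sum(s$polarity == "positive"), sum(s$polarity == "negative"),
              sum(s$polarity == "neutral"), sum(s$is_key), x$key_threshold))
  if (any(s$is_key))
    cat("  key clusters:", paste(s$cluster[s$is_key], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.feature_model <- function(object, ...) {
  s <- object$scores
  s[order(-s$I), ]
}

#' @export
coef.feature_model <- function(object, ...) {
  stats::setNames(object$scores$W, object$scores$cluster)
}

#' Bar chart of feature weights
#'
#' Plots W per cluster with the key-feature threshold line; key features
#' are filled, shape clusters hatched gray.
#'
#' @param x a `feature_model`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.feature_model <- function(x, ...) {
  s <- x$scores
  cols <- ifelse(s$is_key, "firebrick",
                 ifelse(s$morphology == "shape", "gray70", "steelblue"))
  graphics::barplot(s$W, names.arg = s$cluster, col = cols,
                    ylim = c(0, 1.55), xpd = FALSE,
                    xlab = "cluster (feature)", ylab = "weight W", ...)
  graphics::abline(h = x$key_threshold, lty = 2)
  invisible(x)
}

#' Weighted per-slide feature vectors
#'
#' For each slide, value_k = (fraction of the slide's QC-passed patches
#' assigned to cluster k) x W_k. Dividing the vector elementwise by W
#' therefore recovers the occupancy fractions, which sum to 1.
#'
#' @param assignments `patch_assignment` data.frame with `slide_id` and
#'   `cluster` columns (new slides: from [assign_latents()] on encodings
#'   of their QC-passed patches).
#' @param model a `feature_model` (its `scores$W` supplies the weights).
#' @param slide_ids slides to build vectors for; defaults to all slides
#'   present in `assignments`. A requested slide with no surviving
#'   patches is an error, never a silent zero vector.
#' @return numeric matrix, rows = slides (rownames = slide_id),
#'   columns = k clusters; attribute `"n_patches"` counts the patches
#'   behind each row.
#' @export
build_slide_vectors <- function(assignments, model, slide_ids = NULL) {
  stopifnot(inherits(model, "feature_model"),
            all(c("slide_id", "cluster") %in% names(assignments)))
  slide_ids <- slide_ids %||% unique(assignments$slide_id)
  missing <- setdiff(slide_ids, assignments$slide_id)
  if (length(missing))
    stop("slide(s) with zero QC-passed patches: ",
         paste(missing, collapse = ", "), call. = FALSE)
  W <- model$scores$W
  k <- model$k
  out <- matrix(0, length(slide_ids), k,
                dimnames = list(slide_ids, paste0("f", seq_len(k))))
  n_patches <- integer(length(slide_ids))
  for (i in seq_along(slide_ids)) {
    cl <- assignments$cluster[assignments$slide_id == slide_ids[i]]
    n_patches[i] <- length(cl)
    frac <- tabulate(cl, nbins = k) / length(cl)
    out[i, ] <- frac * W
  }
  attr(out, "n_patches") <- stats::setNames(n_patches, slide_ids)
  out
}

#' @describeIn feature_model `predict` maps new latent vectors to weighted
#'   slide feature vectors (assignment to nearest centroid, occupancy
#'   fractions, W weighting).
#' @param object a `feature_model`.
#' @param newdata latent matrix with provenance (or supply `slide_ids`).
#' @export
predict.feature_model <- function(object, newdata, slide_ids = NULL, ...) {
  prov <- if (!is.null(slide_ids))
    data.frame(slide_id = slide_ids, stringsAsFactors = FALSE)
  else attr(newdata, "provenance")
  if (is.null(prov))
    stop("newdata carries no provenance; supply slide_ids", call. = FALSE)
  a <- assign_latents(newdata, object$centroids, provenance = prov)
  build_slide_vectors(a, object)
}
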