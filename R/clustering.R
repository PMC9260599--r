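#' Cluster latent vectors into image-based features
#'
#' K-means on the patch latent vectors; each resulting cluster is one
#' "feature". Initialization is k-means++ under a fixed seed with
#' `nstart` independent restarts, keeping the solution with the lowest
#' within-cluster sum of squares; Lloyd iterations are delegated to
#' [stats::kmeans()]. Following the original design, `k` defaults to the
#' number of distinct training slides.
#'
#' @param latents numeric matrix, one row per patch (see
#'   [encode_patches()]).
#' @param k number of clusters (>= 2); at most `nrow(latents)`.
#' @param seed integer seed for initialization.
#' @param nstart k-means++ restarts (default 10).
#' @param iter.max Lloyd iteration cap per restart (default 100).
#' @return object of class `centroid_set`: list with `k`, `centroids`
#'   (k x latent_dim matrix), `inertia`, `seed` and the training
#'   `assignment` vector.
#' @export
fit_kmeans <- function(latents, k, seed = 1L, nstart = 10L, iter.max = 100L) {
  latents <- as.matrix(latents)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (nrow(latents) < k)
    stop("need at least k = ", k, " latent vectors, got ", nrow(latents),
         call. = FALSE)
  best <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      centers <- kmeanspp_init(latents, k)
      fit <- suppressWarnings(
        kmeans(latents, centers = centers, iter.max = iter.max,
               algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    best
  })
  structure(list(k = k, centroids = unname(best$centers),
                 inertia = best$tot.withinss, iterations = best$iter,
                 seed = seed, assignment = unname(best$cluster)),
            class = "centroid_set")
}

# k-means++ seeding: first center uniform, then each next center drawn
# with probability proportional to squared distance to the nearest
# already-chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = p)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("Centroid set: k = %d, dim = %d, inertia = %.4g (seed %d)\n",
              x$k, ncol(x$centroids), x$inertia, x$seed))
  invisible(x)
}

#' Assign latent vectors to their nearest centroid
#'
#' For each patch latent the Euclidean distance to every centroid is
#' computed and the patch is assigned to the cluster with the smallest
#' distance (the indicator u is 1 at the argmin and 0 elsewhere); exact
#' ties break to the lowest cluster index.
#'
#' @param latents numeric matrix (rows = patches) or a single vector.
#' @param centroids a `centroid_set` or a bare k x latent_dim matrix.
#' @param provenance optional data.frame (`slide_id`, `x`, `y`) with one
#'   row per latent; defaults to the `"provenance"` attribute attached by
#'   [encode_patches()], if present.
#' @return data.frame of class `patch_assignment` with columns `slide_id`,
#'   `x`, `y` (when provenance is known), `cluster` (1-based argmin index)
#'   and `distance` (Euclidean distance to the assigned centroid); the
#'   full k-column distance matrix is attached as attribute `"distances"`.
#' @export
assign_latents <- function(latents, centroids, provenance = NULL) {
  cents <- if (inherits(centroids, "centroid_set")) centroids$centroids
           else as.matrix(centroids)
  if (is.null(dim(latents))) latents <- matrix(latents, nrow = 1L)
  provenance <- provenance %||% attr(latents, "provenance")
  latents <- as.matrix(latents)
  if (ncol(latents) != ncol(cents))
    stop("latent dimension ", ncol(latents),
         " does not match centroid dimension ", ncol(cents), call. = FALSE)
  k <- nrow(cents)
  d <- matrix(0, nrow(latents), k)
  for (j in seq_len(k))
    d[, j] <- sqrt(rowSums(sweep(latents, 2L, cents[j, ])^2))
  cl <- apply(d, 1L, which.min)          # first minimum: lowest index wins ties
  out <- data.frame(cluster = as.integer(cl),
                    distance = d[cbind(seq_len(nrow(d)), cl)])
  if (!is.null(provenance)) out <- cbind(provenance, out)
  attr(out, "distances") <- d
  class(out) <- c("patch_assignment", "data.frame")
  out
}
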