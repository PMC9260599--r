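#' Texture class specification
#'
#' Defines one procedural texture class for the synthetic pseudo-slide
#' generator. Classes are 2-D procedural textures (not histology
#' simulants): they only need to be mutually separable in latent space so
#' that cluster recovery and impact-score estimation can be tested
#' against known ground truth. Each class carries a designed enrichment
#' `rho`: the intended impact score r+/(r+ + r-) of the cluster of its
#' patches under a balanced cohort.
#'
#' @param class_id integer id (1-based).
#' @param kind one of `"blobs"` (Gaussian-falloff blobs), `"stripes"`
#'   (oriented sinusoidal stripes), `"speckle"` (dark speckles),
#'   `"checker"` (block checkerboard) or `"near_blank"` (background-like
#'   tile that the QC blank criterion must reject).
#' @param base_color,element_color RGB triples, 0-255.
#' @param density element count (blobs), fill probability (speckle), or
#'   unused.
#' @param element_size blob sigma / stripe period / speckle block edge /
#'   checker block edge, pixels.
#' @param noise_sd per-channel Gaussian noise sd (default 8).
#' @param rho designed enrichment in \[0, 1\] (default 0.5).
#' @return list of class `texture_class`.
#' @export
texture_class <- function(class_id, kind = c("blobs", "stripes", "speckle",
                                             "checker", "near_blank"),
                          base_color, element_color, density = 20,
                          element_size = 8, noise_sd = 8, rho = 0.5) {
  kind <- match.arg(kind)
  stopifnot(rho >= 0, rho <= 1, length(base_color) == 3L,
            length(element_color) == 3L)
  structure(list(class_id = as.integer(class_id), kind = kind,
                 base_color = base_color, element_color = element_color,
                 density = density, element_size = element_size,
                 noise_sd = noise_sd, rho = rho),
            class = "texture_class")
}

#' Default texture classes
#'
#' Four visually distinct, QC-passing texture classes with designed
#' enrichments 0.8, 0.6, 0.4 and 0.2 — spanning clearly positive,
#' weakly positive, weakly negative and clearly negative clusters.
#'
#' @param rho length-4 numeric of designed enrichments.
#' @return list of four `texture_class` specs.
#' @export
default_texture_classes <- function(rho = c(0.8, 0.6, 0.4, 0.2)) {
  stopifnot(length(rho) == 4L)
  list(
    texture_class(1L, "blobs", base_color = c(225, 170, 185),
                  element_color = c(95, 60, 130), density = 70,
                  element_size = 4, rho = rho[1]),
    texture_class(2L, "stripes", base_color = c(205, 175, 140),
                  element_color = c(110, 70, 50), element_size = 18,
                  rho = rho[2]),
    texture_class(3L, "speckle", base_color = c(160, 180, 215),
                  element_color = c(40, 55, 110), density = 0.04,
                  element_size = 3, rho = rho[3]),
    texture_class(4L, "checker", base_color = c(165, 200, 160),
                  element_color = c(80, 120, 75), element_size = 16,
                  rho = rho[4]))
}

#' Near-blank texture class
#'
#' A background-like tile (>= 75% near-white pixels) that the QC blank
#' criterion is expected to reject; used to exercise the filter.
#' @param class_id integer id.
#' @return a `texture_class`.
#' @export
near_blank_class <- function(class_id = 99L) {
  texture_class(class_id, "near_blank", base_color = c(252, 252, 252),
                element_color = c(215, 215, 220), density = 4,
                element_size = 6, noise_sd = 1.5, rho = 0.5)
}

#' Generate one synthetic patch
#'
#' Deterministic per (spec, seed): the same call yields bit-identical
#' pixels.
#'
#' @param spec a [texture_class()].
#' @param seed integer seed.
#' @param slide_id,x,y provenance stamped on the patch.
#' @param size patch edge in pixels (default 128).
#' @return an `olp_patch`.
#' @export
make_patch <- function(spec, seed, slide_id = "synthetic", x = 0L, y = 0L,
                       size = 128L) {
  stopifnot(inherits(spec, "texture_class"))
  px <- with_seed(seed, render_texture(spec, size))
  new_patch(slide_id, x, y, px)
}

render_texture <- function(spec, size) {
  g <- seq_len(size)
  xg <- matrix(g, size, size, byrow = TRUE)   # column index
  yg <- matrix(g, size, size)                 # row index
  wt <- switch(spec$kind,
    blobs = {
      w <- matrix(0, size, size)
      n <- round(spec$density)
      cx <- runif(n, 1, size); cy <- runif(n, 1, size)
      s2 <- 2 * spec$element_size^2
      for (i in seq_len(n))
        w <- w + exp(-((xg - cx[i])^2 + (yg - cy[i])^2) / s2)
      pmin(w, 1)
    },
    stripes = {
      theta <- pi / 4
      phase <- (cos(theta) * xg + sin(theta) * yg) / spec$element_size
      (sin(2 * pi * phase) + 1) / 2
    },
    speckle = {
      w <- matrix(0, size, size)
      n <- round(spec$density * size^2)
      cx <- sample.int(size - spec$element_size, n, replace = TRUE)
      cy <- sample.int(size - spec$element_size, n, replace = TRUE)
      b <- spec$element_size - 1L
      for (i in seq_len(n))
        w[cy[i]:(cy[i] + b), cx[i]:(cx[i] + b)] <- 1
      w
    },
    checker = {
      (floor((xg - 1) / spec$element_size) +
         floor((yg - 1) / spec$element_size)) %% 2
    },
    near_blank = {
      # a few faint marks covering well under 25% of the tile
      w <- matrix(0, size, size)
      n <- round(spec$density)
      cx <- runif(n, 1, size); cy <- runif(n, 1, size)
      s2 <- 2 * spec$element_size^2
      for (i in seq_len(n))
        w <- w + exp(-((xg - cx[i])^2 + (yg - cy[i])^2) / s2)
      pmin(w, 1) * (pmin(w, 1) > 0.5)
    })
  px <- array(0, dim = c(size, size, 3L))
  for (c in 1:3)
    px[, , c] <- spec$base_color[c] * (1 - wt) + spec$element_color[c] * wt +
      rnorm(size^2, sd = spec$noise_sd)
  px[px < 0] <- 0; px[px > 255] <- 255
  storage.mode(px) <- "integer"
  px
}

#' Assemble a labeled pseudo-slide
#'
#' Builds a slide raster from a grid of independently sampled texture
#' cells, where the per-class sampling probabilities are conditional on
#' the slide's response label — the single mechanism that creates a
#' cluster-outcome association with known ground truth.
#'
#' @param slide_id slide identifier.
#' @param label `"effective"` or `"ineffective"`.
#' @param classes list of [texture_class()] specs.
#' @param probs per-class sampling probabilities (sums to 1).
#' @param grid `c(rows, cols)` of 128-px cells (each >= 2).
#' @param seed integer seed.
#' @param cell_size cell edge in pixels (default 128).
#' @return list with `raster` (integer array), `truth` (data.frame
#'   `slide_id`, `x`, `y`, `class_id`), `slide_id`, `label`.
#' @export
make_pseudo_slide <- function(slide_id, label, classes, probs,
                              grid = c(6L, 6L), seed = 1L, cell_size = 128L) {
  stopifnot(length(probs) == length(classes), abs(sum(probs) - 1) < 1e-8,
            all(grid >= 2L))
  rows <- grid[1]; cols <- grid[2]
  with_seed(seed, {
    cell_class <- sample(seq_along(classes), rows * cols, replace = TRUE,
                         prob = probs)
    cell_seed <- sample.int(.Machine$integer.max - 1L, rows * cols)
    raster <- array(0L, dim = c(rows * cell_size, cols * cell_size, 3L))
    truth <- data.frame(slide_id = character(0), x = integer(0),
                        y = integer(0), class_id = integer(0))
    i <- 0L
    for (r in seq_len(rows)) {
      for (cc in seq_len(cols)) {
        i <- i + 1L
        spec <- classes[[cell_class[i]]]
        px <- with_seed(cell_seed[i], render_texture(spec, cell_size))
        rr <- ((r - 1L) * cell_size + 1L):(r * cell_size)
        cs <- ((cc - 1L) * cell_size + 1L):(cc * cell_size)
        raster[rr, cs, ] <- px
        truth <- rbind(truth, data.frame(
          slide_id = slide_id, x = (cc - 1L) * cell_size,
          y = (r - 1L) * cell_size, class_id = spec$class_id))
      }
    }
    list(raster = raster, truth = truth, slide_id = slide_id, label = label)
  })
}

#' Generate a synthetic cohort of labeled pseudo-slides
#'
#' Produces a complete runnable input set: a manifest, one raster per
#' slide and the per-cell ground truth. By default the class composition
#' of effective slides is `(0.4, 0.3, 0.2, 0.1)` over the four default
#' classes and of ineffective slides `(0.1, 0.2, 0.3, 0.4)`, so with a
#' balanced cohort the analytic impact score of class c equals its
#' designed enrichment `rho` of 0.8 / 0.6 / 0.4 / 0.2.
#'
#' @param n_slides number of slides (>= 4); one patient per slide.
#' @param classes list of [texture_class()] specs.
#' @param grid cells per slide, `c(rows, cols)` (default 6 x 6).
#' @param balance fraction of effective slides (default 0.5).
#' @param probs_effective,probs_ineffective label-conditional class
#'   compositions (sum to 1 each).
#' @param seed single cohort seed; all randomness derives from it.
#' @param out_dir when given, writes `manifest.csv`, `slides/<id>.png`
#'   and `truth.json` there.
#' @return list of class `synthetic_cohort`: `manifest` (data.frame),
#'   `slides` (named list of rasters), `truth` (data.frame over all
#'   cells), `classes`, `seed`.
#' @export
make_cohort <- function(n_slides = 20L, classes = default_texture_classes(),
                        grid = c(6L, 6L), balance = 0.5,
                        probs_effective = c(0.4, 0.3, 0.2, 0.1),
                        probs_ineffective = c(0.1, 0.2, 0.3, 0.4),
                        seed = 1L, out_dir = NULL) {
  n_slides <- as.integer(n_slides)
  if (n_slides < 4L) stop("n_slides must be >= 4", call. = FALSE)
  stopifnot(length(probs_effective) == length(classes),
            length(probs_ineffective) == length(classes))
  n_eff <- round(n_slides * balance)
  labels <- c(rep("effective", n_eff), rep("ineffective", n_slides - n_eff))
  slide_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_slides))
  slides <- list()
  truth <- NULL
  manifest <- data.frame(slide_id = sprintf("slide%02d", seq_len(n_slides)),
                         patient_id = sprintf("pt%02d", seq_len(n_slides)),
                         path = NA_character_, role = "train-feature-set",
                         label = labels, stringsAsFactors = FALSE)
  for (i in seq_len(n_slides)) {
    probs <- if (labels[i] == "effective") probs_effective else probs_ineffective
    ps <- make_pseudo_slide(manifest$slide_id[i], labels[i], classes, probs,
                            grid = grid, seed = slide_seeds[i])
    slides[[manifest$slide_id[i]]] <- ps$raster
    truth <- rbind(truth, ps$truth)
  }
  cohort <- structure(list(manifest = manifest, slides = slides,
                           truth = truth, classes = classes, seed = seed),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d slides (%d effective), %d classes, seed %d\n",
              nrow(x$manifest), sum(x$manifest$label == "effective"),
              length(x$classes), x$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (created if needed).
#' @return the updated cohort (manifest paths filled in), invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "slides"), recursive = TRUE,
             showWarnings = FALSE)
  for (i in seq_len(nrow(cohort$manifest))) {
    sid <- cohort$manifest$slide_id[i]
    p <- file.path(out_dir, "slides", paste0(sid, ".png"))
    png::writePNG(cohort$slides[[sid]] / 255, p)
    cohort$manifest$path[i] <- p
  }
  write.csv(cohort$manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows")
  invisible(cohort)
}

#' Tile and QC-filter a synthetic cohort
#'
#' Convenience wrapper running [tile_slide()] and [qc_filter()] over every
#' slide of a cohort, inheriting each slide's label onto its patches.
#'
#' @param cohort a `synthetic_cohort` (rasters in memory).
#' @param params [qc_params()].
#' @param patch_size tile edge (default 128).
#' @return list with `patches` (QC-passed, all slides, slide order),
#'   `report` (pooled `qc_report`) and `truth_class`, the ground-truth
#'   class id aligned with `patches`.
#' @export
prepare_cohort_patches <- function(cohort, params = qc_params(),
                                   patch_size = 128L) {
  patches <- list()
  for (i in seq_len(nrow(cohort$manifest))) {
    sid <- cohort$manifest$slide_id[i]
    patches <- c(patches,
                 tile_slide(cohort$slides[[sid]], sid, patch_size,
                            label = cohort$manifest$label[i]))
  }
  res <- qc_filter(patches, params)
  key <- paste(cohort$truth$slide_id, cohort$truth$x, cohort$truth$y)
  pkey <- vapply(res$passed, function(p) paste(p$slide_id, p$x, p$y),
                 character(1))
  list(patches = res$passed, report = res$report,
       truth_class = cohort$truth$class_id[match(pkey, key)])
}

#' Match fitted clusters to ground-truth texture classes
#'
#' For each fitted cluster, reports the modal ground-truth class among its
#' member patches, together with the purity (fraction of members in that
#' class). Used to compare estimated impact scores against the designed
#' enrichments of a synthetic cohort.
#'
#' @param clusters integer vector of fitted cluster assignments.
#' @param truth_class integer vector of ground-truth class ids, aligned
#'   with `clusters`.
#' @return data.frame with `cluster`, `class_id` (modal class) and
#'   `purity`.
#' @export
match_clusters <- function(clusters, truth_class) {
  stopifnot(length(clusters) == length(truth_class))
  out <- NULL
  for (cl in sort(unique(clusters))) {
    tc <- truth_class[clusters == cl]
    tab <- sort(table(tc), decreasing = TRUE)
    out <- rbind(out, data.frame(cluster = cl,
                                 class_id = as.integer(names(tab)[1]),
                                 purity = as.numeric(tab[1]) / length(tc)))
  }
  out
}
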