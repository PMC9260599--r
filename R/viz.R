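#' Overlay style
#'
#' Colors and border width for the polarity overlay: patches of positive
#' clusters get a red border, negative clusters blue, neutral gray.
#'
#' @param positive,negative,neutral RGB triples, 0-255.
#' @param width border width in pixels (default 3).
#' @return list of class `overlay_style`.
#' @export
overlay_style <- function(positive = c(255, 0, 0), negative = c(0, 0, 255),
                          neutral = c(128, 128, 128), width = 3L) {
  stopifnot(!identical(positive, negative))
  structure(list(positive = positive, negative = negative,
                 neutral = neutral, width = as.integer(width)),
            class = "overlay_style")
}

#' Render the polarity overlay on a slide raster
#'
#' Draws a border around every assigned patch in the color of its
#' cluster's polarity; pixels outside the borders are untouched and the
#' image dimensions are unchanged. The per-patch details (cluster id,
#' weight W) that a viewer would show on hover are returned as a sidecar
#' list keyed by `"x_y"`.
#'
#' @param raster slide raster, integer array `c(h, w, 3)`.
#' @param assignments `patch_assignment` rows for this slide (`x`, `y`,
#'   `cluster`); origins must lie inside the raster.
#' @param model a `feature_model` supplying per-cluster polarity and W.
#' @param style an [overlay_style()].
#' @param patch_size patch edge in pixels (default 128).
#' @return list with `raster` (annotated copy) and `sidecar` (named list:
#'   per patch `cluster`, `W`, `polarity`).
#' @export
render_overlay <- function(raster, assignments, model,
                           style = overlay_style(), patch_size = 128L) {
  validate_pixels(raster)
  stopifnot(inherits(model, "feature_model"))
  h <- nrow(raster); w <- ncol(raster)
  out <- raster
  sidecar <- list()
  for (i in seq_len(nrow(assignments))) {
    x0 <- assignments$x[i]; y0 <- assignments$y[i]
    if (x0 < 0 || y0 < 0 || x0 + patch_size > w || y0 + patch_size > h)
      stop("assignment at (", x0, ",", y0, ") lies outside the raster",
           call. = FALSE)
    cl <- assignments$cluster[i]
    pol <- model$scores$polarity[model$scores$cluster == cl]
    col <- as.integer(style[[pol]])
    rows <- (y0 + 1L):(y0 + patch_size)
    cols <- (x0 + 1L):(x0 + patch_size)
    b <- style$width
    for (c in 1:3) {
      out[rows[seq_len(b)], cols, c] <- col[c]
      out[rows[patch_size - seq_len(b) + 1L], cols, c] <- col[c]
      out[rows, cols[seq_len(b)], c] <- col[c]
      out[rows, cols[patch_size - seq_len(b) + 1L], c] <- col[c]
    }
    sidecar[[paste0(x0, "_", y0)]] <-
      list(cluster = cl, W = model$scores$W[model$scores$cluster == cl],
           polarity = pol)
  }
  list(raster = out, sidecar = sidecar)
}

#' Write a run-level report
#'
#' Emits a self-contained Markdown report with the feature score table,
#' a weight bar chart, ROC curve(s) for the supplied cross-validation
#' results and optional holdout metrics, plus a config echo. All numbers
#' are read from the passed (already-computed) artifacts; nothing is
#' recomputed.
#'
#' @param model a `feature_model`.
#' @param cv_results a `cv_result` or list of them (one per model family).
#' @param holdout optional result of [evaluate_holdout()].
#' @param dir output directory (created if needed).
#' @param figures also write `weights.png` and `roc.png` (default TRUE).
#' @return path of the written `report.md`, invisibly.
#' @export
render_report <- function(model, cv_results = NULL, holdout = NULL,
                          dir = ".", figures = TRUE) {
  stopifnot(inherits(model, "feature_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(cv_results, "cv_result")) cv_results <- list(cv_results)
  lines <- c("# Image-based feature run report", "",
             sprintf("- clusters: %d (key threshold W > %g, seed %d)",
                     model$k, model$key_threshold, model$seed),
             sprintf("- key features: %s",
                     if (any(model$scores$is_key))
                       paste(model$scores$cluster[model$scores$is_key],
                             collapse = ", ") else "none"),
             "", "## Feature scores", "",
             md_table(model$scores[c("cluster", "size", "n_pos", "n_neg",
                                     "r_plus", "r_minus", "I", "W",
                                     "polarity", "morphology", "is_key")]))
  if (figures) {
    grDevices::png(file.path(dir, "weights.png"), width = 720, height = 420)
    plot(model)
    grDevices::dev.off()
    lines <- c(lines, "", "![feature weights](weights.png)")
  }
  for (cv in cv_results %||% list()) {
    lines <- c(lines, "",
               sprintf("## Cross-validation (%s)", cv$family), "",
               sprintf("- mean accuracy %.4f (max %.4f, min %.4f) over %d folds",
                       cv$mean_accuracy, cv$max_accuracy, cv$min_accuracy,
                       cv$folds),
               sprintf("- pooled AUC %.4f; mean fold AUC 95%% CI [%.3f, %.3f]",
                       cv$auc, cv$auc_ci[1], cv$auc_ci[2]))
  }
  if (figures && length(cv_results %||% list())) {
    grDevices::png(file.path(dir, "roc.png"), width = 480, height = 480)
    graphics::plot(NA, xlim = 0:1, ylim = 0:1,
                   xlab = "false positive rate", ylab = "true positive rate")
    graphics::abline(0, 1, lty = 3)
    for (i in seq_along(cv_results))
      graphics::lines(cv_results[[i]]$roc$fpr, cv_results[[i]]$roc$tpr,
                      col = i + 1)
    graphics::legend("bottomright", bty = "n", col = seq_along(cv_results) + 1,
                     lty = 1, legend = vapply(cv_results, function(cv)
                       sprintf("%s (AUC %.3f)", cv$family, cv$auc),
                       character(1)))
    grDevices::dev.off()
    lines <- c(lines, "", "![ROC](roc.png)")
  }
  if (!is.null(holdout))
    lines <- c(lines, "", "## Holdout evaluation", "",
               sprintf("- accuracy %.4f, AUC %.4f",
                       holdout$accuracy, holdout$auc))
  path <- file.path(dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

md_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(v == round(v), format(v, trim = TRUE),
           formatC(v, digits = 4, format = "f")))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}
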