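#' Patch objects
#'
#' A patch is the atomic unit of the pipeline: one fixed-size RGB tile cut
#' from a slide raster, carrying its slide of origin, its pixel offset in
#' slide coordinates and (once assigned) the binary treatment-response
#' label inherited from its parent slide.
#'
#' Pixels are stored as an integer array `dim = c(height, width, 3)` on the
#' 0-255 scale, top-left origin, `x` = column offset and `y` = row offset,
#' both 0-based and multiples of the patch size for grid-tiled patches.
#'
#' @param slide_id character scalar identifying the parent slide.
#' @param x,y 0-based pixel offset of the patch's top-left corner.
#' @param pixels integer array `c(h, w, 3)` with values in 0-255.
#' @param label optional slide-level response label, `"effective"` or
#'   `"ineffective"`; `NA` until assigned.
#' @return An object of class `olp_patch`.
#' @export
new_patch <- function(slide_id, x, y, pixels, label = NA_character_) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  validate_pixels(pixels)
  structure(
    list(slide_id = slide_id, x = as.integer(x), y = as.integer(y),
         width = ncol(pixels), height = nrow(pixels),
         pixels = pixels, label = label),
    class = "olp_patch")
}

validate_pixels <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("patch pixels must be an h x w x 3 array", call. = FALSE)
  if (!is.numeric(pixels))
    stop("patch pixels must be numeric on the 0-255 scale", call. = FALSE)
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("patch pixels must be 8-bit values in [0, 255]", call. = FALSE)
  invisible(pixels)
}

#' @export
print.olp_patch <- function(x, ...) {
  cat(sprintf("<patch %s @(%d,%d) %dx%d label=%s>\n",
              x$slide_id, x$x, x$y, x$width, x$height,
              if (is.na(x$label)) "unset" else x$label))
  invisible(x)
}

#' @export
dim.olp_patch <- function(x) dim(x$pixels)

# Stack patches into the c(h, w, 3, n) double array in [0, 1] that the
# autoencoder consumes. All patches must share one shape.
patches_to_array <- function(patches) {
  stopifnot(length(patches) >= 1L)
  d <- dim(patches[[1L]]$pixels)
  out <- array(0, dim = c(d, length(patches)))
  for (i in seq_along(patches)) {
    p <- patches[[i]]$pixels
    if (!identical(dim(p), d))
      stop("all patches must have identical dimensions (got ",
           paste(dim(p), collapse = "x"), " vs ",
           paste(d, collapse = "x"), ")", call. = FALSE)
    out[, , , i] <- p / 255
  }
  out
}

# 0-255 integer raster from a [0,1] double array (decoder output, slides).
clamp_raster <- function(x) {
  x <- round(x * 255)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}
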