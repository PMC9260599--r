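#' Read a slide manifest
#'
#' The manifest is a CSV/TSV with header columns `slide_id`, `patient_id`,
#' `path`, `role` and `label`. `role` distinguishes the feature-discovery
#' training set from the held-out validation set; `label` is the slide's
#' treatment-response label (`effective` / `ineffective`), which may be
#' empty until the clinical score assigns it.
#'
#' @param path manifest file; field separator is inferred from the
#'   extension (`.tsv` = tab, otherwise comma).
#' @return data.frame with one row per slide; `slide_id` values are
#'   guaranteed unique.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  m <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("slide_id", "patient_id")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m$slide_id))
    stop("duplicate slide_id in manifest: ",
         paste(unique(m$slide_id[duplicated(m$slide_id)]), collapse = ", "),
         call. = FALSE)
  if (!"label" %in% names(m)) m$label <- NA_character_
  m$label[!is.na(m$label) & m$label == ""] <- NA_character_
  if (!"role" %in% names(m)) m$role <- "train-feature-set"
  bad <- !is.na(m$label) & !m$label %in% c("effective", "ineffective")
  if (any(bad))
    stop("invalid label(s): ", paste(unique(m$label[bad]), collapse = ", "),
         "; expected 'effective' or 'ineffective'", call. = FALSE)
  m
}

#' Read a slide raster from an image file
#'
#' Reads PNG (and TIFF when the tiff package is installed) rasters as
#' 8-bit RGB arrays. Whole-slide pyramidal formats are out of reach of a
#' pure-R stack; the pipeline operates on a raster exported at the working
#' magnification (for the original study, a 50x zoom level), which for the
#' synthetic cohorts used in testing is simply the stored image.
#'
#' @param path image file (.png, .tif/.tiff).
#' @return integer array `c(h, w, 3)`, values 0-255.
#' @export
read_slide <- function(path) {
  if (!file.exists(path)) stop("cannot read slide raster: ", path, call. = FALSE)
  lower <- tolower(path)
  img <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    stop("unsupported raster format: ", path, call. = FALSE)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  clamp_raster(img)
}

#' Cut a slide raster gaplessly into patches
#'
#' Tiles the raster on a non-overlapping grid of `patch_size`-pixel cells
#' in deterministic row-major order (left to right, then top to bottom).
#' Partial cells at the right and bottom edges are emitted with their
#' true (smaller) size; downstream quality control rejects them by the
#' size criterion, mirroring the pipeline's processing order.
#'
#' @param raster integer array `c(h, w, 3)` (see [read_slide()]), or an
#'   `olp_patch`-free slide produced by [make_pseudo_slide()].
#' @param slide_id identifier stamped on every patch.
#' @param patch_size grid cell edge in pixels (default 128).
#' @param label optional response label inherited by every patch.
#' @return list of [new_patch()] objects covering every pixel exactly once.
#' @examples
#' r <- array(128L, dim = c(256, 256, 3))
#' length(tile_slide(r, "s1"))  # 4
#' @export
tile_slide <- function(raster, slide_id, patch_size = 128L,
                       label = NA_character_) {
  validate_pixels(raster)
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L) stop("patch_size must be >= 1", call. = FALSE)
  h <- nrow(raster); w <- ncol(raster)
  ys <- seq.int(0L, h - 1L, by = patch_size)
  xs <- seq.int(0L, w - 1L, by = patch_size)
  out <- vector("list", length(xs) * length(ys))
  i <- 0L
  for (y in ys) {
    for (x in xs) {
      i <- i + 1L
      rows <- (y + 1L):min(y + patch_size, h)
      cols <- (x + 1L):min(x + patch_size, w)
      out[[i]] <- new_patch(slide_id, x, y,
                            raster[rows, cols, , drop = FALSE], label = label)
    }
  }
  out
}
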