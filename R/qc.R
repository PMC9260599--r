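#' Quality-control parameters
#'
#' Thresholds for the four patch-rejection criteria, with the defaults used
#' throughout: a patch is rejected when (in this order) (d) its width or
#' height is below `min_size` (edge-of-slide tile); (a) the fraction of
#' blank pixels is at least `blank_fraction_max`; (b) its mean brightness
#' over all channel values falls outside `(brightness_min, brightness_max)`;
#' (c) the population variance of all its channel values is below
#' `variance_min`. A "blank" pixel is near-white background: all three
#' channels at or above `blank_threshold`.
#'
#' Brightness and variance are computed on the flattened 3N channel values
#' of the patch on the 0-255 scale; the variance is the population variance
#' (denominator N, not N-1).
#'
#' @param blank_threshold channel intensity at or above which a pixel
#'   counts as blank (default 240).
#' @param blank_fraction_max maximum tolerated blank-pixel fraction
#'   (default 0.75; rejection when fraction `>=` this value).
#' @param brightness_min,brightness_max accepted open interval for mean
#'   brightness (defaults 120 and 250; rejection when `< min` or `> max`).
#' @param variance_min minimum pooled channel variance (default 80;
#'   rejection when strictly below).
#' @param min_size minimum width and height in pixels (default 128).
#' @return list of class `qc_params`.
#' @export
qc_params <- function(blank_threshold = 240, blank_fraction_max = 0.75,
                      brightness_min = 120, brightness_max = 250,
                      variance_min = 80, min_size = 128L) {
  structure(list(blank_threshold = blank_threshold,
                 blank_fraction_max = blank_fraction_max,
                 brightness_min = brightness_min,
                 brightness_max = brightness_max,
                 variance_min = variance_min,
                 min_size = as.integer(min_size)),
            class = "qc_params")
}

#' Is a pixel blank (near-white background)?
#'
#' @param pixel numeric length-3 RGB triple on the 0-255 scale.
#' @param blank_threshold intensity threshold (default 240).
#' @return `TRUE` iff all three channels are `>= blank_threshold`.
#' @export
is_blank_pixel <- function(pixel, blank_threshold = 240) {
  stopifnot(length(pixel) == 3L, all(pixel >= 0), all(pixel <= 255))
  all(pixel >= blank_threshold)
}

#' Fraction of blank pixels in a patch
#'
#' @param patch an `olp_patch` or an `h x w x 3` pixel array.
#' @param blank_threshold intensity threshold (default 240).
#' @return fraction in `[0, 1]` of pixels whose three channels are all at
#'   or above the threshold.
#' @export
blank_fraction <- function(patch, blank_threshold = 240) {
  px <- if (inherits(patch, "olp_patch")) patch$pixels else patch
  blank <- px[, , 1] >= blank_threshold &
           px[, , 2] >= blank_threshold &
           px[, , 3] >= blank_threshold
  mean(blank)
}

#' Apply the four rejection criteria to one patch
#'
#' Returns the first failing criterion in the fixed order size, blank,
#' brightness, variance (size first: it is the cheapest check and edge
#' patches cannot be meaningfully scored), or `"accept"`.
#'
#' @param patch an `olp_patch`.
#' @param params a [qc_params()] list.
#' @return character scalar: `"accept"`, `"size"`, `"blank"`,
#'   `"brightness"` or `"variance"`.
#' @export
qc_patch <- function(patch, params = qc_params()) {
  stopifnot(inherits(patch, "olp_patch"))
  validate_pixels(patch$pixels)
  if (patch$width < params$min_size || patch$height < params$min_size)
    return("size")
  if (blank_fraction(patch, params$blank_threshold) >= params$blank_fraction_max)
    return("blank")
  v <- as.numeric(patch$pixels)
  brightness <- mean(v)
  if (brightness < params$brightness_min || brightness > params$brightness_max)
    return("brightness")
  pop_var <- mean((v - brightness)^2)
  if (pop_var < params$variance_min)
    return("variance")
  "accept"
}

#' Filter a patch set
#'
#' Applies [qc_patch()] to every patch, preserving input order among the
#' survivors, and tallies first-cause rejections per criterion.
#'
#' @param patches list of `olp_patch` objects.
#' @param params a [qc_params()] list.
#' @return list with `passed` (the accepted patches, input order) and
#'   `report`, a list of class `qc_report` with fields `n_input`,
#'   `n_rejected_by_criterion` (named vector over blank/brightness/
#'   variance/size) and `n_passed`.
#' @export
qc_filter <- function(patches, params = qc_params()) {
  verdicts <- vapply(patches, qc_patch, character(1), params = params)
  rejected <- c(blank = sum(verdicts == "blank"),
                brightness = sum(verdicts == "brightness"),
                variance = sum(verdicts == "variance"),
                size = sum(verdicts == "size"))
  report <- structure(list(n_input = length(patches),
                           n_rejected_by_criterion = rejected,
                           n_passed = sum(verdicts == "accept")),
                      class = "qc_report")
  list(passed = patches[verdicts == "accept"], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Patch QC: %d in, %d passed\n", x$n_input, x$n_passed))
  r <- x$n_rejected_by_criterion
  for (nm in names(r))
    if (r[[nm]] > 0) cat(sprintf("  rejected (%s): %d\n", nm, r[[nm]]))
  invisible(x)
}
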