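#' Oral sites of the clinical sign score
#'
#' The 11 oral sites scored at every visit.
#' @export
olp_sites <- function() c(
  "upper lip", "lower lip", "left cheek", "right cheek",
  "maxillary gum", "mandibular gum", "left tongue", "right tongue",
  "floor of mouth", "hard palate", "soft palate")

#' Total clinical sign score
#'
#' Each of the 11 oral sites is scored for three lesion types —
#' reticulation/patch, erythema/congestion, erosion/ulcer — with extent
#' 0 (absent), 1 (present, at most half the site) or 2 (more than half).
#' The total weights erythema 1.5x and erosion 2x:
#' total = sum over sites of (reticulation + 1.5 * erythema + 2 * erosion),
#' so the range is 0 to 11 * 2 * 4.5 = 99.
#'
#' @param assessment data.frame with columns `reticulation`, `erythema`,
#'   `erosion` and exactly 11 rows (one per site), or an 11 x 3 numeric
#'   matrix in that column order.
#' @param weights lesion-type weights, default `c(1, 1.5, 2)`.
#' @return numeric total score.
#' @export
total_sign_score <- function(assessment, weights = c(1, 1.5, 2)) {
  m <- if (is.data.frame(assessment)) {
    need <- c("reticulation", "erythema", "erosion")
    if (!all(need %in% names(assessment)))
      stop("assessment needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    as.matrix(assessment[need])
  } else as.matrix(assessment)
  if (nrow(m) != 11L || ncol(m) != 3L)
    stop("assessment must cover exactly 11 sites x 3 lesion types",
         call. = FALSE)
  if (!all(m %in% c(0, 1, 2)))
    stop("extent scores must be 0, 1 or 2", call. = FALSE)
  sum(m %*% weights)
}

#' Treatment-response label from first and third visit
#'
#' A patient responds to immunosuppressive therapy ("effective") when the
#' total sign score at the third visit is strictly more than 10% lower
#' than at the first; a reduction of exactly 10% or less is
#' "ineffective". (An intermediate second visit, when recorded, does not
#' enter the rule.)
#'
#' @param visit1,visit3 assessments (see [total_sign_score()]) or
#'   already-computed numeric totals.
#' @param reduction required fractional reduction, default 0.1.
#' @return `"effective"` or `"ineffective"`.
#' @export
response_label <- function(visit1, visit3, reduction = 0.1) {
  s1 <- if (is.numeric(visit1) && length(visit1) == 1L) visit1
        else total_sign_score(visit1)
  s3 <- if (is.numeric(visit3) && length(visit3) == 1L) visit3
        else total_sign_score(visit3)
  if (s1 <= 0)
    stop("first-visit score must be positive (relative change undefined)",
         call. = FALSE)
  if (s3 < (1 - reduction) * s1) "effective" else "ineffective"
}

#' Read clinical assessments from CSV
#'
#' Long format: one row per patient x visit x site with columns
#' `patient_id`, `visit`, `site`, `reticulation`, `erythema`, `erosion`.
#'
#' @param path CSV file.
#' @return nested list: `x[[patient_id]][[visit]]` is an 11-row assessment
#'   data.frame ordered as [olp_sites()].
#' @export
read_assessments <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "visit", "site", "reticulation", "erythema", "erosion")
  if (!all(need %in% names(df)))
    stop("assessments need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (pid in unique(df$patient_id)) {
    sub <- df[df$patient_id == pid, ]
    out[[as.character(pid)]] <- lapply(
      stats::setNames(nm = sort(unique(sub$visit))), function(v) {
        a <- sub[sub$visit == v, ]
        missing <- setdiff(olp_sites(), a$site)
        if (length(missing))
          stop("patient ", pid, " visit ", v, " lacks site(s): ",
               paste(missing, collapse = ", "), call. = FALSE)
        a <- a[match(olp_sites(), a$site), ]
        a[c("site", "reticulation", "erythema", "erosion")]
      })
  }
  out
}
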