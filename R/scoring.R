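#' Attach slide response labels to patch assignments
#'
#' Every patch inherits the binary treatment-response label of its parent
#' slide: patches from slides of patients who responded to
#' immunosuppressive therapy are positive, the rest negative.
#'
#' @param assignments a `patch_assignment` data.frame with a `slide_id`
#'   column (see [assign_latents()]).
#' @param manifest manifest data.frame with `slide_id` and `label`
#'   (`effective` / `ineffective`); see [read_manifest()].
#' @return `assignments` with an added `label` column.
#' @export
label_assignments <- function(assignments, manifest) {
  stopifnot(is.data.frame(assignments), "slide_id" %in% names(assignments))
  idx <- match(assignments$slide_id, manifest$slide_id)
  if (anyNA(idx))
    stop("slide(s) missing from manifest: ",
         paste(unique(assignments$slide_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  lab <- manifest$label[idx]
  if (anyNA(lab))
    stop("slide(s) without a response label: ",
         paste(unique(assignments$slide_id[is.na(lab)]), collapse = ", "),
         call. = FALSE)
  assignments$label <- lab
  assignments
}

#' Per-cluster positivity rates, impact scores and weights
#'
#' For cluster k, `r_plus` is the number of its positive member patches
#' divided by the total number of positive patches across all clusters,
#' and `r_minus` the analogue for negative patches. The impact score is
#' `I = r_plus / (r_plus + r_minus)` and the weight `W = 1 + |0.5 - I|`,
#' so `I` lies in \[0, 1\] and `W` in \[1, 1.5\]. Polarity is positive for
#' `I > 0.5`, negative for `I < 0.5`, neutral at exactly 0.5. A cluster
#' with no labeled members of either sign has an undefined impact score;
#' it is recorded as neutral (`I = 0.5`, `W = 1`) and flagged `empty`.
#'
#' @param assignments labeled assignments (see [label_assignments()]):
#'   data.frame with `cluster` and `label` columns.
#' @param k number of clusters; clusters are indexed 1..k.
#' @return data.frame of class `feature_scores` with one row per cluster:
#'   `cluster`, `size`, `n_pos`, `n_neg`, `r_plus`, `r_minus`, `I`, `W`,
#'   `polarity`, `empty`.
#' @export
compute_feature_scores <- function(assignments, k) {
  stopifnot(all(c("cluster", "label") %in% names(assignments)))
  k <- as.integer(k)
  if (any(assignments$cluster < 1L | assignments$cluster > k))
    stop("cluster index outside 1..k", call. = FALSE)
  pos <- assignments$label == "effective"
  n_plus <- sum(pos)
  n_minus <- sum(!pos)
  if (n_plus < 1L || n_minus < 1L)
    stop("both labels must be present to compute impact scores (n+ = ",
         n_plus, ", n- = ", n_minus, ")", call. = FALSE)
  cl <- factor(assignments$cluster, levels = seq_len(k))
  n_pos <- as.integer(table(cl[pos]))
  n_neg <- as.integer(table(cl[!pos]))
  r_plus <- n_pos / n_plus
  r_minus <- n_neg / n_minus
  denom <- r_plus + r_minus
  I <- ifelse(denom > 0, r_plus / denom, 0.5)
  scores <- data.frame(cluster = seq_len(k), size = n_pos + n_neg,
                       n_pos = n_pos, n_neg = n_neg,
                       r_plus = r_plus, r_minus = r_minus,
                       I = I, W = feature_weight(I),
                       polarity = feature_polarity(I),
                       empty = denom == 0,
                       stringsAsFactors = FALSE)
  class(scores) <- c("feature_scores", "data.frame")
  scores
}

#' Feature weight from impact score
#'
#' `W = 1 + |0.5 - I|`: the further a cluster's impact score is from
#' outcome neutrality, the larger its weight, bounded in \[1, 1.5\].
#'
#' @param I impact score(s) in \[0, 1\].
#' @return numeric weight(s).
#' @export
feature_weight <- function(I) {
  stopifnot(all(I >= 0 & I <= 1))
  1 + abs(0.5 - I)
}

#' @rdname feature_weight
#' @return `feature_polarity` returns `"positive"`, `"negative"` or
#'   `"neutral"` per score.
#' @export
feature_polarity <- function(I) {
  ifelse(I > 0.5, "positive", ifelse(I < 0.5, "negative", "neutral"))
}

#' Select key features
#'
#' A key feature is a cluster whose weight strictly exceeds
#' `key_threshold` and whose morphology class is not `shape` (clusters
#' grouped by tile geometry — blank edges, partial tiles — rather than by
#' tissue appearance are excluded no matter how extreme their weight).
#'
#' @param scores a `feature_scores` data.frame (or any data.frame with
#'   `cluster` and `I` columns; `W` is recomputed from `I` if absent).
#' @param key_threshold weight threshold, default 1.1.
#' @param morphology optional data.frame with columns `cluster` and
#'   `morphology` (`"shape"` or `"histology"`), e.g. an expert annotation
#'   file; clusters not covered default to `"unknown"`. When `NULL`, all
#'   clusters are `"unknown"` (treated as non-shape).
#' @return `scores` with added columns `morphology` and `is_key`.
#' @export
select_key_features <- function(scores, key_threshold = 1.1,
                                morphology = NULL) {
  stopifnot(is.data.frame(scores), all(c("cluster", "I") %in% names(scores)))
  if (!"W" %in% names(scores)) scores$W <- feature_weight(scores$I)
  morph <- rep("unknown", nrow(scores))
  if (!is.null(morphology)) {
    stopifnot(all(c("cluster", "morphology") %in% names(morphology)))
    unknown <- setdiff(morphology$cluster, scores$cluster)
    if (length(unknown))
      stop("morphology annotation references unknown cluster(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bad <- !morphology$morphology %in% c("shape", "histology")
    if (any(bad))
      stop("morphology must be 'shape' or 'histology', got: ",
           paste(unique(morphology$morphology[bad]), collapse = ", "),
           call. = FALSE)
    idx <- match(scores$cluster, morphology$cluster)
    morph[!is.na(idx)] <- morphology$morphology[idx[!is.na(idx)]]
  }
  scores$morphology <- morph
  scores$is_key <- scores$W > key_threshold & morph != "shape"
  scores
}

#' Shape-versus-histology heuristic
#'
#' Stand-in for the expert annotation step when no morphology file is
#' supplied: clusters whose members are dominated by blank (near-white)
#' area are grouped by tile geometry rather than by tissue appearance, so
#' a cluster whose mean blank-pixel fraction exceeds `blank_cutoff` is
#' classified as `shape`, otherwise `histology`.
#'
#' @param members list of `olp_patch` objects belonging to one cluster.
#' @param blank_cutoff mean blank fraction above which the cluster is a
#'   shape cluster (default 0.35).
#' @param blank_threshold per-pixel blank intensity threshold (default 240).
#' @return `"shape"` or `"histology"`; with no member pixels available the
#'   heuristic falls back to `"histology"` with a warning.
#' @export
classify_shape_heuristic <- function(members, blank_cutoff = 0.35,
                                     blank_threshold = 240) {
  if (length(members) == 0L) {
    warning("no member patches with pixels; defaulting to 'histology'")
    return("histology")
  }
  bf <- vapply(members, blank_fraction, numeric(1),
               blank_threshold = blank_threshold)
  if (mean(bf) > blank_cutoff) "shape" else "histology"
}
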