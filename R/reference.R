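#' Reference cluster score table from the original OLP cohort
#'
#' The published per-cluster impact scores of the original 56-patient
#' oral-lichen-planus study: 38 clusters discovered from 38 training
#' whole-slide images, each with its impact score I, member patch count
#' and the expert morphology classification (`shape` = grouped by tile
#' geometry, `histology` = grouped by tissue appearance, with the expert
#' description retained verbatim in `description`). Shipped as a worked
#' example: feeding the `I` column through [feature_weight()],
#' [feature_polarity()] and [select_key_features()] reproduces the
#' study's 25 positive / 13 negative split and its six key features.
#'
#' @return data.frame with columns `cluster`, `I`, `size`, `morphology`,
#'   `description`.
#' @examples
#' ref <- reference_cluster_scores()
#' table(feature_polarity(ref$I))
#' keyed <- select_key_features(ref, key_threshold = 1.1,
#'                              morphology = ref[c("cluster", "morphology")])
#' keyed$cluster[keyed$is_key]
#' @export
reference_cluster_scores <- function() {
  path <- system.file("extdata", "reference_cluster_scores.csv",
                      package = "olpfeat", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
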