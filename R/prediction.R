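#' Fit a response classifier on slide feature vectors
#'
#' @param x numeric matrix of weighted slide feature vectors
#'   ([build_slide_vectors()]).
#' @param y response labels, `"effective"` / `"ineffective"` (factor or
#'   character).
#' @param family `"logistic"` (binomial GLM) or `"svm"` (linear-kernel
#'   support-vector machine, unit cost).
#' @param cost SVM regularization constant (default 1).
#' @return object of class `response_classifier`.
#' @export
fit_classifier <- function(x, y, family = c("logistic", "svm"), cost = 1) {
  family <- match.arg(family)
  y <- factor(as.character(y), levels = c("ineffective", "effective"))
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present to fit a classifier", call. = FALSE)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- if (family == "logistic") {
    df <- data.frame(.y = y, x, check.names = FALSE)
    suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  } else {
    e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  }
  structure(list(fit = fit, family = family,
                 feature_names = colnames(x),
                 levels = levels(y)),
            class = "response_classifier")
}

# Continuous score oriented so that larger means more likely "effective".
classifier_scores <- function(object, x) {
  x <- as.matrix(x)
  if (object$family == "logistic") {
    df <- as.data.frame(x, optional = TRUE)
    colnames(df) <- object$feature_names %||% paste0("f", seq_len(ncol(x)))
    as.numeric(predict(object$fit, newdata = df, type = "response"))
  } else {
    pr <- predict(object$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    s <- as.numeric(dv[, 1])
    # decision values are oriented toward the first class named in the
    # column label; flip if that class is "ineffective"
    first <- strsplit(colnames(dv)[1], "/")[[1]][1]
    if (first == "ineffective") s <- -s
    s
  }
}

#' @export
#' @describeIn fit_classifier predicted class labels (`type = "class"`,
#'   default), or continuous scores oriented toward `"effective"`
#'   (`type = "score"`: predicted probability for the logistic family,
#'   decision-function value for the SVM).
predict.response_classifier <- function(object, newdata,
                                        type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- classifier_scores(object, newdata)
  if (type == "score") return(s)
  threshold <- if (object$family == "logistic") 0.5 else 0
  factor(ifelse(s > threshold, "effective", "ineffective"),
         levels = c("ineffective", "effective"))
}

# Stratified fold assignment: within each class, shuffled slides are dealt
# round-robin over folds, so per-fold class proportions differ from the
# global ones by at most one slide.
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (lv in unique(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated evaluation of a response classifier
#'
#' Stratified k-fold cross-validation under a fixed seed: the slides are
#' randomly partitioned into `folds` disjoint folds with approximately
#' equal class balance; each fold in turn is held out while the model is
#' fit on the rest. Reports per-fold accuracy (mean/max/min), a pooled
#' ROC curve built from the held-out continuous scores of all folds, the
#' pooled AUC, and a normal-approximation confidence interval for the
#' mean of the per-fold AUCs.
#'
#' @inheritParams fit_classifier
#' @param folds number of folds (default 10); at most the size of the
#'   smaller class times folds must allow both classes in every training
#'   split.
#' @param seed integer seed for the fold partition.
#' @param hard_scores use predicted class labels (0/1) instead of
#'   continuous scores for the ROC, mimicking pipelines that compute ROC
#'   from categorical predictions (default `FALSE`).
#' @return object of class `cv_result`: per-fold accuracies and AUCs,
#'   mean/max/min accuracy, pooled ROC data.frame, pooled `auc`, `auc_ci`
#'   (95%, normal approximation over folds), `family`, `seed`, `fold`
#'   assignment vector.
#' @export
crossvalidate <- function(x, y, family = c("logistic", "svm"), folds = 10L,
                          seed = 1L, cost = 1, hard_scores = FALSE) {
  family <- match.arg(family)
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("ineffective", "effective"))
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (length(y) < folds)
    stop("need at least as many labeled slides as folds", call. = FALSE)
  fold <- with_seed(seed, {
    f <- stratified_folds(y, folds)
    # a training split lacking a class cannot be fit; re-stratify
    tries <- 0L
    while (any(vapply(seq_len(folds), function(j)
      nlevels(droplevels(y[f != j])) < 2L, logical(1))) && tries < 100L) {
      f <- stratified_folds(y, folds)
      tries <- tries + 1L
    }
    f
  })
  acc <- auc_fold <- numeric(folds)
  score <- numeric(length(y))
  for (j in seq_len(folds)) {
    test <- fold == j
    clf <- fit_classifier(x[!test, , drop = FALSE], y[!test],
                          family = family, cost = cost)
    pred <- predict(clf, x[test, , drop = FALSE], type = "class")
    acc[j] <- mean(pred == y[test])
    score[test] <- if (hard_scores)
      as.numeric(pred == "effective")
    else classifier_scores(clf, x[test, , drop = FALSE])
    auc_fold[j] <- if (nlevels(droplevels(y[test])) == 2L)
      roc_auc(y[test], score[test]) else NA_real_
  }
  roc <- roc_curve(y, score)
  auc_ok <- auc_fold[!is.na(auc_fold)]
  ci <- if (length(auc_ok) > 1L)
    mean(auc_ok) + c(-1, 1) * qnorm(0.975) * sd(auc_ok) / sqrt(length(auc_ok))
  else c(NA_real_, NA_real_)
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 max_accuracy = max(acc), min_accuracy = min(acc),
                 fold_auc = auc_fold, auc = roc_auc(y, score),
                 auc_ci = ci, roc = roc, family = family,
                 folds = folds, seed = seed, fold = fold,
                 scores = score, labels = y),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("%d-fold cross-validation (%s, seed %d)\n",
                     "  accuracy: mean %.4f, max %.4f, min %.4f\n",
                     "  pooled AUC %.4f; mean fold AUC 95%% CI [%.3f, %.3f]\n"),
              x$folds, x$family, x$seed, x$mean_accuracy, x$max_accuracy,
              x$min_accuracy, x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' @export
plot.cv_result <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("%s: AUC %.3f", x$family, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Evaluate a fitted classifier on a held-out validation set
#'
#' @param object a `response_classifier` fit on the full training set.
#' @param x validation slide feature vectors (built against the same
#'   feature model).
#' @param y validation labels.
#' @return list with `accuracy`, `roc` (data.frame `fpr`, `tpr`) and
#'   `auc`, all computed once from continuous scores on the holdout.
#' @export
evaluate_holdout <- function(object, x, y) {
  stopifnot(inherits(object, "response_classifier"))
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty validation set", call. = FALSE)
  y <- factor(as.character(y), levels = c("ineffective", "effective"))
  pred <- predict(object, x, type = "class")
  s <- classifier_scores(object, x)
  list(accuracy = mean(pred == y), roc = roc_curve(y, s),
       auc = roc_auc(y, s))
}

# ROC/AUC via pROC, with the direction pinned (higher score = effective)
# so that an anti-predictive classifier honestly reports AUC < 0.5.
roc_auc <- function(y, score) {
  r <- pROC::roc(response = y, predictor = score,
                 levels = c("ineffective", "effective"),
                 direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

roc_curve <- function(y, score) {
  r <- pROC::roc(response = y, predictor = score,
                 levels = c("ineffective", "effective"),
                 direction = "<", quiet = TRUE)
  data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
}
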