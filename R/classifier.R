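# Cross-dataset disease classification with sub-network features.
#
# Significant sub-networks from the training dataset are ranked by
# synergy; the top-k aggregate expression profiles become features for a
# linear-kernel SVM trained on one cohort and evaluated on the other,
# scored by the F-measure with the disease class as positive.

#' Select and rank sub-network features
#'
#' Keeps the significant assessments, sorted by `phi` descending; ties
#' broken by smaller size, then seed ID, then kind (lexicographic), so
#' the ranking is deterministic.
#'
#' @param assessments a list of `synergy_assessment` objects computed on
#'   the training dataset.
#' @return the significant assessments, ranked.  Zero significant
#'   sub-networks is an error (nothing to classify with).
#' @export
select_features <- function(assessments) {
  keep <- Filter(function(a) isTRUE(a$significant), assessments)
  if (!length(keep)) {
    stop("no sub-network is significant on the training dataset; nothing to rank",
         call. = FALSE)
  }
  ord <- order(-vapply(keep, `[[`, 0, "phi"),
               vapply(keep, `[[`, 0L, "size"),
               vapply(keep, `[[`, "", "seed"),
               vapply(keep, `[[`, "", "kind"))
  keep[ord]
}

#' F-measure from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `F = 2PR / (P + R)`.  By convention all three are 0 when `tp = 0`.
#'
#' @param tp,fp,fn true positive, false positive, false negative counts.
#' @return list with `precision`, `recall`, `f_measure`.
#' @export
f_measure <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp == 0) return(list(precision = 0, recall = 0, f_measure = 0))
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  list(precision = p, recall = r, f_measure = 2 * p * r / (p + r))
}

# Internal: k x m feature matrix of aggregate profiles for one dataset.
# Returns NULL rows for features with no measured genes.
feature_rows <- function(features, data) {
  lapply(features, function(f) {
    genes <- intersect(f$members, rownames(data$expr))
    if (!length(genes)) return(NULL)
    colSums(data$expr[genes, , drop = FALSE]) / sqrt(length(genes))
  })
}

#' Cross-dataset classification with top-k sub-network features
#'
#' Builds the aggregate expression profiles of the `k` top-ranked
#' sub-networks on both datasets (each feature's gene set is intersected
#' with the genes measured in each dataset; features with an empty
#' intersection on either side are dropped from both with a warning),
#' standardizes each feature with training-set statistics, trains a
#' linear-kernel SVM (cost 1) on the training cohort, and predicts the
#' held-out cohort.  Performance is precision/recall/F with the disease
#' class (label 1) as positive.
#'
#' @param train,test row-normalized [expression_dataset()] objects
#'   (normalized independently of each other).
#' @param ranked a [select_features()] ranking (assessments carrying
#'   member gene sets).
#' @param k number of top features to use (`k <= length(ranked)`).
#' @return object of class `classification_result`: list with `k`
#'   (features actually used), `precision`, `recall`, `f_measure`, and
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
cross_classify <- function(train, test, ranked, k) {
  stopifnot(inherits(train, "expression_dataset"),
            inherits(test, "expression_dataset"),
            k >= 1L, k <= length(ranked))
  feats <- ranked[seq_len(k)]
  tr <- feature_rows(feats, train)
  te <- feature_rows(feats, test)
  ok <- !vapply(tr, is.null, TRUE) & !vapply(te, is.null, TRUE)
  if (!all(ok)) {
    warning(sprintf("%d feature(s) had no measured genes in one dataset and were dropped",
                    sum(!ok)), call. = FALSE)
  }
  if (!any(ok)) stop("no usable features remain for classification", call. = FALSE)
  Xtr <- do.call(cbind, tr[ok])          # samples x features
  Xte <- do.call(cbind, te[ok])
  # standardize with training statistics only
  mu <- colMeans(Xtr)
  sds <- apply(Xtr, 2L, stats::sd)
  sds[sds == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sds, "/")
  Xte <- sweep(sweep(Xte, 2L, mu), 2L, sds, "/")

  ytr <- factor(train$labels, levels = c(0L, 1L))
  fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = 1, scale = FALSE)
  pred <- stats::predict(fit, Xte)
  truth <- test$labels
  tp <- sum(pred == "1" & truth == 1L)
  fp <- sum(pred == "1" & truth == 0L)
  fn <- sum(pred == "0" & truth == 1L)
  tn <- sum(pred == "0" & truth == 0L)
  fm <- f_measure(tp, fp, fn)
  structure(list(k = sum(ok), precision = fm$precision, recall = fm$recall,
                 f_measure = fm$f_measure, tp = tp, fp = fp, fn = fn, tn = tn),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Cross-classification with %d feature(s): precision %.3f, recall %.3f, F %.3f\n",
              x$k, x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' Classification performance curve over the number of features
#'
#' Runs [cross_classify()] for `k = 1..max_k` and tabulates the
#' precision/recall/F curve (each `k` is evaluated independently).
#'
#' @param train,test row-normalized [expression_dataset()] objects.
#' @param ranked a [select_features()] ranking.
#' @param max_k largest number of features (capped at `length(ranked)`).
#' @return data frame with columns `k`, `precision`, `recall`,
#'   `f_measure`.
#' @export
classification_curve <- function(train, test, ranked, max_k = length(ranked)) {
  max_k <- min(max_k, length(ranked))
  rows <- lapply(seq_len(max_k), function(k) {
    r <- cross_classify(train, test, ranked, k)
    data.frame(k = k, precision = r$precision, recall = r$recall,
               f_measure = r$f_measure)
  })
  do.call(rbind, rows)
}
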