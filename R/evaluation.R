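#' Confusion-matrix classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, positive
#' predictive value TP/(TP+FP) (0 when nothing is predicted positive), and
#' the geometric mean GM = sqrt(sensitivity x specificity), the selection
#' criterion used throughout for imbalanced data. A metric whose
#' denominator is empty (e.g. sensitivity with no true positives in the
#' labels) is reported as 0.
#'
#' @param labels,predictions equal-length binary vectors.
#' @return list with \code{sens}, \code{spec}, \code{acc}, \code{ppv},
#'   \code{gm} and the confusion counts \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}.
#' @export
classificationMetrics <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  if (!length(labels)) stop("empty input")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  tn <- sum(labels == 0L & predictions == 0L)
  fn <- sum(labels == 1L & predictions == 0L)
  safe <- function(num, den) if (den > 0) num / den else 0
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  list(sens = sens, spec = spec,
       acc = (tp + tn) / length(labels),
       ppv = safe(tp, tp + fp),
       gm = sqrt(sens * spec),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC and precision-recall curves by threshold sweep
#'
#' Thresholds sweep the distinct score values (predict positive when score
#' >= threshold) plus a +Inf sentinel, so the ROC starts at (0,0) and ends
#' at (1,1). The ROC AUC is the trapezoidal area, which equals the
#' Mann-Whitney pairwise-comparison statistic.
#'
#' @param labels binary vector with both classes present.
#' @param scores finite numeric scores.
#' @return list with data.frames \code{roc} (threshold, fpr, tpr) and
#'   \code{pr} (threshold, recall, precision), plus \code{auc}.
#' @export
rocPrCurves <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    stop("labels and scores differ in length")
  if (length(unique(labels)) < 2L)
    stop("both classes are required to build a ROC curve")
  if (any(!is.finite(scores))) stop("scores must be finite")
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- t(vapply(thresholds, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0L) / nNeg,
      tpr = sum(pred & labels == 1L) / nPos)
  }, c(fpr = 0, tpr = 0)))
  rocDf <- data.frame(threshold = thresholds, fpr = roc[, "fpr"],
                      tpr = roc[, "tpr"])
  prT <- thresholds[-1L]  # every attained threshold predicts >= 1 positive
  pr <- t(vapply(prT, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1L)
    c(recall = tp / nPos, precision = tp / sum(pred))
  }, c(recall = 0, precision = 0)))
  prDf <- data.frame(threshold = prT, recall = pr[, "recall"],
                     precision = pr[, "precision"])
  auc <- sum(diff(rocDf$fpr) * (head(rocDf$tpr, -1) + tail(rocDf$tpr, -1)) / 2)
  list(roc = rocDf, pr = prDf, auc = auc)
}

.overlapFromCounts <- function(A, B, C, D = NA_real_) {
  if (B <= 0) stop("no predicted bases (B = 0): metrics undefined")
  if (A < 0 || A > min(B, C))
    stop("A must satisfy 0 <= A <= min(B, C)")
  if (!is.na(D) && (D < 0 || D > B))
    stop("D must satisfy 0 <= D <= B")
  list(A = A, B = B, C = C, D = D,
       ppv = A / B,
       jaccard = A / (B + C - A),
       f1 = 2 * A / (B + C),
       pof = if (is.na(D)) NA_real_ else D / B)
}

#' Base-pair overlap metrics between predictions and a support set
#'
#' Computes the base-pair quantities A (predicted bases with experimental
#' support), B (total predicted bases), C (total support bases) and,
#' when a promoter-candidate set is supplied, D (predicted bases
#' overlapping promoter candidates), then PPV = A/B, Jaccard =
#' A/(B+C-A), F1 = 2A/(B+C) and promoter-overlap fraction POF = D/B.
#' All metrics are proportions in [0,1].
#'
#' @param pred GRanges of predicted enhancers (non-empty).
#' @param support GRanges of the support set (e.g. p300 or DHS peaks).
#' @param promoters optional GRanges of promoter candidates.
#' @return list with A, B, C, D and ppv, jaccard, f1, pof.
#' @export
overlapMetrics <- function(pred, support, promoters = NULL) {
  if (!length(pred)) stop("empty prediction set (B = 0): metrics undefined")
  .overlapFromCounts(
    A = overlapBp(pred, support),
    B = totalBp(pred),
    C = totalBp(support),
    D = if (is.null(promoters)) NA_real_ else overlapBp(pred, promoters))
}

#' Overlap metrics from precomputed base-pair counts
#'
#' Same formulas as \code{\link{overlapMetrics}} applied to already-counted
#' quantities, e.g. to reproduce published worked examples.
#'
#' @param A,B,C,D base-pair counts (D optional).
#' @return list as in \code{\link{overlapMetrics}}.
#' @export
overlapMetricsFromCounts <- function(A, B, C, D = NA_real_) {
  .overlapFromCounts(A, B, C, D)
}

#' Promoter-candidate regions from Pol II and TBP peaks
#'
#' Bases supported by both RNA polymerase II and TATA-binding-protein
#' ChIP peaks, the stricter evidence used for promoter-type regions.
#'
#' @param pol2,tbp GRanges of ChIP peaks.
#' @return merged GRanges intersection.
#' @export
promoterCandidates <- function(pol2, tbp) intersectIntervals(pol2, tbp)

#' Rank methods across multiple evaluation tests
#'
#' Ranks each method 1..m within every test, respecting the test's
#' direction (higher- or lower-is-better); tied values share the minimum
#' (competition) rank. The overall score of a method is the sum of its
#' ranks and the average rank is score / number of tests; lower is better.
#'
#' @param table numeric matrix, methods x tests (finite values).
#' @param directions per-test flags: \code{"higher"} or \code{"lower"}
#'   (recycled if length 1).
#' @return list with \code{ranks} (matrix), \code{score} and
#'   \code{averageRank} (named vectors).
#' @export
rankMethods <- function(table, directions = "higher") {
  table <- as.matrix(table)
  if (any(!is.finite(table))) stop("table entries must be finite")
  directions <- rep_len(directions, ncol(table))
  ranks <- vapply(seq_len(ncol(table)), function(j) {
    v <- table[, j]
    if (directions[j] == "higher") v <- -v
    else if (directions[j] != "lower") stop("unknown direction: ",
                                            directions[j])
    rank(v, ties.method = "min")
  }, numeric(nrow(table)))
  ranks <- matrix(ranks, nrow = nrow(table),
                  dimnames = dimnames(table))
  score <- rowSums(ranks)
  list(ranks = ranks, score = score, averageRank = score / ncol(table))
}
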