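#' @importFrom nnet nnet
NULL

.stratifiedFolds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    if (length(idx) < folds)
      stop("class ", cls, " has fewer samples (", length(idx),
           ") than folds (", folds, ")")
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

.fitAnn <- function(x, y, size, seed, maxit = 300L, decay = 1e-3) {
  set.seed(seed)
  nnet(x = x, y = y, size = size, entropy = TRUE, maxit = maxit,
       decay = decay, trace = FALSE)
}

#' Tune and fit the second-layer neural network
#'
#' One hidden layer with logistic activations and a single sigmoid output
#' over the per-ensemble confidence scores. The hidden size is chosen by
#' stratified k-fold cross-validation: for each candidate the mean CV GM
#' at threshold 0.5 is computed, the best size (ties to the fewest units)
#' is refit on all rows.
#'
#' @param scores numeric matrix of confidence scores in [0,1], one column
#'   per first-layer ensemble.
#' @param labels binary labels.
#' @param hiddenCandidates candidate hidden sizes (default 1:10).
#' @param folds CV folds (default 5).
#' @param seed integer RNG seed (fold assignment and weight init).
#' @return an \linkS4class{AggregatorModel} of kind \code{"ann"}, with the
#'   per-candidate mean CV GM attached as attribute \code{"cvGM"}.
#' @export
tuneAnn <- function(scores, labels, hiddenCandidates = 1:10, folds = 5L,
                    seed) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("labels are degenerate: both classes required")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]")
  fold <- .stratifiedFolds(labels, folds, seed)
  cvGM <- vapply(hiddenCandidates, function(h) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- .fitAnn(scores[tr, , drop = FALSE], labels[tr], h,
                     seed = seed + 31L * h + f)
      p <- as.vector(predict(fit, scores[!tr, , drop = FALSE]))
      .gmOf(labels[!tr], as.integer(p >= 0.5))
    }, 0))
  }, 0)
  best <- hiddenCandidates[which.max(cvGM)]  # which.max takes first tie
  fit <- .fitAnn(scores, labels, best, seed = seed)
  model <- new("AggregatorModel", kind = "ann",
               inputNames = colnames(scores) %||%
                 sprintf("score_%d", seq_len(ncol(scores))),
               hiddenUnits = as.integer(best), fit = fit, threshold = 0.5)
  attr(model, "cvGM") <- stats::setNames(cvGM, hiddenCandidates)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A majority-vote aggregator
#'
#' @param inputNames expected score columns.
#' @param columnCut per-column cut deciding a positive column vote
#'   (default 0.5).
#' @return an AggregatorModel of kind \code{"majority"}.
#' @export
majorityAggregator <- function(inputNames, columnCut = 0.5) {
  new("AggregatorModel", kind = "majority", inputNames = inputNames,
      hiddenUnits = 0L, fit = NULL, threshold = columnCut)
}

#' Final per-sample decision from confidence scores
#'
#' For the ANN kind, the output probability is thresholded (label positive
#' when probability >= threshold). For the majority kind, the probability
#' is the fraction of columns at or above the column cut and the label is
#' positive only for a strict majority, so exact ties vote negative.
#'
#' @param model an AggregatorModel.
#' @param scores numeric matrix with \code{length(inputNames)} columns.
#' @param threshold optional override of the model's decision threshold.
#' @return data.frame with columns \code{probability} and \code{label}.
#' @export
aggregatePredict <- function(model, scores, threshold = NULL) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(model@inputNames))
    stop(sprintf("score arity %d does not match the model's %d inputs",
                 ncol(scores), length(model@inputNames)))
  if (model@kind == "ann") {
    thr <- threshold %||% model@threshold
    p <- as.vector(predict(model@fit, scores))
    data.frame(probability = p, label = as.integer(p >= thr))
  } else {
    cut <- threshold %||% model@threshold
    p <- rowMeans(scores >= cut)
    data.frame(probability = p, label = as.integer(p > 0.5))
  }
}

#' Majority vote over score columns
#'
#' A row is positive when strictly more than half of the columns reach the
#' column cut; exact ties vote negative.
#'
#' @param scores numeric matrix of per-ensemble scores.
#' @param columnCut per-column cut in [0,1] (default 0.5).
#' @return integer vector of 0/1 labels.
#' @export
majorityVote <- function(scores, columnCut = 0.5) {
  if (columnCut < 0 || columnCut > 1) stop("columnCut must lie in [0,1]")
  scores <- as.matrix(scores)
  as.integer(rowSums(scores >= columnCut) > ncol(scores) / 2)
}
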