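#' @describeIn LabeledDataset feature matrix accessor
#' @param x a LabeledDataset
#' @export
setMethod("featureMatrix", "LabeledDataset", function(x) x@features)

#' @describeIn LabeledDataset binary labels accessor
#' @export
setMethod("classLabels", "LabeledDataset", function(x) x@labels)

#' @describeIn LabeledDataset row identifiers
#' @export
setMethod("sampleIds", "LabeledDataset", function(x) x@ids)

#' @describeIn LabeledDataset feature schema identifier
#' @export
setMethod("schemaId", "LabeledDataset", function(x) x@schemaId)

#' @describeIn EnsembleModel feature schema identifier
#' @param x an EnsembleModel
#' @export
setMethod("schemaId", "EnsembleModel", function(x) x@schemaId)

#' @describeIn EnsembleModel number of committee members
#' @export
setMethod("memberCount", "EnsembleModel", function(x) length(x@members))

#' @describeIn PredictionSet merged predicted regions with scores
#' @param x a PredictionSet
#' @export
setMethod("predictedRegions", "PredictionSet", function(x) x@regions)

#' @describeIn PredictionSet bases covered by the predictions
#' @export
setMethod("totalBp", "PredictionSet", function(x) x@totalBp)

#' @describeIn PredictionSet fraction of the genome predicted
#' @export
setMethod("genomeFraction", "PredictionSet", function(x) x@genomeFraction)

#' @describeIn BinFeatureMatrix whether min-max scaling was applied
#' @param x a BinFeatureMatrix
#' @export
setMethod("isNormalized", "BinFeatureMatrix", function(x) x@normalized)

#' @describeIn BinFeatureMatrix bins x marks value matrix
#' @export
setMethod("binValues", "BinFeatureMatrix", function(x) x@values)

#' @describeIn BinFeatureMatrix the bins, one per row
#' @export
setMethod("binRanges", "BinFeatureMatrix", function(x) x@bins)

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf("LabeledDataset: %d rows x %d attributes [%s]\n",
              nrow(object@features), ncol(object@features), object@schemaId))
  cat(sprintf("  enhancers: %d, non-enhancers: %d\n",
              sum(object@labels == 1L), sum(object@labels == 0L)))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel '%s': %d Gaussian-kernel SVM members [%s]\n",
              object@name, length(object@members), object@schemaId))
})

setMethod("show", "AggregatorModel", function(object) {
  cat(sprintf("AggregatorModel (%s): %d inputs", object@kind,
              length(object@inputNames)))
  if (object@kind == "ann")
    cat(sprintf(", %d hidden units", object@hiddenUnits))
  cat(sprintf(", threshold %.2f\n", object@threshold))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf(
    "PredictionSet: %d regions, %s bp (%.3f%% of genome)\n",
    length(object@regions), format(object@totalBp, big.mark = ","),
    100 * object@genomeFraction))
})

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack: %d chromosome(s): %s\n",
              length(object@values),
              paste(names(object@values), collapse = ", ")))
})

setMethod("show", "FrameworkConfig", function(object) {
  cat(sprintf(
    "FrameworkConfig '%s': schema %s, %d x %d members, %s partitioning,\n  train fraction %.2f, normalize %s, bin width %d bp\n",
    object@flavor, object@schemaId, object@nFirstLayer, object@nParts,
    object@partitionMode, object@trainFraction, object@normalize,
    object@binWidth))
})

setMethod("show", "SynthSpec", function(object) {
  cat(sprintf(
    "SynthSpec: %d x %d bp genome, %d enhancers (%d-%d bp), GC %.2f -> %.2f,\n  %d dataset(s), sharing %.2f, seed %d\n",
    object@nChroms, object@chromLength, object@nEnhancers,
    object@enhancerLengthRange[1], object@enhancerLengthRange[2],
    object@gcBackground, object@gcEnhancer, object@nDatasets,
    object@sharing, object@seed))
})
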