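#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("schemaId", function(x) standardGeneric("schemaId"))

#' @export
setGeneric("memberCount", function(x) standardGeneric("memberCount"))

#' @export
setGeneric("predictedRegions", function(x) standardGeneric("predictedRegions"))

#' Total bases covered by a region set or prediction set
#'
#' Bases covered by the merged set; double-covered bases count once.
#' @param x a GRanges or a PredictionSet.
#' @return numeric bp count.
#' @export
setGeneric("totalBp", function(x) standardGeneric("totalBp"))

#' @export
setGeneric("genomeFraction", function(x) standardGeneric("genomeFraction"))

#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' Per-attribute min-max scaling to [0,1]
#'
#' Each column is mapped by (v - min) / (max - min) using the column's own
#' minimum and maximum within this one dataset; constant columns map to 0.
#' Scaling is never pooled across datasets.
#'
#' @param x a numeric matrix or a BinFeatureMatrix.
#' @return object of the same class, scaled.
#' @export
setGeneric("minmaxNormalize", function(x) standardGeneric("minmaxNormalize"))
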