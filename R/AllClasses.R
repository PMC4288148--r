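#' @import methods
#' @importFrom S4Vectors isConstant
NULL

#' Genome-wide signal track with explicit coverage
#'
#' Per-chromosome, per-base numeric signal stored run-length encoded,
#' together with a logical mask recording which bases were covered by a
#' record in the source file. Uncovered bases hold 0 in \code{values} and
#' contribute 0 wherever signal is averaged.
#'
#' @slot values RleList, one numeric Rle per chromosome (full chromosome
#'   length; 0 at uncovered bases).
#' @slot covered RleList, one logical Rle per chromosome.
#' @exportClass SignalTrack
setClass("SignalTrack",
  representation(values = "RleList", covered = "RleList"))

setValidity("SignalTrack", function(object) {
  if (!identical(names(object@values), names(object@covered)))
    return("values and covered must name the same chromosomes")
  lv <- vapply(object@values, length, 0L)
  lc <- vapply(object@covered, length, 0L)
  if (!identical(lv, lc))
    return("values and covered must have equal per-chromosome lengths")
  for (chrom in names(object@values)) {
    v <- object@values[[chrom]]
    if (any(!is.finite(S4Vectors::runValue(v))))
      return(sprintf("non-finite signal on %s", chrom))
  }
  TRUE
})

#' Binned feature matrix over uniform genomic bins
#'
#' @slot bins GRanges of uniform-width bins, one per matrix row.
#' @slot values numeric matrix, bins x marks.
#' @slot normalized logical; TRUE once min-max scaled to [0,1].
#' @exportClass BinFeatureMatrix
setClass("BinFeatureMatrix",
  representation(bins = "GRanges", values = "matrix", normalized = "logical"))

setValidity("BinFeatureMatrix", function(object) {
  if (length(object@bins) != nrow(object@values))
    return("number of bins must equal number of matrix rows")
  if (length(object@normalized) != 1L)
    return("normalized must be a single flag")
  if (isTRUE(object@normalized)) {
    rng <- range(object@values)
    if (length(object@values) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
      return("normalized matrix must lie in [0,1]")
  }
  TRUE
})

#' Labeled feature dataset
#'
#' A feature matrix with binary enhancer labels and provenance ids, tied
#' to a feature schema (\code{"hist11"} or \code{"seq351"}).
#'
#' @slot ids character, one identifier per row.
#' @slot features numeric matrix, rows x attributes.
#' @slot labels integer, 1 = enhancer, 0 = non-enhancer.
#' @slot schemaId character scalar, \code{"hist11"} or \code{"seq351"}.
#' @exportClass LabeledDataset
setClass("LabeledDataset",
  representation(ids = "character", features = "matrix",
                 labels = "integer", schemaId = "character"))

setValidity("LabeledDataset", function(object) {
  n <- nrow(object@features)
  if (length(object@ids) != n || length(object@labels) != n)
    return("ids, labels and feature rows must agree in count")
  if (!all(object@labels %in% c(0L, 1L)))
    return("labels must be binary 0/1")
  if (length(object@schemaId) != 1L)
    return("schemaId must be a single string")
  if (any(!is.finite(object@features)))
    return("features must be finite")
  TRUE
})

#' Partition scheme for committee training
#'
#' In \code{"both-classes"} mode positives and negatives are independently
#' split into \code{nParts} disjoint subsets and learning subset k is the
#' union of positive part k and negative part k (ratio approximately 1:10).
#' In \code{"majority-only"} mode only negatives are split; every learning
#' subset contains all positives. Positive rows carry assignment 0 in that
#' mode, meaning "member of every part".
#'
#' @slot mode character, \code{"both-classes"} or \code{"majority-only"}.
#' @slot nParts integer.
#' @slot assignments integer per dataset row.
#' @exportClass PartitionScheme
setClass("PartitionScheme",
  representation(mode = "character", nParts = "integer",
                 assignments = "integer"))

setValidity("PartitionScheme", function(object) {
  if (!object@mode %in% c("both-classes", "majority-only"))
    return("mode must be 'both-classes' or 'majority-only'")
  if (object@nParts < 1L) return("nParts must be >= 1")
  a <- object@assignments
  if (object@mode == "both-classes") {
    if (!all(a %in% seq_len(object@nParts)))
      return("both-classes assignments must lie in 1..nParts")
  } else {
    if (!all(a %in% c(0L, seq_len(object@nParts))))
      return("majority-only assignments must lie in 0..nParts")
  }
  TRUE
})

#' Hyperparameter grid for the two-round SVM search
#'
#' @slot log10Step numeric, round-1 lattice step in log10 units.
#' @slot refineFactor integer, round-2 step = log10Step / refineFactor.
#' @slot cBounds,gammaBounds numeric(2), inclusive search boxes.
#' @exportClass GridSpec
setClass("GridSpec",
  representation(log10Step = "numeric", refineFactor = "integer",
                 cBounds = "numeric", gammaBounds = "numeric"))

setValidity("GridSpec", function(object) {
  if (object@log10Step <= 0) return("log10Step must be positive")
  if (object@refineFactor < 2L) return("refineFactor must be >= 2")
  for (b in list(object@cBounds, object@gammaBounds)) {
    if (length(b) != 2L || any(b <= 0) || b[1] >= b[2])
      return("bounds must be positive increasing pairs")
  }
  TRUE
})

#' Committee of Gaussian-kernel SVMs
#'
#' @slot members list; each element holds the fitted SVM, its tuned
#'   hyperparameters and its partition index.
#' @slot schemaId character, feature schema shared by all members.
#' @slot name character tag (dataset / cell line / tissue).
#' @slot featureNames character, column names the members expect.
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  representation(members = "list", schemaId = "character",
                 name = "character", featureNames = "character"))

setValidity("EnsembleModel", function(object) {
  if (length(object@members) < 1L) return("ensemble needs >= 1 member")
  TRUE
})

#' Second-layer decision model
#'
#' Either a single-hidden-layer neural network over per-ensemble
#' confidence scores, or a per-column majority vote.
#'
#' @slot kind character, \code{"ann"} or \code{"majority"}.
#' @slot inputNames character, expected score columns.
#' @slot hiddenUnits integer (ann only; 0 for majority).
#' @slot fit fitted nnet object or NULL.
#' @slot threshold numeric decision cut on the output (default 0.5). For
#'   the majority kind it is the per-column cut and ties vote negative.
#' @exportClass AggregatorModel
setClass("AggregatorModel",
  representation(kind = "character", inputNames = "character",
                 hiddenUnits = "integer", fit = "ANY",
                 threshold = "numeric"))

setValidity("AggregatorModel", function(object) {
  if (!object@kind %in% c("ann", "majority"))
    return("kind must be 'ann' or 'majority'")
  if (length(object@inputNames) < 1L) return("need >= 1 input column")
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must lie in [0,1]")
  TRUE
})

#' Named framework configuration
#'
#' Bundles the defaults of the three published flavors: histone-mark
#' committees over four cell lines (\code{"encode"}), sequence-composition
#' committees over five tissues (\code{"fantom5"}), and a single
#' sequence-composition committee (\code{"vista"}).
#'
#' @slot flavor character.
#' @slot schemaId character, \code{"hist11"} or \code{"seq351"}.
#' @slot nFirstLayer integer, number of first-layer ensembles.
#' @slot nParts integer, committee size per ensemble.
#' @slot partitionMode character.
#' @slot trainFraction numeric.
#' @slot normalize logical, per-dataset min-max scaling of features.
#' @slot binWidth integer, scanning bin width in bp.
#' @slot vistaPooled logical; with a single ensemble, feed the aggregator
#'   the pooled vote fraction (TRUE) or the individual member votes (FALSE).
#' @exportClass FrameworkConfig
setClass("FrameworkConfig",
  representation(flavor = "character", schemaId = "character",
                 nFirstLayer = "integer", nParts = "integer",
                 partitionMode = "character", trainFraction = "numeric",
                 normalize = "logical", binWidth = "integer",
                 vistaPooled = "logical"))

#' Merged genome-scan predictions
#'
#' @slot regions GRanges of merged positive bins with a \code{score}
#'   metadata column (mean constituent-bin probability).
#' @slot totalBp numeric, bases covered by the predictions.
#' @slot genomeFraction numeric in [0,1].
#' @exportClass PredictionSet
setClass("PredictionSet",
  representation(regions = "GRanges", totalBp = "numeric",
                 genomeFraction = "numeric"))

setValidity("PredictionSet", function(object) {
  if (object@genomeFraction < 0 || object@genomeFraction > 1)
    return("genomeFraction must lie in [0,1]")
  TRUE
})

#' Synthetic-data generator settings
#'
#' Defines the study conditions the generators emulate: genome shape,
#' enhancer placement, base-composition shift inside enhancers, planted
#' 4-mers, per-mark signal amplitudes, and multi-dataset sharing.
#'
#' @slot nChroms,chromLength integer genome shape.
#' @slot nEnhancers integer, enhancers per dataset collection.
#' @slot enhancerLengthRange integer(2) bp.
#' @slot gcBackground,gcEnhancer numeric GC proportions.
#' @slot gcPromoter numeric GC proportion of decoy promoters.
#' @slot plantedKmers named numeric, 4-mer -> enrichment fold.
#' @slot markProfiles data.frame with columns mark, enhancerAmp,
#'   promoterAmp, noiseSd (11 rows, hist11 order).
#' @slot nDatasets integer, cell-line / tissue replicas.
#' @slot sharing numeric in [0,1], fraction of enhancers shared.
#' @slot seed integer.
#' @exportClass SynthSpec
setClass("SynthSpec",
  representation(nChroms = "integer", chromLength = "integer",
                 nEnhancers = "integer", enhancerLengthRange = "integer",
                 gcBackground = "numeric", gcEnhancer = "numeric",
                 gcPromoter = "numeric", plantedKmers = "numeric",
                 markProfiles = "data.frame", nDatasets = "integer",
                 sharing = "numeric", seed = "integer"))

setValidity("SynthSpec", function(object) {
  p <- c(object@gcBackground, object@gcEnhancer, object@gcPromoter,
         object@sharing)
  if (any(p < 0 | p > 1)) return("proportions must lie in [0,1]")
  if (object@chromLength < 1L || object@nChroms < 1L)
    return("genome shape must be positive")
  if (length(object@enhancerLengthRange) != 2L ||
      any(object@enhancerLengthRange < 1L))
    return("enhancerLengthRange must be two positive lengths")
  if (length(object@plantedKmers) &&
      (any(nchar(names(object@plantedKmers)) != 4L) ||
       any(object@plantedKmers < 1)))
    return("plantedKmers must be named 4-mers with folds >= 1")
  if (nrow(object@markProfiles) != 11L)
    return("markProfiles must describe exactly 11 marks")
  TRUE
})
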