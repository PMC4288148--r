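#' Construct a FrameworkConfig
#'
#' Flavor defaults: \code{"encode"} = hist11 schema, 4 first-layer
#' ensembles of 1000 members, both-classes partitioning, train fraction
#' 0.20, per-dataset min-max normalization; \code{"fantom5"} = seq351,
#' 5 ensembles of 10 members, majority-only, train fraction 0.40, no
#' normalization; \code{"vista"} = seq351, 1 ensemble of 10 members,
#' majority-only, train fraction 0.20, no normalization. \code{nParts} and
#' \code{trainFraction} may be overridden for scaled-down runs; schema,
#' layer count, partition mode and normalization are fixed by the flavor.
#'
#' @param flavor \code{"encode"}, \code{"fantom5"} or \code{"vista"}.
#' @param nParts committee size override.
#' @param trainFraction training fraction override.
#' @param binWidth scanning bin width (default 200 bp).
#' @param vistaPooled single-ensemble aggregator input: pooled vote
#'   fraction (TRUE) or the individual member votes (FALSE, default).
#' @return a \linkS4class{FrameworkConfig}.
#' @export
frameworkConfig <- function(flavor = c("encode", "fantom5", "vista"),
                            nParts = NULL, trainFraction = NULL,
                            binWidth = 200L, vistaPooled = FALSE) {
  flavor <- match.arg(flavor)
  def <- switch(flavor,
    encode  = list(schemaId = "hist11", nFirstLayer = 4L, nParts = 1000L,
                   partitionMode = "both-classes", trainFraction = 0.20,
                   normalize = TRUE),
    fantom5 = list(schemaId = "seq351", nFirstLayer = 5L, nParts = 10L,
                   partitionMode = "majority-only", trainFraction = 0.40,
                   normalize = FALSE),
    vista   = list(schemaId = "seq351", nFirstLayer = 1L, nParts = 10L,
                   partitionMode = "majority-only", trainFraction = 0.20,
                   normalize = FALSE))
  new("FrameworkConfig", flavor = flavor, schemaId = def$schemaId,
      nFirstLayer = def$nFirstLayer,
      nParts = as.integer(nParts %||% def$nParts),
      partitionMode = def$partitionMode,
      trainFraction = trainFraction %||% def$trainFraction,
      normalize = def$normalize, binWidth = as.integer(binWidth),
      vistaPooled = vistaPooled)
}

.frameworkScoreMatrix <- function(ensembles, config, features) {
  if (length(ensembles) == 1L && !config@vistaPooled) {
    votes <- .memberVotes(ensembles[[1]], features)
    colnames(votes) <- sprintf("%s_member_%d", ensembles[[1]]@name,
                               seq_len(ncol(votes)))
    votes
  } else {
    scores <- vapply(ensembles, ensembleConfidence,
                     numeric(nrow(features)), features = features)
    scores <- matrix(scores, nrow = nrow(features))
    colnames(scores) <- vapply(ensembles, function(e) e@name, "")
    scores
  }
}

#' Build a full two-layer framework
#'
#' Trains one SVM committee per training dataset, scores the union of the
#' training rows with every committee to form the second-layer score
#' matrix, and tunes the neural-network aggregator on it by stratified
#' 5-fold cross-validation. With a single first-layer ensemble the
#' aggregator consumes the individual member votes (or the pooled vote
#' fraction if the config says so).
#'
#' @param config a FrameworkConfig.
#' @param trainingSets named list of LabeledDatasets (training portions),
#'   one per first-layer ensemble, schema matching the config.
#' @param grid GridSpec for the member hyperparameter search.
#' @param seed integer RNG seed.
#' @param hiddenCandidates ANN hidden sizes tried (default 1:10).
#' @return list with \code{ensembles}, \code{aggregator}, \code{config}.
#' @export
buildFramework <- function(config, trainingSets, grid = gridSpec(), seed,
                           hiddenCandidates = 1:10) {
  if (length(trainingSets) != config@nFirstLayer)
    stop(sprintf("flavor '%s' requires %d training sets, got %d",
                 config@flavor, config@nFirstLayer, length(trainingSets)))
  if (is.null(names(trainingSets)))
    names(trainingSets) <- sprintf("dataset_%d", seq_along(trainingSets))
  for (ds in trainingSets)
    if (!identical(ds@schemaId, config@schemaId))
      stop("training set schema ", ds@schemaId,
           " does not match config schema ", config@schemaId)
  ensembles <- vector("list", length(trainingSets))
  for (i in seq_along(trainingSets)) {
    ds <- trainingSets[[i]]
    scheme <- partitionDataset(ds, config@partitionMode, config@nParts,
                               seed = seed + 1000L * i)
    ensembles[[i]] <- trainEnsemble(ds, scheme, grid,
                                    seed = seed + 1000L * i,
                                    name = names(trainingSets)[i])
  }
  names(ensembles) <- names(trainingSets)
  unionFeatures <- do.call(rbind, lapply(trainingSets, featureMatrix))
  unionLabels <- unlist(lapply(trainingSets, classLabels),
                        use.names = FALSE)
  scores <- .frameworkScoreMatrix(ensembles, config, unionFeatures)
  aggregator <- tuneAnn(scores, unionLabels,
                        hiddenCandidates = hiddenCandidates,
                        seed = seed + 77L)
  list(ensembles = ensembles, aggregator = aggregator, config = config)
}

#' Score labeled samples through both layers
#'
#' Composition of the committee confidence scores and the aggregator
#' decision; deterministic.
#'
#' @param framework list returned by \code{\link{buildFramework}} (or a
#'   list with ensembles, aggregator, config).
#' @param ds LabeledDataset (or bare feature matrix) matching the schema.
#' @param threshold optional decision-threshold override.
#' @return data.frame with \code{probability} and \code{label} per row.
#' @export
predictSamples <- function(framework, ds, threshold = NULL) {
  features <- if (is(ds, "LabeledDataset")) {
    if (!identical(ds@schemaId, framework$config@schemaId))
      stop("dataset schema ", ds@schemaId, " does not match framework ",
           framework$config@schemaId)
    ds@features
  } else as.matrix(ds)
  scores <- .frameworkScoreMatrix(framework$ensembles, framework$config,
                                  features)
  aggregatePredict(framework$aggregator, scores, threshold = threshold)
}

#' Scan a genome bin by bin and merge positive bins
#'
#' Tiles the genome into fixed-width bins, featurizes every bin (histone
#' path: per-bin mean signal of the 11 marks, min-max scaled over the
#' scanned dataset; sequence path: the 351 composition attributes of the
#' bin sequence), scores each bin through both layers, and merges
#' adjacent (bookended) positive bins into predicted regions. Each
#' region's score is the mean probability of its constituent bins.
#'
#' @param framework list from \code{\link{buildFramework}}.
#' @param inputs named list of \linkS4class{SignalTrack} (hist11 schema)
#'   or a DNAStringSet of chromosome sequences (seq351 schema).
#' @param genome named integer vector of chromosome lengths.
#' @param threshold optional decision-threshold override.
#' @return a \linkS4class{PredictionSet}.
#' @export
scanGenome <- function(framework, inputs, genome, threshold = NULL) {
  config <- framework$config
  bins <- makeBins(genome, config@binWidth)
  features <- if (config@schemaId == "hist11") {
    bfm <- histoneFeatureMatrix(inputs, bins)
    if (config@normalize) bfm <- minmaxNormalize(bfm)
    binValues(bfm)
  } else {
    sequenceFeatureMatrix(extractRegions(inputs, bins))
  }
  rownames(features) <- NULL
  pred <- predictSamples(framework, features, threshold = threshold)
  posIdx <- which(pred$label == 1L)
  if (!length(posIdx)) {
    regions <- GRanges()
  } else {
    posBins <- bins[posIdx]
    regions <- GenomicRanges::reduce(posBins)  # merges bookended bins
    hits <- findOverlaps(posBins, regions)
    mcols(regions)$score <- as.numeric(
      tapply(pred$probability[posIdx][queryHits(hits)],
             subjectHits(hits), mean))
  }
  tb <- if (length(regions)) totalBp(regions) else 0
  new("PredictionSet", regions = regions, totalBp = tb,
      genomeFraction = tb / sum(as.numeric(genome)))
}
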