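#' Construct a LabeledDataset
#'
#' @param features numeric matrix, rows x attributes.
#' @param labels binary vector (1 = enhancer).
#' @param ids optional row identifiers (default row names or row_i).
#' @param schemaId \code{"hist11"} or \code{"seq351"}.
#' @return a \linkS4class{LabeledDataset}.
#' @export
labeledDataset <- function(features, labels, ids = NULL, schemaId) {
  if (is.null(ids))
    ids <- if (!is.null(rownames(features))) rownames(features)
           else sprintf("row_%d", seq_len(nrow(features)))
  new("LabeledDataset", ids = as.character(ids), features = features,
      labels = as.integer(labels), schemaId = schemaId)
}

.subsetDataset <- function(ds, idx) {
  new("LabeledDataset", ids = ds@ids[idx],
      features = ds@features[idx, , drop = FALSE],
      labels = ds@labels[idx], schemaId = ds@schemaId)
}

#' Sample negative bins avoiding exclusion regions
#'
#' Draws \code{ratio} times the number of positive bins uniformly without
#' replacement from the bin universe, after removing every bin that
#' overlaps the exclusion set (typically annotated enhancers and
#' promoters) by at least 1 bp.
#'
#' @param positiveBins GRanges of positive (enhancer) bins.
#' @param allBins GRanges bin universe.
#' @param exclusions GRanges never to be sampled from.
#' @param ratio negatives per positive (default 10).
#' @param seed integer RNG seed.
#' @return GRanges of sampled negative bins.
#' @export
sampleNegativeBins <- function(positiveBins, allBins, exclusions,
                               ratio = 10L, seed) {
  h <- .harmonize(allBins, exclusions)
  eligible <- h$x[countOverlaps(h$x, h$y, ignore.strand = TRUE) == 0L]
  n <- ratio * length(positiveBins)
  if (length(eligible) < n)
    stop(sprintf("eligible bin pool too small: need %d, have %d (short %d)",
                 n, length(eligible), n - length(eligible)))
  set.seed(seed)
  eligible[sort(sample.int(length(eligible), n))]
}

#' Sample length-matched negative regions
#'
#' Region lengths are drawn by resampling (with replacement) from the
#' positive length multiset, then the positive minimum and maximum lengths
#' are forced to appear at least once, so the negative set matches the
#' positives' minimum and maximum exactly and the mean closely. Start
#' positions are uniform over the genome; draws overlapping the exclusion
#' set are rejected and redrawn.
#'
#' @param positives GRanges of positive regions (non-empty).
#' @param genome named integer vector of chromosome lengths.
#' @param exclusions GRanges that negatives must not overlap.
#' @param ratio negatives per positive (default 10).
#' @param seed integer RNG seed.
#' @param maxDraws cap on total rejection-sampling draws (default
#'   1000 x the requested count).
#' @return GRanges of sampled negative regions.
#' @export
sampleNegativeRegions <- function(positives, genome, exclusions,
                                  ratio = 10L, seed, maxDraws = NULL) {
  if (!length(positives)) stop("positives must be non-empty")
  n <- ratio * length(positives)
  if (is.null(maxDraws)) maxDraws <- 1000L * n
  posLens <- width(positives)
  set.seed(seed)
  lens <- sample(posLens, n, replace = TRUE)
  if (!min(posLens) %in% lens) lens[1L] <- min(posLens)
  if (!max(posLens) %in% lens) lens[2L] <- max(posLens)
  excl <- .chromTable(.mergeSet(exclusions))
  chromNames <- names(genome)
  outChrom <- character(n); outStart <- integer(n)
  draws <- 0L
  for (i in seq_len(n)) {
    len <- lens[i]
    repeat {
      draws <- draws + 1L
      if (draws > maxDraws)
        stop(sprintf(
          "rejection sampling exceeded %d draws (%d of %d regions placed)",
          maxDraws, i - 1L, n))
      fit <- pmax(genome - len + 1L, 0L)
      chrom <- sample(chromNames, 1L, prob = fit)
      st <- sample.int(fit[[chrom]], 1L)
      if (!.hitsTable(excl, chrom, st, st + len - 1L)) break
    }
    outChrom[i] <- chrom; outStart[i] <- st
  }
  out <- GRanges(outChrom, IRanges(outStart, width = lens))
  seqlevels(out) <- chromNames
  out
}

## per-chromosome start/end coordinate lists for fast scalar overlap tests
.chromTable <- function(gr) {
  chroms <- as.character(seqnames(gr))
  lapply(split(data.frame(s = start(gr), e = end(gr)), chroms),
         function(d) d[order(d$s), , drop = FALSE])
}

.hitsTable <- function(tab, chrom, st, en) {
  d <- tab[[chrom]]
  !is.null(d) && any(d$s <= en & d$e >= st)
}

#' Partition a dataset into disjoint learning subsets
#'
#' \code{"both-classes"}: positives and negatives are independently
#' shuffled and split into \code{nParts} near-equal disjoint subsets;
#' learning subset k is positive part k plus negative part k, preserving
#' the overall class ratio in every subset. \code{"majority-only"}: only
#' negatives are split; every learning subset contains all positives.
#' Remainder rows when a class size is not divisible by \code{nParts} go
#' to the last parts, one each.
#'
#' @param ds a LabeledDataset.
#' @param mode \code{"both-classes"} or \code{"majority-only"}.
#' @param nParts number of committee members.
#' @param seed integer RNG seed.
#' @return a \linkS4class{PartitionScheme}.
#' @export
partitionDataset <- function(ds, mode = c("both-classes", "majority-only"),
                             nParts, seed) {
  mode <- match.arg(mode)
  nParts <- as.integer(nParts)
  pos <- which(ds@labels == 1L); neg <- which(ds@labels == 0L)
  if (mode == "both-classes" && length(pos) < nParts)
    stop(sprintf("both-classes mode needs >= %d positives, have %d",
                 nParts, length(pos)))
  if (length(neg) < nParts)
    stop(sprintf("need >= %d negatives, have %d", nParts, length(neg)))
  set.seed(seed)
  splitClass <- function(idx) {
    idx <- sample(idx)
    base <- length(idx) %/% nParts
    rem <- length(idx) %% nParts
    sizes <- rep(base, nParts)
    if (rem > 0)  # remainder rows to the last parts, one each
      sizes[(nParts - rem + 1L):nParts] <- base + 1L
    parts <- rep(seq_len(nParts), times = sizes)
    stats::setNames(parts, idx)
  }
  assignments <- integer(nrow(ds@features))
  negParts <- splitClass(neg)
  assignments[as.integer(names(negParts))] <- negParts
  if (mode == "both-classes") {
    posParts <- splitClass(pos)
    assignments[as.integer(names(posParts))] <- posParts
  } else {
    assignments[pos] <- 0L
  }
  new("PartitionScheme", mode = mode, nParts = nParts,
      assignments = assignments)
}

#' Extract one learning subset defined by a partition scheme
#'
#' @param ds the LabeledDataset the scheme was built for.
#' @param scheme a PartitionScheme.
#' @param part part index, 1..nParts.
#' @return LabeledDataset of the learning subset.
#' @export
learningSubset <- function(ds, scheme, part) {
  if (part < 1L || part > scheme@nParts) stop("part out of range")
  idx <- if (scheme@mode == "majority-only")
    which(scheme@assignments == part | ds@labels == 1L)
  else which(scheme@assignments == part)
  .subsetDataset(ds, idx)
}

#' Stratified train/test split
#'
#' Splits each class independently so both sides preserve the class ratio;
#' deterministic given the seed.
#'
#' @param ds a LabeledDataset.
#' @param trainFraction proportion of each class assigned to training
#'   (0 < f < 1); the histone-mark flavor default is 0.20, the
#'   tissue-sequence flavor default 0.40.
#' @param seed integer RNG seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
trainTestSplit <- function(ds, trainFraction, seed) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0,1)")
  set.seed(seed)
  trainIdx <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(ds@labels == cls)
    if (length(idx) < 2L)
      stop("each class needs >= 2 samples to split; class ", cls,
           " has ", length(idx))
    nTrain <- max(1L, min(length(idx) - 1L,
                          round(trainFraction * length(idx))))
    trainIdx <- c(trainIdx, sample(idx, nTrain))
  }
  trainIdx <- sort(trainIdx)
  list(train = .subsetDataset(ds, trainIdx),
       test = .subsetDataset(ds, setdiff(seq_along(ds@labels), trainIdx)))
}

.rowKeys <- function(m) {
  apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
}

#' Drop training positives with feature vectors identical to test positives
#'
#' Removes from the training set every enhancer row whose feature vector
#' is exactly equal, attribute by attribute, to some enhancer row of the
#' test set (a leakage guard for exactly duplicated regions).
#'
#' @param train,test LabeledDatasets with matching schemas.
#' @return the filtered training LabeledDataset.
#' @export
dropDuplicateFeatureRows <- function(train, test) {
  if (!identical(train@schemaId, test@schemaId))
    stop("schema mismatch: ", train@schemaId, " vs ", test@schemaId)
  testKeys <- .rowKeys(test@features[test@labels == 1L, , drop = FALSE])
  pos <- which(train@labels == 1L)
  if (!length(pos) || !length(testKeys)) return(train)
  trainKeys <- .rowKeys(train@features[pos, , drop = FALSE])
  drop <- pos[trainKeys %in% testKeys]
  if (!length(drop)) return(train)
  .subsetDataset(train, setdiff(seq_along(train@labels), drop))
}

#' Serialize / load a LabeledDataset as a TSV directory
#'
#' Writes \code{features.tsv}, \code{labels.tsv} and a plain-text
#' \code{manifest.txt} (schema id and provenance).
#'
#' @param ds a LabeledDataset.
#' @param dir directory path (created if absent).
#' @export
writeDataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- ds@features
  rownames(m) <- ds@ids
  writeFeatureMatrix(m, file.path(dir, "features.tsv"))
  utils::write.table(data.frame(id = ds@ids, label = ds@labels),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("schema_id\t%s", ds@schemaId),
               sprintf("n_rows\t%d", length(ds@ids)),
               sprintf("n_attributes\t%d", ncol(ds@features))),
             file.path(dir, "manifest.txt"))
}

#' @rdname writeDataset
#' @return \code{readDataset}: the LabeledDataset.
#' @export
readDataset <- function(dir) {
  m <- readFeatureMatrix(file.path(dir, "features.tsv"))
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  manifest <- utils::read.delim(file.path(dir, "manifest.txt"),
                                header = FALSE)
  schemaId <- manifest$V2[manifest$V1 == "schema_id"]
  stopifnot(identical(as.character(lab$id), rownames(m)))
  labeledDataset(m, lab$label, ids = rownames(m), schemaId = schemaId)
}
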