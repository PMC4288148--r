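#' Default per-mark signal profiles
#'
#' Enhancer-associated marks (H3K4me1, H3K27ac) carry large amplitude at
#' enhancers; promoter-associated marks (H3K4me3, H3K9ac, H3K4me2) at the
#' decoy promoters; repressive/transcription marks are pure noise. Units
#' are arbitrary signal units over a truncated-Gaussian noise floor of
#' standard deviation 1.
#'
#' @return data.frame with columns mark, enhancerAmp, promoterAmp, noiseSd
#'   (11 rows, schema order).
#' @export
defaultMarkProfiles <- function() {
  data.frame(
    mark = histFeatureSchema(),
    enhancerAmp = c(1.5, 4, 0, 0, 4, 1.5, 0.5, 0, 1, 0, 0),
    promoterAmp = c(1.5, 1, 0, 0, 0.5, 2, 4, 1, 2, 0, 0),
    noiseSd = rep(1, 11))
}

#' Construct a SynthSpec
#'
#' Defaults describe a desk-scale testbed: a 2 x 120 kb genome, 15
#' enhancers of 600-1000 bp per dataset with GC raised from a 0.41
#' background to 0.56 and a CGCG 4-mer planted at 5-fold enrichment,
#' decoy promoters at GC 0.50, 5 datasets sharing half their enhancers.
#'
#' @param nChroms,chromLength genome shape.
#' @param nEnhancers enhancers per dataset.
#' @param enhancerLengthRange bp range (uniform).
#' @param gcBackground,gcEnhancer,gcPromoter GC proportions.
#' @param plantedKmers named numeric: 4-mer -> enrichment fold.
#' @param markProfiles 11-row data.frame (see
#'   \code{\link{defaultMarkProfiles}}).
#' @param nDatasets number of cell-line / tissue replicas.
#' @param sharing fraction of enhancers shared across datasets.
#' @param seed integer.
#' @return a \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(nChroms = 2L, chromLength = 120000L,
                      nEnhancers = 15L, enhancerLengthRange = c(600L, 1000L),
                      gcBackground = 0.41, gcEnhancer = 0.56,
                      gcPromoter = 0.50, plantedKmers = c(CGCG = 5),
                      markProfiles = defaultMarkProfiles(),
                      nDatasets = 5L, sharing = 0.5, seed = 0L) {
  new("SynthSpec", nChroms = as.integer(nChroms),
      chromLength = as.integer(chromLength),
      nEnhancers = as.integer(nEnhancers),
      enhancerLengthRange = as.integer(enhancerLengthRange),
      gcBackground = gcBackground, gcEnhancer = gcEnhancer,
      gcPromoter = gcPromoter, plantedKmers = plantedKmers,
      markProfiles = markProfiles, nDatasets = as.integer(nDatasets),
      sharing = sharing, seed = as.integer(seed))
}

.randomBases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a random genome
#'
#' I.i.d. bases at the background GC proportion; deterministic per seed.
#'
#' @param spec a SynthSpec.
#' @return list with \code{sequences} (DNAStringSet) and \code{sizes}
#'   (named integer vector).
#' @export
makeGenome <- function(spec) {
  set.seed(spec@seed)
  chroms <- sprintf("chr%d", seq_len(spec@nChroms))
  seqs <- DNAStringSet(vapply(chroms, function(chrom)
    paste(.randomBases(spec@chromLength, spec@gcBackground),
          collapse = ""), ""))
  names(seqs) <- chroms
  list(sequences = seqs,
       sizes = stats::setNames(rep(spec@chromLength, spec@nChroms),
                               chroms))
}

## place n non-overlapping regions with >= gap bp between any two placed
## regions (enhancers and decoys alike)
.placeRegions <- function(sizes, lens, gap = 1000L, maxTries = 10000L) {
  n <- length(lens)
  chroms <- character(n); starts <- integer(n)
  placed <- lapply(sizes, function(.) list(s = integer(0), e = integer(0)))
  for (i in seq_len(n)) {
    len <- lens[i]
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("genome too small to place all regions with the required gap")
      fit <- pmax(sizes - len + 1L, 0L)
      chrom <- sample(names(sizes), 1L, prob = fit)
      st <- sample.int(fit[[chrom]], 1L)
      p <- placed[[chrom]]
      ## enforce >= gap bp between any two placed regions
      if (!any(p$s <= st + len - 1L + gap & p$e >= st - gap)) break
    }
    chroms[i] <- chrom; starts[i] <- st
    placed[[chrom]]$s <- c(placed[[chrom]]$s, st)
    placed[[chrom]]$e <- c(placed[[chrom]]$e, st + len - 1L)
  }
  out <- GRanges(chroms, IRanges(starts, width = lens))
  seqlevels(out) <- names(sizes)
  out
}

.kmerBackgroundProb <- function(kmer, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  prod(p[strsplit(kmer, "")[[1]]])
}

.rewriteSegment <- function(chromChars, gr1, gc, plantedKmers = NULL,
                            foldBaseGc = NULL) {
  st <- start(gr1); en <- end(gr1); len <- en - st + 1L
  seg <- .randomBases(len, gc)
  if (!is.null(plantedKmers) && length(plantedKmers)) {
    for (kmer in names(plantedKmers)) {
      k <- nchar(kmer)
      copies <- ceiling(plantedKmers[[kmer]] *
                          .kmerBackgroundProb(kmer, foldBaseGc) *
                          (len - k + 1L))
      at <- sample.int(len - k + 1L, copies, replace = FALSE)
      for (a in at) seg[a:(a + k - 1L)] <- strsplit(kmer, "")[[1]]
    }
  }
  chromChars[st:en] <- seg
  chromChars
}

#' Plant enhancers and decoy promoters into a genome
#'
#' Rewrites \code{n} enhancer segments at the enhancer GC proportion with
#' the configured 4-mers planted at their enrichment fold over the background
#' rate, and \code{nPromoters} decoy promoter segments at a distinct
#' composition. All placed regions are pairwise separated by at least
#' 1 kb.
#'
#' @param genome list from \code{\link{makeGenome}}.
#' @param spec a SynthSpec.
#' @param n number of enhancers (default \code{spec@nEnhancers}).
#' @param nPromoters number of decoy promoters (default
#'   \code{spec@nEnhancers}).
#' @param promoterLength bp (default 500).
#' @param seed integer RNG seed (default \code{spec@seed + 1}).
#' @return list with \code{sequences} (modified DNAStringSet),
#'   \code{enhancers} and \code{promoters} (disjoint GRanges).
#' @export
plantEnhancers <- function(genome, spec, n = spec@nEnhancers,
                           nPromoters = spec@nEnhancers,
                           promoterLength = 500L,
                           seed = spec@seed + 1L) {
  set.seed(seed)
  lens <- c(sample(seq(spec@enhancerLengthRange[1],
                       spec@enhancerLengthRange[2]), n, replace = TRUE),
            rep(promoterLength, nPromoters))
  placed <- .placeRegions(genome$sizes, lens)
  enhancers <- placed[seq_len(n)]
  promoters <- placed[n + seq_len(nPromoters)]
  chars <- lapply(as.character(genome$sequences),
                  function(s) strsplit(s, "")[[1]])
  rewriteAll <- function(chars, gr, gc, kmers = NULL) {
    for (i in seq_along(gr)) {
      chrom <- as.character(seqnames(gr))[i]
      chars[[chrom]] <- .rewriteSegment(chars[[chrom]], gr[i], gc,
                                        kmers, spec@gcBackground)
    }
    chars
  }
  chars <- rewriteAll(chars, enhancers, spec@gcEnhancer, spec@plantedKmers)
  chars <- rewriteAll(chars, promoters, spec@gcPromoter)
  seqs <- DNAStringSet(vapply(chars, paste, "", collapse = ""))
  names(seqs) <- names(genome$sequences)
  list(sequences = seqs, enhancers = sort(enhancers),
       promoters = sort(promoters))
}

#' Simulate the 11 histone-mark signal tracks
#'
#' Per base: Gaussian noise truncated at 0 plus the mark's enhancer
#' amplitude within enhancers and promoter amplitude within decoy
#' promoters. Fully covered; deterministic per seed.
#'
#' @param sizes named integer vector of chromosome lengths.
#' @param enhancers,promoters GRanges.
#' @param spec a SynthSpec (uses \code{markProfiles}).
#' @param seed integer RNG seed (default \code{spec@seed + 2}).
#' @param ampFactor multiplicative jitter on the amplitudes (default 1).
#' @return named list of \linkS4class{SignalTrack}, one per mark.
#' @export
makeHistoneTracks <- function(sizes, enhancers, promoters, spec,
                              seed = spec@seed + 2L, ampFactor = 1) {
  set.seed(seed)
  prof <- spec@markProfiles
  masks <- lapply(list(enh = enhancers, prom = promoters), function(gr) {
    lapply(names(sizes), function(chrom) {
      v <- logical(sizes[[chrom]])
      sel <- which(as.character(seqnames(gr)) == chrom)
      for (i in sel) v[start(gr)[i]:end(gr)[i]] <- TRUE
      v
    })
  })
  tracks <- lapply(seq_len(nrow(prof)), function(j) {
    vals <- list(); cov <- list()
    for (ci in seq_along(sizes)) {
      chrom <- names(sizes)[ci]
      L <- sizes[[chrom]]
      v <- pmax(stats::rnorm(L, 0, prof$noiseSd[j]), 0)
      v <- v + ampFactor * prof$enhancerAmp[j] * masks$enh[[ci]] +
        ampFactor * prof$promoterAmp[j] * masks$prom[[ci]]
      vals[[chrom]] <- Rle(v)
      cov[[chrom]] <- Rle(rep(TRUE, L))
    }
    new("SignalTrack", values = RleList(vals, compress = FALSE),
        covered = RleList(cov, compress = FALSE))
  })
  stats::setNames(tracks, prof$mark)
}

#' Generate a multi-dataset collection
#'
#' Builds one genome, plants a pool of enhancers such that every dataset
#' holds \code{nEnhancers} of which a \code{sharing} fraction is common to
#' all datasets and the remainder is private, plus one shared set of decoy
#' promoters. For the histone flavor each dataset gets its own 11 signal
#' tracks (amplitudes jittered by roughly 10 percent per dataset); for the
#' sequence flavors the planted genome sequence itself carries the signal.
#'
#' @param spec a SynthSpec.
#' @param flavor \code{"encode"}, \code{"fantom5"} or \code{"vista"}.
#' @return list with \code{sequences}, \code{sizes}, \code{enhancerPool},
#'   \code{promoters}, \code{flavor} and \code{datasets} (named list; each
#'   element has \code{enhancers} and, for the histone flavor,
#'   \code{tracks}).
#' @export
makeMultiDatasets <- function(spec,
                              flavor = c("encode", "fantom5", "vista")) {
  flavor <- match.arg(flavor)
  nShared <- round(spec@sharing * spec@nEnhancers)
  nPrivate <- spec@nEnhancers - nShared
  poolSize <- nShared + spec@nDatasets * nPrivate
  genome <- makeGenome(spec)
  planted <- plantEnhancers(genome, spec, n = poolSize,
                            nPromoters = spec@nEnhancers)
  pool <- planted$enhancers
  shared <- if (nShared > 0) pool[seq_len(nShared)] else GRanges()
  datasets <- list()
  for (i in seq_len(spec@nDatasets)) {
    priv <- if (nPrivate > 0)
      pool[nShared + (i - 1L) * nPrivate + seq_len(nPrivate)]
    else GRanges()
    enh <- sort(suppressWarnings(c(shared, priv)))
    entry <- list(enhancers = enh)
    if (flavor == "encode") {
      set.seed(spec@seed + 500L + i)
      amp <- stats::runif(1, 0.9, 1.1)
      entry$tracks <- makeHistoneTracks(genome$sizes, enh,
                                        planted$promoters, spec,
                                        seed = spec@seed + 600L + i,
                                        ampFactor = amp)
    }
    datasets[[sprintf("dataset_%d", i)]] <- entry
  }
  list(sequences = planted$sequences, sizes = genome$sizes,
       enhancerPool = pool, promoters = planted$promoters,
       flavor = flavor, datasets = datasets)
}

#' Materialize a collection as LabeledDatasets
#'
#' Histone flavor: positives are the 200-bp bins overlapping the dataset's
#' enhancers, negatives are sampled bins excluding the entire enhancer
#' pool and the promoters, features are per-bin mean mark signal, min-max
#' scaled per dataset. Sequence flavors: positives are the enhancer
#' regions themselves, negatives are length-matched random regions
#' avoiding the pool and promoters, features are the 351 composition
#' attributes (no scaling).
#'
#' @param collection list from \code{\link{makeMultiDatasets}}.
#' @param ratio negatives per positive (default 10).
#' @param binWidth histone-flavor bin width (default 200).
#' @param seed integer RNG seed.
#' @return named list of \linkS4class{LabeledDataset}.
#' @export
asLabeledDatasets <- function(collection, ratio = 10L, binWidth = 200L,
                              seed) {
  exclusions <- suppressWarnings(c(collection$enhancerPool,
                                   collection$promoters))
  out <- list()
  for (i in seq_along(collection$datasets)) {
    entry <- collection$datasets[[i]]
    name <- names(collection$datasets)[i]
    if (collection$flavor == "encode") {
      bins <- makeBins(collection$sizes, binWidth)
      posBins <- bins[countOverlaps(bins, entry$enhancers,
                                    ignore.strand = TRUE) > 0L]
      negBins <- sampleNegativeBins(posBins, bins, exclusions,
                                    ratio = ratio, seed = seed + i)
      nPos <- length(posBins)
      regions <- suppressWarnings(c(posBins, negBins))
      bfm <- histoneFeatureMatrix(entry$tracks, regions)
      features <- minmaxNormalize(binValues(bfm))
      schema <- "hist11"
    } else {
      pos <- entry$enhancers
      neg <- sampleNegativeRegions(pos, collection$sizes, exclusions,
                                   ratio = ratio, seed = seed + i)
      nPos <- length(pos)
      regions <- suppressWarnings(c(pos, neg))
      features <- sequenceFeatureMatrix(
        extractRegions(collection$sequences, regions))
      rownames(features) <- NULL
      schema <- "seq351"
    }
    labels <- c(rep(1L, nPos), rep(0L, length(regions) - nPos))
    ids <- sprintf("%s:%d-%d", as.character(seqnames(regions)),
                   start(regions) - 1L, end(regions))
    out[[name]] <- labeledDataset(features, labels, ids = ids,
                                  schemaId = schema)
  }
  out
}
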