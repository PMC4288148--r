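#' Mean signal per bin
#'
#' Per-bin mean of the per-base signal; bases without coverage contribute
#' 0 (they hold 0 in the track by construction).
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param bins GRanges of bins lying within the track's genome.
#' @return numeric vector, one mean per bin, in bin order.
#' @export
binSignal <- function(track, bins) {
  chroms <- as.character(seqnames(bins))
  missing <- setdiff(unique(chroms), names(track@values))
  if (length(missing))
    stop("bins on chromosome(s) absent from the signal track: ",
         paste(missing, collapse = ", "))
  out <- numeric(length(bins))
  for (chrom in unique(chroms)) {
    sel <- which(chroms == chrom)
    v <- track@values[[chrom]]
    if (max(end(bins)[sel]) > length(v))
      stop("bins extend beyond chromosome ", chrom)
    out[sel] <- viewMeans(Views(v, start = start(bins)[sel],
                                end = end(bins)[sel]))
  }
  out
}

#' Build the 11-mark binned feature matrix
#'
#' One column per histone mark in schema order, one row per bin; values are
#' per-bin mean signal, unnormalized (see \code{\link{minmaxNormalize}}).
#'
#' @param tracks named list of \linkS4class{SignalTrack}, one per mark.
#' @param bins GRanges of uniform bins.
#' @param schema ordered mark names (default \code{\link{histFeatureSchema}}).
#' @return a \linkS4class{BinFeatureMatrix}, unnormalized.
#' @export
histoneFeatureMatrix <- function(tracks, bins, schema = histFeatureSchema()) {
  missing <- setdiff(schema, names(tracks))
  if (length(missing))
    stop("missing signal track(s) for mark(s): ",
         paste(missing, collapse = ", "))
  values <- vapply(schema, function(mark) binSignal(tracks[[mark]], bins),
                   numeric(length(bins)))
  values <- matrix(values, nrow = length(bins),
                   dimnames = list(NULL, schema))
  new("BinFeatureMatrix", bins = bins, values = values, normalized = FALSE)
}

.minmaxMatrix <- function(m) {
  if (!length(m)) stop("cannot normalize an empty matrix")
  apply(m, 2L, function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, length(v))
  })
}

#' @describeIn minmaxNormalize scale each column of a plain matrix
#' @export
setMethod("minmaxNormalize", "matrix", function(x) {
  out <- .minmaxMatrix(x)
  dimnames(out) <- dimnames(x)
  out
})

#' @describeIn minmaxNormalize scale a BinFeatureMatrix (error if already
#'   normalized)
#' @export
setMethod("minmaxNormalize", "BinFeatureMatrix", function(x) {
  if (isTRUE(x@normalized)) stop("matrix is already normalized")
  new("BinFeatureMatrix", bins = x@bins,
      values = minmaxNormalize(x@values), normalized = TRUE)
})

#' Export a binned matrix as headered TSV with bin coordinates
#'
#' @param x a BinFeatureMatrix.
#' @param path file path.
#' @export
writeBinMatrix <- function(x, path) {
  df <- data.frame(chrom = as.character(seqnames(x@bins)),
                   start = start(x@bins) - 1L, end = end(x@bins),
                   x@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeBinMatrix
#' @param normalized flag recorded on the re-imported object.
#' @return \code{readBinMatrix}: the BinFeatureMatrix.
#' @export
readBinMatrix <- function(path, normalized = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE)
  bins <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  new("BinFeatureMatrix", bins = bins, values = vals,
      normalized = normalized)
}
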