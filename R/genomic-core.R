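#' @importFrom GenomicRanges GRanges reduce findOverlaps pintersect width
#'   start end seqnames countOverlaps
#' @importFrom IRanges IRanges Views viewMeans RleList subsetByOverlaps
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<-
#'   seqnames<-
#' @importFrom S4Vectors Rle queryHits subjectHits runValue mcols mcols<-
#' @importFrom Biostrings readDNAStringSet DNAStringSet
NULL

## put two region sets on a common seqlevel universe so set operations
## never warn about disjoint sequence universes
.harmonize <- function(x, y) {
  lv <- union(seqlevels(x), seqlevels(y))
  seqlevels(x) <- lv
  seqlevels(y) <- lv
  list(x = x, y = y)
}

.mergeSet <- function(x) GenomicRanges::reduce(x, ignore.strand = TRUE)

#' Read a two-column chromosome-size table
#'
#' @param path text file with chromosome name and length per line.
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  if (any(tab$length <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(as.integer(tab$length), tab$chrom)
}

#' Write a chromosome-size table
#'
#' @param genome named integer vector of chromosome lengths.
#' @param path output path.
#' @export
writeChromSizes <- function(genome, path) {
  utils::write.table(data.frame(names(genome), unname(genome)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BED3+ file into a GRanges
#'
#' BED coordinates are 0-based half-open; the returned GRanges follows the
#' usual 1-based closed convention, so a BED line \code{chr1 0 200} becomes
#' \code{chr1:1-200}. \code{track}, \code{browser} and \code{#} lines are
#' skipped. Malformed lines (fewer than 3 columns, non-integer or negative
#' coordinates, end <= start) raise an error naming the line.
#'
#' @param path BED file path.
#' @return GRanges (strandless).
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("line %d: fewer than 3 tab-separated columns",
                 idx[which(nf < 3L)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(s) | !is.finite(e) | s != floor(s) | e != floor(e))
  if (length(bad))
    stop(sprintf("line %d: non-integer coordinates", idx[bad[1]]))
  if (any(s < 0))
    stop(sprintf("line %d: negative start", idx[which(s < 0)[1]]))
  bad <- which(e <= s)
  if (length(bad))
    stop(sprintf("line %d: zero- or negative-length interval (end <= start)",
                 idx[bad[1]]))
  GRanges(chrom, IRanges(s + 1, e))
}

#' Write a GRanges as BED3 (plus optional name/score columns)
#'
#' Inverse of \code{\link{readBed}}: start coordinates are shifted back to
#' the 0-based half-open convention. If the input carries a numeric
#' \code{score} metadata column in [0,1] it is written to BED column 5
#' scaled to 0-1000, with column 4 a running region name.
#'
#' @param gr GRanges.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(mcols(gr)$score)) {
    df$name <- sprintf("region_%d", seq_along(gr))
    df$score <- as.integer(round(1000 * pmin(pmax(mcols(gr)$score, 0), 1)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a FASTA file
#'
#' Sequence names are the first whitespace token of each header; letters
#' are uppercased. Duplicate record names are an error (ambiguous
#' addressing).
#'
#' @param path FASTA path.
#' @return DNAStringSet.
#' @export
readFasta <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' Write a DNAStringSet as FASTA
#'
#' @param seqs DNAStringSet.
#' @param path output path.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 70L)
}

#' Read a bedGraph or wiggle signal track
#'
#' Accepts 4-column bedGraph or fixedStep/variableStep wiggle (the text
#' dialects of genome-wide signal). Bases not covered by any record are
#' flagged uncovered and hold value 0; where records overlap, the last
#' record in file order wins.
#'
#' @param path signal file path; format inferred from the extension
#'   (\code{.bedGraph}/\code{.bg} vs \code{.wig}) or forced via
#'   \code{format}.
#' @param genome named integer vector of chromosome lengths.
#' @param format NULL, \code{"bedGraph"} or \code{"wig"}.
#' @return a \linkS4class{SignalTrack}.
#' @export
readSignal <- function(path, genome, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedGraph" else "wig"
  }
  gr <- rtracklayer::import(path, format = format)
  chroms <- as.character(seqnames(gr))
  unknown <- setdiff(unique(chroms), names(genome))
  if (length(unknown))
    stop("signal records on chromosome(s) absent from the genome table: ",
         paste(unknown, collapse = ", "))
  over <- tapply(end(gr), chroms, max)
  bad <- names(over)[over > genome[names(over)]]
  if (length(bad))
    stop("signal record beyond chromosome length on: ",
         paste(bad, collapse = ", "))
  signalTrackFromRanges(gr, genome)
}

#' Build a SignalTrack from scored ranges
#'
#' @param gr GRanges with a numeric \code{score} column.
#' @param genome named integer vector of chromosome lengths; every
#'   chromosome gets a track (fully uncovered when no record touches it).
#' @return a \linkS4class{SignalTrack}.
#' @export
signalTrackFromRanges <- function(gr, genome) {
  vals <- list(); cov <- list()
  chroms <- as.character(seqnames(gr))
  for (chrom in names(genome)) {
    L <- genome[[chrom]]
    v <- numeric(L); m <- logical(L)
    sel <- which(chroms == chrom)
    for (i in sel) {  # file order: last record wins on overlap
      span <- start(gr)[i]:end(gr)[i]
      v[span] <- mcols(gr)$score[i]
      m[span] <- TRUE
    }
    vals[[chrom]] <- Rle(v); cov[[chrom]] <- Rle(m)
  }
  new("SignalTrack", values = RleList(vals, compress = FALSE),
      covered = RleList(cov, compress = FALSE))
}

#' Write a SignalTrack as bedGraph
#'
#' Only covered runs are written.
#' @param track a SignalTrack.
#' @param path output path.
#' @export
writeSignal <- function(track, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (chrom in names(track@values)) {
    v <- track@values[[chrom]]
    m <- track@covered[[chrom]]
    ## segment on the union of value and coverage runs
    both <- S4Vectors::Rle(paste(as.vector(v), as.vector(m)))
    ends <- cumsum(S4Vectors::runLength(both))
    starts <- c(1L, head(ends, -1L) + 1L)
    vv <- as.vector(v)[starts]; mm <- as.vector(m)[starts]
    keep <- which(mm)
    if (length(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep] - 1L,
                         ends[keep], format(vv[keep], trim = TRUE)), con)
  }
  invisible(NULL)
}

#' Tile a genome into fixed-width bins
#'
#' Non-overlapping tiling per chromosome; a trailing partial bin shorter
#' than \code{width} is dropped so every bin is exactly \code{width} bp.
#'
#' @param genome named integer vector of chromosome lengths.
#' @param width bin width in bp (framework default 200).
#' @return GRanges of \code{floor(L / width)} bins per chromosome.
#' @export
makeBins <- function(genome, width = 200L) {
  if (length(width) != 1L || width <= 0) stop("width must be positive")
  width <- as.integer(width)
  nPer <- genome %/% width
  starts <- unlist(lapply(nPer, function(n)
    if (n > 0L) seq.int(1L, by = width, length.out = n) else integer(0)),
    use.names = FALSE)
  ans <- GRanges(rep(names(genome), nPer), IRanges(starts, width = width),
                 seqlengths = genome)
  seqlevels(ans) <- names(genome)
  ans
}

#' Bases in the intersection of two region sets
#'
#' Both sets are merged internally; returns total bases covered by both.
#' Symmetric in its arguments.
#'
#' @param x,y GRanges.
#' @return numeric bp count.
#' @export
overlapBp <- function(x, y) {
  h <- .harmonize(x, y)
  sum(as.numeric(width(GenomicRanges::intersect(
    .mergeSet(h$x), .mergeSet(h$y), ignore.strand = TRUE))))
}

#' @describeIn totalBp bases covered by the merged GRanges
#' @export
setMethod("totalBp", "GRanges", function(x) {
  sum(as.numeric(width(.mergeSet(x))))
})

#' Merged intersection of two region sets
#'
#' Covers exactly the bases covered by both inputs.
#' @param x,y GRanges.
#' @return merged GRanges.
#' @export
intersectIntervals <- function(x, y) {
  h <- .harmonize(x, y)
  GenomicRanges::intersect(.mergeSet(h$x), .mergeSet(h$y),
                           ignore.strand = TRUE)
}

#' Remove test regions that overlap training regions
#'
#' Keeps the test intervals whose total overlap with the union of the
#' training set is below \code{minOverlap} base pairs; with the default
#' (1 bp) any test region sharing at least one base with a training region
#' is removed.
#'
#' @param test,train GRanges.
#' @param minOverlap minimum bp of overlap that triggers removal (>= 1).
#' @return filtered test GRanges.
#' @export
filterOverlapping <- function(test, train, minOverlap = 1L) {
  if (minOverlap < 1L) stop("minOverlap must be >= 1")
  if (!length(train) || !length(test)) return(test)
  h <- .harmonize(test, .mergeSet(train))
  ov <- findOverlaps(h$x, h$y, ignore.strand = TRUE)
  if (!length(ov)) return(test)
  w <- width(pintersect(h$x[queryHits(ov)], h$y[subjectHits(ov)]))
  perQuery <- tapply(w, queryHits(ov), sum)
  drop <- as.integer(names(perQuery))[perQuery >= minOverlap]
  test[setdiff(seq_along(test), drop)]
}

#' Extract region sequences from a genome
#'
#' @param seqs DNAStringSet of chromosome sequences.
#' @param gr GRanges within those chromosomes.
#' @return DNAStringSet, one sequence per range.
#' @export
extractRegions <- function(seqs, gr) {
  chroms <- as.character(seqnames(gr))
  missing <- setdiff(unique(chroms), names(seqs))
  if (length(missing))
    stop("chromosome(s) absent from the sequence set: ",
         paste(missing, collapse = ", "))
  out <- DNAStringSet(rep("", length(gr)))
  for (chrom in unique(chroms)) {
    sel <- which(chroms == chrom)
    out[sel] <- Biostrings::extractAt(
      seqs[[chrom]], IRanges(start(gr)[sel], end(gr)[sel]))
  }
  names(out) <- sprintf("%s:%d-%d", chroms, start(gr) - 1L, end(gr))
  out
}
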