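#' @importFrom Biostrings oligonucleotideFrequency letterFrequency
#'   vcountPattern DNAString
NULL

.BASES <- c("A", "C", "G", "T")

.kmerNames <- function(k) {
  grid <- expand.grid(rep(list(.BASES), k), stringsAsFactors = FALSE)
  ## lexicographic AA.. < .. < TT..: vary last position fastest
  apply(grid[, rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
}

#' The 351-attribute sequence feature schema
#'
#' Ordered attribute names: 4 mononucleotide, 16 dinucleotide, 64
#' trinucleotide and 256 tetranucleotide frequencies (lexicographic over
#' A/C/G/T), a CpG-island indicator, the C+G and A+T aggregate
#' frequencies, the sequence length, the count of unambiguous bases, and
#' six composition attributes derived from the preceding blocks
#' (CpG observed/expected ratio, GC skew, AT skew, purine fraction, keto
#' fraction, and the C+G minus A+T frequency difference).
#'
#' @return character vector of 351 names, with a \code{blocks} attribute
#'   giving the index range of each block.
#' @export
seqFeatureSchema <- function() {
  nm <- c(unlist(lapply(1:4, .kmerNames)),
          "cpg_island", "cg_content", "at_content",
          "seq_length", "n_bp",
          "cpg_obs_exp", "gc_skew", "at_skew",
          "purine_frac", "keto_frac", "cg_at_diff")
  stopifnot(length(nm) == 351L)
  ends <- cumsum(c(4L, 16L, 64L, 256L, 1L, 2L, 1L, 1L, 6L))
  starts <- c(1L, head(ends, -1L) + 1L)
  attr(nm, "blocks") <- data.frame(
    block = c("mono", "di", "tri", "tetra", "island",
              "aggregates", "length", "bp_count", "combinations"),
    start = starts, end = ends)
  nm
}

#' The 11-mark histone feature schema
#'
#' @return character vector of the 11 histone-modification mark names in
#'   their fixed order.
#' @export
histFeatureSchema <- function() {
  c("H2AFZ", "H3K27ac", "H3K27me3", "H3K36me3", "H3K4me1", "H3K4me2",
    "H3K4me3", "H3K79me2", "H3K9ac", "H3K9me3", "H4K20me1")
}

.asDNAStringSet <- function(seqs) {
  if (is(seqs, "DNAStringSet")) return(seqs)
  ans <- DNAStringSet(toupper(as.character(seqs)))
  names(ans) <- names(seqs)
  ans
}

#' k-mer frequencies of a DNA sequence
#'
#' Counts all length-k windows consisting solely of A/C/G/T (windows
#' containing any other character are excluded from both numerator and
#' denominator) and divides by the number of such valid windows. A
#' sequence with no valid window yields an all-zero vector.
#'
#' @param seq character or DNAString(Set); a single sequence.
#' @param k word size, 1 to 4.
#' @return named numeric vector of 4^k frequencies, lexicographic order.
#' @export
kmerFrequencies <- function(seq, k) {
  if (length(k) != 1L || !k %in% 1:4) stop("k must be in 1..4")
  ss <- .asDNAStringSet(if (is(seq, "DNAString")) DNAStringSet(seq) else seq)
  if (length(ss) != 1L) stop("expected a single sequence")
  if (width(ss)[1] == 0L) stop("sequence is empty")
  counts <- oligonucleotideFrequency(ss[[1]], width = k)
  s <- sum(counts)
  if (s == 0) counts * 0 else counts / s
}

.letterCounts <- function(ss) {
  lc <- letterFrequency(ss, letters = .BASES)
  colnames(lc) <- .BASES
  lc
}

#' CpG-island indicator
#'
#' Flags a sequence as a CpG island when its length is at least 200 bp,
#' its GC fraction (over unambiguous bases) is at least 0.5, and the
#' observed/expected CpG ratio
#' \code{count(CG) * N_valid / (count(C) * count(G))} is at least 0.6.
#' Returns 0 when \code{count(C) * count(G)} is zero.
#'
#' @param seq character or DNAString(Set); a single sequence.
#' @return 0 or 1.
#' @export
cpgIslandFlag <- function(seq) {
  ss <- .asDNAStringSet(if (is(seq, "DNAString")) DNAStringSet(seq) else seq)
  if (length(ss) != 1L) stop("expected a single sequence")
  unname(.islandFlags(ss))
}

.islandFlags <- function(ss) {
  lc <- .letterCounts(ss)
  nValid <- rowSums(lc)
  cg <- vcountPattern("CG", ss)
  denom <- lc[, "C"] * lc[, "G"]
  oe <- ifelse(denom > 0, cg * nValid / denom, 0)
  gc <- ifelse(nValid > 0, (lc[, "C"] + lc[, "G"]) / nValid, 0)
  as.numeric(width(ss) >= 200L & gc >= 0.5 & oe >= 0.6)
}

#' Full 351-attribute feature matrix for a set of sequences
#'
#' Vectorized computation of \code{\link{seqFeatureSchema}} attributes, one
#' row per sequence. No scaling is applied: the sequence-composition
#' models are trained and applied on raw attribute values.
#'
#' @param seqs DNAStringSet or character vector.
#' @return numeric matrix, \code{length(seqs)} x 351, columns in schema
#'   order.
#' @export
sequenceFeatureMatrix <- function(seqs) {
  ss <- .asDNAStringSet(seqs)
  if (!length(ss)) stop("no sequences given")
  lc <- .letterCounts(ss)
  nValid <- rowSums(lc)
  if (any(nValid == 0))
    stop("sequence(s) without any unambiguous base: ",
         paste(which(nValid == 0), collapse = ", "))
  kblocks <- lapply(1:4, function(k) {
    counts <- oligonucleotideFrequency(ss, width = k)
    s <- rowSums(counts)
    out <- counts / ifelse(s > 0, s, 1)
    out[s == 0, ] <- 0
    out
  })
  A <- lc[, "A"]; C <- lc[, "C"]; G <- lc[, "G"]; Tn <- lc[, "T"]
  cg <- vcountPattern("CG", ss)
  safeRatio <- function(num, den) ifelse(den > 0, num / den, 0)
  cgContent <- (C + G) / nValid
  atContent <- (A + Tn) / nValid
  extra <- cbind(
    cpg_island = .islandFlags(ss),
    cg_content = cgContent,
    at_content = atContent,
    seq_length = as.numeric(width(ss)),
    n_bp = as.numeric(nValid),
    cpg_obs_exp = safeRatio(cg * nValid, C * G),
    gc_skew = safeRatio(G - C, G + C),
    at_skew = safeRatio(A - Tn, A + Tn),
    purine_frac = (A + G) / nValid,
    keto_frac = (G + Tn) / nValid,
    cg_at_diff = cgContent - atContent)
  out <- cbind(do.call(cbind, kblocks), extra)
  colnames(out) <- as.character(seqFeatureSchema())
  rownames(out) <- names(ss)
  out
}

#' 351-attribute feature vector of one sequence
#'
#' @param seq character or DNAString(Set); a single sequence with at least
#'   one unambiguous base.
#' @return named numeric vector of length 351.
#' @export
sequenceFeatureVector <- function(seq) {
  ss <- .asDNAStringSet(if (is(seq, "DNAString")) DNAStringSet(seq) else seq)
  if (length(ss) != 1L) stop("expected a single sequence")
  sequenceFeatureMatrix(ss)[1L, ]
}

#' Write / read a feature matrix as headered TSV
#'
#' @param mat numeric matrix with column names (row names optional).
#' @param path file path.
#' @export
writeFeatureMatrix <- function(mat, path) {
  df <- data.frame(id = if (is.null(rownames(mat)))
    sprintf("row_%d", seq_len(nrow(mat))) else rownames(mat),
    mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeFeatureMatrix
#' @return \code{readFeatureMatrix}: the matrix, with ids as row names.
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
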