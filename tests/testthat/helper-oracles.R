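## Independent brute-force oracles used across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## per-base boolean-array overlap oracle on a small genome
boolCover <- function(gr, genome) {
  lapply(names(genome), function(chrom) {
    v <- logical(genome[[chrom]])
    sel <- which(as.character(seqnames(gr)) == chrom)
    for (i in sel) v[start(gr)[i]:end(gr)[i]] <- TRUE
    v
  })
}

bruteOverlapBp <- function(x, y, genome) {
  cx <- boolCover(x, genome); cy <- boolCover(y, genome)
  sum(mapply(function(a, b) sum(a & b), cx, cy))
}

bruteTotalBp <- function(x, genome) {
  sum(vapply(boolCover(x, genome), sum, 0L))
}

randomIntervalSet <- function(n, genome, maxLen = 400L) {
  chroms <- sample(names(genome), n, replace = TRUE)
  lens <- sample.int(maxLen, n, replace = TRUE)
  starts <- vapply(seq_len(n), function(i)
    sample.int(genome[[chroms[i]]] - lens[i] + 1L, 1L), 0L)
  gr <- GRanges(chroms, IRanges(starts, width = lens))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  gr
}

## Mann-Whitney pairwise-comparison AUC oracle
pairwiseAUC <- function(labels, scores) {
  sp <- scores[labels == 1L]; sn <- scores[labels == 0L]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## exhaustive sliding-window k-mer oracle (skips windows with non-ACGT)
bruteKmerFreq <- function(seq, k) {
  chars <- strsplit(toupper(seq), "")[[1]]
  kmers <- character(0)
  if (length(chars) >= k) {
    for (i in seq_len(length(chars) - k + 1L)) {
      w <- chars[i:(i + k - 1L)]
      if (all(w %in% c("A", "C", "G", "T")))
        kmers <- c(kmers, paste(w, collapse = ""))
    }
  }
  all4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[,
    rev(seq_len(k)), drop = FALSE], 1L, paste, collapse = "")
  counts <- table(factor(kmers, levels = all4))
  if (length(kmers) == 0) as.numeric(counts) * 0
  else as.numeric(counts) / length(kmers)
}

randomDna <- function(n, gc = 0.5, withN = 0) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2, withN)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = probs / sum(probs)), collapse = "")
}

## gaussian toy LabeledDataset: class 1 shifted by `shift` on all columns
toyDataset <- function(nPos, nNeg, shift = 2, d = 11L, seed = 1L,
                       schemaId = "hist11") {
  set.seed(seed)
  x <- rbind(matrix(rnorm(nPos * d, shift), nPos),
             matrix(rnorm(nNeg * d, 0), nNeg))
  colnames(x) <- if (d == 11L) histFeatureSchema()
                 else sprintf("f%d", seq_len(d))
  labeledDataset(x, c(rep(1L, nPos), rep(0L, nNeg)), schemaId = schemaId)
}

## small grid for fast unit tests (the default search box is exercised in
## the acceptance suite)
smallGrid <- function() gridSpec(log10Step = 0.5, refineFactor = 5L,
                                 cBounds = c(1, 100),
                                 gammaBounds = c(1e-3, 10))
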