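test_that("readBed parses 0-based half-open records and skips headers", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("browser position chr1",
               "track name=test",
               "# a comment",
               "chr1\t0\t200",
               "chr2\t10\t20\tnamed\t0"), p)
  gr <- readBed(p)
  expect_length(gr, 2L)
  expect_identical(start(gr), c(1L, 11L))
  expect_identical(end(gr), c(200L, 20L))
  expect_identical(as.character(seqnames(gr)), c("chr1", "chr2"))
})

test_that("readBed rejects malformed lines naming the line number", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t200", "chr1\t50\t50"), p)
  expect_error(readBed(p), "line 2.*end <= start")
  writeLines(c("chr1\t0\tx"), p)
  expect_error(readBed(p), "line 1.*non-integer")
  writeLines("chr1\t100", p)
  expect_error(readBed(p), "line 1.*3 tab-separated")
})

test_that("BED round-trip is lossless for sorted merged sets", {
  set.seed(11)
  genome <- c(chr1 = 50000L, chr2 = 30000L)
  gr <- GenomicRanges::reduce(sort(randomIntervalSet(100L, genome)))
  p <- withr::local_tempfile(fileext = ".bed")
  writeBed(gr, p)
  back <- readBed(p)
  expect_identical(as.character(seqnames(back)), as.character(seqnames(gr)))
  expect_identical(start(back), start(gr))
  expect_identical(end(back), end(gr))
  ## empty set -> empty file
  writeBed(GRanges(), p)
  expect_length(readBed(p), 0L)
})

test_that("readFasta uppercases, concatenates, names by first token", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a some description", "acgt", "ACGT", ">b", "nnnA"), p)
  seqs <- readFasta(p)
  expect_identical(names(seqs), c("a", "b"))
  expect_identical(as.character(seqs[["a"]]), "ACGTACGT")
  expect_identical(as.character(seqs[["b"]]), "NNNA")
  writeLines(c(">a", "AC", ">a", "GT"), p)
  expect_error(readFasta(p), "duplicate")
})

test_that("readSignal covers bedGraph semantics", {
  genome <- c(chr1 = 100L)
  p <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t2.5", "chr1\t10\t12\t1.0"), p)
  tr <- readSignal(p, genome)
  v <- as.numeric(tr@values[["chr1"]])
  m <- as.logical(tr@covered[["chr1"]])
  expect_equal(v[1:10], rep(2.5, 10))
  expect_equal(v[11:12], rep(1.0, 2))
  expect_true(all(v[13:100] == 0))
  expect_identical(m, c(rep(TRUE, 12), rep(FALSE, 88)))
  ## overlapping records: last wins
  writeLines(c("chr1\t0\t10\t2.0", "chr1\t5\t10\t7.0"), p)
  tr2 <- readSignal(p, genome)
  expect_equal(as.numeric(tr2@values[["chr1"]])[c(5, 6)], c(2, 7))
  ## record beyond chromosome end errors naming the chromosome
  writeLines("chr1\t90\t200\t1.0", p)
  expect_error(readSignal(p, genome), "chr1")
  writeLines("chrX\t0\t10\t1.0", p)
  expect_error(readSignal(p, genome), "chrX")
})

test_that("wiggle fixedStep start=1 maps to the first base", {
  genome <- c(chr1 = 10L)
  p <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1",
               "1.0", "2.0", "3.0", "4.0", "5.0"), p)
  tr <- readSignal(p, genome)
  ## hand conversion: wiggle is 1-based, so values sit on bases 1..5
  expect_equal(as.numeric(tr@values[["chr1"]])[1:5], 1:5)
  expect_equal(sum(as.logical(tr@covered[["chr1"]])), 5L)
})

test_that("signal round-trips through bedGraph", {
  genome <- c(chr1 = 300L, chr2 = 200L)
  set.seed(3)
  gr <- randomIntervalSet(10L, genome, maxLen = 40L)
  S4Vectors::mcols(gr)$score <- round(runif(10), 3)
  tr <- signalTrackFromRanges(gr, genome)
  p <- withr::local_tempfile(fileext = ".bedGraph")
  writeSignal(tr, p)
  back <- readSignal(p, genome)
  for (chrom in names(genome)) {
    expect_equal(as.numeric(back@values[[chrom]]),
                 as.numeric(tr@values[[chrom]]))
    expect_identical(as.logical(back@covered[[chrom]]),
                     as.logical(tr@covered[[chrom]]))
  }
})

test_that("makeBins tiles exactly floor(L/width) full-width bins", {
  bins <- makeBins(c(chr1 = 1000L), 200)
  expect_length(bins, 5L)
  expect_true(all(width(bins) == 200L))
  bins2 <- makeBins(c(chr1 = 1001L, chr2 = 399L), 200)
  expect_identical(as.vector(table(as.character(seqnames(bins2)))),
                   c(5L, 1L))
  expect_true(all(width(bins2) == 200L))
  expect_equal(totalBp(bins2), 6L * 200L)  # disjoint
  expect_error(makeBins(c(chr1 = 1000L), 0), "positive")
  expect_error(makeBins(c(chr1 = 1000L), -5), "positive")
})

test_that("overlap arithmetic matches the per-base boolean oracle", {
  genome <- c(chr1 = 60000L, chr2 = 40000L)
  for (seed in 1:5) {
    set.seed(seed)
    x <- randomIntervalSet(200L, genome)
    y <- randomIntervalSet(200L, genome)
    expect_equal(overlapBp(x, y), bruteOverlapBp(x, y, genome))
    expect_equal(totalBp(x), bruteTotalBp(x, genome))
    expect_equal(totalBp(y), bruteTotalBp(y, genome))
    ## symmetry and A <= min(B, C)
    expect_equal(overlapBp(x, y), overlapBp(y, x))
    expect_lte(overlapBp(x, y), min(totalBp(x), totalBp(y)))
    ## intersect cross-checks
    expect_equal(totalBp(intersectIntervals(x, y)), overlapBp(x, y))
  }
})

test_that("intersecting a set with itself merges it", {
  set.seed(42)
  x <- randomIntervalSet(50L, c(chr1 = 20000L))
  self <- intersectIntervals(x, x)
  merged <- GenomicRanges::reduce(x)
  expect_identical(start(self), start(merged))
  expect_identical(end(self), end(merged))
})

test_that("disjoint chromosomes never overlap", {
  x <- GRanges("chr1", IRanges(1, 100))
  y <- GRanges("chr2", IRanges(1, 100))
  expect_equal(overlapBp(x, y), 0)
})

test_that("filterOverlapping drops test regions at >= minOverlap shared bp", {
  test <- GRanges("chr1", IRanges(1, 100))
  train <- GRanges("chr1", IRanges(100, 200))
  expect_length(filterOverlapping(test, train, 1L), 0L)  # 1 shared bp
  expect_length(filterOverlapping(test, GRanges(), 1L), 1L)
  ## boundary: 49 bp shared, threshold 50 -> kept
  train2 <- GRanges("chr1", IRanges(52, 200))
  expect_length(filterOverlapping(test, train2, 50L), 1L)
  expect_length(filterOverlapping(test, train2, 49L), 0L)
  expect_error(filterOverlapping(test, train, 0L), ">= 1")
})

test_that("filterOverlapping agrees with a per-region oracle", {
  genome <- c(chr1 = 30000L)
  set.seed(7)
  test <- randomIntervalSet(60L, genome)
  train <- randomIntervalSet(60L, genome)
  for (minOv in c(1L, 25L, 100L)) {
    kept <- filterOverlapping(test, train, minOv)
    oracleKeep <- vapply(seq_along(test), function(i)
      bruteOverlapBp(test[i], train, genome) < minOv, TRUE)
    expect_identical(start(kept), start(test[oracleKeep]))
    expect_identical(end(kept), end(test[oracleKeep]))
  }
})

test_that("chrom-size tables round-trip", {
  p <- withr::local_tempfile()
  writeChromSizes(c(chr1 = 1000L, chr2 = 500L), p)
  g <- readChromSizes(p)
  expect_identical(g, c(chr1 = 1000L, chr2 = 500L))
})
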