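test_that("sampleNegativeBins draws ratio x positives outside exclusions", {
  genome <- c(chr1 = 40000L)
  bins <- makeBins(genome, 200)
  pos <- bins[1:10]
  excl <- bins[1:30]
  neg <- sampleNegativeBins(pos, bins, excl, ratio = 10L, seed = 1)
  expect_length(neg, 100L)
  expect_equal(overlapBp(neg, excl), 0)
  ## determinism and seed sensitivity
  neg2 <- sampleNegativeBins(pos, bins, excl, ratio = 10L, seed = 1)
  expect_identical(start(neg), start(neg2))
  neg3 <- sampleNegativeBins(pos, bins, excl, ratio = 10L, seed = 2)
  expect_false(identical(start(neg), start(neg3)))
  ## shortfall reported
  expect_error(
    sampleNegativeBins(bins[1:50], bins, bins[1:150], ratio = 10L, seed = 1),
    "short")
})

test_that("sampleNegativeRegions matches the positive length profile", {
  genome <- c(chr1 = 200000L, chr2 = 200000L)
  set.seed(99)
  pos <- randomIntervalSet(50L, genome, maxLen = 900L)
  pos <- pos[width(pos) >= 100]
  excl <- pos
  neg <- sampleNegativeRegions(pos, genome, excl, ratio = 10L, seed = 0)
  expect_length(neg, 10L * length(pos))
  expect_equal(min(width(neg)), min(width(pos)))
  expect_equal(max(width(neg)), max(width(pos)))
  expect_lt(abs(mean(width(neg)) - mean(width(pos))) / mean(width(pos)),
            0.05)
  expect_equal(overlapBp(neg, excl), 0)
  neg2 <- sampleNegativeRegions(pos, genome, excl, ratio = 10L, seed = 0)
  expect_identical(start(neg), start(neg2))
  expect_error(sampleNegativeRegions(GRanges(), genome, excl, seed = 0),
               "non-empty")
})

test_that("impossible region sampling hits the draw cap with a message", {
  genome <- c(chr1 = 5000L)
  pos <- GRanges("chr1", IRanges(1, 500))
  excl <- GRanges("chr1", IRanges(1, 5000))  # everything excluded
  expect_error(
    sampleNegativeRegions(pos, genome, excl, ratio = 2L, seed = 1,
                          maxDraws = 50L),
    "exceeded 50 draws")
})

test_that("both-classes partitioning preserves the 1:10 ratio per part", {
  ds <- toyDataset(20, 200, seed = 3)
  sch <- partitionDataset(ds, "both-classes", 4L, seed = 5)
  expect_s4_class(sch, "PartitionScheme")
  labels <- classLabels(ds)
  for (part in 1:4) {
    sub <- learningSubset(ds, sch, part)
    expect_equal(sum(classLabels(sub) == 1L), 5L)
    expect_equal(sum(classLabels(sub) == 0L), 50L)
  }
  ## disjoint and exhaustive per class
  expect_equal(sort(unlist(lapply(1:4, function(p)
    sampleIds(learningSubset(ds, sch, p))))), sort(sampleIds(ds)))
})

test_that("ratio stays within +/-1 when class sizes do not divide evenly", {
  ds <- toyDataset(22, 223, seed = 3)
  sch <- partitionDataset(ds, "both-classes", 4L, seed = 5)
  posCounts <- integer(4); negCounts <- integer(4)
  for (part in 1:4) {
    sub <- learningSubset(ds, sch, part)
    posCounts[part] <- sum(classLabels(sub) == 1L)
    negCounts[part] <- sum(classLabels(sub) == 0L)
  }
  expect_equal(sum(posCounts), 22L)
  expect_equal(sum(negCounts), 223L)
  expect_lte(diff(range(posCounts)), 1L)
  expect_lte(diff(range(negCounts)), 1L)
})

test_that("majority-only partitioning splits negatives and keeps all positives", {
  ds <- toyDataset(8, 80, seed = 3)
  sch <- partitionDataset(ds, "majority-only", 10L, seed = 6)
  negSeen <- character(0)
  for (part in 1:10) {
    sub <- learningSubset(ds, sch, part)
    expect_equal(sum(classLabels(sub) == 1L), 8L)
    expect_equal(sum(classLabels(sub) == 0L), 8L)
    negSeen <- c(negSeen, sampleIds(sub)[classLabels(sub) == 0L])
  }
  expect_false(anyDuplicated(negSeen) > 0)   # disjoint negative parts
  expect_length(negSeen, 80L)                # exhaustive
})

test_that("partitioning is reproducible and validates its inputs", {
  ds <- toyDataset(10, 100, seed = 3)
  s1 <- partitionDataset(ds, "both-classes", 5L, seed = 7)
  s2 <- partitionDataset(ds, "both-classes", 5L, seed = 7)
  expect_identical(s1@assignments, s2@assignments)
  s3 <- partitionDataset(ds, "both-classes", 5L, seed = 8)
  expect_false(identical(s1@assignments, s3@assignments))
  expect_error(partitionDataset(ds, "both-classes", 11L, seed = 1),
               ">= 11 positives")
  expect_error(partitionDataset(toyDataset(5, 3, seed = 1), "majority-only",
                                4L, seed = 1),
               ">= 4 negatives")
})

test_that("trainTestSplit stratifies and is seeded", {
  ds <- toyDataset(10, 90, seed = 4)   # 100 rows
  sp <- trainTestSplit(ds, 0.2, seed = 9)
  expect_equal(length(sampleIds(sp$train)), 20L)
  expect_equal(length(sampleIds(sp$test)), 80L)
  expect_equal(sum(classLabels(sp$train) == 1L), 2L)
  expect_equal(sum(classLabels(sp$test) == 1L), 8L)
  expect_length(intersect(sampleIds(sp$train), sampleIds(sp$test)), 0L)
  sp2 <- trainTestSplit(ds, 0.2, seed = 9)
  expect_identical(sampleIds(sp2$train), sampleIds(sp$train))
  expect_error(trainTestSplit(ds, 0, seed = 1), "\\(0,1\\)")
  oneOfAKind <- toyDataset(1, 30, seed = 1)
  expect_error(trainTestSplit(oneOfAKind, 0.5, seed = 1), ">= 2 samples")
})

test_that("duplicate positive feature vectors are dropped from training", {
  set.seed(8)
  x <- matrix(rnorm(60), 6); colnames(x) <- sprintf("f%d", 1:10)
  train <- labeledDataset(x, c(1, 1, 1, 0, 0, 0), schemaId = "toy")
  ## test positive row 2 duplicates train positive row 1 exactly
  test <- labeledDataset(rbind(x[4, ] + 9, x[1, ], x[5, ] + 9),
                         c(1, 1, 1), schemaId = "toy")
  kept <- dropDuplicateFeatureRows(train, test)
  expect_equal(length(sampleIds(kept)), 5L)
  expect_false("row_1" %in% sampleIds(kept))
  ## no shared vectors -> unchanged
  kept2 <- dropDuplicateFeatureRows(train,
    labeledDataset(x + 1, c(1, 1, 1, 0, 0, 0), schemaId = "toy"))
  expect_identical(sampleIds(kept2), sampleIds(train))
  expect_error(dropDuplicateFeatureRows(train,
    labeledDataset(x, rep(1, 6), schemaId = "other")), "schema mismatch")
})

test_that("duplicate dropping agrees with a quadratic scan oracle", {
  set.seed(12)
  for (rep in 1:5) {
    ## coarse values force collisions
    xt <- matrix(sample(0:2, 80, replace = TRUE), 20)
    xe <- matrix(sample(0:2, 40, replace = TRUE), 10)
    train <- labeledDataset(xt, rep(c(1L, 0L), 10), schemaId = "toy")
    test <- labeledDataset(xe, rep(c(1L, 0L), 5), schemaId = "toy")
    kept <- dropDuplicateFeatureRows(train, test)
    posTest <- which(classLabels(test) == 1L)
    survivors <- vapply(seq_len(20), function(i) {
      if (classLabels(train)[i] == 0L) return(TRUE)
      !any(vapply(posTest, function(j)
        all(xt[i, ] == xe[j, ]), TRUE))
    }, TRUE)
    expect_identical(sampleIds(kept), sampleIds(train)[survivors])
  }
})

test_that("datasets serialize to a TSV directory and back", {
  ds <- toyDataset(4, 8, seed = 2)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("features.tsv", "labels.tsv", "manifest.txt")))))
  back <- readDataset(dir)
  expect_equal(featureMatrix(back), featureMatrix(ds), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(classLabels(back), classLabels(ds))
  expect_identical(schemaId(back), schemaId(ds))
})
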