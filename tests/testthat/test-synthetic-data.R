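test_that("genomes are reproducible, shaped and composed as specified", {
  spec <- synthSpec(nChroms = 2L, chromLength = 50000L, seed = 3L)
  g1 <- makeGenome(spec)
  g2 <- makeGenome(spec)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$sizes, c(chr1 = 50000L, chr2 = 50000L))
  gc <- sum(Biostrings::letterFrequency(g1$sequences, "GC")) / 100000
  expect_lt(abs(gc - spec@gcBackground), 0.02)
  g3 <- makeGenome(synthSpec(nChroms = 2L, chromLength = 50000L, seed = 4L))
  expect_false(identical(as.character(g1$sequences),
                         as.character(g3$sequences)))
})

test_that("planted enhancers shift GC and enrich the planted 4-mer", {
  spec <- synthSpec(nChroms = 1L, chromLength = 100000L, nEnhancers = 12L,
                    seed = 0L)
  g <- makeGenome(spec)
  pl <- plantEnhancers(g, spec)
  expect_length(pl$enhancers, 12L)
  expect_length(pl$promoters, 12L)
  expect_equal(overlapBp(pl$enhancers, pl$promoters), 0)
  enhSeq <- extractRegions(pl$sequences, pl$enhancers)
  bgSeq <- extractRegions(pl$sequences,
    filterOverlapping(makeBins(g$sizes, 1000),
                      c(pl$enhancers, pl$promoters)))
  gcOf <- function(ss) sum(Biostrings::letterFrequency(ss, "GC")) /
    sum(Biostrings::width(ss))
  expect_gt(gcOf(enhSeq), gcOf(bgSeq) + 0.10)
  freqOf <- function(ss, kmer) {
    hits <- sum(Biostrings::vcountPattern(kmer, ss))
    hits / sum(Biostrings::width(ss) - nchar(kmer) + 1)
  }
  for (kmer in names(spec@plantedKmers)) {
    fold <- spec@plantedKmers[[kmer]]
    expect_gte(freqOf(enhSeq, kmer), fold * freqOf(bgSeq, kmer) * 0.8)
  }
})

test_that("histone tracks are enriched where and only where profiled", {
  spec <- synthSpec(nChroms = 1L, chromLength = 60000L, nEnhancers = 8L,
                    seed = 0L)
  g <- makeGenome(spec)
  pl <- plantEnhancers(g, spec)
  tracks <- makeHistoneTracks(g$sizes, pl$enhancers, pl$promoters, spec)
  expect_identical(names(tracks), histFeatureSchema())
  prof <- spec@markProfiles
  inEnh <- boolCover(pl$enhancers, g$sizes)[[1]]
  for (mark in c("H3K4me1", "H3K27ac")) {
    amp <- prof$enhancerAmp[prof$mark == mark]
    v <- as.numeric(tracks[[mark]]@values[["chr1"]])
    expect_gt(mean(v[inEnh]) - mean(v[!inEnh]), amp / 2)
  }
  ## a zero-amplitude mark is pure noise
  v0 <- as.numeric(tracks[["H3K9me3"]]@values[["chr1"]])
  expect_lt(abs(mean(v0[inEnh]) - mean(v0[!inEnh])), 0.2)
})

test_that("dataset sharing spans identical to disjoint enhancer sets", {
  base <- list(nChroms = 2L, chromLength = 80000L, nEnhancers = 6L,
               nDatasets = 3L, seed = 1L)
  full <- do.call(synthSpec, c(base, sharing = 1.0))
  collFull <- makeMultiDatasets(full, "fantom5")
  sets <- lapply(collFull$datasets, `[[`, "enhancers")
  for (i in 2:3)
    expect_identical(start(sets[[i]]), start(sets[[1]]))
  none <- do.call(synthSpec, c(base, sharing = 0.0))
  collNone <- makeMultiDatasets(none, "fantom5")
  sets0 <- lapply(collNone$datasets, `[[`, "enhancers")
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(overlapBp(sets0[[i]], sets0[[j]]), 0)
})

test_that("collections are deterministic in the generator seed", {
  spec <- synthSpec(nChroms = 1L, chromLength = 60000L, nEnhancers = 6L,
                    nDatasets = 2L, seed = 11L)
  c1 <- makeMultiDatasets(spec, "encode")
  c2 <- makeMultiDatasets(spec, "encode")
  expect_identical(as.character(c1$sequences), as.character(c2$sequences))
  expect_identical(start(c1$enhancerPool), start(c2$enhancerPool))
  expect_identical(
    as.numeric(c1$datasets[[1]]$tracks[["H3K27ac"]]@values[[1]]),
    as.numeric(c2$datasets[[1]]$tracks[["H3K27ac"]]@values[[1]]))
})

test_that("generated negatives never touch planted enhancers", {
  coll <- cachedEncodeCollection()
  dss <- cachedEncodeDatasets()
  for (name in names(dss)) {
    ds <- dss[[name]]
    neg <- sampleIds(ds)[classLabels(ds) == 0L]
    parts <- do.call(rbind, strsplit(neg, "[:-]"))
    gr <- GRanges(parts[, 1],
                  IRanges(as.integer(parts[, 2]) + 1L,
                          as.integer(parts[, 3])))
    expect_equal(overlapBp(gr, coll$enhancerPool), 0)
    expect_equal(overlapBp(gr, coll$promoters), 0)
  }
})

test_that("labeled datasets keep the 1:10 ratio and schema", {
  dss <- cachedEncodeDatasets()
  for (ds in dss) {
    expect_identical(schemaId(ds), "hist11")
    expect_equal(sum(classLabels(ds) == 0L),
                 10L * sum(classLabels(ds) == 1L))
    expect_true(all(featureMatrix(ds) >= 0 & featureMatrix(ds) <= 1))
  }
  seqDs <- cachedSeqDataset()
  expect_identical(schemaId(seqDs), "seq351")
  expect_equal(ncol(featureMatrix(seqDs)), 351L)
  expect_equal(sum(classLabels(seqDs) == 0L),
               10L * sum(classLabels(seqDs) == 1L))
})

test_that("raising the planted amplitude never hurts end-to-end GM", {
  gms <- vapply(c(0.5, 1, 2), function(amp) {
    spec <- synthSpec(nChroms = 2L, chromLength = 80000L, nEnhancers = 5L,
                      nDatasets = 2L, sharing = 0.5, seed = 0L,
                      markProfiles = within(defaultMarkProfiles(), {
                        enhancerAmp <- enhancerAmp * amp
                        promoterAmp <- promoterAmp * amp
                      }))
    coll <- makeMultiDatasets(spec, "encode")
    dss <- asLabeledDatasets(coll, seed = 40L)
    sp <- trainTestSplit(dss[[1]], 0.4, seed = 41L)
    sch <- partitionDataset(sp$train, "majority-only", 2L, seed = 42L)
    em <- trainEnsemble(sp$train, sch, smallGrid(), seed = 43L)
    conf <- ensembleConfidence(em, featureMatrix(sp$test))
    classificationMetrics(classLabels(sp$test), as.integer(conf >= 0.5))$gm
  }, 0)
  expect_true(all(diff(gms) >= -0.02))   # monotone within noise
  expect_gt(gms[3], 0.8)
})
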