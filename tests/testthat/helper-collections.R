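## Memoized synthetic collections shared across test files (built once per
## test run; every generator call is itself seeded, so caching does not
## hide nondeterminism — determinism has dedicated tests).

.collCache <- new.env(parent = emptyenv())

cachedEncodeCollection <- function() {
  if (is.null(.collCache$encode)) {
    spec <- synthSpec(seed = 0L)
    .collCache$encodeSpec <- spec
    .collCache$encode <- makeMultiDatasets(spec, "encode")
  }
  .collCache$encode
}

cachedEncodeDatasets <- function() {
  if (is.null(.collCache$encodeDs))
    .collCache$encodeDs <- asLabeledDatasets(cachedEncodeCollection(),
                                             seed = 100L)
  .collCache$encodeDs
}

cachedSeqCollection <- function() {
  if (is.null(.collCache$seq)) {
    spec <- synthSpec(nDatasets = 1L, nEnhancers = 40L, sharing = 0,
                      seed = 0L)
    .collCache$seq <- makeMultiDatasets(spec, "vista")
  }
  .collCache$seq
}

cachedSeqDataset <- function() {
  if (is.null(.collCache$seqDs))
    .collCache$seqDs <- asLabeledDatasets(cachedSeqCollection(),
                                          seed = 100L)[[1]]
  .collCache$seqDs
}
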