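#' @importFrom e1071 svm
NULL

#' Construct a GridSpec
#'
#' The search box defaults to C in [1, 500] and gamma in [1e-5, 50000],
#' explored on a base-10 logarithmic lattice with step 0.2 in round 1 and
#' step 0.02 (a ten-fold refinement) in a +/- 0.2 window around the
#' round-1 optimum in round 2.
#'
#' @param log10Step round-1 lattice step in log10 units (default 0.2).
#' @param refineFactor round-2 refinement factor (default 10).
#' @param cBounds,gammaBounds inclusive positive bounds.
#' @return a \linkS4class{GridSpec}.
#' @export
gridSpec <- function(log10Step = 0.2, refineFactor = 10L,
                     cBounds = c(1, 500), gammaBounds = c(1e-5, 50000)) {
  new("GridSpec", log10Step = log10Step,
      refineFactor = as.integer(refineFactor),
      cBounds = as.numeric(cBounds), gammaBounds = as.numeric(gammaBounds))
}

#' Base-10 logarithmic lattice spanning a bound pair
#'
#' Points at \code{log10(lo), log10(lo)+step, ...}; the upper bound is
#' appended when the stepping does not land on it.
#'
#' @param bounds positive numeric pair (lo, hi).
#' @param step log10 step.
#' @return numeric vector of lattice values (natural scale, increasing).
#' @export
logLattice <- function(bounds, step) {
  lo <- log10(bounds[1]); hi <- log10(bounds[2])
  pts <- seq(lo, hi, by = step)
  if (hi - pts[length(pts)] > 1e-9) pts <- c(pts, hi)
  10^pts
}

## libsvm's internal per-column standardization (the e1071 default) is
## kept on: it is part of the classifier, not a dataset normalization
## step, and the raw-scale length attributes of the sequence schema would
## otherwise dominate the RBF distance. Constant columns within a small
## learning subset trigger a harmless "cannot scale" warning.
.fitSvm <- function(x, y, C, gamma) {
  suppressWarnings(
    svm(x, y, kernel = "radial", cost = C, gamma = gamma, scale = TRUE))
}

.gmOf <- function(labels, predicted) {
  m <- classificationMetrics(labels, predicted)
  m$gm
}

.stratifiedIdx <- function(labels, fraction) {
  idx <- integer(0)
  for (cls in unique(labels)) {
    cl <- which(labels == cls)
    n <- max(1L, min(length(cl) - 1L, round(fraction * length(cl))))
    idx <- c(idx, sample(cl, n))
  }
  sort(idx)
}

#' Two-round GM-maximizing grid search for SVM hyperparameters
#'
#' A random stratified \code{tuneFraction} of the learning subset is used
#' to fit each candidate (C, gamma); the geometric mean of sensitivity and
#' specificity (GM) is scored on the remaining rows. Round 1 walks the full
#' log10 lattice; round 2 refines a +/- one-step window around the round-1
#' optimum at ten-fold resolution, clipped to the bounds. Ties are broken
#' toward smaller C, then smaller gamma.
#'
#' @param subset LabeledDataset with both classes present.
#' @param grid a \linkS4class{GridSpec}.
#' @param tuneFraction fraction fitted during tuning (default 0.70).
#' @param seed integer RNG seed (controls the tune split).
#' @return list with elements \code{C}, \code{gamma} and \code{gm} (the
#'   held-out GM of the winner).
#' @export
gridSearchSvm <- function(subset, grid = gridSpec(), tuneFraction = 0.7,
                          seed) {
  y <- factor(subset@labels, levels = c(0L, 1L))
  if (length(unique(subset@labels)) < 2L)
    stop("learning subset must contain both classes")
  set.seed(seed)
  fitIdx <- .stratifiedIdx(subset@labels, tuneFraction)
  evalIdx <- setdiff(seq_along(y), fitIdx)
  if (length(unique(subset@labels[evalIdx])) < 2L ||
      length(unique(subset@labels[fitIdx])) < 2L)
    stop("tune split left a side without both classes; ",
         "use a larger subset or stratified sampling")
  xFit <- subset@features[fitIdx, , drop = FALSE]
  yFit <- y[fitIdx]
  xEval <- subset@features[evalIdx, , drop = FALSE]
  lEval <- subset@labels[evalIdx]
  evalPoint <- function(C, gamma) {
    fit <- .fitSvm(xFit, yFit, C, gamma)
    pred <- as.integer(as.character(predict(fit, xEval)))
    .gmOf(lEval, pred)
  }
  searchLattice <- function(cVals, gVals, best) {
    for (C in cVals) for (g in gVals) {
      gm <- evalPoint(C, g)
      if (gm > best$gm + 1e-12) best <- list(C = C, gamma = g, gm = gm)
    }
    best
  }
  best <- searchLattice(logLattice(grid@cBounds, grid@log10Step),
                        logLattice(grid@gammaBounds, grid@log10Step),
                        list(C = NA_real_, gamma = NA_real_, gm = -Inf))
  fine <- grid@log10Step / grid@refineFactor
  window <- function(center, bounds) {
    lo <- max(log10(bounds[1]), log10(center) - grid@log10Step)
    hi <- min(log10(bounds[2]), log10(center) + grid@log10Step)
    10^seq(lo, hi, by = fine)
  }
  best <- searchLattice(window(best$C, grid@cBounds),
                        window(best$gamma, grid@gammaBounds),
                        best)
  best
}

#' Train the committee of Gaussian-kernel SVMs
#'
#' One member per learning subset: each is independently tuned by
#' \code{\link{gridSearchSvm}} on its own subset, then refit on the full
#' subset at the tuned hyperparameters. Members are independent, so
#' training order does not matter.
#'
#' @param ds LabeledDataset (the training portion).
#' @param scheme PartitionScheme built for \code{ds}.
#' @param grid a GridSpec.
#' @param seed integer RNG seed; member k uses \code{seed + k}.
#' @param name tag stored on the model (cell line / tissue).
#' @return an \linkS4class{EnsembleModel}.
#' @export
trainEnsemble <- function(ds, scheme, grid = gridSpec(), seed,
                          name = "ensemble") {
  if (length(scheme@assignments) != length(ds@labels))
    stop("scheme was not built for this dataset")
  members <- vector("list", scheme@nParts)
  for (part in seq_len(scheme@nParts)) {
    subset <- learningSubset(ds, scheme, part)
    if (length(unique(subset@labels)) < 2L)
      stop("learning subset ", part, " contains a single class")
    hp <- gridSearchSvm(subset, grid, seed = seed + part)
    fit <- .fitSvm(subset@features,
                   factor(subset@labels, levels = c(0L, 1L)),
                   hp$C, hp$gamma)
    members[[part]] <- list(fit = fit, C = hp$C, gamma = hp$gamma,
                            part = part, tunedGM = hp$gm)
  }
  new("EnsembleModel", members = members, schemaId = ds@schemaId,
      name = name, featureNames = colnames(ds@features))
}

.memberVotes <- function(model, features) {
  if (ncol(features) != length(model@featureNames))
    stop("feature arity does not match the ensemble's schema")
  if (!is.null(colnames(features)) &&
      !identical(colnames(features), model@featureNames))
    stop("feature columns do not match the ensemble's schema")
  votes <- vapply(model@members, function(m) {
    as.integer(as.character(predict(m$fit, features)))
  }, integer(nrow(features)))
  matrix(votes, nrow = nrow(features))
}

#' Committee confidence scores
#'
#' Each member casts a hard vote; the confidence score of a row is the
#' fraction of members voting enhancer, so scores live on the lattice
#' \code{0, 1/M, ..., 1} for an M-member committee.
#'
#' @param model an EnsembleModel.
#' @param features numeric matrix with the model's feature columns.
#' @return numeric vector of scores in [0,1].
#' @export
ensembleConfidence <- function(model, features) {
  rowMeans(.memberVotes(model, features))
}

#' All non-empty subsets of a mark set
#'
#' @param marks character vector (default the 11-mark schema).
#' @return list of character vectors, all 2^n - 1 non-empty subsets.
#' @export
markSubsets <- function(marks = histFeatureSchema()) {
  n <- length(marks)
  lapply(seq_len(2^n - 1L), function(code) {
    marks[bitwAnd(code, 2^(seq_len(n) - 1L)) > 0L]
  })
}

#' Exhaustive histone-mark subset search
#'
#' For every candidate subset of marks, fits a single Gaussian-kernel SVM
#' per dataset on the restricted columns (fixed hyperparameters; this is a
#' screening pass, not a committee) and records the GM on a held-out
#' stratified split. Subsets are ranked by mean GM across datasets.
#'
#' @param datasets list of LabeledDatasets sharing the hist11 schema.
#' @param subsets list of mark-name subsets; default all 2047 non-empty
#'   subsets of the 11 marks.
#' @param cap refuse to evaluate more than this many subsets unless
#'   explicitly raised (guards toy runs; default 2047 evaluates all).
#' @param heldFraction fraction held out for scoring (default 0.3).
#' @param C,gammaPerFeature fixed SVM hyperparameters; gamma =
#'   gammaPerFeature / number of marks in the subset.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{subset} (comma-joined marks),
#'   \code{size} and \code{meanGM}, sorted by decreasing mean GM.
#' @export
featureSubsetSearch <- function(datasets, subsets = NULL, cap = 2047L,
                                heldFraction = 0.3, C = 10,
                                gammaPerFeature = 1, seed) {
  if (is.null(subsets)) subsets <- markSubsets()
  if (length(subsets) > cap)
    stop(sprintf("%d subsets exceeds cap %d; raise cap to confirm",
                 length(subsets), cap))
  splits <- lapply(seq_along(datasets), function(i)
    trainTestSplit(datasets[[i]], 1 - heldFraction, seed = seed + i))
  gms <- vapply(subsets, function(sub) {
    mean(vapply(splits, function(sp) {
      xTr <- sp$train@features[, sub, drop = FALSE]
      xTe <- sp$test@features[, sub, drop = FALSE]
      fit <- .fitSvm(xTr, factor(sp$train@labels, levels = c(0L, 1L)),
                     C, gammaPerFeature / length(sub))
      pred <- as.integer(as.character(predict(fit, xTe)))
      .gmOf(sp$test@labels, pred)
    }, 0))
  }, 0)
  out <- data.frame(
    subset = vapply(subsets, paste, "", collapse = ","),
    size = lengths(subsets), meanGM = gms)
  out[order(-out$meanGM, out$size), ]
}

#' Serialize an ensemble with a diff-able manifest
#'
#' Writes \code{manifest.txt} (schema, feature names, per-member
#' hyperparameters) plus one RDS blob per member.
#'
#' @param model an EnsembleModel.
#' @param dir output directory.
#' @export
writeEnsemble <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- c(sprintf("name\t%s", model@name),
           sprintf("schema_id\t%s", model@schemaId),
           sprintf("features\t%s", paste(model@featureNames,
                                         collapse = ",")),
           sprintf("members\t%d", length(model@members)))
  rows <- vapply(model@members, function(m)
    sprintf("member\t%d\t%.10g\t%.10g", m$part, m$C, m$gamma), "")
  writeLines(c(hdr, rows), file.path(dir, "manifest.txt"))
  for (m in model@members)
    saveRDS(m, file.path(dir, sprintf("member_%04d.rds", m$part)))
  invisible(NULL)
}

#' @rdname writeEnsemble
#' @return \code{readEnsemble}: the EnsembleModel.
#' @export
readEnsemble <- function(dir) {
  lines <- readLines(file.path(dir, "manifest.txt"))
  field <- function(key) sub(paste0("^", key, "\t"), "",
                             grep(paste0("^", key, "\t"), lines,
                                  value = TRUE)[1])
  paths <- sort(list.files(dir, pattern = "^member_\\d+\\.rds$",
                           full.names = TRUE))
  new("EnsembleModel", members = lapply(paths, readRDS),
      schemaId = field("schema_id"), name = field("name"),
      featureNames = strsplit(field("features"), ",")[[1]])
}
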