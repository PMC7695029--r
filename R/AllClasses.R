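#' Canonical fatty acid feature set
#'
#' The 17 fatty acids (relative % of identified FAMEs) quantified per
#' chromatogram, in canonical chromatographic elution order.  Two entries
#' are co-eluting peak pairs quantified as one feature
#' (`"22:1n11+22:1n9"`, `"20:3n3+20:4n6"`); identifiers carry no internal
#' whitespace so they are safe as map keys and CSV headers.
#'
#' @return Character vector of the 17 canonical feature identifiers.
#' @examples
#' fameFeatures()
#' @export
fameFeatures <- function() {
  c("14:0", "16:0", "16:1", "18:0", "18:1n9c", "18:1n7", "18:2n6c",
    "18:3n3", "20:1n9", "18:4n3", "20:2n6", "22:1n11+22:1n9",
    "20:3n3+20:4n6", "20:5n3", "24:1n9", "22:5n3", "22:6n3")
}

#' Class labels of the four-group salmon design
#'
#' Fixed bijection between integer class codes and group names:
#' 0 — Norway farmed, 1 — Chile farmed, 2 — Canada farmed, 3 — Canada wild.
#'
#' @return Character vector of the four group names, in code order, so that
#'   `fameClasses()[code + 1]` maps a code to its name.
#' @examples
#' fameClasses()
#' @export
fameClasses <- function() {
  c("Norway farmed", "Chile farmed", "Canada farmed", "Canada wild")
}

# normalize a user-supplied class specification to the canonical factor
.asClassFactor <- function(x) {
  cls <- fameClasses()
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% 0:3))
      stop("class codes must lie in 0..3", call. = FALSE)
    x <- cls[x + 1L]
  }
  bad <- setdiff(unique(x), cls)
  if (length(bad))
    stop("unknown class name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  factor(x, levels = cls)
}

#' Container for labeled FAME chromatogram profiles
#'
#' `FameExperiment` extends [SummarizedExperiment] to hold one assay
#' (`"relabund"`, features x instances, relative percentages) together
#' with per-instance metadata: the sample (fish) identifier, the class
#' label, and the replicate index within the sample block.  All replicate
#' chromatograms sharing a `sampleId` form a *block*, the unit of
#' resampling for every validation scheme in the package.
#'
#' Validity requires a numeric assay, consistent labels within every
#' block, replicate indices in 1..6, and — when the features are exactly
#' the canonical 17 of [fameFeatures()] — values in \[0, 100\] with each
#' profile summing to 100 within the closure tolerance stored in
#' `metadata(x)$closureTol` (default 0.5 percentage points, matching the
#' rounding slack of published composition tables).  Derived datasets
#' (e.g. t-SNE coordinates from [tsneFeatureStage()]) carry arbitrary
#' feature sets and skip the compositional checks.
#'
#' @slot .. see [SummarizedExperiment]; no additional slots.
#' @seealso [FameExperiment()] for construction, [profileMatrix()],
#'   [sampleId()], [classLabel()], [replicateIndex()] for access.
#' @export
setClass("FameExperiment", contains = "SummarizedExperiment")

setValidity("FameExperiment", function(object) {
  msg <- character(0)
  if (!"relabund" %in% assayNames(object))
    return("assay 'relabund' is missing")
  a <- assay(object, "relabund")
  if (!is.numeric(a)) msg <- c(msg, "assay must be numeric")
  cd <- colData(object)
  need <- c("sampleId", "classLabel", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  if (anyNA(a)) msg <- c(msg, "assay contains NA values")
  lab <- as.character(cd$classLabel)
  if (!all(lab %in% fameClasses()))
    msg <- c(msg, "classLabel contains unknown class names")
  perBlock <- tapply(lab, as.character(cd$sampleId),
                     function(l) length(unique(l)))
  if (length(perBlock) && any(perBlock > 1L))
    msg <- c(msg, "instances sharing a sampleId must share one class label")
  rep <- cd$replicate
  if (!all(rep %in% 1:6))
    msg <- c(msg, "replicate indices must lie in 1..6")
  blockSize <- table(as.character(cd$sampleId))
  if (length(blockSize) && any(blockSize > 6L))
    msg <- c(msg, "a sample block holds at most 6 chromatograms")
  if (setequal(rownames(object), fameFeatures()) && !anyNA(a)) {
    tol <- metadata(object)$closureTol
    if (is.null(tol)) tol <- 0.5
    if (any(a < 0) || any(a > 100))
      msg <- c(msg, "relative percentages must lie in [0, 100]")
    dev <- abs(colSums(a) - 100)
    if (any(dev > tol + 1e-8))
      msg <- c(msg, sprintf(
        "%d profile(s) violate sum-closure to 100 beyond tolerance %.3g",
        sum(dev > tol + 1e-8), tol))
  }
  if (length(msg)) msg else TRUE
})

#' Per-group generator parameters for the synthetic salmon design
#'
#' Holds, for each of the four groups and each of the 17 canonical
#' features, the between-specimen mean and standard deviation (in relative
#' % units) that drive [simulateFame()], plus the number of fish sampled
#' per group and the number of replicate chromatograms per fish.
#'
#' @slot mean 17 x 4 numeric matrix of group means (features x groups,
#'   groups in class-code order).
#' @slot sd matching matrix of between-specimen standard deviations.
#' @slot nSamples integer(4), fish per group, class-code order.
#' @slot nReplicates integer(1), chromatograms per fish (3 extractions x
#'   2 injections in the emulated design).
#' @seealso [defaultParameters()]
#' @export
setClass("FameParameters",
  representation(mean = "matrix", sd = "matrix",
                 nSamples = "integer", nReplicates = "integer"))

setValidity("FameParameters", function(object) {
  msg <- character(0)
  if (!identical(dim(object@mean), dim(object@sd)))
    msg <- c(msg, "mean and sd matrices must share dimensions")
  if (!identical(rownames(object@mean), fameFeatures()))
    msg <- c(msg, "rows must be the canonical 17 features, canonical order")
  if (!identical(colnames(object@mean), fameClasses()))
    msg <- c(msg, "columns must be the four class names in code order")
  if (any(object@mean <= 0)) msg <- c(msg, "all means must be > 0")
  if (any(object@sd < 0)) msg <- c(msg, "all sds must be >= 0")
  if (length(object@nSamples) != 4L || any(object@nSamples < 1L))
    msg <- c(msg, "nSamples must give >= 1 fish for each of 4 groups")
  if (object@nReplicates < 1L || object@nReplicates > 6L)
    msg <- c(msg, "nReplicates must lie in 1..6")
  if (length(msg)) msg else TRUE
})

#' Gain-ratio feature ranking
#'
#' Result of [rankFeatures()]: features sorted non-increasing by
#' information gain ratio, ties broken by canonical feature order.
#'
#' @slot ranking data.frame with columns `feature` and `gainRatio`.
#' @export
setClass("FameRanking", representation(ranking = "data.frame"))

#' Minimal-feature search result
#'
#' Result of [minimalFeatureSearch()] or [linearScanMinimal()].
#'
#' @slot k integer, minimal number of ranked features meeting the
#'   threshold (or all features if none does).
#' @slot selected character, the first `k` ranked feature identifiers.
#' @slot prefixAccuracies named numeric, accuracy of every evaluated
#'   prefix length.
#' @slot threshold numeric accuracy threshold as a fraction.
#' @slot usedAllFeatures logical, TRUE when no prefix met the threshold.
#' @slot nCalls integer, number of distinct evaluator invocations.
#' @export
setClass("FameSelection",
  representation(k = "integer", selected = "character",
                 prefixAccuracies = "numeric", threshold = "numeric",
                 usedAllFeatures = "logical", nCalls = "integer"))

#' Two-dimensional embedding result
#'
#' Result of [pcaProject()] or [tsneMap()].
#'
#' @slot coordinates n x d score matrix, one row per instance, input order
#'   preserved.
#' @slot explainedVariance per-component fraction of total variance (PCA
#'   only; length 0 for t-SNE).
#' @slot method `"pca"` or `"tsne"`.
#' @slot parameters list of the features used and method hyperparameters
#'   (including the seed, for t-SNE).
#' @export
setClass("FameEmbedding",
  representation(coordinates = "matrix", explainedVariance = "numeric",
                 method = "character", parameters = "list"))

#' Classifier evaluation report
#'
#' Result of [evaluateHoldout()] or [evaluateLosoCv()]: classification
#' accuracy (CA), class-frequency-weighted F1, confusion matrices in
#' counts and proportion-of-actual form, per-fold detail for
#' cross-validation, and provenance (classifier, feature set, scheme,
#' seed).  Wall-clock prediction time is logged for information only; it
#' is hardware-dependent and never asserted.
#'
#' @slot accuracy fraction of correctly classified test chromatograms.
#' @slot f1 class-frequency-weighted mean per-class F1.
#' @slot confusionCounts K x K integer matrix, true classes in rows.
#' @slot confusionProportion row-normalized confusion (proportion of
#'   actual); rows of absent classes are zero.
#' @slot perFold data.frame of per-fold accuracies (LOSO only; 0 rows for
#'   holdout).
#' @slot classifier character, classifier family evaluated.
#' @slot featureSet character, features given to the classifier.
#' @slot scheme `"holdout"` or `"loso"`.
#' @slot seed integer seed of the split / learner.
#' @slot elapsed numeric, seconds spent predicting (logged only).
#' @export
setClass("FameEvaluation",
  representation(accuracy = "numeric", f1 = "numeric",
                 confusionCounts = "matrix", confusionProportion = "matrix",
                 perFold = "data.frame", classifier = "character",
                 featureSet = "character", scheme = "character",
                 seed = "integer", elapsed = "numeric"))
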