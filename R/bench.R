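.assertNoLeakage <- function(train, test) {
  common <- intersect(unique(sampleId(train)), unique(sampleId(test)))
  if (length(common))
    stop("internal error: sample block(s) straddle train/test: ",
         paste(common, collapse = ", "))
  invisible(TRUE)
}

#' Block-aware stratified holdout split
#'
#' Assigns whole sample blocks (all replicate chromatograms of a fish) to
#' either side, so no fish's replicates leak between train and test.  By
#' default the split is stratified per class, drawing
#' `round(testFraction * nBlocks)` blocks of each class into the test
#' side — with the emulated design (25/24/25/26 fish) this gives 20 test
#' blocks, 5 per class.  Deterministic for a fixed seed; the block
#' disjointness invariant is asserted on every call.
#'
#' @param fe a [FameExperiment].
#' @param testFraction fraction of sample blocks assigned to the test
#'   side (default 0.2, the published 20:80 split).
#' @param stratified draw test blocks per class (default TRUE).
#' @param seed integer seed.
#' @return list with [FameExperiment] elements `train` and `test`.
#' @export
splitHoldout <- function(fe, testFraction = 0.2, stratified = TRUE,
                         seed = 1L) {
  stopifnot(is(fe, "FameExperiment"), testFraction > 0, testFraction < 1)
  set.seed(seed)
  sid <- sampleId(fe)
  blockClass <- tapply(as.character(classLabel(fe)), sid,
                       function(l) l[[1L]])
  testBlocks <- character(0)
  if (stratified) {
    for (cl in unique(blockClass)) {
      bl <- names(blockClass)[blockClass == cl]
      if (length(bl) < 2L)
        stop("class '", cl, "' has a single sample block; ",
             "stratified splitting impossible")
      nTest <- max(1L, round(testFraction * length(bl)))
      testBlocks <- c(testBlocks, sample(bl, nTest))
    }
  } else {
    bl <- names(blockClass)
    testBlocks <- sample(bl, max(1L, round(testFraction * length(bl))))
  }
  testIdx <- sid %in% testBlocks
  out <- list(train = fe[, !testIdx], test = fe[, testIdx])
  .assertNoLeakage(out$train, out$test)
  out
}

#' Classification metrics: accuracy, weighted F1, confusion matrices
#'
#' Computes the classification accuracy (CA, fraction correct), the
#' class-frequency-weighted mean of per-class F1 scores (per-class F1 is
#' the harmonic mean of precision and recall; classes never predicted
#' and never occurring contribute 0 with weight 0), and the confusion
#' matrix in counts and proportion-of-actual form (each row divided by
#' the row's true-class count; rows of absent classes stay 0).
#'
#' @param yTrue,yPred equal-length class vectors (factors or coercible);
#'   the level set is their union unless `levels` is given.
#' @param levels optional explicit class level order.
#' @param average `"weighted"` (default) or `"macro"` F1 averaging.
#' @return list with elements `accuracy`, `f1`, `confusionCounts`,
#'   `confusionProportion`, `perClassF1`.
#' @examples
#' computeMetrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
#' @export
computeMetrics <- function(yTrue, yPred, levels = NULL,
                           average = c("weighted", "macro")) {
  average <- match.arg(average)
  if (!length(yTrue)) stop("empty label vectors")
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (is.null(levels))
    levels <- sort(unique(c(as.character(yTrue), as.character(yPred))))
  yTrue <- factor(as.character(yTrue), levels = levels)
  yPred <- factor(as.character(yPred), levels = levels)
  cm <- table(true = yTrue, pred = yPred)
  counts <- matrix(as.integer(cm), nrow(cm), ncol(cm),
                   dimnames = dimnames(cm))
  acc <- sum(diag(counts)) / sum(counts)
  tp <- diag(counts)
  prec <- ifelse(colSums(counts) > 0, tp / colSums(counts), 0)
  rec  <- ifelse(rowSums(counts) > 0, tp / rowSums(counts), 0)
  f1c  <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- if (average == "weighted") rowSums(counts) / sum(counts)
         else rep(1 / sum(rowSums(counts) > 0), length(f1c)) *
              (rowSums(counts) > 0)
  prop <- counts / pmax(rowSums(counts), 1L)
  list(accuracy = acc, f1 = sum(f1c * wts), confusionCounts = counts,
       confusionProportion = prop, perClassF1 = f1c)
}

.evaluation <- function(met, perFold, spec, features, scheme, seed, elapsed)
  new("FameEvaluation", accuracy = met$accuracy, f1 = met$f1,
      confusionCounts = met$confusionCounts,
      confusionProportion = met$confusionProportion,
      perFold = perFold, classifier = spec$family,
      featureSet = features, scheme = scheme,
      seed = as.integer(seed), elapsed = elapsed)

#' Evaluate a classifier on a block-aware holdout split
#'
#' Splits with [splitHoldout()], trains on the 80% side and predicts
#' each test chromatogram independently.  Block disjointness is asserted
#' on every run; wall-clock prediction time is logged in the report but
#' carries no assertion.
#'
#' @param fe a [FameExperiment].
#' @param spec a [fameClassifier()] specification.
#' @param features optional feature subset handed to the classifier
#'   (default: all features of `fe`).
#' @param testFraction,stratified,seed see [splitHoldout()].
#' @return A [FameEvaluation].
#' @examples
#' fe <- simulateFame(seed = 1)
#' evaluateHoldout(fe, fameClassifier("kNN"), seed = 1)
#' @export
evaluateHoldout <- function(fe, spec, features = NULL, testFraction = 0.2,
                            stratified = TRUE, seed = 1L) {
  sp <- splitHoldout(fe, testFraction, stratified, seed)
  Xtr <- profileMatrix(sp$train); Xte <- profileMatrix(sp$test)
  if (!is.null(features)) {
    Xtr <- Xtr[, features, drop = FALSE]
    Xte <- Xte[, features, drop = FALSE]
  }
  fit <- .fitClassifier(spec, Xtr, classLabel(sp$train))
  t0 <- proc.time()[["elapsed"]]
  pred <- fit$predict(Xte)
  elapsed <- proc.time()[["elapsed"]] - t0
  met <- computeMetrics(classLabel(sp$test), pred, levels = fameClasses())
  .evaluation(met, data.frame(), spec, colnames(Xtr), "holdout", seed,
              elapsed)
}

#' Evaluate a classifier by leave-one-sample-out cross-validation
#'
#' One fold per sample block: the fold's test set is the block's
#' replicate chromatograms in their entirety, the training set all other
#' blocks, so replicate leakage is impossible by construction (and
#' asserted).  Metrics are pooled over all predictions; per-fold
#' accuracies are kept in the report.
#'
#' @inheritParams evaluateHoldout
#' @return A [FameEvaluation] with one `perFold` row per block.
#' @export
evaluateLosoCv <- function(fe, spec, features = NULL) {
  stopifnot(is(fe, "FameExperiment"))
  sid <- sampleId(fe)
  blocks <- unique(sid)
  if (length(blocks) < 2L) stop("LOSO needs >= 2 sample blocks")
  X <- profileMatrix(fe)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- classLabel(fe)
  yTrue <- character(0); yPred <- character(0)
  foldAcc <- numeric(length(blocks))
  elapsed <- 0
  for (i in seq_along(blocks)) {
    te <- sid == blocks[i]
    stopifnot(!any(sid[!te] == blocks[i]))   # block never straddles the fold
    fit <- .fitClassifier(spec, X[!te, , drop = FALSE], y[!te])
    t0 <- proc.time()[["elapsed"]]
    p <- as.character(fit$predict(X[te, , drop = FALSE]))
    elapsed <- elapsed + (proc.time()[["elapsed"]] - t0)
    yTrue <- c(yTrue, as.character(y[te]))
    yPred <- c(yPred, p)
    foldAcc[i] <- mean(p == as.character(y[te]))
  }
  met <- computeMetrics(yTrue, yPred, levels = fameClasses())
  .evaluation(met, data.frame(block = blocks, accuracy = foldAcc),
              spec, colnames(X), "loso", spec$seed, elapsed)
}

#' Run the classifier bench
#'
#' Evaluates a roster of classifiers on one shared seeded split (or LOSO
#' scheme) and returns a performance table sorted by accuracy.
#'
#' @param fe a [FameExperiment].
#' @param specs named list of [fameClassifier()] specifications (default
#'   [defaultClassifiers()]).
#' @param features optional feature subset.
#' @param scheme `"holdout"` (default) or `"loso"`.
#' @param seed split seed (holdout).
#' @return data.frame with columns `model`, `CA`, `F1`, `testTime`
#'   (seconds, logged only), plus the list of full [FameEvaluation]
#'   objects as attribute `"evaluations"`.
#' @export
runBench <- function(fe, specs = defaultClassifiers(), features = NULL,
                     scheme = c("holdout", "loso"), seed = 1L) {
  scheme <- match.arg(scheme)
  evs <- lapply(specs, function(sp) {
    if (scheme == "holdout")
      evaluateHoldout(fe, sp, features = features, seed = seed)
    else evaluateLosoCv(fe, sp, features = features)
  })
  out <- data.frame(model = vapply(evs, slot, character(1), "classifier"),
                    CA = vapply(evs, slot, numeric(1), "accuracy"),
                    F1 = vapply(evs, slot, numeric(1), "f1"),
                    testTime = vapply(evs, slot, numeric(1), "elapsed"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$CA, -out$F1), ]
  rownames(out) <- NULL
  attr(out, "evaluations") <- evs
  out
}

setMethod("show", "FameEvaluation", function(object) {
  cat(sprintf("FameEvaluation (%s, %s): CA = %.3f, F1 = %.3f\n",
              object@classifier, object@scheme, object@accuracy,
              object@f1))
  cat("  features:", paste(object@featureSet, collapse = ", "), "\n")
  if (nrow(object@perFold))
    cat("  folds:", nrow(object@perFold), "\n")
})

#' Accessors for FameEvaluation
#'
#' @param x a [FameEvaluation].
#' @name FameEvaluation-accessors
#' @aliases accuracy f1score confusionMatrix
#' @export
accuracy <- function(x) x@accuracy

#' @rdname FameEvaluation-accessors
#' @export
f1score <- function(x) x@f1

#' @rdname FameEvaluation-accessors
#' @param proportions return proportion-of-actual instead of counts.
#' @export
confusionMatrix <- function(x, proportions = FALSE)
  if (proportions) x@confusionProportion else x@confusionCounts
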