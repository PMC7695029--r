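.asFraction <- function(threshold) {
  if (threshold > 1) threshold <- threshold / 100
  stopifnot(threshold > 0, threshold <= 1)
  threshold
}

.memoizeEvaluator <- function(evaluator) {
  cache <- new.env(parent = emptyenv())
  calls <- 0L
  f <- function(m) {
    key <- as.character(m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    a <- evaluator(m)
    if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1)
      stop("evaluator must return a single accuracy fraction in [0, 1]")
    calls <<- calls + 1L
    cache[[key]] <- a
    a
  }
  list(eval = f,
       calls = function() calls,
       table = function() {
         ks <- sort(as.integer(ls(cache)))
         setNames(vapply(as.character(ks), function(k) cache[[k]],
                         numeric(1)), ks)
       })
}

.selectionResult <- function(ranking, k, mem, threshold, usedAll) {
  new("FameSelection", k = as.integer(k),
      selected = rankedFeatures(ranking)[seq_len(k)],
      prefixAccuracies = mem$table(), threshold = threshold,
      usedAllFeatures = usedAll, nCalls = mem$calls())
}

#' Minimal feature count by binary search over the ranked prefix
#'
#' Finds the smallest prefix of the gain-ratio ranking whose accuracy
#' meets `threshold`, by bisection over the prefix length.  The published
#' bisection scheme is followed with two corrections adopted here: the
#' success predicate is *accuracy >= threshold* (the strict `>`/`<` pair
#' in the printed pseudocode leaves accuracy exactly at the threshold
#' driving neither branch), and on termination the reported count is
#' `R + 1` — the smallest prefix length whose accuracy met the threshold
#' among those evaluated — rather than the final midpoint, whose prefix
#' can fail the threshold.  The returned prefix is always re-verified
#' against the memoized accuracy; a warning flags the non-monotone case
#' where verification fails (bisection assumes prefix accuracy is
#' non-decreasing; see [linearScanMinimal()] for the exhaustive
#' alternative).
#'
#' If even the full feature set misses the threshold the search stops
#' immediately and returns all `n` features with `usedAllFeatures` set.
#' The evaluator is memoized: no prefix length is evaluated twice, and
#' the number of evaluator calls is O(log n) plus the initial full-set
#' call.
#'
#' @param ranking a [FameRanking].
#' @param evaluator function mapping a prefix length m (number of
#'   top-ranked features used) to an accuracy fraction in \[0, 1\]; must
#'   be deterministic for a fixed prefix (fix the validation seed, as
#'   [prefixEvaluator()] does).
#' @param threshold required accuracy, as a fraction (0.99) or a
#'   percentage (99); default 0.99.
#' @param linearSweep logical; when TRUE run [linearScanMinimal()]
#'   instead (exact under non-monotone accuracy, n evaluator calls).
#' @return A [FameSelection].
#' @examples
#' acc <- c(0.50, 0.70, 0.80, 0.95, 0.992, 0.995, 0.997, 0.999, 1, 1)
#' rk <- new("FameRanking", ranking = data.frame(
#'   feature = paste0("f", 1:10), gainRatio = seq(1, 0.1, by = -0.1)))
#' minimalFeatureSearch(rk, function(m) acc[m])
#' @export
minimalFeatureSearch <- function(ranking, evaluator, threshold = 0.99,
                                 linearSweep = FALSE) {
  stopifnot(is(ranking, "FameRanking"))
  if (linearSweep)
    return(linearScanMinimal(ranking, evaluator, threshold))
  threshold <- .asFraction(threshold)
  n <- length(rankedFeatures(ranking))
  stopifnot(n >= 1L)
  mem <- .memoizeEvaluator(evaluator)
  if (mem$eval(n) < threshold)
    return(.selectionResult(ranking, n, mem, threshold, TRUE))
  L <- 0L; R <- n - 1L; mOld <- n - 1L
  repeat {
    m <- (L + R) %/% 2L
    if (mem$eval(m + 1L) >= threshold) R <- m else L <- m
    if (m == mOld) break
    mOld <- m
  }
  k <- R + 1L
  if (mem$eval(k) < threshold)
    warning("prefix accuracy is not monotone: returned prefix fails the ",
            "threshold; consider linearSweep = TRUE")
  .selectionResult(ranking, k, mem, threshold, FALSE)
}

#' Minimal feature count by exhaustive prefix scan
#'
#' Evaluates prefixes 1..n in order and returns the first meeting the
#' threshold — the definitional answer, used as ground truth for
#' [minimalFeatureSearch()] (the two agree whenever prefix accuracy is
#' non-decreasing).  Evaluation is lazy: no prefix beyond the returned
#' one is evaluated.
#'
#' @inheritParams minimalFeatureSearch
#' @return A [FameSelection].
#' @export
linearScanMinimal <- function(ranking, evaluator, threshold = 0.99) {
  stopifnot(is(ranking, "FameRanking"))
  threshold <- .asFraction(threshold)
  n <- length(rankedFeatures(ranking))
  stopifnot(n >= 1L)
  mem <- .memoizeEvaluator(evaluator)
  for (m in seq_len(n)) {
    if (mem$eval(m) >= threshold)
      return(.selectionResult(ranking, m, mem, threshold, FALSE))
  }
  .selectionResult(ranking, n, mem, threshold, TRUE)
}

#' Prefix-accuracy evaluator over a validation scheme
#'
#' Builds the evaluator consumed by [minimalFeatureSearch()]: given a
#' prefix length m it takes the first m ranked features, optionally
#' remaps them to 2-D with the transductive t-SNE stage
#' ([tsneFeatureStage()]), and returns the accuracy of the classifier
#' under the chosen validation scheme.  The seed is fixed once per
#' evaluator so repeated prefix evaluations within one search are
#' coherent.
#'
#' @param fe a [FameExperiment].
#' @param ranking a [FameRanking] of its features.
#' @param classifier a classifier specification from [fameClassifier()];
#'   default the bench kNN.
#' @param scheme `"loso"` (leave-one-sample-out cross-validation, the
#'   default) or `"holdout"` (block-aware 20:80 split).
#' @param tsneStage logical, insert the t-SNE feature-mapping stage
#'   between the prefix and the classifier.
#' @param tsneArgs list of arguments passed on to [tsneFeatureStage()].
#' @param seed integer seed for the split and any stochastic learner.
#' @return function(m) -> accuracy fraction.
#' @export
prefixEvaluator <- function(fe, ranking, classifier = fameClassifier("kNN"),
                            scheme = c("loso", "holdout"), tsneStage = FALSE,
                            tsneArgs = list(), seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(is(fe, "FameExperiment"), is(ranking, "FameRanking"))
  feats <- rankedFeatures(ranking)
  function(m) {
    use <- feats[seq_len(m)]
    dat <- if (tsneStage)
      do.call(tsneFeatureStage, c(list(fe, features = use, seed = seed),
                                  tsneArgs))
    else fe
    useF <- if (tsneStage) NULL else use
    ev <- if (scheme == "loso")
      evaluateLosoCv(dat, classifier, features = useF)
    else
      evaluateHoldout(dat, classifier, features = useF, seed = seed)
    ev@accuracy
  }
}

setMethod("show", "FameSelection", function(object) {
  cat("FameSelection: k =", object@k,
      if (object@usedAllFeatures) "(threshold never met; all features)\n"
      else sprintf("(accuracy %.4f >= %.4f)\n",
                   object@prefixAccuracies[as.character(object@k)],
                   object@threshold))
  cat("  selected:", paste(object@selected, collapse = ", "), "\n")
  cat("  evaluator calls:", object@nCalls, "\n")
})

#' @rdname FameSelection-accessors
#' @export
selectedFeatures <- function(x) x@selected

#' Accessors for FameSelection
#'
#' `selectedFeatures()` returns the chosen feature identifiers,
#' `selectionSize()` the count k, `prefixAccuracies()` the accuracies of
#' all evaluated prefixes (named by prefix length).
#'
#' @param x a [FameSelection].
#' @name FameSelection-accessors
#' @aliases selectedFeatures selectionSize prefixAccuracies
#' @export
selectionSize <- function(x) x@k

#' @rdname FameSelection-accessors
#' @export
prefixAccuracies <- function(x) x@prefixAccuracies
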