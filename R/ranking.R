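# Shannon entropy (bits) of a class-count vector
.entropyCounts <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(0)
  p <- cnt[cnt > 0] / n
  -sum(p * log2(p))
}

#' Entropy-based discretization of a continuous feature (Fayyad-Irani MDL)
#'
#' Recursively splits the value range at the boundary minimizing the
#' class-conditional entropy, accepting a split only while the minimum
#' description length criterion holds: the information gain of the split
#' must exceed \eqn{(\log_2(N-1) + \Delta)/N} with
#' \eqn{\Delta = \log_2(3^k - 2) - (k E - k_1 E_1 - k_2 E_2)}, where
#' \eqn{k, k_1, k_2} count the classes present in the segment and its two
#' halves and \eqn{E} denotes entropy in bits.  Zero returned cut points
#' signal a feature whose values carry no usable class information at
#' this sample size.
#'
#' @param values numeric vector.
#' @param labels class vector of equal length (anything coercible to a
#'   factor); a single class present yields no cuts.
#' @return Strictly increasing numeric vector of cut points (possibly
#'   length 0), each the midpoint of an adjacent value pair.
#' @examples
#' discretizeMdl(c(1, 2, 3, 101, 102, 103), rep(c("A", "B"), each = 3))
#' @export
discretizeMdl <- function(values, labels) {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have equal length")
  if (length(values) < 2L) return(numeric(0))
  y <- as.integer(factor(labels))
  K <- max(y)
  o <- order(values)
  xs <- values[o]; ys <- y[o]
  # one-hot cumulative class counts over the sorted sequence
  cum <- matrix(0L, length(xs) + 1L, K)
  oneHot <- matrix(0L, length(xs), K)
  oneHot[cbind(seq_along(ys), ys)] <- 1L
  cum[-1L, ] <- apply(oneHot, 2L, cumsum)

  segCounts <- function(lo, hi) cum[hi + 1L, ] - cum[lo, ]
  cuts <- numeric(0)

  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L) return()
    cand <- which(xs[lo:(hi - 1L)] < xs[(lo + 1L):hi]) + lo - 1L
    if (!length(cand)) return()
    total <- segCounts(lo, hi)
    E <- .entropyCounts(total)
    if (E == 0) return()
    leftCnt <- cum[cand + 1L, , drop = FALSE] -
      matrix(cum[lo, ], length(cand), K, byrow = TRUE)
    rightCnt <- matrix(total, length(cand), K, byrow = TRUE) - leftCnt
    ent <- function(M) {
      ns <- rowSums(M)
      P <- M / ns
      H <- -rowSums(ifelse(P > 0, P * log2(P), 0))
      list(n = ns, H = H)
    }
    l <- ent(leftCnt); r <- ent(rightCnt)
    wEnt <- (l$n * l$H + r$n * r$H) / n
    best <- which.min(wEnt)
    i <- cand[best]
    gain <- E - wEnt[best]
    k  <- sum(total > 0)
    k1 <- sum(leftCnt[best, ] > 0)
    k2 <- sum(rightCnt[best, ] > 0)
    delta <- log2(3^k - 2) -
      (k * E - k1 * l$H[best] - k2 * r$H[best])
    if (gain > (log2(n - 1) + delta) / n) {
      cuts <<- c(cuts, (xs[i] + xs[i + 1L]) / 2)
      recurse(lo, i)
      recurse(i + 1L, hi)
    }
  }
  recurse(1L, length(xs))
  sort(cuts)
}

#' Information gain ratio of a continuous feature
#'
#' Discretizes `values` with [discretizeMdl()], then scores the induced
#' partition by the gain ratio in bits:
#' \deqn{GR = \frac{H(Y) - \sum_v \frac{n_v}{n} H(Y \mid v)}
#'            {-\sum_v \frac{n_v}{n}\log_2 \frac{n_v}{n}},}
#' information gain normalized by the split information (the entropy of
#' the partition sizes), which penalizes fragmenting the data into many
#' bins.  A feature yielding a single bin (no cut points) has split
#' information 0 and scores 0: an unsplittable feature carries no usable
#' information.
#'
#' @inheritParams discretizeMdl
#' @param cuts optional pre-computed cut points; when supplied the MDL
#'   discretization step is skipped and the given partition is scored
#'   as-is.
#' @return Non-negative unitless score.
#' @examples
#' gainRatio(c(1, 2, 3, 101, 102, 103), rep(c("A", "B"), each = 3))
#' @export
gainRatio <- function(values, labels, cuts = NULL) {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have equal length")
  if (is.null(cuts)) cuts <- discretizeMdl(values, labels)
  if (!length(cuts)) return(0)
  bin <- findInterval(values, cuts)
  y <- as.integer(factor(labels))
  n <- length(values)
  binCnt <- table(bin)
  ig <- .entropyCounts(tabulate(y)) -
    sum(vapply(split(y, bin),
               function(yy) length(yy) / n * .entropyCounts(tabulate(yy)),
               numeric(1)))
  si <- .entropyCounts(as.numeric(binCnt))
  if (si == 0) return(0)
  max(ig / si, 0)
}

#' Rank features by information gain ratio
#'
#' Scores every feature of the dataset with [gainRatio()] against the
#' class labels and sorts non-increasing; ties are broken by canonical
#' feature order so the ranking is deterministic and invariant to
#' instance order.
#'
#' @param fe a [FameExperiment] with at least 2 instances and 2 classes
#'   present.
#' @param features optional subset of feature identifiers to rank
#'   (default: all features of `fe`).
#' @return A [FameRanking].
#' @examples
#' fe <- simulateFame(seed = 1)
#' head(as.data.frame(rankFeatures(fe)), 3)
#' @export
rankFeatures <- function(fe, features = NULL) {
  stopifnot(is(fe, "FameExperiment"))
  X <- profileMatrix(fe)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  y <- classLabel(fe)
  if (ncol(fe) < 2L || length(unique(y)) < 2L)
    stop("ranking needs >= 2 instances and >= 2 classes present")
  scores <- vapply(colnames(X), function(f) gainRatio(X[, f], y), numeric(1))
  ord <- order(-scores, match(colnames(X), colnames(X)))
  new("FameRanking",
      ranking = data.frame(feature = colnames(X)[ord],
                           gainRatio = unname(scores[ord]),
                           stringsAsFactors = FALSE))
}

#' Accessors for FameRanking
#'
#' `rankedFeatures()` returns the ordered feature identifiers,
#' `gainRatios()` the scores named by feature; `as.data.frame()` the full
#' table.
#'
#' @param x a [FameRanking].
#' @name FameRanking-accessors
#' @aliases rankedFeatures gainRatios
NULL

#' @rdname FameRanking-accessors
#' @export
setMethod("rankedFeatures", "FameRanking", function(x) x@ranking$feature)

#' @rdname FameRanking-accessors
#' @export
setMethod("gainRatios", "FameRanking",
          function(x) setNames(x@ranking$gainRatio, x@ranking$feature))

#' @export
#' @method as.data.frame FameRanking
as.data.frame.FameRanking <- function(x, ...) x@ranking

setMethod("show", "FameRanking", function(object) {
  cat("FameRanking:", nrow(object@ranking), "features by gain ratio\n")
  top <- head(object@ranking, 5L)
  cat(paste(sprintf("  %-15s %.3f", top$feature, top$gainRatio),
            collapse = "\n"), "\n")
})
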