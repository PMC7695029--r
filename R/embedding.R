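# standardize columns; zero-variance columns are centered only
.scaleMatrix <- function(X, standardize) {
  ctr <- colMeans(X)
  if (standardize) {
    s <- apply(X, 2L, stats::sd)
    s[s == 0] <- 1
  } else s <- rep(1, ncol(X))
  sweep(sweep(X, 2L, ctr), 2L, s, "/")
}

#' Principal component projection of a FAME dataset
#'
#' Eigendecomposition of the feature covariance (or, with the default
#' `standardize = TRUE`, correlation) matrix; returns per-instance scores
#' and per-component explained-variance fractions.  Standardization is
#' the default because the 17 relative-percentage features span two
#' orders of magnitude (44% oleic acid vs 0.2% nervonic acid) and an
#' unscaled decomposition is dominated by the few most abundant acids;
#' the covariance-only behavior is retained behind the flag.  Component
#' signs are canonicalized (the largest-magnitude loading of each
#' component is made positive) so projections are reproducible across
#' platforms.
#'
#' @param fe a [FameExperiment].
#' @param features optional subset of features to project (default all).
#' @param nComponents number of score columns returned (default 2).
#' @param standardize scale features to unit variance first (default
#'   TRUE).
#' @return A [FameEmbedding] with `explainedVariance` holding the
#'   fraction of total variance per returned component.
#' @examples
#' fe <- simulateFame(seed = 1)
#' emb <- pcaProject(fe)
#' sum(explainedVariance(emb))  # variance captured by PC1 + PC2
#' @export
pcaProject <- function(fe, features = NULL, nComponents = 2L,
                       standardize = TRUE) {
  stopifnot(is(fe, "FameExperiment"))
  X <- profileMatrix(fe)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  if (nrow(X) < 2L) stop("PCA needs at least 2 instances")
  if (nComponents > ncol(X))
    stop("nComponents exceeds the number of features")
  p <- prcomp(.scaleMatrix(X, standardize), center = FALSE, scale. = FALSE)
  # canonical sign: largest-magnitude loading positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  fr <- p$sdev^2 / sum(p$sdev^2)
  keep <- seq_len(nComponents)
  new("FameEmbedding",
      coordinates = p$x[, keep, drop = FALSE],
      explainedVariance = fr[keep],
      method = "pca",
      parameters = list(features = colnames(X), standardize = standardize,
                        loadings = p$rotation[, keep, drop = FALSE],
                        allVarianceFractions = fr))
}

#' t-SNE embedding of a FAME dataset
#'
#' Two-dimensional t-distributed stochastic neighbor embedding of *all*
#' instances jointly (transductive: train/test membership plays no role
#' in the mapping).  Exact (non-Barnes-Hut) gradients and PCA
#' initialization are used so a fixed seed reproduces coordinates
#' bit-identically.  Features are standardized by default, for the same
#' scale-spread reason as in [pcaProject()].
#'
#' @param fe a [FameExperiment].
#' @param features optional subset of features (default all).
#' @param perplexity t-SNE perplexity (default 30); when the instance
#'   count cannot support it (n < 3*perplexity + 1) it is shrunk with a
#'   warning.
#' @param maxIter gradient-descent iterations (default 1000).
#' @param standardize scale features to unit variance first (default
#'   TRUE).
#' @param seed integer seed.
#' @return A [FameEmbedding] (`explainedVariance` is empty: t-SNE
#'   preserves neighborhoods, not variance).
#' @export
tsneMap <- function(fe, features = NULL, perplexity = 30, maxIter = 1000L,
                    standardize = TRUE, seed = 1L) {
  stopifnot(is(fe, "FameExperiment"))
  X <- profileMatrix(fe)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  n <- nrow(X)
  if (all(apply(X, 2L, function(v) length(unique(v)) == 1L)))
    stop("degenerate input: all instances identical")
  maxPerp <- (n - 1) / 3
  if (perplexity > maxPerp) {
    warning(sprintf("perplexity %.4g too large for %d instances; using %.4g",
                    perplexity, n, floor(maxPerp)))
    perplexity <- floor(maxPerp)
  }
  Xs <- .scaleMatrix(X, standardize)
  # PCA initialization (first two PCs scaled to sd 1e-4): stable global
  # structure and bit-reproducibility regardless of the RNG state
  p <- prcomp(Xs, center = FALSE, scale. = FALSE)
  Y0 <- p$x[, seq_len(min(2L, ncol(p$x))), drop = FALSE]
  if (ncol(Y0) < 2L) Y0 <- cbind(Y0, 0)
  Y0 <- sweep(Y0, 2L, apply(Y0, 2L, stats::sd) + 1e-12, "/") * 1e-4
  set.seed(seed)
  fit <- Rtsne::Rtsne(Xs, dims = 2L, perplexity = perplexity, theta = 0,
                      max_iter = as.integer(maxIter), Y_init = Y0,
                      pca = TRUE, partial_pca = FALSE,
                      check_duplicates = FALSE,
                      verbose = FALSE, num_threads = 1L)
  coords <- fit$Y
  colnames(coords) <- c("tSNE1", "tSNE2")
  new("FameEmbedding", coordinates = coords, explainedVariance = numeric(0),
      method = "tsne",
      parameters = list(features = colnames(X), perplexity = perplexity,
                        maxIter = as.integer(maxIter),
                        standardize = standardize, seed = as.integer(seed)))
}

#' Transductive t-SNE feature-mapping stage
#'
#' Re-expresses the dataset through its 2-D t-SNE coordinates, preserving
#' sample blocks, labels and instance order, so classifiers can be
#' trained on the embedded space.  The mapping is fitted on all instances
#' jointly *before* any train/test split: this mirrors the published
#' pipeline but is information leakage in the strict inductive sense —
#' test instances shape the embedding of training instances — and
#' accuracies measured downstream must be read as transductive.  See the
#' vignette for discussion.
#'
#' @inheritParams tsneMap
#' @return A [FameExperiment] whose two features are the t-SNE
#'   coordinates.
#' @export
tsneFeatureStage <- function(fe, features = NULL, perplexity = 30,
                             maxIter = 1000L, standardize = TRUE, seed = 1L) {
  emb <- tsneMap(fe, features = features, perplexity = perplexity,
                 maxIter = maxIter, standardize = standardize, seed = seed)
  out <- FameExperiment(coordinates(emb), sampleId = sampleId(fe),
                        classLabel = classLabel(fe),
                        replicate = replicateIndex(fe))
  metadata(out)$tsneStage <- emb@parameters
  out
}

#' Accessors for FameEmbedding
#'
#' `coordinates()` returns the n x d score matrix (instance order
#' preserved); `explainedVariance()` the per-component variance fractions
#' (PCA only).
#'
#' @param x a [FameEmbedding].
#' @name FameEmbedding-accessors
#' @aliases coordinates explainedVariance
NULL

#' @rdname FameEmbedding-accessors
#' @export
setMethod("coordinates", "FameEmbedding", function(x) x@coordinates)

#' @rdname FameEmbedding-accessors
#' @export
setMethod("explainedVariance", "FameEmbedding",
          function(x) x@explainedVariance)

setMethod("show", "FameEmbedding", function(object) {
  cat("FameEmbedding (", object@method, "): ",
      nrow(object@coordinates), " instances x ",
      ncol(object@coordinates), " components\n", sep = "")
  if (length(object@explainedVariance))
    cat("  explained variance:",
        paste(sprintf("%.1f%%", 100 * object@explainedVariance),
              collapse = " + "),
        sprintf("= %.1f%%\n", 100 * sum(object@explainedVariance)))
})
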