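#' Default generator parameters: the published four-group salmon design
#'
#' Returns the per-group, per-feature means and between-specimen standard
#' deviations (relative % of identified FAMEs) of the emulated study:
#' 25 Norway farmed, 24 Chile farmed, 25 Canada farmed and 26 Canada wild
#' fish, six replicate chromatograms per fish (three extractions, two
#' injections each).  Each group's 17 means sum to 100 within 0.5,
#' the closure slack left by rounding to two decimals.
#'
#' @return A [FameParameters] object.
#' @examples
#' prm <- defaultParameters()
#' groupMeans(prm)[, "Canada wild"]
#' @export
defaultParameters <- function() {
  # per feature: wild, Canada farmed, Chile farmed, Norway farmed (mean, sd)
  raw <- matrix(c(
    3.86, 0.40,  1.99, 0.47,  1.98, 0.10,  2.14, 0.06,
    15.75, 1.70, 11.64, 0.83, 12.22, 0.78,  9.13, 0.24,
    3.73, 0.58,  3.48, 0.80,  2.78, 0.25,  2.67, 0.07,
    3.61, 0.65,  3.54, 0.22,  3.78, 0.31,  2.60, 0.10,
    12.89, 2.89, 42.15, 4.42, 41.98, 1.58, 43.89, 0.29,
    2.19, 0.28,  3.82, 0.33,  4.05, 0.41,  3.81, 0.28,
    1.76, 0.15, 14.35, 1.52, 16.36, 0.72, 16.31, 0.21,
    6.72, 1.52,  5.02, 0.57,  4.47, 0.40,  7.79, 0.27,
    3.57, 0.94,  2.09, 0.65,  2.36, 0.22,  2.17, 0.24,
    2.51, 0.51,  0.58, 0.14,  0.61, 0.09,  0.69, 0.08,
    0.48, 0.10,  0.87, 0.09,  1.04, 0.06,  0.90, 0.06,
    9.30, 2.90,  1.10, 1.11,  0.64, 0.27,  0.67, 0.05,
    1.83, 0.33,  0.79, 0.11,  0.60, 0.05,  0.66, 0.02,
    9.12, 0.97,  2.74, 0.42,  2.54, 0.23,  2.69, 0.15,
    1.06, 0.17,  0.24, 0.05,  0.21, 0.02,  0.26, 0.02,
    2.75, 0.30,  1.37, 0.34,  1.28, 0.13,  1.17, 0.05,
    18.83, 2.82,  4.23, 0.62,  3.12, 1.11,  2.45, 0.13),
    nrow = 17, byrow = TRUE)
  dn <- list(fameFeatures(), fameClasses())
  # reorder columns from (wild, CanadaF, Chile, Norway) to class-code order
  mu <- raw[, c(7, 5, 3, 1)]; sd <- raw[, c(8, 6, 4, 2)]
  dimnames(mu) <- dn; dimnames(sd) <- dn
  new("FameParameters", mean = mu, sd = sd,
      nSamples = c(25L, 24L, 25L, 26L), nReplicates = 6L)
}

#' @rdname FameParameters-accessors
#' @export
groupMeans <- function(params) params@mean

#' Accessors for FameParameters
#'
#' `groupMeans()` / `groupSds()` return the 17 x 4 parameter matrices
#' (features x groups, class-code order); `groupSizes()` the fish count
#' per group; `closedMeanProfile()` a group's mean vector renormalized to
#' sum exactly 100 (the profile every chromatogram collapses to when all
#' noise is switched off).
#'
#' @param params a [FameParameters] object.
#' @param group a class name from [fameClasses()].
#' @name FameParameters-accessors
#' @aliases groupMeans groupSds groupSizes closedMeanProfile
#' @export
groupSds <- function(params) params@sd

#' @rdname FameParameters-accessors
#' @export
groupSizes <- function(params) setNames(params@nSamples, fameClasses())

#' @rdname FameParameters-accessors
#' @export
closedMeanProfile <- function(params, group) {
  m <- params@mean[, group]
  100 * m / sum(m)
}

setMethod("show", "FameParameters", function(object) {
  cat("FameParameters: 17 features x 4 groups,",
      paste(object@nSamples, collapse = "/"),
      "fish,", object@nReplicates, "replicates each\n")
  cat("  group mean sums:",
      paste(sprintf("%s=%.2f", abbreviate(fameClasses(), 9),
                    colSums(object@mean)), collapse = ", "), "\n")
})

#' Draw specimen-level feature vectors for one group
#'
#' The specimen-level model behind [simulateFame()]: each fish's profile
#' is Gaussian with the group's per-feature mean and SD.  Within the two
#' farmed groups that the study found hardest to separate (Chile farmed
#' and Canada farmed) — or within all groups, if `correlatedGroups` says
#' so — a single latent "feed composition" factor with loading
#' `sqrt(correlation)` on every feature induces an inter-feature
#' correlation of `correlation` while leaving each feature's marginal
#' mean and SD untouched:
#' \deqn{x_f = \mu_f + \sigma_f(\sqrt{\rho}\, t + \sqrt{1-\rho}\,
#'   \epsilon_f), \quad t, \epsilon_f \sim N(0,1).}
#' Draws are returned untruncated and unclosed, so at large `n` the
#' sample moments recover the parameter table exactly; truncation at 0
#' and compositional closure are applied downstream by [simulateFame()].
#'
#' @param params a [FameParameters] object.
#' @param group class name of the group to draw from.
#' @param n number of specimens.
#' @param correlation latent-factor correlation in \[0, 1).
#' @param applyFactor logical, whether this group carries the latent
#'   factor.
#' @return n x 17 numeric matrix (specimens x features).
#' @export
drawSpecimens <- function(params, group, n, correlation = 0,
                          applyFactor = FALSE) {
  stopifnot(correlation >= 0, correlation < 1, n >= 1)
  mu <- params@mean[, group]; sg <- params@sd[, group]
  eps <- matrix(rnorm(n * 17L), n, 17L)
  if (applyFactor && correlation > 0) {
    t <- rnorm(n)
    z <- sqrt(1 - correlation) * eps + sqrt(correlation) * t
  } else z <- eps
  out <- rep(mu, each = n) + rep(sg, each = n) * z
  colnames(out) <- fameFeatures()
  out
}

#' Simulate a labeled FAME dataset
#'
#' Generates a synthetic dataset with the structure of the emulated
#' study: for each group, one specimen-level profile per fish (Gaussian
#' per-feature, see [drawSpecimens()]); six replicate chromatograms per
#' fish obtained by multiplying the specimen profile with independent
#' relative Gaussian noise of SD `replicateCv`; negative values truncated
#' at 0; every chromatogram renormalized to sum exactly 100
#' (compositional closure); finally `missingInstances` chromatograms
#' removed uniformly at random, emulating injections lost to
#' chromatographic problems.  Under the defaults this yields 596 usable
#' instances in 100 sample blocks.  Generation is bit-reproducible from
#' `seed`.
#'
#' The default `groupCorrelation` of 0.9 encodes that within-group
#' specimen variation in compositional GC-FID data is dominated by one
#' common "feed/fat content" axis rather than by independent per-acid
#' noise; see the package vignette for the calibration argument.
#'
#' @param params a [FameParameters] object; defaults to the published
#'   design.
#' @param replicateCv relative SD of within-sample analytical noise
#'   (unitless, default 0.02).
#' @param groupCorrelation latent-factor inter-feature correlation in
#'   \[0, 1) applied within `correlatedGroups` (default 0.9).
#' @param correlatedGroups class names carrying the latent factor;
#'   default the Chile farmed / Canada farmed pair whose overlap the
#'   study reports.
#' @param missingInstances chromatograms to drop at random (default 4).
#' @param seed integer seed; every source of randomness is derived from
#'   it.
#' @return A [FameExperiment] with `metadata(x)$generator` recording the
#'   configuration.
#' @examples
#' fe <- simulateFame(seed = 1)
#' fe
#' @export
simulateFame <- function(params = defaultParameters(), replicateCv = 0.02,
                         groupCorrelation = 0.9,
                         correlatedGroups = c("Chile farmed", "Canada farmed"),
                         missingInstances = 4L, seed = 1L) {
  stopifnot(replicateCv >= 0, missingInstances >= 0,
            groupCorrelation >= 0, groupCorrelation < 1)
  validObject(params)
  set.seed(seed)
  nrep <- params@nReplicates
  cls <- fameClasses()
  vals <- list(); sid <- character(0); lab <- character(0); rep_ <- integer(0)
  s <- 0L
  for (g in seq_along(cls)) {
    spec <- drawSpecimens(params, cls[g], params@nSamples[g],
                          correlation = groupCorrelation,
                          applyFactor = cls[g] %in% correlatedGroups)
    spec <- pmax(spec, 0)
    for (i in seq_len(params@nSamples[g])) {
      s <- s + 1L
      noise <- matrix(1 + replicateCv * rnorm(nrep * 17L), nrep, 17L)
      x <- pmax(rep(spec[i, ], each = nrep) * noise, 0)
      x <- 100 * x / rowSums(x)
      vals[[s]] <- x
      sid <- c(sid, rep(sprintf("S%03d", s), nrep))
      lab <- c(lab, rep(cls[g], nrep))
      rep_ <- c(rep_, seq_len(nrep))
    }
  }
  X <- do.call(rbind, vals)
  colnames(X) <- fameFeatures()
  if (missingInstances > 0) {
    drop <- sample(nrow(X), missingInstances)
    X <- X[-drop, , drop = FALSE]
    sid <- sid[-drop]; lab <- lab[-drop]; rep_ <- rep_[-drop]
  }
  fe <- FameExperiment(X, sampleId = sid, classLabel = lab, replicate = rep_)
  metadata(fe)$generator <- list(
    replicateCv = replicateCv, groupCorrelation = groupCorrelation,
    correlatedGroups = correlatedGroups,
    missingInstances = as.integer(missingInstances), seed = as.integer(seed))
  fe
}
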