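# small hand-built datasets used across test files

# one block per (class, center); replicates identical within a block
blockDataset <- function(centers, classes, nrep = 3L, jitter = 0) {
  stopifnot(nrow(centers) == length(classes))
  vals <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rep(centers[i, ], each = nrep), nrow = nrep) +
      jitter * matrix(seq_len(nrep * ncol(centers)), nrow = nrep)
  }))
  colnames(vals) <- colnames(centers)
  FameExperiment(vals,
                 sampleId = rep(sprintf("B%02d", seq_len(nrow(centers))),
                                each = nrep),
                 classLabel = rep(classes, each = nrep))
}

# a valid canonical profile matrix: closed group-mean rows
closedRows <- function(group, n) {
  cm <- closedMeanProfile(defaultParameters(), group)
  matrix(rep(cm, each = n), nrow = n,
         dimnames = list(NULL, fameFeatures()))
}

# ranking object over synthetic feature names, scores descending
fakeRanking <- function(n) {
  new("FameRanking",
      ranking = data.frame(feature = sprintf("f%02d", seq_len(n)),
                           gainRatio = seq(1, 0.01, length.out = n)))
}

# evaluator over a fixed accuracy-by-prefix vector, with call counting
vectorEvaluator <- function(acc) {
  calls <- integer(0)
  list(fn = function(m) { calls <<- c(calls, m); acc[m] },
       calls = function() calls)
}
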