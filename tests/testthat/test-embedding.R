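planarDataset <- function(n = 30) {
  # rank-2 data in 5-D: affine image of a 2-D latent sheet
  set.seed(12)
  latent <- cbind(rnorm(n), rnorm(n))
  A <- matrix(rnorm(10), 2, 5)
  vals <- latent %*% A + matrix(rep(1:5, each = n), n)
  colnames(vals) <- paste0("f", 1:5)
  FameExperiment(vals, sampleId = sprintf("B%02d", seq_len(n)),
                 classLabel = rep("Canada wild", n))
}

test_that("rank-2 data is fully captured by two components", {
  fe <- planarDataset()
  emb <- pcaProject(fe, nComponents = 2, standardize = FALSE)
  expect_equal(sum(explainedVariance(emb)), 1, tolerance = 1e-9)
  expect_identical(nrow(coordinates(emb)), 30L)
})

test_that("collinear points reproduce the hand eigendecomposition", {
  vals <- cbind(f1 = c(0, 1, 2), f2 = c(0, 0, 0))
  fe <- FameExperiment(vals, sampleId = c("A", "B", "C"),
                       classLabel = rep("Canada wild", 3))
  emb <- pcaProject(fe, nComponents = 2, standardize = FALSE)
  expect_equal(explainedVariance(emb)[1], 1, tolerance = 1e-12)
  expect_equal(unname(coordinates(emb)[, 1]), c(-1, 0, 1),
               tolerance = 1e-12)
  expect_equal(unname(coordinates(emb)[, 2]), c(0, 0, 0),
               tolerance = 1e-12)
})

test_that("variance fractions are in [0,1], non-increasing, sum <= 1", {
  fe <- simulateFame(seed = 6)
  emb <- pcaProject(fe, nComponents = 5)
  ev <- explainedVariance(emb)
  expect_true(all(ev >= 0 & ev <= 1))
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-12)
  full <- pcaProject(fe, nComponents = 17)
  expect_equal(sum(explainedVariance(full)), 1, tolerance = 1e-9)
})

test_that("PCA scores are translation-invariant and scale as c^2", {
  fe <- planarDataset()
  vals <- profileMatrix(fe)
  shifted <- FameExperiment(vals + 7, sampleId = sampleId(fe),
                            classLabel = classLabel(fe))
  a <- pcaProject(fe, standardize = FALSE)
  b <- pcaProject(shifted, standardize = FALSE)
  expect_equal(coordinates(a), coordinates(b), tolerance = 1e-9)
  # scaling one feature by c multiplies its variance contribution by c^2
  v2 <- cbind(f1 = rnorm(50), f2 = rnorm(50))
  totalVar <- function(M) sum(apply(M, 2, var))
  expect_equal(totalVar(cbind(v2[, 1] * 3, v2[, 2])),
               9 * var(v2[, 1]) + var(v2[, 2]), tolerance = 1e-12)
})

test_that("t-SNE returns one 2-D row per instance, reproducibly", {
  fe <- simulateFame(seed = 2)
  emb <- tsneMap(fe, maxIter = 260, seed = 5)
  expect_identical(dim(coordinates(emb)), c(596L, 2L))
  emb2 <- tsneMap(fe, maxIter = 260, seed = 5)
  expect_identical(coordinates(emb), coordinates(emb2))
})

test_that("undersized datasets shrink the perplexity with a warning", {
  fe <- planarDataset(n = 25)
  expect_warning(emb <- tsneMap(fe, perplexity = 30, maxIter = 100, seed = 1),
                 "perplexity")
  expect_identical(nrow(coordinates(emb)), 25L)
})

test_that("degenerate all-identical input is refused", {
  vals <- matrix(1, 20, 2, dimnames = list(NULL, c("f1", "f2")))
  fe <- FameExperiment(vals, sampleId = sprintf("B%02d", 1:20),
                       classLabel = rep("Canada wild", 20))
  expect_error(tsneMap(fe, seed = 1), "degenerate")
})

test_that("the t-SNE stage preserves blocks, labels and instance count", {
  fe <- simulateFame(seed = 2)
  top3 <- rankedFeatures(rankFeatures(fe))[1:3]
  mapped <- tsneFeatureStage(fe, features = top3, maxIter = 260, seed = 2)
  expect_identical(ncol(mapped), ncol(fe))
  expect_identical(rownames(mapped), c("tSNE1", "tSNE2"))
  expect_identical(sampleId(mapped), sampleId(fe))
  expect_identical(classLabel(mapped), classLabel(fe))
  expect_identical(replicateIndex(mapped), replicateIndex(fe))
})
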