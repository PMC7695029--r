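test_that("holdout split assigns 20 whole blocks, 5 per class", {
  fe <- simulateFame(seed = 1)
  sp <- splitHoldout(fe, seed = 3)
  testBlocks <- unique(sampleId(sp$test))
  expect_identical(length(testBlocks), 20L)
  blockClass <- tapply(as.character(classLabel(sp$test)),
                       sampleId(sp$test), function(x) x[[1L]])
  expect_true(all(table(factor(blockClass, fameClasses())) == 5L))
  # no block straddles the split, and all instances are used exactly once
  expect_length(intersect(unique(sampleId(sp$train)), testBlocks), 0L)
  expect_identical(ncol(sp$train) + ncol(sp$test), ncol(fe))
  # deterministic per seed
  sp2 <- splitHoldout(fe, seed = 3)
  expect_identical(sampleId(sp2$test), sampleId(sp$test))
  sp3 <- splitHoldout(fe, seed = 4)
  expect_false(identical(sampleId(sp3$test), sampleId(sp$test)))
})

test_that("stratification fails loudly on a single-block class", {
  fe <- simulateFame(seed = 1)
  keep <- classLabel(fe) != "Canada wild" | sampleId(fe) == "S076"
  expect_error(splitHoldout(fe[, keep], seed = 1), "single sample block")
})

test_that("metrics match the hand-computed worked example", {
  m <- computeMetrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(m$accuracy, 0.75)
  # class-0 F1 = 2/3, class-1 F1 = 4/5, equal true-class weights
  expect_equal(m$f1, 0.5 * 2 / 3 + 0.5 * 4 / 5, tolerance = 1e-12)
  expect_identical(m$confusionCounts["0", "1"], 1L)
  expect_equal(unname(rowSums(m$confusionProportion)), c(1, 1))
})

test_that("perfect and constant predictors bound the metrics", {
  y <- rep(fameClasses(), times = 5)
  p <- computeMetrics(y, y)
  expect_equal(p$accuracy, 1)
  expect_equal(p$f1, 1)
  expect_equal(unname(p$confusionProportion), diag(4))
  # always predicting class 0 on a balanced 4-class set
  c0 <- computeMetrics(y, rep("Norway farmed", 20), levels = fameClasses())
  expect_equal(c0$accuracy, 0.25)
})

test_that("confusion counts total the test set and proportions row-normalize", {
  fe <- simulateFame(seed = 2)
  ev <- evaluateHoldout(fe, fameClassifier("naiveBayes"), seed = 2)
  cm <- confusionMatrix(ev)
  expect_identical(sum(cm), ncol(splitHoldout(fe, seed = 2)$test))
  pr <- confusionMatrix(ev, proportions = TRUE)
  occ <- rowSums(cm) > 0
  expect_equal(unname(rowSums(pr)[occ]), rep(1, sum(occ)))
})

test_that("LOSO builds one fold per block and pools predictions", {
  centers <- rbind(c(1, 0), c(1.1, 0), c(1.2, 0),
                   c(5, 0), c(5.1, 0), c(5.2, 0))
  colnames(centers) <- c("f1", "f2")
  fe <- blockDataset(centers, rep(c("Canada wild", "Chile farmed"),
                                  each = 3))
  ev <- evaluateLosoCv(fe, fameClassifier("kNN"))
  expect_identical(nrow(ev@perFold), 6L)
  # identical replicates per block, distinct blocks within a class:
  # distance-weighted kNN classifies every held-out block perfectly
  expect_equal(ev@accuracy, 1)
  expect_equal(sum(confusionMatrix(ev)), ncol(fe))
})

test_that("metrics are invariant to instance order", {
  set.seed(5)
  y <- sample(fameClasses(), 40, replace = TRUE)
  p <- sample(fameClasses(), 40, replace = TRUE)
  perm <- sample(40)
  a <- computeMetrics(y, p)
  b <- computeMetrics(y[perm], p[perm])
  expect_identical(a, b)
})

test_that("stochastic learners are reproducible under a fixed seed", {
  fe <- simulateFame(seed = 3)
  for (fam in c("randomForest", "ANN", "adaBoost")) {
    e1 <- evaluateHoldout(fe, fameClassifier(fam, seed = 7), seed = 3)
    e2 <- evaluateHoldout(fe, fameClassifier(fam, seed = 7), seed = 3)
    expect_identical(confusionMatrix(e1), confusionMatrix(e2))
  }
})

test_that("at least six of the seven families reach 99% on the default data", {
  fe <- simulateFame(seed = 1)
  tb <- runBench(fe, defaultClassifiers(seed = 1), seed = 1)
  expect_identical(nrow(tb), 7L)
  expect_gte(sum(tb$CA >= 0.99), 6L)
})
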