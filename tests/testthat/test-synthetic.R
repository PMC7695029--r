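test_that("default parameters hold the published group statistics", {
  prm <- defaultParameters()
  mu <- groupMeans(prm); sg <- groupSds(prm)
  expect_equal(mu["22:6n3", "Canada wild"], 18.83)
  expect_equal(sg["22:6n3", "Canada wild"], 2.82)
  expect_equal(mu["16:0", "Canada wild"], 15.75)
  expect_equal(sg["16:0", "Canada wild"], 1.70)
  expect_equal(mu["18:2n6c", "Chile farmed"], 16.36)
  expect_equal(sg["18:2n6c", "Chile farmed"], 0.72)
  expect_equal(mu["18:1n9c", "Norway farmed"], 43.89)
  expect_equal(sg["18:1n9c", "Norway farmed"], 0.29)
  expect_identical(unname(groupSizes(prm)), c(25L, 24L, 25L, 26L))
  # each group's means sum to 100 within the closure slack
  expect_true(all(abs(colSums(mu) - 100) <= 0.5))
})

test_that("the default design yields 596 usable instances in 100 blocks", {
  fe <- simulateFame(seed = 1)
  expect_identical(ncol(fe), 596L)
  expect_identical(length(unique(sampleId(fe))), 100L)
  # sample-level class counts are intact: dropping 4 chromatograms at
  # random cannot remove a whole 6-replicate block
  blockClass <- tapply(as.character(classLabel(fe)), sampleId(fe),
                       function(x) x[[1L]])
  counts <- table(factor(blockClass, fameClasses()))
  expect_identical(as.vector(counts), c(25L, 24L, 25L, 26L))
})

test_that("every generated profile satisfies the compositional invariants", {
  fe <- simulateFame(seed = 4)
  X <- profileMatrix(fe)
  expect_true(all(X >= 0 & X <= 100))
  expect_true(all(abs(rowSums(X) - 100) < 1e-9))
  expect_true(validObject(fe))
})

test_that("generation is bit-reproducible from the seed", {
  a <- simulateFame(seed = 123)
  b <- simulateFame(seed = 123)
  expect_identical(profileMatrix(a), profileMatrix(b))
  expect_identical(sampleId(a), sampleId(b))
  c <- simulateFame(seed = 124)
  expect_false(identical(profileMatrix(a), profileMatrix(c)))
})

test_that("with all noise off every profile equals the closed group mean", {
  prm <- defaultParameters()
  prm@sd[] <- 0
  fe <- simulateFame(prm, replicateCv = 0, groupCorrelation = 0,
                     missingInstances = 0, seed = 9)
  expect_identical(ncol(fe), 600L)
  X <- profileMatrix(fe)
  for (g in fameClasses()) {
    cm <- closedMeanProfile(defaultParameters(), g)
    rows <- X[classLabel(fe) == g, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, cm))), 1e-10)
  }
})

test_that("specimen draws recover the parameter table moments", {
  prm <- defaultParameters()
  set.seed(31)
  n <- 5000
  M <- drawSpecimens(prm, "Canada wild", n)
  mu <- groupMeans(prm)[, "Canada wild"]
  sg <- groupSds(prm)[, "Canada wild"]
  expect_true(all(abs(colMeans(M) - mu) < 3 * sg / sqrt(n) + 1e-12))
  expect_true(all(abs(apply(M, 2, sd) - sg) < 4 * sg / sqrt(n) + 1e-12))
  # the latent factor preserves marginal moments while correlating features
  set.seed(32)
  Mc <- drawSpecimens(prm, "Chile farmed", n, correlation = 0.9,
                      applyFactor = TRUE)
  muc <- groupMeans(prm)[, "Chile farmed"]
  sgc <- groupSds(prm)[, "Chile farmed"]
  expect_true(all(abs(colMeans(Mc) - muc) < 3 * sgc / sqrt(n) + 1e-12))
  expect_true(all(abs(apply(Mc, 2, sd) - sgc) < 5 * sgc / sqrt(n) + 1e-12))
  cors <- cor(Mc)
  expect_gt(mean(cors[upper.tri(cors)]), 0.8)
})

test_that("invalid generator settings are refused", {
  prm <- defaultParameters()
  expect_error(simulateFame(prm, replicateCv = -0.1), "replicateCv")
  expect_error(simulateFame(prm, groupCorrelation = 1), "groupCorrelation")
  prm@sd[1, 1] <- -1
  expect_error(simulateFame(prm), "sds")
})
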