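test_that("zero-variance data reproduces the closed-mean composition sums", {
  prm <- defaultParameters()
  prm@sd[] <- 0
  fe <- simulateFame(prm, replicateCv = 0, groupCorrelation = 0,
                     missingInstances = 0, seed = 1)
  s <- suppressWarnings(summarizeGroups(fe))
  wildSfa <- s$mean[s$quantity == "SFA" & s$group == "Canada wild"]
  # 14:0 + 16:0 + 18:0 at the published means: 3.86 + 15.75 + 3.61 = 23.22
  # (the published table prints 23.25; per-sample summation under closure
  # stays within the 0.1 rounding tolerance)
  expect_lt(abs(wildSfa - 23.22), 0.1)
  expect_identical(unique(s$sd), 0)
})

test_that("SFA + MUFA + PUFA partition the closed composition exactly", {
  fe <- simulateFame(seed = 4)
  s <- summarizeGroups(fe)
  sums <- tapply(s$mean[s$quantity %in% c("SFA", "MUFA", "PUFA")],
                 s$group[s$quantity %in% c("SFA", "MUFA", "PUFA")], sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("replicates are averaged before group statistics", {
  # two samples per group whose replicates differ but whose sample means
  # are fixed: the group SD must reflect sample-level spread only
  centers <- rbind(c(10, 90), c(12, 88), c(30, 70), c(34, 66))
  colnames(centers) <- c("f1", "f2")
  fe <- blockDataset(centers, rep(c("Canada wild", "Chile farmed"),
                                  each = 2), nrep = 2L)
  # perturb replicates symmetrically: sample means unchanged
  vals <- profileMatrix(fe)
  vals[, "f1"] <- vals[, "f1"] + rep(c(-1, 1), 4)
  fe2 <- FameExperiment(vals, sampleId = sampleId(fe),
                        classLabel = classLabel(fe),
                        replicate = replicateIndex(fe))
  at <- anovaTukey(fe2, "f1")
  expect_equal(unname(at$means["Canada wild"]), 11)
  expect_equal(unname(at$sds["Canada wild"]), sd(c(10, 12)))
})

test_that("hand-computed two-group ANOVA gives a huge F and distinct letters", {
  centers <- cbind(f1 = c(1, 2, 3, 101, 102, 103), f2 = 7)
  fe <- blockDataset(centers, rep(c("Canada wild", "Chile farmed"),
                                  each = 3), nrep = 1L)
  at <- anovaTukey(fe, "f1")
  expect_equal(at$F, 15000, tolerance = 1e-9)
  expect_lt(at$p, 1e-6)
  expect_identical(sort(unique(at$letters)), c("a", "b"))
  expect_false(at$letters["Canada wild"] == at$letters["Chile farmed"])
})

test_that("identically distributed groups share one letter", {
  set.seed(21)
  centers <- cbind(f1 = rnorm(12), f2 = 5)
  fe <- blockDataset(centers, rep(c("Norway farmed", "Chile farmed",
                                    "Canada farmed"), each = 4), nrep = 1L)
  at <- anovaTukey(fe, "f1")
  expect_identical(unname(at$letters), rep("a", 3))
})

test_that("letters are a valid compact display of the pairwise tests", {
  fe <- simulateFame(seed = 1)
  for (q in c("16:0", "18:2n6c", "22:6n3", "n3/n6")) {
    at <- anovaTukey(fe, q)
    share <- function(a, b) {
      la <- strsplit(at$letters[[a]], "")[[1]]
      lb <- strsplit(at$letters[[b]], "")[[1]]
      length(intersect(la, lb)) > 0
    }
    for (nm in names(at$pairwise)) {
      gg <- strsplit(nm, "-", fixed = TRUE)[[1]]
      expect_identical(share(gg[1], gg[2]), at$pairwise[[nm]] >= 0.05,
                       label = paste(q, nm))
    }
  }
})

test_that("published significance pattern for linoleic acid is reproduced", {
  fe <- simulateFame(seed = 1)
  at <- anovaTukey(fe, "18:2n6c")
  # wild alone on a letter; Chile and Norway share one distinct from
  # Canada farmed
  expect_false(at$letters["Canada wild"] %in%
                 at$letters[c("Chile farmed", "Norway farmed",
                              "Canada farmed")])
  expect_identical(at$letters[["Chile farmed"]],
                   at$letters[["Norway farmed"]])
  expect_false(at$letters[["Canada farmed"]] == at$letters[["Chile farmed"]])
})

test_that("exact ties are reported fully significant with a warning", {
  centers <- cbind(f1 = rep(c(1, 5), each = 3), f2 = 2)
  fe <- blockDataset(centers, rep(c("Canada wild", "Chile farmed"),
                                  each = 3), nrep = 1L)
  expect_warning(at <- anovaTukey(fe, "f1"), "zero within-group variance")
  expect_identical(at$F, Inf)
  expect_false(at$letters[["Canada wild"]] == at$letters[["Chile farmed"]])
})

test_that("single-sample groups summarize with zero SD and a warning", {
  centers <- rbind(c(10, 90), c(12, 88), c(30, 70))
  colnames(centers) <- c("f1", "f2")
  fe <- blockDataset(centers, c("Canada wild", "Canada wild",
                                "Chile farmed"), nrep = 2L)
  expect_warning(s <- summarizeGroups(fe), "single sample")
  expect_identical(s$sd[s$group == "Chile farmed"], c(0, 0))
})

test_that("both co-eluting peak conventions are available for n3/n6", {
  fe <- simulateFame(seed = 3)
  ex <- anovaTukey(fe, "n3/n6", apportionCoeluting = "exclude")
  hf <- anovaTukey(fe, "n3/n6", apportionCoeluting = "half")
  expect_false(isTRUE(all.equal(ex$means, hf$means)))
  # wild is far above all farmed groups under either convention
  expect_gt(min(ex$means["Canada wild"], hf$means["Canada wild"]), 10)
  expect_lt(max(ex$means[c("Norway farmed", "Chile farmed",
                           "Canada farmed")]), 2)
})
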