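test_that("constructor reorders canonical features and keeps block metadata", {
  cm <- closedMeanProfile(defaultParameters(), "Canada wild")
  shuffled <- sample(fameFeatures())
  vals <- matrix(rep(cm[shuffled], each = 2), nrow = 2,
                 dimnames = list(NULL, shuffled))
  fe <- FameExperiment(vals, sampleId = c("F1", "F1"),
                       classLabel = c(3L, 3L))
  expect_identical(rownames(fe), fameFeatures())
  expect_equal(unname(profileMatrix(fe)[1, ]), unname(cm[fameFeatures()]))
  expect_identical(replicateIndex(fe), c(1L, 2L))
  expect_identical(as.character(classLabel(fe)),
                   rep("Canada wild", 2))
  expect_identical(classCode(fe), c(3L, 3L))
})

test_that("compositional invariants are enforced on canonical datasets", {
  vals <- closedRows("Canada wild", 1)
  # profile summing to 92 is rejected
  expect_error(FameExperiment(vals * 0.92, sampleId = "F1",
                              classLabel = "Canada wild"),
               "closure")
  # negative or > 100 values are rejected
  bad <- vals; bad[1, 1] <- -1; bad[1, 2] <- bad[1, 2] + 1
  expect_error(FameExperiment(bad, sampleId = "F1",
                              classLabel = "Canada wild"),
               "\\[0, 100\\]")
  # a wider tolerance admits a mild closure deficit
  expect_s4_class(FameExperiment(vals * 0.99, sampleId = "F1",
                                 classLabel = "Canada wild",
                                 closureTol = 1.5),
                  "FameExperiment")
})

test_that("a block cannot mix class labels and holds at most 6 replicates", {
  vals <- closedRows("Canada wild", 2)
  expect_error(FameExperiment(vals, sampleId = c("F1", "F1"),
                              classLabel = c("Canada wild", "Chile farmed")),
               "share one class label")
  vals7 <- closedRows("Canada wild", 7)
  expect_error(FameExperiment(vals7, sampleId = rep("F1", 7),
                              classLabel = "Canada wild",
                              replicate = c(1:6, 1L)),
               "at most 6")
})

test_that("class coding follows the fixed bijection", {
  expect_identical(fameClasses(),
                   c("Norway farmed", "Chile farmed", "Canada farmed",
                     "Canada wild"))
  vals <- closedRows("Norway farmed", 4)
  fe <- FameExperiment(vals, sampleId = paste0("F", 1:4),
                       classLabel = c(0L, 1L, 2L, 3L))
  expect_identical(as.character(classLabel(fe)), fameClasses())
  expect_error(FameExperiment(vals, sampleId = paste0("F", 1:4),
                              classLabel = c(0L, 1L, 2L, 4L)),
               "0..3")
})

test_that("CSV round trip is the identity on a full synthetic dataset", {
  fe <- simulateFame(seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFameCsv(fe, path)
  back <- readFameCsv(path)
  expect_identical(nrow(metadata(back)$rejected), 0L)
  ord <- order(sampleId(fe), replicateIndex(fe))
  expect_equal(profileMatrix(back),
               profileMatrix(fe)[ord, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(sampleId(back), sampleId(fe)[ord])
  expect_identical(as.character(classLabel(back)),
                   as.character(classLabel(fe))[ord])
  expect_identical(replicateIndex(back), replicateIndex(fe)[ord])
})

test_that("row-level rejection diagnoses bad rows without losing good ones", {
  fe <- simulateFame(seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFameCsv(fe[, 1:6], path)
  df <- read.csv(path, check.names = FALSE)
  df[2, "16:0"] <- df[[2, "16:0"]] * 0.5       # break closure
  df[3, "class"] <- "Atlantis farmed"          # unknown class
  df[4, "18:0"] <- "not-a-number"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  rej <- withr::local_tempfile(fileext = ".json")
  back <- readFameCsv(path, rejectPath = rej)
  report <- metadata(back)$rejected
  expect_identical(sort(report$row), c(2L, 3L, 4L))
  expect_match(report$reason[report$row == 2L], "closure")
  expect_match(report$reason[report$row == 3L], "unknown class")
  expect_match(report$reason[report$row == 4L], "non-numeric")
  expect_identical(ncol(back), 3L)
  expect_true(file.exists(rej))
  expect_identical(nrow(jsonlite::read_json(rej, simplifyVector = TRUE)), 3L)
})

test_that("missing feature columns abort the read", {
  fe <- simulateFame(seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFameCsv(fe[, 1:2], path)
  df <- read.csv(path, check.names = FALSE)
  df[["22:6n3"]] <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(readFameCsv(path), "22:6n3")
})

test_that("writing a single-instance dataset yields a header plus one row", {
  fe <- FameExperiment(closedRows("Chile farmed", 1), sampleId = "F1",
                       classLabel = "Chile farmed")
  path <- withr::local_tempfile(fileext = ".csv")
  writeFameCsv(fe, path)
  expect_identical(length(readLines(path)), 2L)
})
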