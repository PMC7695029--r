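#' Pipeline configuration
#'
#' Bundles every stage option of [runPipeline()] behind one master seed.
#' Stage seeds are derived deterministically from the master seed and the
#' stage index, so changing one stage's options never perturbs another
#' stage's randomness.
#'
#' @param seed master integer seed.
#' @param generator named list of [simulateFame()] arguments (less the
#'   seed).
#' @param threshold selection accuracy threshold (default 0.99).
#' @param classifiers character vector of bench families (default all
#'   seven).
#' @param tsneTopK how many top-ranked features feed the t-SNE stage
#'   regime (default 3).
#' @param perplexity,maxIter t-SNE options.
#' @param testFraction holdout test fraction (default 0.2).
#' @param outputDir optional directory; when given, [runPipeline()]
#'   writes all artifacts (CSV/JSON) and a manifest there.
#' @return list of class `"famePipelineConfig"`.
#' @export
famePipelineConfig <- function(seed = 1L, generator = list(),
                               threshold = 0.99,
                               classifiers = names(defaultClassifiers()),
                               tsneTopK = 3L, perplexity = 30,
                               maxIter = 1000L, testFraction = 0.2,
                               outputDir = NULL) {
  known <- names(defaultClassifiers())
  bad <- setdiff(classifiers, known)
  if (length(bad))
    stop("unknown classifier name(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), generator = generator,
                 threshold = threshold, classifiers = classifiers,
                 tsneTopK = as.integer(tsneTopK), perplexity = perplexity,
                 maxIter = as.integer(maxIter),
                 testFraction = testFraction, outputDir = outputDir),
            class = "famePipelineConfig")
}

.stageSeed <- function(master, stage) {
  as.integer((as.double(master) * 131L + stage * 7919L) %% 2147483647L)
}

# wall-clock is deliberately excluded: report files must be byte-identical
# across reruns of one configuration; timings go to timings.json instead
.evalToList <- function(ev)
  list(classifier = ev@classifier, CA = ev@accuracy, F1 = ev@f1,
       confusionCounts = unname(ev@confusionCounts),
       confusionProportion = unname(ev@confusionProportion),
       scheme = ev@scheme, features = ev@featureSet,
       seed = ev@seed)

#' Run the full analysis pipeline
#'
#' Executes, from one configuration: data simulation, gain-ratio feature
#' ranking, minimal-feature binary search (kNN evaluator, LOSO), the same
#' search with the t-SNE stage inserted, PCA and t-SNE embeddings, the
#' classifier bench under the three feature regimes (all 17 features /
#' the selected subset / the t-SNE mapping of the top-`tsneTopK`
#' features), and the per-group compositional summary.  The returned
#' bundle is fully determined by the configuration; with `outputDir` set,
#' all tables are additionally written as CSV/JSON plus a manifest
#' recording the configuration, stage seeds and package version.
#'
#' @param config a [famePipelineConfig()].
#' @return list of class `"fameReport"` with elements `data`, `ranking`,
#'   `selection`, `selectionTsne`, `pca`, `tsne`, `bench` (one
#'   performance table per regime), `summary`, `manifest`.
#' @examples
#' \donttest{
#' rep <- runPipeline(famePipelineConfig(seed = 7,
#'   classifiers = c("kNN", "SVM")))
#' rep$bench$all17
#' }
#' @export
runPipeline <- function(config = famePipelineConfig()) {
  stopifnot(inherits(config, "famePipelineConfig"))
  seeds <- vapply(1:6, function(i) .stageSeed(config$seed, i), integer(1))
  fe <- do.call(simulateFame,
                c(config$generator, list(seed = seeds[[1L]])))
  ranking <- rankFeatures(fe)

  knn <- fameClassifier("kNN", seed = seeds[[2L]])
  sel <- minimalFeatureSearch(
    ranking, prefixEvaluator(fe, ranking, knn, scheme = "loso",
                             seed = seeds[[2L]]),
    threshold = config$threshold)
  selTsne <- minimalFeatureSearch(
    ranking, prefixEvaluator(fe, ranking, knn, scheme = "loso",
                             tsneStage = TRUE,
                             tsneArgs = list(perplexity = config$perplexity,
                                             maxIter = config$maxIter),
                             seed = seeds[[3L]]),
    threshold = config$threshold)

  pca <- pcaProject(fe)
  tsne <- tsneMap(fe, perplexity = config$perplexity,
                  maxIter = config$maxIter, seed = seeds[[4L]])
  topK <- rankedFeatures(ranking)[seq_len(config$tsneTopK)]
  feTsne <- tsneFeatureStage(fe, features = topK,
                             perplexity = config$perplexity,
                             maxIter = config$maxIter, seed = seeds[[4L]])

  specs <- setNames(lapply(config$classifiers, fameClassifier,
                           seed = seeds[[5L]]), config$classifiers)
  benchSeed <- seeds[[6L]]
  bench <- list(
    all17 = runBench(fe, specs, scheme = "holdout", seed = benchSeed),
    selected = runBench(fe, specs, features = selectedFeatures(sel),
                        scheme = "holdout", seed = benchSeed),
    tsneTop = runBench(feTsne, specs, scheme = "holdout", seed = benchSeed))

  summary <- summarizeGroups(fe)
  manifest <- list(package = "fameclass",
                   version = as.character(utils::packageVersion("fameclass")),
                   masterSeed = config$seed, stageSeeds = seeds,
                   generator = metadata(fe)$generator,
                   threshold = config$threshold,
                   classifiers = config$classifiers,
                   regimes = list(all17 = fameFeatures(),
                                  selected = selectedFeatures(sel),
                                  tsneTop = topK))
  rep <- structure(list(data = fe, ranking = ranking, selection = sel,
                        selectionTsne = selTsne, pca = pca, tsne = tsne,
                        bench = bench, summary = summary,
                        manifest = manifest),
                   class = "fameReport")
  if (!is.null(config$outputDir)) .writeReport(rep, config$outputDir)
  rep
}

.writeReport <- function(rep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeFameCsv(rep$data, file.path(dir, "dataset.csv"))
  jsonlite::write_json(as.data.frame(rep$ranking),
                       file.path(dir, "ranking.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(k = rep$selection@k, selected = rep$selection@selected,
         prefixAccuracies = as.list(rep$selection@prefixAccuracies),
         usedAllFeatures = rep$selection@usedAllFeatures,
         tsneStage = list(k = rep$selectionTsne@k,
                          selected = rep$selectionTsne@selected)),
    file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(coordinates(rep$pca),
                              class = as.character(classLabel(rep$data))),
                   file.path(dir, "pca.csv"), row.names = FALSE)
  utils::write.csv(data.frame(coordinates(rep$tsne),
                              class = as.character(classLabel(rep$data))),
                   file.path(dir, "tsne.csv"), row.names = FALSE)
  benchOut <- lapply(rep$bench, function(tb)
    lapply(attr(tb, "evaluations"), .evalToList))
  jsonlite::write_json(benchOut, file.path(dir, "bench.json"),
                       auto_unbox = TRUE, digits = NA)
  timings <- lapply(rep$bench, function(tb)
    setNames(as.list(tb$testTime), tb$model))
  jsonlite::write_json(timings, file.path(dir, "timings.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(rep$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rep$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.fameReport <- function(x, ...) {
  cat("fameReport (seed", x$manifest$masterSeed, ")\n")
  cat("  dataset:", ncol(x$data), "instances\n")
  cat("  top features:",
      paste(head(rankedFeatures(x$ranking), 3L), collapse = ", "), "\n")
  cat("  selection: k =", x$selection@k,
      "| with t-SNE stage: k =", x$selectionTsne@k, "\n")
  cat("  PCA PC1+PC2:",
      sprintf("%.1f%%", 100 * sum(explainedVariance(x$pca))), "\n")
  for (nm in names(x$bench)) {
    tb <- x$bench[[nm]]
    cat(sprintf("  bench[%s]: best %s CA=%.3f\n", nm, tb$model[1L],
                tb$CA[1L]))
  }
  invisible(x)
}
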