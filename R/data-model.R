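#' Construct a FameExperiment from a profile matrix
#'
#' Builds the package's central container from an instances-by-features
#' matrix of relative percentages plus per-instance block metadata.  When
#' the supplied features are the canonical 17 (in any order) they are
#' reordered canonically and the compositional invariants (values in
#' \[0, 100\], sum-closure to 100 within `closureTol`) are enforced by the
#' class validity.
#'
#' @param values numeric matrix, instances x features, with feature
#'   identifiers as column names.
#' @param sampleId character (or coercible), one fish identifier per
#'   instance; all instances sharing an identifier form one sample block.
#' @param classLabel class of each instance: names from [fameClasses()],
#'   a factor over them, or integer codes 0..3.
#' @param replicate integer replicate index (1..6) within the block;
#'   defaults to 1, 2, ... within each block in input order.
#' @param closureTol closure tolerance in percentage points (default 0.5).
#' @return A [FameExperiment].
#' @examples
#' prm <- defaultParameters()
#' x <- matrix(rep(closedMeanProfile(prm, "Canada wild"), 2),
#'             nrow = 2, byrow = TRUE, dimnames = list(NULL, fameFeatures()))
#' fe <- FameExperiment(x, sampleId = c("F1", "F1"),
#'                      classLabel = c("Canada wild", "Canada wild"))
#' fe
#' @export
FameExperiment <- function(values, sampleId, classLabel, replicate = NULL,
                           closureTol = 0.5) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("'values' must carry feature identifiers as column names")
  if (setequal(colnames(values), fameFeatures()))
    values <- values[, fameFeatures(), drop = FALSE]
  sampleId <- as.character(sampleId)
  if (length(sampleId) != nrow(values))
    stop("one sampleId per instance is required")
  classLabel <- .asClassFactor(classLabel)
  if (length(classLabel) == 1L) classLabel <- rep(classLabel, nrow(values))
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(sampleId), sampleId, FUN = seq_along)
  cd <- DataFrame(sampleId = sampleId, classLabel = classLabel,
                  replicate = as.integer(replicate))
  se <- SummarizedExperiment(
    assays = list(relabund = t(values)), colData = cd,
    metadata = list(closureTol = closureTol))
  new("FameExperiment", se)
}

#' Accessors for FameExperiment
#'
#' `profileMatrix()` returns the instances-by-features numeric matrix;
#' `sampleId()`, `classLabel()`, `classCode()` and `replicateIndex()`
#' return the per-instance block metadata.  Class codes follow the fixed
#' bijection of [fameClasses()] (0 — Norway farmed ... 3 — Canada wild).
#'
#' @param x a [FameExperiment].
#' @return `profileMatrix`: numeric matrix; `sampleId`: character;
#'   `classLabel`: factor; `classCode`: integer 0..3; `replicateIndex`:
#'   integer.
#' @name FameExperiment-accessors
#' @aliases profileMatrix sampleId classLabel classCode replicateIndex
#' @examples
#' fe <- simulateFame(seed = 1)
#' dim(profileMatrix(fe))
#' table(classLabel(fe))
NULL

#' @rdname FameExperiment-accessors
#' @export
setMethod("profileMatrix", "FameExperiment",
          function(x) t(assay(x, "relabund")))

#' @rdname FameExperiment-accessors
#' @export
setMethod("sampleId", "FameExperiment",
          function(x) as.character(colData(x)$sampleId))

#' @rdname FameExperiment-accessors
#' @export
setMethod("classLabel", "FameExperiment",
          function(x) colData(x)$classLabel)

#' @rdname FameExperiment-accessors
#' @export
setMethod("classCode", "FameExperiment",
          function(x) as.integer(colData(x)$classLabel) - 1L)

#' @rdname FameExperiment-accessors
#' @export
setMethod("replicateIndex", "FameExperiment",
          function(x) as.integer(colData(x)$replicate))

setMethod("show", "FameExperiment", function(object) {
  cat("FameExperiment:", ncol(object), "chromatograms,",
      length(unique(sampleId(object))), "sample blocks,",
      nrow(object), "features\n")
  tab <- table(classLabel(object))
  cat("  instances per class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

# ---- CSV interchange --------------------------------------------------------

.defaultSchema <- function() {
  list(sampleId = "sample_id", classLabel = "class", replicate = "replicate")
}

#' Read a labeled FAME dataset from CSV
#'
#' Expects a comma-separated, dot-decimal, UTF-8 file with a header row
#' holding a sample-identifier column, a class column, optionally a
#' replicate column, and the 17 canonical feature columns (any order;
#' whitespace around feature names is ignored).  Rows violating the
#' profile invariants — unknown class name, non-numeric feature cell, or
#' sum-closure beyond `closureTol` — are rejected individually; the
#' surviving rows form the returned dataset and the row-level diagnostics
#' are stored in `metadata(result)$rejected` (and optionally written as a
#' JSON report).
#'
#' @param path CSV file path.
#' @param schema named list mapping the roles `sampleId`, `classLabel`,
#'   `replicate` to actual column names; defaults to `sample_id`, `class`,
#'   `replicate`.
#' @param closureTol closure tolerance in percentage points.
#' @param rejectPath optional path; when given, the rejection report is
#'   written there as JSON.
#' @return A [FameExperiment]; `metadata(x)$rejected` is a data.frame
#'   with columns `row` and `reason` (zero rows when all passed).
#' @seealso [writeFameCsv()]
#' @export
readFameCsv <- function(path, schema = NULL, closureTol = 0.5,
                        rejectPath = NULL) {
  schema <- utils::modifyList(.defaultSchema(), as.list(schema))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  names(df) <- trimws(names(df))
  for (role in c("sampleId", "classLabel")) {
    if (!schema[[role]] %in% names(df))
      stop("column '", schema[[role]], "' (", role, ") missing from ", path)
  }
  featCols <- gsub("[[:space:]]", "", names(df))
  missing <- setdiff(fameFeatures(), featCols)
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  names(df) <- ifelse(featCols %in% fameFeatures(), featCols, names(df))

  reasons <- character(0); rows <- integer(0)
  vals <- matrix(NA_real_, nrow(df), 17,
                 dimnames = list(NULL, fameFeatures()))
  for (f in fameFeatures()) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    vals[, f] <- v
  }
  reject <- function(i, why) { rows <<- c(rows, i); reasons <<- c(reasons, why) }
  classOk <- as.character(df[[schema$classLabel]]) %in% fameClasses()
  for (i in seq_len(nrow(df))) {
    if (!classOk[i]) { reject(i, "unknown class name"); next }
    if (anyNA(vals[i, ])) { reject(i, "non-numeric feature value"); next }
    if (any(vals[i, ] < 0) || any(vals[i, ] > 100)) {
      reject(i, "feature value outside [0, 100]"); next
    }
    if (abs(sum(vals[i, ]) - 100) > closureTol + 1e-8)
      reject(i, sprintf("profile sums to %.4g, violating closure to 100",
                        sum(vals[i, ])))
  }
  keep <- setdiff(seq_len(nrow(df)), rows)
  if (!length(keep))
    stop("no valid rows in ", path)
  rejected <- data.frame(row = rows, reason = reasons,
                         stringsAsFactors = FALSE)
  if (!is.null(rejectPath))
    jsonlite::write_json(rejected, rejectPath, auto_unbox = TRUE, digits = NA)
  rep <- if (schema$replicate %in% names(df))
    as.integer(df[[schema$replicate]][keep]) else NULL
  fe <- FameExperiment(vals[keep, , drop = FALSE],
                       sampleId = df[[schema$sampleId]][keep],
                       classLabel = df[[schema$classLabel]][keep],
                       replicate = rep, closureTol = closureTol)
  metadata(fe)$rejected <- rejected
  fe
}

#' Write a labeled FAME dataset to CSV
#'
#' Emits the canonical interchange form: columns `sample_id`, `class`,
#' `replicate`, then the 17 features in canonical order; rows sorted by
#' (`sample_id`, `replicate`).  Numeric cells are written at full double
#' precision so that `readFameCsv(writeFameCsv(x))` reproduces `x`.
#'
#' @param fe a [FameExperiment] over the canonical feature set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readFameCsv()]
#' @export
writeFameCsv <- function(fe, path) {
  stopifnot(is(fe, "FameExperiment"))
  ord <- order(sampleId(fe), replicateIndex(fe))
  df <- data.frame(sample_id = sampleId(fe)[ord],
                   class = as.character(classLabel(fe))[ord],
                   replicate = replicateIndex(fe)[ord],
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- profileMatrix(fe)[ord, , drop = FALSE]
  for (f in colnames(m)) df[[f]] <- format(m[, f], digits = 15, trim = TRUE,
                                           scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
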