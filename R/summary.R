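.SFA  <- c("14:0", "16:0", "18:0")
.MUFA <- c("16:1", "18:1n9c", "18:1n7", "20:1n9", "22:1n11+22:1n9", "24:1n9")
.PUFA <- c("18:2n6c", "18:3n3", "18:4n3", "20:2n6", "20:3n3+20:4n6",
           "20:5n3", "22:5n3", "22:6n3")
.N3   <- c("18:3n3", "18:4n3", "20:5n3", "22:5n3", "22:6n3")
.N6   <- c("18:2n6c", "20:2n6")

# per-sample feature table: replicates averaged, one row per fish
.sampleLevel <- function(fe) {
  X <- profileMatrix(fe)
  sid <- sampleId(fe)
  M <- apply(X, 2L, function(v) tapply(v, sid, mean))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L, dimnames = list(
    unique(sid), colnames(X)))
  cls <- tapply(as.character(classLabel(fe)), sid, function(l) l[[1L]])
  list(X = M, class = factor(cls[rownames(M)], levels = fameClasses()))
}

# derived compositional quantities per sample
.derivedQuantities <- function(M, apportionCoeluting = c("exclude", "half")) {
  apportionCoeluting <- match.arg(apportionCoeluting)
  co <- M[, "20:3n3+20:4n6"]
  n3 <- rowSums(M[, .N3, drop = FALSE])
  n6 <- rowSums(M[, .N6, drop = FALSE])
  if (apportionCoeluting == "half") { n3 <- n3 + co / 2; n6 <- n6 + co / 2 }
  cbind("SFA" = rowSums(M[, .SFA, drop = FALSE]),
        "MUFA" = rowSums(M[, .MUFA, drop = FALSE]),
        "PUFA" = rowSums(M[, .PUFA, drop = FALSE]),
        "n3/n6" = n3 / n6)
}

# insert-and-absorb compact letter display from a pairwise significance
# matrix (TRUE = significantly different); groups ordered by mean ascending
.compactLetters <- function(signif, meansAsc) {
  groups <- names(meansAsc)
  sets <- list(groups)
  pairs <- which(signif & upper.tri(signif), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    gi <- rownames(signif)[pairs[r, 1L]]
    gj <- colnames(signif)[pairs[r, 2L]]
    for (s in seq_along(sets)) {
      if (all(c(gi, gj) %in% sets[[s]])) {
        a <- setdiff(sets[[s]], gi)
        b <- setdiff(sets[[s]], gj)
        sets[[s]] <- a
        sets[[length(sets) + 1L]] <- b
      }
    }
    keep <- rep(TRUE, length(sets))          # absorb contained sets
    for (s in seq_along(sets)) for (t in seq_along(sets)) {
      if (s != t && keep[t] && all(sets[[s]] %in% sets[[t]]) &&
          length(sets[[s]]) < length(sets[[t]]))
        keep[s] <- FALSE
    }
    sets <- sets[keep]
    sets <- unique(sets)
  }
  # letters ordered by the lowest-mean member of each set
  lowRank <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(lowRank)]
  out <- setNames(rep("", length(groups)), groups)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Tests a feature (or derived quantity) for group differences at the
#' sample level — replicate chromatograms are averaged per fish first,
#' so the analysis unit is the specimen and replicates are not treated
#' as independent observations.  Pairwise comparisons use Tukey's honest
#' significant difference on the studentized range; groups sharing a
#' compact-display letter do not differ significantly at `alpha`.
#'
#' @param fe a [FameExperiment].
#' @param feature a feature identifier or one of `"SFA"`, `"MUFA"`,
#'   `"PUFA"`, `"n3/n6"`.
#' @param alpha significance level (default 0.05).
#' @param apportionCoeluting how the co-eluting 20:3n3+20:4n6 peak enters
#'   the n3/n6 ratio: `"exclude"` (default) or `"half"` (50/50 split).
#' @return list with `F`, `p`, `pairwise` (Tukey adjusted p-values),
#'   `letters`, `means`, `sds`, `n`.
#' @examples
#' fe <- simulateFame(seed = 1)
#' anovaTukey(fe, "18:2n6c")$letters
#' @export
anovaTukey <- function(fe, feature, alpha = 0.05,
                       apportionCoeluting = c("exclude", "half")) {
  sl <- .sampleLevel(fe)
  vals <- if (feature %in% colnames(sl$X)) sl$X[, feature]
  else {
    der <- .derivedQuantities(sl$X, apportionCoeluting)
    if (!feature %in% colnames(der))
      stop("unknown feature or derived quantity: ", feature)
    der[, feature]
  }
  grp <- droplevels(sl$class)
  if (nlevels(grp) < 2L) stop("ANOVA needs >= 2 groups present")
  if (any(table(grp) < 2L)) stop("every group needs >= 2 samples")
  means <- tapply(vals, grp, mean)
  sds <- tapply(vals, grp, stats::sd)
  ns <- as.vector(table(grp))
  df <- data.frame(v = vals, g = grp)
  fit <- aov(v ~ g, data = df)
  an <- summary(fit)[[1L]]
  ssRes <- an["Residuals", "Sum Sq"]
  if (ssRes < 1e-12 * max(abs(vals), 1)) {
    warning("zero within-group variance: groups with different means ",
            "reported as fully significant")
    cmb <- utils::combn(levels(grp), 2L)
    pw <- setNames(ifelse(abs(means[cmb[2L, ]] - means[cmb[1L, ]]) > 0,
                          0, 1),
                   paste(cmb[2L, ], cmb[1L, ], sep = "-"))
    Fstat <- Inf; pval <- 0
  } else {
    Fstat <- an["g", "F value"]; pval <- an["g", "Pr(>F)"]
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
    pw <- setNames(tk[, "p adj"], rownames(tk))
  }
  lv <- levels(grp)
  sig <- matrix(FALSE, length(lv), length(lv), dimnames = list(lv, lv))
  for (nm in names(pw)) {
    gg <- strsplit(nm, "-", fixed = TRUE)[[1L]]
    sig[gg[1L], gg[2L]] <- sig[gg[2L], gg[1L]] <- pw[[nm]] < alpha
  }
  ordAsc <- order(means)
  lettersOut <- .compactLetters(sig[ordAsc, ordAsc, drop = FALSE],
                                means[ordAsc])
  list(F = Fstat, p = pval, pairwise = pw,
       letters = lettersOut[lv], means = means, sds = sds,
       n = setNames(ns, lv))
}

#' Per-group compositional summary with significance letters
#'
#' Reproduces the descriptive layer of a published composition table:
#' for every fatty acid and for the derived quantities (saturated,
#' monounsaturated and polyunsaturated sums, omega-3/omega-6 ratio) the
#' per-group mean and SD over sample-level values (replicates averaged
#' first; derived quantities computed per sample, then summarized — mean
#' of ratios, not ratio of means) and the Tukey compact-letter display.
#'
#' @inheritParams anovaTukey
#' @param fe a [FameExperiment] over the canonical features.
#' @return data.frame in long form: `quantity`, `group`, `mean`, `sd`,
#'   `n`, `letter`.
#' @examples
#' fe <- simulateFame(seed = 1)
#' s <- summarizeGroups(fe)
#' subset(s, quantity == "16:0")
#' @export
summarizeGroups <- function(fe, alpha = 0.05,
                            apportionCoeluting = c("exclude", "half")) {
  apportionCoeluting <- match.arg(apportionCoeluting)
  sl <- .sampleLevel(fe)
  if (any(table(droplevels(sl$class)) < 1L)) stop("empty group")
  single <- names(which(table(sl$class) == 1L))
  if (length(single))
    warning("degenerate group(s) with a single sample (SD reported as 0): ",
            paste(single, collapse = ", "))
  grp <- droplevels(sl$class)
  canLetter <- nlevels(grp) >= 2L && all(table(grp) >= 2L)
  # derived sums exist only over the canonical compositional feature set
  full <- if (setequal(colnames(sl$X), fameFeatures()))
    cbind(sl$X, .derivedQuantities(sl$X, apportionCoeluting))
  else sl$X
  quantities <- colnames(full)
  rows <- lapply(quantities, function(q) {
    means <- tapply(full[, q], grp, mean)
    sds <- tapply(full[, q], grp, stats::sd)
    ns <- as.vector(table(grp))
    lt <- if (canLetter)
      anovaTukey(fe, q, alpha = alpha,
                 apportionCoeluting = apportionCoeluting)$letters
    else setNames(rep("", nlevels(grp)), levels(grp))
    data.frame(quantity = q, group = names(means),
               mean = unname(means),
               sd = ifelse(is.na(sds), 0, unname(sds)),
               n = ns, letter = unname(lt[names(means)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
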