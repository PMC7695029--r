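.famFamilies <- c("kNN", "decisionTree", "SVM", "randomForest", "ANN",
                  "naiveBayes", "adaBoost")

.defaultParams <- function(family) {
  switch(family,
    kNN          = list(neighbors = 3L, metric = "euclidean",
                        weight = "distance"),
    decisionTree = list(maxDepth = 100L, minSplit = 2L, minLeaf = 3L),
    SVM          = list(cost = 15, kernel = "rbf", gamma = "auto"),
    randomForest = list(nTrees = 15L, minSplit = 5L),
    ANN          = list(hidden = 300L, activation = "relu", solver = "adam",
                        alpha = 0.02),
    naiveBayes   = list(),
    adaBoost     = list(nEstimators = 80L, learningRate = 0.7,
                        algorithm = "SAMME.R"))
}

#' Classifier specification with the bench hyperparameters
#'
#' Creates the specification of one of the seven bench classifier
#' families, with the published parametrization as defaults:
#' kNN (3 neighbors, Euclidean, distance-weighted votes), decision tree
#' (depth limit 100, min split 2, min leaf 3), SVM (C = 15, RBF kernel,
#' gamma = 1/n_features), random forest (15 trees, do not split subsets
#' smaller than 5), ANN (one hidden layer of 300 ReLU units, Adam, L2
#' regularization 0.02), Gaussian naive Bayes (parameter-free), and
#' AdaBoost (80 SAMME.R-boosted depth-1 stumps, learning rate 0.7).
#'
#' Backend notes: kNN, the ANN and SAMME.R boosting are implemented in
#' the package (see the vignette); the decision tree and boosting stumps
#' use \pkg{rpart} (whose depth limit caps at 30 — immaterial at this
#' data size), the SVM and naive Bayes use \pkg{e1071}, the forest
#' \pkg{randomForest} (the subset-size floor is mapped to
#' `nodesize = 3`, the closest terminal-node control).
#'
#' @param family one of `"kNN"`, `"decisionTree"`, `"SVM"`,
#'   `"randomForest"`, `"ANN"`, `"naiveBayes"`, `"adaBoost"`.
#' @param ... named hyperparameter overrides (see defaults above).
#' @param seed integer seed used by stochastic learners (forest, ANN,
#'   boosting); deterministic learners ignore it.
#' @return A list of class `"fameClassifier"` with elements `family`,
#'   `params`, `seed`.
#' @examples
#' fameClassifier("kNN")
#' fameClassifier("SVM", cost = 10)
#' @export
fameClassifier <- function(family = .famFamilies, ..., seed = 1L) {
  family <- match.arg(family)
  params <- utils::modifyList(.defaultParams(family), list(...))
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "fameClassifier")
}

#' @export
print.fameClassifier <- function(x, ...) {
  cat("fameClassifier:", x$family, "\n")
  if (length(x$params))
    cat(" ", paste(sprintf("%s=%s", names(x$params),
                           vapply(x$params, format, character(1))),
                   collapse = ", "), "\n")
  invisible(x)
}

#' The full seven-classifier bench roster
#'
#' @param seed integer seed shared by the stochastic learners.
#' @return Named list of the seven [fameClassifier()] specifications.
#' @export
defaultClassifiers <- function(seed = 1L)
  setNames(lapply(.famFamilies, fameClassifier, seed = seed), .famFamilies)

# ---- internal fit/predict ---------------------------------------------------
# All fitters take X (numeric matrix, syntactic colnames), y (factor with
# the full level set), and return list(predict = function(Xnew) -> factor).

.fitKnn <- function(X, y, p) {
  k <- p$neighbors
  force(X); force(y)
  list(predict = function(Xn) {
    d2 <- outer(rowSums(Xn^2), rep(1, nrow(X))) +
      outer(rep(1, nrow(Xn)), rowSums(X^2)) - 2 * Xn %*% t(X)
    d2[d2 < 0] <- 0
    lv <- levels(y)
    idx <- apply(d2, 1L, function(dd) order(dd)[seq_len(k)])
    pred <- vapply(seq_len(nrow(Xn)), function(i) {
      nb <- idx[, i]
      dn <- sqrt(d2[i, nb])
      if (any(dn == 0)) {        # exact match: those neighbors decide alone
        votes <- table(y[nb[dn == 0]])
      } else {
        w <- 1 / dn
        votes <- tapply(w, y[nb], sum)
        votes[is.na(votes)] <- 0
      }
      names(which.max(votes))
    }, character(1))
    factor(pred, levels = lv)
  })
}

.fitTree <- function(X, y, p) {
  df <- data.frame(X, check.names = TRUE)
  df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = min(p$maxDepth, 30L),
                        minsplit = p$minSplit, minbucket = p$minLeaf,
                        cp = 0, xval = 0))
  list(predict = function(Xn) {
    dn <- data.frame(Xn, check.names = TRUE)
    factor(as.character(predict(fit, dn, type = "class")),
           levels = levels(y))
  })
}

.fitSvm <- function(X, y, p) {
  gamma <- if (identical(p$gamma, "auto")) 1 / ncol(X) else p$gamma
  fit <- e1071::svm(x = X, y = y, cost = p$cost, kernel = "radial",
                    gamma = gamma, scale = FALSE)
  list(predict = function(Xn) {
    factor(as.character(predict(fit, Xn)), levels = levels(y))
  })
}

.fitForest <- function(X, y, p, seed) {
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = y, ntree = p$nTrees,
                                    nodesize = 3L)
  list(predict = function(Xn) {
    factor(as.character(predict(fit, Xn)), levels = levels(y))
  })
}

.fitNaiveBayes <- function(X, y, p) {
  fit <- e1071::naiveBayes(x = as.data.frame(X), y = y)
  list(predict = function(Xn) {
    factor(as.character(predict(fit, as.data.frame(Xn))),
           levels = levels(y))
  })
}

# single-hidden-layer perceptron, ReLU + softmax, full-batch Adam,
# cross-entropy with L2 penalty alpha/(2n)*||W||^2 on the weights
.fitMlp <- function(X, y, p, seed, epochs = 400L, lr = 0.01) {
  set.seed(seed)
  ctr <- colMeans(X); scl <- apply(X, 2L, stats::sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  n <- nrow(Xs); d <- ncol(Xs); H <- p$hidden; K <- nlevels(y)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  W1 <- matrix(rnorm(d * H, sd = sqrt(2 / d)), d, H); b1 <- rep(0, H)
  W2 <- matrix(rnorm(H * K, sd = sqrt(2 / H)), H, K); b2 <- rep(0, K)
  adam <- function() list(m = 0, v = 0)
  st <- list(W1 = adam(), b1 = adam(), W2 = adam(), b2 = adam())
  b1v <- 0.9; b2v <- 0.999; eps <- 1e-8
  step <- function(s, g, t) {
    s$m <- b1v * s$m + (1 - b1v) * g
    s$v <- b2v * s$v + (1 - b2v) * g^2
    mh <- s$m / (1 - b1v^t); vh <- s$v / (1 - b2v^t)
    list(state = s, upd = lr * mh / (sqrt(vh) + eps))
  }
  for (t in seq_len(epochs)) {
    A1 <- sweep(Xs %*% W1, 2L, b1, "+")
    Z1 <- pmax(A1, 0)
    A2 <- sweep(Z1 %*% W2, 2L, b2, "+")
    A2 <- A2 - apply(A2, 1L, max)
    P <- exp(A2); P <- P / rowSums(P)
    dA2 <- (P - Y) / n
    gW2 <- t(Z1) %*% dA2 + (p$alpha / n) * W2
    gb2 <- colSums(dA2)
    dZ1 <- dA2 %*% t(W2) * (A1 > 0)
    gW1 <- t(Xs) %*% dZ1 + (p$alpha / n) * W1
    gb1 <- colSums(dZ1)
    r <- step(st$W1, gW1, t); st$W1 <- r$state; W1 <- W1 - r$upd
    r <- step(st$b1, gb1, t); st$b1 <- r$state; b1 <- b1 - r$upd
    r <- step(st$W2, gW2, t); st$W2 <- r$state; W2 <- W2 - r$upd
    r <- step(st$b2, gb2, t); st$b2 <- r$state; b2 <- b2 - r$upd
  }
  list(predict = function(Xn) {
    Xn <- sweep(sweep(Xn, 2L, ctr), 2L, scl, "/")
    Z1 <- pmax(sweep(Xn %*% W1, 2L, b1, "+"), 0)
    A2 <- sweep(Z1 %*% W2, 2L, b2, "+")
    factor(levels(y)[apply(A2, 1L, which.max)], levels = levels(y))
  })
}

# SAMME.R real boosting over depth-1 rpart stumps
.fitAdaBoost <- function(X, y, p, seed) {
  set.seed(seed)
  n <- nrow(X); K <- nlevels(y); lr <- p$learningRate
  df <- data.frame(X, check.names = TRUE)
  df$.y <- y
  Ycode <- matrix(-1 / (K - 1), n, K)
  Ycode[cbind(seq_len(n), as.integer(y))] <- 1
  w <- rep(1 / n, n)
  stumps <- vector("list", p$nEstimators)
  used <- 0L
  fml <- .y ~ .
  environment(fml) <- environment()
  for (b in seq_len(p$nEstimators)) {
    wCase <- w * n                       # rpart prefers weights near 1
    fit <- rpart::rpart(fml, data = df, weights = wCase,
                        method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1L, minsplit = 2L, minbucket = 1L,
                          cp = 0, xval = 0))
    P <- predict(fit, df, type = "prob")
    P <- pmin(pmax(P, 1e-10), 1)
    used <- used + 1L
    stumps[[used]] <- fit
    logP <- log(P)
    w <- w * exp(-lr * (K - 1) / K * rowSums(Ycode * logP))
    s <- sum(w)
    if (!is.finite(s) || s <= 0) break
    w <- w / s
  }
  stumps <- stumps[seq_len(used)]
  list(predict = function(Xn) {
    dn <- data.frame(Xn, check.names = TRUE)
    F <- matrix(0, nrow(Xn), K)
    for (fit in stumps) {
      P <- predict(fit, dn, type = "prob")
      P <- pmin(pmax(P, 1e-10), 1)
      logP <- log(P)
      F <- F + lr * (K - 1) * (logP - rowMeans(logP))
    }
    factor(levels(y)[apply(F, 1L, which.max)], levels = levels(y))
  })
}

.fitClassifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "fameClassifier"))
  colnames(X) <- make.names(colnames(X))
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("training data holds fewer than 2 classes")
  fit <- switch(spec$family,
    kNN          = .fitKnn(X, y, spec$params),
    decisionTree = .fitTree(X, y, spec$params),
    SVM          = .fitSvm(X, y, spec$params),
    randomForest = .fitForest(X, y, spec$params, spec$seed),
    ANN          = .fitMlp(X, y, spec$params, spec$seed),
    naiveBayes   = .fitNaiveBayes(X, y, spec$params),
    adaBoost     = .fitAdaBoost(X, y, spec$params, spec$seed))
  inner <- fit$predict
  fit$predict <- function(Xn) {
    colnames(Xn) <- make.names(colnames(Xn))
    inner(Xn)
  }
  fit
}
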