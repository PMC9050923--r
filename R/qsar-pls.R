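# Partial least squares regression (NIPALS PLS1) on the field descriptor
# matrix: train/test splitting, leave-one-out component selection, model
# statistics and the prediction report.

#' Split a dataset into training and test sets
#'
#' With \code{explicitTest} given the membership is used verbatim (the
#' packaged default reproduces the published 19/6 split). Otherwise a greedy
#' maximin ("diverse molecule") selection on descriptor-space Euclidean
#' distances picks the test set: the seeded first pick, then repeatedly the
#' compound farthest from the current test set.
#'
#' @param dataset a \linkS4class{QsarDataset}.
#' @param X descriptor matrix with rownames = compound ids (required for
#'   maximin mode).
#' @param nTest number of test compounds.
#' @param seed RNG seed for the maximin first pick.
#' @param explicitTest explicit test-set ids, or NULL for maximin.
#' @return list with sorted integer \code{train}, \code{test}, and
#'   \code{method}.
#' @export
diverseSplit <- function(dataset, X = NULL, nTest = 6, seed = 1,
                         explicitTest = NULL) {
  ids <- datasetEntries(dataset)$id
  if (!is.null(explicitTest)) {
    missing <- setdiff(explicitTest, ids)
    if (length(missing)) stop("explicit test id not in dataset: ", missing[1])
    test <- sort(as.integer(explicitTest))
    return(list(train = sort(setdiff(ids, test)), test = test,
                method = "explicit"))
  }
  if (nTest >= length(ids)) stop("nTest must be smaller than the dataset")
  if (nTest == 0)
    return(list(train = sort(ids), test = integer(0), method = "diverse"))
  if (is.null(X)) stop("descriptor matrix required for maximin selection")
  Xs <- X[match(ids, as.numeric(rownames(X))), , drop = FALSE]
  D <- as.matrix(stats::dist(Xs))
  set.seed(seed)
  picked <- sample.int(length(ids), 1)
  while (length(picked) < nTest) {
    dmin <- apply(D[, picked, drop = FALSE], 1, min)
    dmin[picked] <- -Inf
    picked <- c(picked, which.max(dmin))
  }
  test <- sort(ids[picked])
  list(train = sort(setdiff(ids, test)), test = test, method = "diverse")
}

#' The published test-set membership
#' @return integer(6) compound ids.
#' @export
defaultTestIds <- function() c(58L, 73L, 78L, 99L, 101L, 120L)

#' Fit a NIPALS PLS1 regression
#'
#' Column-centered X, centered y; no column scaling (field descriptors share
#' kcal/mol units). The implied regression vector b satisfies
#' yhat = (X - xMean) b + yMean.
#'
#' @param X n x p descriptor matrix.
#' @param y response vector (pGI50).
#' @param ncomp number of latent components, at most min(n - 1, p).
#' @param columnIndex optional data.frame mapping columns to (field, point),
#'   carried into the model for contour back-mapping.
#' @return a \linkS4class{PlsModel}.
#' @export
fitPls <- function(X, y, ncomp, columnIndex = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 || length(y) != n) stop("need >= 2 training rows matching y")
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (ncomp > min(n - 1, ncol(X)))
    stop("ncomp exceeds admissible rank min(n - 1, p)")
  xMean <- colMeans(X)
  yMean <- mean(y)
  E <- sweep(X, 2, xMean)
  f <- y - yMean
  W <- P <- matrix(0, ncol(X), ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { # residual exhausted; stop early
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    p <- as.numeric(crossprod(E, t)) / tt
    q[a] <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - q[a] * t
    W[, a] <- w
    P[, a] <- p
  }
  if (ncomp < 1) stop("no usable component")
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  ci <- if (is.null(columnIndex))
    data.frame(field = character(0), point = integer(0)) else columnIndex
  new("PlsModel", ncomp = as.integer(ncomp), xMean = xMean, yMean = yMean,
      weights = W, xLoadings = P, yLoadings = q, coefficients = b,
      columnIndex = ci)
}

#' Predict responses from a fitted PLS model
#'
#' @param object a \linkS4class{PlsModel}.
#' @param newdata matrix with the training column layout.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "PlsModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object@xMean))
    stop("column mismatch: expected ", length(object@xMean), " descriptors")
  as.numeric(sweep(newdata, 2, object@xMean) %*% object@coefficients +
               object@yMean)
})

#' Leave-one-out cross-validated q2
#'
#' Explicit leave-one-out refits: each compound is held out, the model is
#' refitted on the rest and the held-out residual collected;
#' q2 = 1 - PRESS / SS_tot.
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param ncomp number of components for each refit.
#' @return the LOO q2.
#' @export
looQ2 <- function(X, y, ncomp) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    m <- fitPls(X[-i, , drop = FALSE], y[-i], ncomp)
    press <- press + (y[i] - predict(m, X[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Choose the PLS component count by leave-one-out q2
#'
#' Evaluates q2 for 1..maxComp components and returns the maximizer, ties
#' broken toward fewer components.
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param maxComp largest component count to consider.
#' @return list with \code{ncomp} and the \code{q2} profile.
#' @export
chooseComponents <- function(X, y, maxComp = 5) {
  maxComp <- min(maxComp, nrow(X) - 2, ncol(X))
  if (maxComp < 1) stop("maxComp must be >= 1")
  q2 <- vapply(seq_len(maxComp), function(a) looQ2(X, y, a), numeric(1))
  list(ncomp = which.max(q2), q2 = q2)
}

#' Model statistics: squared Pearson correlation and RMSE
#'
#' r2 is the squared Pearson correlation between observed and predicted;
#' rmse the root-mean-square residual. Zero variance in either vector is an
#' error (r2 undefined), not NaN.
#'
#' @param y observed values.
#' @param yhat predicted values, same length.
#' @return list with \code{r2} and \code{rmse}.
#' @export
modelStats <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    stop("y and yhat must have equal length >= 2")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("r2 undefined for zero-variance input")
  list(r2 = stats::cor(y, yhat)^2, rmse = sqrt(mean((y - yhat)^2)))
}

#' Per-compound prediction report
#'
#' One row per compound with residual = experimental - predicted and the
#' split label; training and pooled statistics attached. The training r2 is
#' the squared Pearson correlation; the coefficient of determination
#' (1 - SSres/SStot) is reported alongside.
#'
#' @param dataset a \linkS4class{QsarDataset}.
#' @param split a list with train/test ids from \code{\link{diverseSplit}}.
#' @param model a fitted \linkS4class{PlsModel}.
#' @param X descriptor matrix with rownames = compound ids covering all
#'   dataset compounds.
#' @return a \linkS4class{QsarReport}.
#' @export
residualTable <- function(dataset, split, model, X) {
  ent <- datasetEntries(dataset)
  Xall <- X[match(ent$id, as.numeric(rownames(X))), , drop = FALSE]
  pred <- predict(model, Xall)
  tb <- data.frame(id = ent$id, experimental = ent$pgi50, predicted = pred,
                   residual = ent$pgi50 - pred,
                   split = ifelse(ent$id %in% split$test, "test", "train"))
  tr <- tb$split == "train"
  st <- modelStats(tb$experimental[tr], tb$predicted[tr])
  sp <- modelStats(tb$experimental, tb$predicted)
  r2det <- 1 - sum(tb$residual[tr]^2) /
    sum((tb$experimental[tr] - mean(tb$experimental[tr]))^2)
  new("QsarReport", table = tb, r2Train = st$r2, rmseTrain = st$rmse,
      r2Det = r2det, r2Pooled = sp$r2, rmsePooled = sp$rmse,
      ncomp = model@ncomp)
}

#' Accessor: the per-compound table of a QsarReport
#' @param x a \linkS4class{QsarReport}.
#' @return data.frame (id, experimental, predicted, residual, split).
#' @export
reportTable <- function(x) {
  stopifnot(is(x, "QsarReport"))
  x@table
}

#' Accessor: statistics block of a QsarReport
#' @param x a \linkS4class{QsarReport}.
#' @return list with r2Train, rmseTrain, r2Det, r2Pooled, rmsePooled, ncomp.
#' @export
reportStats <- function(x) {
  stopifnot(is(x, "QsarReport"))
  list(r2Train = x@r2Train, rmseTrain = x@rmseTrain, r2Det = x@r2Det,
       r2Pooled = x@r2Pooled, rmsePooled = x@rmsePooled,
       ncomp = as.integer(x@ncomp))
}
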