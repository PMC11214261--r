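# Weighted pool-adjacent-violators: least-squares isotonic (non-decreasing)
# fit of y (with weights w) over an x-sorted sequence. Returns the fitted
# value per input position. stats::isoreg has no weights and the
# Venn-ABERS construction pools tied scores, hence this implementation.
.pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  val <- numeric(n); wt <- numeric(n); size <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; size[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      size[top - 1L] <- size[top - 1L] + size[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], times = size[seq_len(top)])
}

# Isotonic fit over calibration (scores, labels01) augmented with the test
# point (t, yTentative); equal scores are pooled before fitting; returns
# the fitted value at the test point.
.vennPoint <- function(scores, labels01, t, yTentative) {
  s <- c(scores, t)
  z <- c(labels01, yTentative)
  u <- sort(unique(s))
  grp <- match(s, u)
  w <- tabulate(grp, length(u))
  ybar <- as.vector(tapply(z, grp, mean))
  fit <- .pava(ybar, w)
  fit[match(t, u)]
}

#' Fit an inductive Venn-ABERS predictor (IVAP)
#'
#' Binary probabilistic calibration: the proper training part fits the
#' scorer, the calibration part is stored as (decision score, 0/1 label)
#' pairs. At prediction time two isotonic regressions that include the
#' test object with tentative labels 0 and 1 give the multi-probability
#' pair (p0, p1), one of which is the true conditional probability.
#'
#' @param data a binary classification \code{SparseFeatureSet}; the second
#'   class of the label domain is the positive class ("1").
#' @param scorer a \code{\link{scorerConfig}}.
#' @param strategy a one-split \code{\link{samplingStrategy}}.
#' @return a \code{\linkS4class{VennAbersModel}} with one fold.
#' @export
fitIVAP <- function(data, scorer, strategy = samplingStrategy()) {
  model <- .fitVennAbers(data, scorer, strategy, expectFolds = 1L)
  model
}

#' Fit a cross Venn-ABERS predictor (CVAP)
#'
#' One IVAP per fold of a folded split; the k multi-probabilities are
#' merged into a single probability with the geometric-mean rule.
#'
#' @inheritParams fitIVAP
#' @param strategy a fold \code{\link{samplingStrategy}} with k >= 2.
#' @export
fitCVAP <- function(data, scorer, strategy) {
  if (strategy@kind != "fold")
    .stopf("fitCVAP: a 'fold' sampling strategy is required")
  .fitVennAbers(data, scorer, strategy, expectFolds = strategy@nSplits)
}

.fitVennAbers <- function(data, scorer, strategy, expectFolds) {
  stopifnot(is(data, "SparseFeatureSet"))
  if (data@task != "classification" || nlevels(data@y) != 2L)
    .stopf("Venn-ABERS prediction is only defined for binary classes")
  classes <- levels(data@y)
  splits <- splitSampling(strategy, nrow(data@x), labels = data@y)
  if (length(splits) != expectFolds && expectFolds == 1L)
    splits <- splits[1]
  folds <- lapply(splits, function(sp) {
    if (!length(sp$calibration)) .stopf("empty calibration part")
    sc <- trainScorer(scorer, data[sp$properTrain])
    sco <- decisionScores(sc, data@x[sp$calibration, , drop = FALSE])[, 2]
    ord <- order(sco)
    list(scorer = sc, scores = sco[ord],
         labels01 = as.integer(data@y[sp$calibration] == classes[2])[ord])
  })
  new("VennAbersModel", folds = folds, classes = classes,
      nFeatures = ncol(data@x))
}

#' Venn-ABERS prediction
#'
#' Returns, per row, the multi-probability pair and the merged single
#' probability of the positive (second) class. For a single fold (IVAP)
#' the merge is \eqn{p = p_1 / (1 - p_0 + p_1)}; for k folds (CVAP) it is
#' \eqn{GM(p_1) / (GM(1 - p_0) + GM(p_1))} with GM the geometric mean, and
#' the reported p0/p1 are the fold-wise minimum/maximum.
#'
#' @param model a \code{VennAbersModel}.
#' @param x rows to predict.
#' @return data.frame with columns \code{p0}, \code{p1}, \code{p}.
#' @export
predictVennAbers <- function(model, x) {
  stopifnot(is(model, "VennAbersModel"))
  if (is(x, "SparseFeatureSet")) x <- x@x
  x <- .asDgc(x)
  if (ncol(x) != model@nFeatures)
    .stopf("predictVennAbers: feature dimensionality mismatch")
  m <- nrow(x)
  k <- length(model@folds)
  p0s <- p1s <- matrix(NA_real_, m, k)
  for (f in seq_len(k)) {
    fold <- model@folds[[f]]
    t <- decisionScores(fold$scorer, x)[, 2]
    for (r in seq_len(m)) {
      p0s[r, f] <- .vennPoint(fold$scores, fold$labels01, t[r], 0)
      p1s[r, f] <- .vennPoint(fold$scores, fold$labels01, t[r], 1)
    }
  }
  gm <- function(z) exp(rowMeans(log(pmax(z, .Machine$double.eps))))
  if (k == 1L) {
    p0 <- p0s[, 1]; p1 <- p1s[, 1]
    p <- p1 / (1 - p0 + p1)
  } else {
    g1 <- gm(p1s); g0 <- gm(1 - p0s)
    p <- g1 / (g0 + g1)
    p0 <- apply(p0s, 1, min); p1 <- apply(p1s, 1, max)
  }
  data.frame(p0 = p0, p1 = p1, p = p)
}
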