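#' Nonconformity measures
#'
#' Classification measures map scorer outputs to a nonconformity
#' \eqn{\alpha(x, y)} (higher = stranger):
#' \itemize{
#' \item \code{negative-distance-to-hyperplane}: \eqn{-d_y(x)} where
#'   \eqn{d_y} is the decision score for class y (the default; requires a
#'   margin-based scorer).
#' \item \code{positive-distance-to-hyperplane}: \eqn{+d_y(x)}.
#' \item \code{inverse-probability}: \eqn{1 - \hat P(y|x)}.
#' \item \code{probability-margin}:
#'   \eqn{0.5 (1 - \hat P(y|x) + \max_{y' \ne y} \hat P(y'|x))}.
#' }
#'
#' @param kind measure name.
#' @return a list of class \code{"ClassificationNCM"}.
#' @export
classificationNCM <- function(kind = c("negative-distance-to-hyperplane",
                                       "positive-distance-to-hyperplane",
                                       "inverse-probability",
                                       "probability-margin")) {
  kind <- match.arg(kind)
  structure(list(kind = kind,
                 needsProbability = kind %in% c("inverse-probability",
                                                "probability-margin")),
            class = "ClassificationNCM")
}

#' @rdname classificationNCM
#'
#' @details Regression measures are \eqn{\alpha = |y - \hat y(x)| / \sigma(x)}
#' with scale \eqn{\sigma(x) = 1} (\code{abs-diff});
#' \eqn{\sigma(x) = \hat e(x) + \beta} where the error model \eqn{\hat e}
#' is trained on absolute proper-training residuals (\code{normalized});
#' or \eqn{\sigma(x) = \exp(\hat g(x)) + \beta} where \eqn{\hat g} is
#' trained on \eqn{\ln(|residual| + \beta)} (\code{log-normalized}).
#' The smoothing factor \eqn{\beta} (default 0.01) stabilizes the scaling
#' and removes the possibility of division by zero.
#'
#' @param beta non-negative smoothing factor.
#' @param errorConfig optional \code{\link{scorerConfig}} for the error
#'   model; default: the midpoint scorer's own configuration.
#' @export
regressionNCM <- function(kind = c("abs-diff", "normalized", "log-normalized"),
                          beta = 0.01, errorConfig = NULL) {
  kind <- match.arg(kind)
  stopifnot(beta >= 0)
  structure(list(kind = kind, beta = beta, errorConfig = errorConfig),
            class = "RegressionNCM")
}

# Nonconformity of every class for every row: n x K matrix.
.alphaMatrix <- function(ncm, scorer, x) {
  if (ncm$needsProbability) {
    P <- probabilityScores(scorer, x)
    if (ncm$kind == "inverse-probability") return(1 - P)
    # probability-margin
    K <- ncol(P)
    out <- P
    for (k in seq_len(K)) {
      other <- P[, -k, drop = FALSE]
      out[, k] <- 0.5 * (1 - P[, k] + apply(other, 1, max))
    }
    return(out)
  }
  d <- decisionScores(scorer, x)
  if (ncm$kind == "negative-distance-to-hyperplane") -d else d
}

#' Fit a mondrian conformal classifier
#'
#' Inductive (one split), aggregated (several random splits, ACP) or cross
#' (folded splits, CCP) conformal classification, depending on the
#' sampling strategy. Calibration is mondrian (class-conditional): the
#' class-y nonconformity store holds \eqn{\alpha(x, y)} of calibration
#' members whose true label is y, giving per-class validity and robust
#' handling of imbalanced data.
#'
#' @param data a classification \code{SparseFeatureSet}.
#' @param scorer a \code{\link{scorerConfig}}.
#' @param ncm a \code{\link{classificationNCM}}.
#' @param strategy a \code{\link{samplingStrategy}}.
#' @param pconfig a \code{\link{pValueConfig}}.
#' @param aggregation multi-split p-value aggregation, "mean" (default) or
#'   "median".
#' @return a \code{\linkS4class{ConformalModel}}.
#' @export
fitConformalClassifier <- function(data, scorer, ncm = classificationNCM(),
                                   strategy = samplingStrategy(),
                                   pconfig = pValueConfig(),
                                   aggregation = c("mean", "median")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is(data, "SparseFeatureSet"), inherits(ncm, "ClassificationNCM"))
  if (data@task != "classification")
    .stopf("fitConformalClassifier: classification data required")
  y <- data@y
  classes <- levels(y)
  splits <- splitSampling(strategy, nrow(data@x), labels = y)
  cfg <- scorer
  if (ncm$needsProbability && cfg$algorithm == "svc") cfg$probability <- TRUE
  fitted <- lapply(seq_along(splits), function(s) {
    sp <- splits[[s]]
    calY <- y[sp$calibration]
    missing <- setdiff(classes, as.character(unique(calY)))
    if (length(missing))
      .stopf("class '%s' absent from calibration part of split %d",
             missing[1], s)
    sc <- trainScorer(cfg, data[sp$properTrain])
    am <- .alphaMatrix(ncm, sc, data@x[sp$calibration, , drop = FALSE])
    calib <- lapply(classes, function(cl)
      sort(am[calY == cl, cl]))
    names(calib) <- classes
    .bumpCalibrationFits()
    list(scorer = sc, calibration = calib)
  })
  new("ConformalModel", task = "classification", splits = fitted,
      ncm = c(unclass(ncm), sampling = strategy@kind),
      pconfig = unclass(pconfig), aggregation = aggregation,
      classes = classes, nFeatures = ncol(data@x))
}

#' Predict conformal p-values
#'
#' One p-value per class per row, computed with the model's configured
#' calculator against the mondrian calibration stores; multi-split models
#' aggregate per-split p-values by the configured rule (mean by default).
#' In smoothed/random mode one tau is drawn per (test object, class),
#' shared across splits, from the calculator's seed.
#'
#' @param model a classification \code{ConformalModel}.
#' @param x rows to predict (matrix-like or \code{SparseFeatureSet}).
#' @return matrix of p-values, one column per class.
#' @export
predictPValues <- function(model, x) {
  stopifnot(is(model, "ConformalModel"), model@task == "classification")
  if (is(x, "SparseFeatureSet")) x <- x@x
  x <- .asDgc(x)
  if (ncol(x) != model@nFeatures)
    .stopf("predictPValues: feature dimensionality mismatch")
  classes <- model@classes
  m <- nrow(x); K <- length(classes)
  tauDraws <- NULL
  if (model@pconfig$mode == "smoothed" && identical(model@pconfig$tau, "random"))
    tauDraws <- withSeed(model@pconfig$seed, matrix(stats::runif(m * K), m, K))
  perSplit <- lapply(model@splits, function(sp) {
    am <- .alphaMatrix(model@ncm, sp$scorer, x)
    p <- matrix(NA_real_, m, K, dimnames = list(NULL, classes))
    for (k in seq_len(K))
      p[, k] <- .computePValues(sp$calibration[[classes[k]]], am[, k],
                                model@pconfig,
                                tauDraws = if (!is.null(tauDraws)) tauDraws[, k])
    p
  })
  if (length(perSplit) == 1L) return(perSplit[[1]])
  arr <- simplify2array(perSplit)
  agg <- apply(arr, c(1, 2), if (model@aggregation == "mean") mean else stats::median)
  dimnames(agg) <- list(NULL, classes)
  agg
}

#' Prediction set at a significance level
#'
#' All labels with p-value greater than or equal to epsilon; may be empty,
#' single- or multi-label.
#'
#' @param pvalues matrix from \code{\link{predictPValues}} (or a named
#'   vector for one object).
#' @param epsilon significance level in (0,1).
#' @return list of character vectors of included labels.
#' @examples
#' predictionSet(c(A = 0.4, B = 0.05), 0.1)  # list("A")
#' @export
predictionSet <- function(pvalues, epsilon) {
  if (epsilon <= 0 || epsilon >= 1) .stopf("epsilon must lie in (0,1)")
  if (is.null(dim(pvalues))) pvalues <- matrix(pvalues, 1,
                                               dimnames = list(NULL, names(pvalues)))
  labs <- colnames(pvalues)
  lapply(seq_len(nrow(pvalues)), function(r) labs[pvalues[r, ] >= epsilon])
}

#' Transductive conformal prediction (classification)
#'
#' No data splitting: for every test object and every tentative label y the
#' scorer is retrained on the full training set plus the test object
#' labeled y; the p-value is the mondrian rank of the test nonconformity
#' among the label-y training instances plus the test instance. Uses all
#' data for both scoring and calibration at a high computational cost, so
#' it suits small datasets.
#'
#' @param data classification \code{SparseFeatureSet} (the training data).
#' @param scorer a \code{\link{scorerConfig}}.
#' @param ncm a \code{\link{classificationNCM}}.
#' @param x rows to predict.
#' @return matrix of p-values, one column per class.
#' @export
tcpPredict <- function(data, scorer, ncm = classificationNCM(), x) {
  stopifnot(is(data, "SparseFeatureSet"), data@task == "classification")
  if (is(x, "SparseFeatureSet")) x <- x@x
  x <- .asDgc(x)
  classes <- levels(data@y)
  m <- nrow(x)
  cfg <- scorer
  if (ncm$needsProbability && cfg$algorithm == "svc") cfg$probability <- TRUE
  out <- matrix(NA_real_, m, length(classes),
                dimnames = list(NULL, classes))
  for (r in seq_len(m)) {
    for (k in seq_along(classes)) {
      cl <- classes[k]
      augX <- rbind(data@x, x[r, , drop = FALSE])
      augY <- factor(c(as.character(data@y), cl), levels = classes)
      aug <- sparseFeatureSet(augX, augY, "classification",
                              labelDomain = classes)
      sc <- trainScorer(cfg, aug)
      am <- .alphaMatrix(ncm, sc, augX)
      alphaY <- am[augY == cl, k]
      aTest <- am[nrow(augX), k]
      out[r, k] <- sum(alphaY >= aTest) / length(alphaY)
    }
  }
  out
}

#' Fit a conformal regressor
#'
#' Inductive or aggregated conformal regression. For the normalized and
#' log-normalized nonconformity measures an additional error model (same
#' algorithm and hyper-parameters unless overridden in the NCM) is trained
#' on the proper-training residual targets; its prediction scales the
#' intervals so difficult objects receive wider bounds.
#'
#' @param data a regression \code{SparseFeatureSet}.
#' @param scorer a \code{\link{scorerConfig}} (algorithm "svr").
#' @param ncm a \code{\link{regressionNCM}}.
#' @param strategy a \code{\link{samplingStrategy}}.
#' @param pconfig a \code{\link{pValueConfig}}; mode
#'   "linear-interpolated" turns on interpolated interval multipliers.
#' @param aggregation multi-split bound aggregation, "median" (default) or
#'   "mean".
#' @return a \code{\linkS4class{ConformalModel}}.
#' @export
fitConformalRegressor <- function(data, scorer, ncm = regressionNCM(),
                                  strategy = samplingStrategy(),
                                  pconfig = pValueConfig(),
                                  aggregation = c("median", "mean")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is(data, "SparseFeatureSet"), inherits(ncm, "RegressionNCM"))
  if (data@task != "regression")
    .stopf("fitConformalRegressor: regression data required")
  y <- data@y
  splits <- splitSampling(strategy, nrow(data@x))
  fitted <- lapply(seq_along(splits), function(s) {
    sp <- splits[[s]]
    if (!length(sp$calibration)) .stopf("empty calibration part in split %d", s)
    train <- data[sp$properTrain]
    sc <- trainScorer(scorer, train)
    errModel <- NULL
    if (ncm$kind != "abs-diff") {
      res <- abs(train@y - decisionScores(sc, train@x))
      target <- if (ncm$kind == "normalized") res else log(res + ncm$beta)
      errCfg <- if (is.null(ncm$errorConfig)) scorer else ncm$errorConfig
      errModel <- trainScorer(errCfg,
        sparseFeatureSet(train@x, target, "regression"))
    }
    calX <- data@x[sp$calibration, , drop = FALSE]
    sigma <- .sigmaValues(ncm, errModel, calX)
    alpha <- abs(y[sp$calibration] - decisionScores(sc, calX)) / sigma
    .bumpCalibrationFits()
    list(scorer = sc, errorModel = errModel, calibration = sort(alpha))
  })
  new("ConformalModel", task = "regression", splits = fitted,
      ncm = c(unclass(ncm), sampling = strategy@kind),
      pconfig = unclass(pconfig), aggregation = aggregation,
      classes = character(0), nFeatures = ncol(data@x))
}

.sigmaValues <- function(ncm, errModel, x) {
  switch(ncm$kind,
    `abs-diff` = rep(1, nrow(x)),
    normalized = pmax(decisionScores(errModel, x), 0) + ncm$beta,
    `log-normalized` = exp(decisionScores(errModel, x)) + ncm$beta)
}

# Finite half-width multiplier(s) from a sorted calibration store, or Inf.
.intervalMultiplier <- function(store, epsilon, interpolate) {
  n <- length(store)
  vapply(epsilon, function(e) {
    if (!interpolate) {
      k <- ceiling((1 - e) * (n + 1))
      if (k > n) Inf else if (k < 1L) store[1] else store[k]
    } else {
      q <- (1 - e) * (n + 1)
      if (q > n) return(Inf)
      lo <- floor(q); frac <- q - lo
      aLo <- if (lo < 1) 0 else store[lo]
      aHi <- store[min(lo + 1, n)]
      aLo + frac * (aHi - aLo)
    }
  }, numeric(1))
}

#' Conformal prediction intervals
#'
#' Standard mode takes the k-th smallest calibration nonconformity with
#' \eqn{k = \lceil (1-\epsilon)(n+1) \rceil} as the half-width multiplier
#' (infinite interval when k exceeds n, so the smallest finite level with
#' n calibration instances is \eqn{1/(n+1)}); interpolated mode (model
#' fitted with mode "linear-interpolated") interpolates linearly between
#' order statistics, smoothing the staircase of a small calibration set.
#' The half-width is multiplier times the difficulty scale
#' \eqn{\sigma(x)} of the model's nonconformity measure. Multi-split
#' models aggregate midpoint and bounds per the configured rule (median
#' by default).
#'
#' @param model a regression \code{ConformalModel}.
#' @param x rows to predict.
#' @param epsilon significance level(s) in (0,1); vectorized.
#' @return data.frame with columns \code{row}, \code{epsilon},
#'   \code{midpoint}, \code{lower}, \code{upper}.
#' @export
predictInterval <- function(model, x, epsilon) {
  stopifnot(is(model, "ConformalModel"), model@task == "regression")
  if (any(epsilon <= 0 | epsilon >= 1)) .stopf("epsilon must lie in (0,1)")
  if (is(x, "SparseFeatureSet")) x <- x@x
  x <- .asDgc(x)
  if (ncol(x) != model@nFeatures)
    .stopf("predictInterval: feature dimensionality mismatch")
  interpolate <- identical(model@pconfig$mode, "linear-interpolated")
  m <- nrow(x)
  perSplit <- lapply(model@splits, function(sp) {
    yhat <- decisionScores(sp$scorer, x)
    sigma <- .sigmaValues(model@ncm, sp$errorModel, x)
    mult <- .intervalMultiplier(sp$calibration, epsilon, interpolate)
    list(yhat = yhat, half = outer(sigma, mult))  # m x |eps|
  })
  aggFun <- if (model@aggregation == "mean") mean else stats::median
  yh <- vapply(perSplit, `[[`, numeric(m), "yhat")
  if (m == 1L) yh <- matrix(yh, nrow = 1)
  lows <- lapply(perSplit, function(s) s$yhat - s$half)
  ups <- lapply(perSplit, function(s) s$yhat + s$half)
  nE <- length(epsilon)
  lower <- upper <- matrix(NA_real_, m, nE)
  for (j in seq_len(nE)) {
    lj <- vapply(lows, function(z) z[, j], numeric(m))
    uj <- vapply(ups, function(z) z[, j], numeric(m))
    if (m == 1L) { lj <- matrix(lj, 1); uj <- matrix(uj, 1) }
    lower[, j] <- apply(lj, 1, aggFun)
    upper[, j] <- apply(uj, 1, aggFun)
  }
  mid <- apply(yh, 1, aggFun)
  data.frame(row = rep(seq_len(m), times = nE),
             epsilon = rep(epsilon, each = m),
             midpoint = rep(mid, times = nE),
             lower = as.vector(lower), upper = as.vector(upper))
}
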