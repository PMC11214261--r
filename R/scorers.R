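#' Scorer configuration
#'
#' Configuration of the underlying scoring algorithm used beneath the
#' conformal and Venn-ABERS layers: a support vector machine (libsvm via
#' \pkg{e1071}) for classification (\code{svc}) or regression (\code{svr}),
#' or an L2-regularized logistic regression (\pkg{glmnet}, a small fixed
#' ridge keeps p > n signature matrices well-posed).
#'
#' Signature count features are used raw; optional per-column
#' standardization applies only to appended external descriptor columns.
#'
#' @param algorithm "svc", "svr" or "logistic".
#' @param kernel "linear" or "rbf" (SVMs).
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width; default \code{1/nFeatures} at fit time.
#' @param epsilon SVR tube width.
#' @param lambda ridge penalty of the logistic scorer.
#' @param probability fit the sigmoid (Platt) calibration needed by
#'   probability-based nonconformity measures (SVC; logistic is native).
#' @param standardize standardize external descriptor columns.
#' @param seed integer seed (all scorers here are deterministic, the seed
#'   is recorded for provenance).
#' @return a list of class \code{"ScorerConfig"}.
#' @export
scorerConfig <- function(algorithm = c("svc", "svr", "logistic"),
                         kernel = c("linear", "rbf"), cost = 1,
                         gamma = NULL, epsilon = 0.1, lambda = 1e-4,
                         probability = FALSE, standardize = FALSE,
                         seed = 1L) {
  algorithm <- match.arg(algorithm)
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, epsilon > 0, lambda > 0)
  if (!is.null(gamma)) stopifnot(gamma > 0)
  structure(list(algorithm = algorithm, kernel = kernel, cost = cost,
                 gamma = gamma, epsilon = epsilon, lambda = lambda,
                 probability = probability, standardize = standardize,
                 seed = as.integer(seed)),
            class = "ScorerConfig")
}

#' Train a scorer
#'
#' @param config a \code{\link{scorerConfig}}.
#' @param data a \code{SparseFeatureSet} with labels.
#' @param standardizeCols indices of (external) columns to standardize when
#'   \code{config$standardize} is TRUE.
#' @return a \code{\linkS4class{Scorer}}.
#' @export
trainScorer <- function(config, data, standardizeCols = integer(0)) {
  stopifnot(inherits(config, "ScorerConfig"), is(data, "SparseFeatureSet"))
  x <- data@x
  y <- data@y
  if (nrow(x) < 2L) .stopf("trainScorer: need at least 2 records")
  if (is.null(y)) .stopf("trainScorer: unlabeled data")
  task <- if (config$algorithm == "svr") "regression" else "classification"
  if (task == "classification") {
    if (data@task != "classification")
      .stopf("'%s' requires classification labels", config$algorithm)
    y <- droplevels(y)
    if (nlevels(y) < 2L) .stopf("trainScorer: single-class input")
  } else if (data@task != "regression")
    .stopf("'svr' requires regression labels")
  std <- NULL
  if (isTRUE(config$standardize) && length(standardizeCols)) {
    xs <- as.matrix(x[, standardizeCols, drop = FALSE])
    ctr <- colMeans(xs)
    scl <- apply(xs, 2, stats::sd); scl[scl == 0] <- 1
    std <- list(cols = standardizeCols, center = ctr, scale = scl)
    x[, standardizeCols] <- Matrix((sweep(xs, 2, ctr) %*% diag(1 / scl,
      length(scl))), sparse = TRUE)
  }
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  svmKernel <- if (config$kernel == "rbf") "radial" else "linear"
  fit <- switch(config$algorithm,
    svc = e1071::svm(x, y, type = "C-classification",
                     kernel = svmKernel, cost = config$cost,
                     gamma = gamma, scale = FALSE),
    svr = e1071::svm(x, y, type = "eps-regression",
                     kernel = svmKernel, cost = config$cost,
                     gamma = gamma, epsilon = config$epsilon, scale = FALSE),
    logistic = {
      if (nlevels(y) != 2L)
        .stopf("logistic scorer supports binary classification only")
      glmnet::glmnet(x, y, family = "binomial", lambda = config$lambda,
                     standardize = FALSE)
    })
  scorer <- new("Scorer", fit = fit, config = unclass(config), task = task,
                classes = if (task == "classification") levels(y) else character(0),
                nFeatures = ncol(x), platt = NULL, standardization = std)
  if (task == "classification" && isTRUE(config$probability) &&
      config$algorithm == "svc")
    scorer@platt <- .fitPlatt(scorer, x, y)
  scorer
}

.applyStandardization <- function(scorer, x) {
  std <- scorer@standardization
  if (is.null(std)) return(x)
  xs <- as.matrix(x[, std$cols, drop = FALSE])
  x[, std$cols] <- Matrix(sweep(xs, 2, std$center) %*%
                            diag(1 / std$scale, length(std$scale)), sparse = TRUE)
  x
}

# Deterministic in-sample Platt scaling: one sigmoid per class pair fitted
# on the training decision values. Libsvm's own CV-based calibration is not
# reproducible (unseeded C RNG), so it is not used.
.fitPlatt <- function(scorer, x, y) {
  cls <- scorer@classes
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  dv <- .rawPairwiseDecisions(scorer, x)
  out <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "/")
    col <- .pairColumn(colnames(dv), pr)
    sel <- y %in% pr
    z01 <- as.integer(y[sel] == pr[1])  # positive score favors first class
    s <- dv[sel, col$name] * col$sign
    coefs <- tryCatch(
      suppressWarnings(stats::coef(stats::glm.fit(cbind(1, s), z01,
        family = stats::binomial()))),
      error = function(e) c(0, 1))
    out[[key]] <- coefs
  }
  out
}

.rawPairwiseDecisions <- function(scorer, x) {
  p <- stats::predict(scorer@fit, .asDgc(x), decision.values = TRUE)
  dv <- attr(p, "decision.values")
  if (is.null(dim(dv))) dv <- matrix(dv, ncol = 1)
  dv
}

.pairColumn <- function(colNames, pair) {
  fwd <- paste(pair, collapse = "/")
  rev <- paste(rev(pair), collapse = "/")
  if (fwd %in% colNames) list(name = fwd, sign = 1)
  else if (rev %in% colNames) list(name = rev, sign = -1)
  else .stopf("decision column for pair %s not found", fwd)
}

#' Decision scores
#'
#' Classification: a matrix with one signed score per class, in class
#' order; for binary problems the two columns are the signed SVM margin
#' (or logistic linear predictor) and its negation, so they sum to zero.
#' Multiclass SVC scores are the per-class means of the signed pairwise
#' libsvm decision values. Regression: the predicted midpoint.
#'
#' @param scorer a fitted \code{Scorer}.
#' @param x matrix-like rows to score.
#' @return numeric matrix (classification) or vector (regression).
#' @export
decisionScores <- function(scorer, x) {
  stopifnot(is(scorer, "Scorer"))
  x <- .asDgc(x)
  if (ncol(x) != scorer@nFeatures)
    .stopf("decisionScores: %d features supplied, scorer trained on %d",
           ncol(x), scorer@nFeatures)
  x <- .applyStandardization(scorer, x)
  if (scorer@task == "regression")
    return(as.numeric(stats::predict(scorer@fit, x)))
  cls <- scorer@classes
  K <- length(cls)
  if (scorer@config$algorithm == "logistic") {
    eta <- as.numeric(stats::predict(scorer@fit, x, type = "link"))
    # glmnet binomial: linear predictor is for the second factor level
    out <- cbind(-eta, eta)
    colnames(out) <- cls
    return(out)
  }
  dv <- .rawPairwiseDecisions(scorer, x)
  out <- matrix(0, nrow(x), K, dimnames = list(NULL, cls))
  for (nm in colnames(dv)) {
    pr <- strsplit(nm, "/", fixed = TRUE)[[1]]
    out[, pr[1]] <- out[, pr[1]] + dv[, nm]
    out[, pr[2]] <- out[, pr[2]] - dv[, nm]
  }
  out / max(K - 1, 1)
}

#' Class probabilities
#'
#' Logistic scorers are natively probabilistic; SVC scorers use the
#' deterministic in-sample Platt sigmoid fitted at training time
#' (\code{probability = TRUE} in the config), with pairwise probabilities
#' averaged and renormalized for multiclass. SVR does not support
#' probabilities.
#'
#' @inheritParams decisionScores
#' @return matrix of per-class probabilities, rows summing to 1.
#' @export
probabilityScores <- function(scorer, x) {
  stopifnot(is(scorer, "Scorer"))
  if (scorer@task != "classification")
    .stopf("probabilityScores: unsupported for regression scorers")
  x <- .asDgc(x)
  if (ncol(x) != scorer@nFeatures)
    .stopf("probabilityScores: %d features supplied, scorer trained on %d",
           ncol(x), scorer@nFeatures)
  x <- .applyStandardization(scorer, x)
  cls <- scorer@classes
  K <- length(cls)
  if (scorer@config$algorithm == "logistic") {
    p <- as.numeric(stats::predict(scorer@fit, x, type = "response"))
    out <- cbind(1 - p, p)
    colnames(out) <- cls
    return(out)
  }
  if (is.null(scorer@platt))
    .stopf("probabilityScores: scorer was trained without probability = TRUE")
  dv <- .rawPairwiseDecisions(scorer, x)
  out <- matrix(0, nrow(x), K, dimnames = list(NULL, cls))
  for (key in names(scorer@platt)) {
    pr <- strsplit(key, "/", fixed = TRUE)[[1]]
    col <- .pairColumn(colnames(dv), pr)
    s <- dv[, col$name] * col$sign
    co <- scorer@platt[[key]]
    p1 <- stats::plogis(co[1] + co[2] * s)  # P(first of pair)
    out[, pr[1]] <- out[, pr[1]] + p1
    out[, pr[2]] <- out[, pr[2]] + (1 - p1)
  }
  out <- out / max(K - 1, 1)
  sw <- rowSums(out)
  out / sw
}
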