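#' Default significance grid
#'
#' 0.01 to 0.30 in steps of 0.01 for classification, 0.05 to 0.30 for
#' regression (70-99 resp. 70-95 percent confidence).
#'
#' @param task "classification" or "regression".
#' @return strictly increasing numeric vector in (0,1).
#' @export
significanceGrid <- function(task = c("classification", "regression")) {
  task <- match.arg(task)
  if (task == "classification") seq(0.01, 0.30, by = 0.01)
  else seq(0.05, 0.30, by = 0.01)
}

#' Conformal classification metrics
#'
#' Computes the epsilon-free observed fuzziness (mean total p-value mass on
#' false labels) and, per significance level: overall and per-class error
#' rate (true label outside the prediction set), average C (mean set
#' size), single-/multi-/empty-set ratios, and the conformal confusion
#' counts per true class (correct-single, wrong-single, multi, empty).
#'
#' @param pvalues matrix from \code{\link{predictPValues}}.
#' @param truth true labels (character or factor).
#' @param grid significance levels; default \code{significanceGrid()}.
#' @return list with \code{observedFuzziness}, \code{perEpsilon}
#'   (data.frame), \code{perClassError} (data.frame), \code{confusion}
#'   (data.frame).
#' @export
classificationMetrics <- function(pvalues, truth,
                                  grid = significanceGrid("classification")) {
  classes <- colnames(pvalues)
  truth <- as.character(truth)
  if (!all(truth %in% classes))
    .stopf("true label(s) outside the model's label domain")
  m <- nrow(pvalues)
  if (m == 0L || length(truth) != m) .stopf("misaligned predictions and truth")
  idxTrue <- match(truth, classes)
  pTrue <- pvalues[cbind(seq_len(m), idxTrue)]
  fuzz <- mean(rowSums(pvalues) - pTrue)
  perEps <- data.frame(epsilon = grid, errorRate = NA_real_,
                       averageC = NA_real_, singleRatio = NA_real_,
                       multiRatio = NA_real_, emptyRatio = NA_real_)
  perClass <- expand.grid(epsilon = grid, class = classes,
                          stringsAsFactors = FALSE)
  perClass$errorRate <- NA_real_
  conf <- expand.grid(epsilon = grid, class = classes,
                      stringsAsFactors = FALSE)
  conf$correctSingle <- conf$wrongSingle <- conf$multi <- conf$empty <- NA_integer_
  for (g in seq_along(grid)) {
    eps <- grid[g]
    inSet <- pvalues >= eps
    size <- rowSums(inSet)
    err <- !inSet[cbind(seq_len(m), idxTrue)]
    perEps$errorRate[g] <- mean(err)
    perEps$averageC[g] <- mean(size)
    perEps$singleRatio[g] <- mean(size == 1L)
    perEps$multiRatio[g] <- mean(size > 1L)
    perEps$emptyRatio[g] <- mean(size == 0L)
    for (cl in classes) {
      sel <- truth == cl
      perClass$errorRate[perClass$epsilon == eps & perClass$class == cl] <-
        if (any(sel)) mean(err[sel]) else NA_real_
      row <- conf$epsilon == eps & conf$class == cl
      single <- sel & size == 1L
      conf$correctSingle[row] <- sum(single & !err)
      conf$wrongSingle[row] <- sum(single & err)
      conf$multi[row] <- sum(sel & size > 1L)
      conf$empty[row] <- sum(sel & size == 0L)
    }
  }
  list(observedFuzziness = fuzz, perEpsilon = perEps,
       perClassError = perClass, confusion = conf)
}

#' Conformal regression metrics
#'
#' Per significance level: error rate (truth outside the interval;
#' infinite intervals never err, so they count toward coverage), mean and
#' median width over the finite intervals, and the count of infinite
#' intervals.
#'
#' @param intervals data.frame from \code{\link{predictInterval}} (columns
#'   \code{row}, \code{epsilon}, \code{lower}, \code{upper}).
#' @param truth numeric true values, indexed by \code{intervals$row}.
#' @return data.frame with one row per significance level.
#' @export
regressionMetrics <- function(intervals, truth) {
  grid <- sort(unique(intervals$epsilon))
  out <- data.frame(epsilon = grid, errorRate = NA_real_,
                    meanWidth = NA_real_, medianWidth = NA_real_,
                    nInfinite = NA_integer_)
  for (g in seq_along(grid)) {
    sel <- intervals$epsilon == grid[g]
    lo <- intervals$lower[sel]; up <- intervals$upper[sel]
    tv <- truth[intervals$row[sel]]
    w <- up - lo
    fin <- is.finite(w)
    out$errorRate[g] <- mean(tv < lo | tv > up)
    out$meanWidth[g] <- if (any(fin)) mean(w[fin]) else NA_real_
    out$medianWidth[g] <- if (any(fin)) stats::median(w[fin]) else NA_real_
    out$nInfinite[g] <- sum(!fin)
  }
  out
}

#' Calibration statistics
#'
#' Quantifies how closely the error-rate curve tracks the significance
#' level: the maximum signed deviation \eqn{\max_i (err_i - \epsilon_i)},
#' the RMSE of the raw deviations, and the capped RMSE where conservative
#' deviations (error below epsilon) are zeroed before squaring, since the
#' conformal guarantee is one-sided.
#'
#' @param errorRates observed error rates over the grid.
#' @param grid the significance levels.
#' @return list with \code{maxSignedDeviation}, \code{rmse},
#'   \code{cappedRMSE}.
#' @examples
#' calibrationStats(c(0.05, 0.25), c(0.1, 0.2))$cappedRMSE  # ~0.0354
#' @export
calibrationStats <- function(errorRates, grid) {
  if (length(errorRates) != length(grid))
    .stopf("calibrationStats: length mismatch")
  dev <- errorRates - grid
  capped <- pmax(dev, 0)
  list(maxSignedDeviation = max(dev),
       rmse = sqrt(mean(dev^2)),
       cappedRMSE = sqrt(mean(capped^2)))
}

#' Write tidy metric files
#'
#' One CSV row per (epsilon, metric) pair plus a JSON summary, consumable
#' by any plotting tool.
#'
#' @param metrics result of \code{\link{classificationMetrics}} or
#'   \code{\link{regressionMetrics}}.
#' @param prefix output path prefix; writes \code{<prefix>.csv} and
#'   \code{<prefix>.json}.
#' @export
writeMetrics <- function(metrics, prefix) {
  if (is.data.frame(metrics)) {  # regression
    long <- stats::reshape(metrics, direction = "long",
      varying = setdiff(names(metrics), "epsilon"),
      v.names = "value", timevar = "metric",
      times = setdiff(names(metrics), "epsilon"))
    long <- long[order(long$epsilon), c("epsilon", "metric", "value")]
    utils::write.csv(long, paste0(prefix, ".csv"), row.names = FALSE)
    jsonlite::write_json(metrics, paste0(prefix, ".json"), digits = NA,
                         dataframe = "rows")
  } else {
    pe <- metrics$perEpsilon
    long <- do.call(rbind, lapply(setdiff(names(pe), "epsilon"), function(mn)
      data.frame(epsilon = pe$epsilon, metric = mn, value = pe[[mn]])))
    long <- rbind(long, data.frame(epsilon = NA_real_,
                                   metric = "observedFuzziness",
                                   value = metrics$observedFuzziness))
    utils::write.csv(long, paste0(prefix, ".csv"), row.names = FALSE)
    jsonlite::write_json(metrics, paste0(prefix, ".json"), digits = NA,
                         dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(prefix)
}

#' Validate a predictor specification
#'
#' Runs k-fold cross-validation, repeated single train/test splits, or
#' leave-one-out over a dataset, fitting the described conformal predictor
#' on each training part and scoring the held-out part. Fold metrics are
#' aggregated as mean and standard deviation across folds; LOO pools the n
#' single-object predictions before computing metrics.
#'
#' @param data a \code{SparseFeatureSet}.
#' @param spec predictor specification: a list with \code{scorer}
#'   (\code{\link{scorerConfig}}), \code{ncm}, \code{strategy},
#'   \code{pconfig} (optional), \code{aggregation} (optional).
#' @param scheme list: \code{list(kind = "kfold", k = 10)},
#'   \code{list(kind = "split", fraction = 0.3)} (test fraction) or
#'   \code{list(kind = "loo")}.
#' @param repetitions number of repetitions (split scheme); repetition r
#'   re-seeds with \code{seed + r - 1}.
#' @param stratified stratify fold/split assignment by class.
#' @param seed integer seed.
#' @param grid significance grid for the metrics.
#' @return list with \code{perFold} (list of per-fold metric objects),
#'   \code{summary} (data.frame of mean and sd per epsilon and metric) and
#'   \code{observedFuzziness} (classification: mean and sd).
#' @export
runValidation <- function(data, spec, scheme = list(kind = "kfold", k = 10),
                          repetitions = 1L, stratified = TRUE, seed = 1L,
                          grid = NULL) {
  stopifnot(is(data, "SparseFeatureSet"))
  n <- nrow(data@x)
  task <- data@task
  if (is.null(grid)) grid <- significanceGrid(task)
  folds <- .validationFolds(scheme, n, data@y, stratified, seed, repetitions)
  isLoo <- identical(scheme$kind, "loo")
  predictions <- list(); truths <- list(); perFold <- list()
  for (f in seq_along(folds)) {
    testIdx <- folds[[f]]
    trainIdx <- setdiff(seq_len(n), testIdx)
    trainData <- data[trainIdx]
    testX <- data@x[testIdx, , drop = FALSE]
    if (task == "classification") {
      model <- fitConformalClassifier(trainData, spec$scorer, spec$ncm,
        spec$strategy, spec$pconfig %||% pValueConfig(),
        spec$aggregation %||% "mean")
      pv <- predictPValues(model, testX)
      predictions[[f]] <- pv
      truths[[f]] <- as.character(data@y[testIdx])
      if (!isLoo)
        perFold[[f]] <- classificationMetrics(pv, truths[[f]], grid)
    } else {
      model <- fitConformalRegressor(trainData, spec$scorer, spec$ncm,
        spec$strategy, spec$pconfig %||% pValueConfig(),
        spec$aggregation %||% "median")
      iv <- predictInterval(model, testX, grid)
      predictions[[f]] <- iv
      truths[[f]] <- data@y[testIdx]
      if (!isLoo) perFold[[f]] <- regressionMetrics(iv, truths[[f]])
    }
  }
  if (isLoo) {
    if (task == "classification") {
      pv <- do.call(rbind, predictions)
      pooled <- classificationMetrics(pv, unlist(truths), grid)
      return(list(perFold = predictions, summary = pooled, pooled = TRUE))
    }
    iv <- do.call(rbind, lapply(seq_along(predictions), function(f) {
      z <- predictions[[f]]; z$row <- f; z
    }))
    pooled <- regressionMetrics(iv, unlist(truths))
    return(list(perFold = predictions, summary = pooled, pooled = TRUE))
  }
  if (task == "classification") {
    tabs <- lapply(perFold, `[[`, "perEpsilon")
    summary <- .foldSummary(tabs)
    fuzz <- vapply(perFold, `[[`, 0, "observedFuzziness")
    list(perFold = perFold, summary = summary,
         observedFuzziness = c(mean = mean(fuzz), sd = stats::sd(fuzz)),
         pooled = FALSE)
  } else {
    summary <- .foldSummary(perFold)
    list(perFold = perFold, summary = summary, pooled = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validationFolds <- function(scheme, n, labels, stratified, seed, repetitions) {
  kind <- scheme$kind
  if (kind == "loo") return(as.list(seq_len(n)))
  if (kind == "kfold") {
    k <- scheme$k
    if (k > n) .stopf("k-fold validation: k > n")
    assign <- withSeed(seed, {
      if (stratified && is.factor(labels)) {
        fold <- integer(n)
        for (lv in levels(labels)) {
          idx <- sample(which(labels == lv))
          fold[idx] <- rep(seq_len(k), length.out = length(idx))
        }
        fold
      } else {
        fold <- rep(seq_len(k), length.out = n)
        sample(fold)
      }
    })
    return(lapply(seq_len(k), function(i) which(assign == i)))
  }
  if (kind == "split") {
    frac <- scheme$fraction
    if (is.null(frac) || frac <= 0 || frac >= 1)
      .stopf("split validation: fraction must lie in (0,1)")
    return(lapply(seq_len(repetitions), function(r) {
      withSeed(seed + r - 1L, {
        if (stratified && is.factor(labels)) {
          unlist(lapply(levels(labels), function(lv) {
            idx <- which(labels == lv)
            sample(idx, max(1L, round(length(idx) * frac)))
          }), use.names = FALSE)
        } else sample.int(n, max(1L, round(n * frac)))
      })
    }))
  }
  .stopf("unknown validation scheme '%s'", kind)
}

.foldSummary <- function(tabs) {
  eps <- tabs[[1]]$epsilon
  metricNames <- setdiff(names(tabs[[1]]), "epsilon")
  out <- list()
  for (mn in metricNames) {
    vals <- vapply(tabs, function(t) t[[mn]], numeric(length(eps)))
    if (length(eps) == 1L) vals <- matrix(vals, nrow = 1)
    out[[length(out) + 1L]] <- data.frame(
      epsilon = eps, metric = mn,
      mean = rowMeans(vals),
      sd = apply(vals, 1, stats::sd))
  }
  do.call(rbind, out)
}
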