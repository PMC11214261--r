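#' Default RBF tuning grid
#'
#' Ten cost values \eqn{2^{-6}, 2^{-4}, ..., 2^{12}} crossed with six
#' kernel widths \eqn{2^{-14}, 2^{-12}, ..., 2^{-4}}: 60 combinations.
#'
#' @return named list of parameter value vectors.
#' @export
defaultRBFGrid <- function() {
  list(cost = 2^seq(-6, 12, by = 2), gamma = 2^seq(-14, -4, by = 2))
}

#' Grid-search hyper-parameter tuning
#'
#' Exhaustively evaluates every combination of the supplied parameter
#' grid. In \code{"scorer-only"} mode only the bare scoring model is
#' cross-validated (macro F1 for classification, RMSE for regression) and
#' no conformal calibration is ever trained, which saves considerable
#' compute when the final model aggregates several ICPs or is a TCP. In
#' \code{"full-predictor"} mode the complete conformal predictor described
#' by \code{spec} is validated and a conformal objective is used: observed
#' fuzziness (classification), median interval width at \code{targetEpsilon}
#' (regression), or capped calibration RMSE. Ties are broken by grid
#' enumeration order.
#'
#' @param data a \code{SparseFeatureSet}.
#' @param baseScorer the \code{\link{scorerConfig}} whose parameters the
#'   grid overrides.
#' @param grid named list of parameter value vectors (names must be
#'   scorerConfig arguments, e.g. \code{cost}, \code{gamma}).
#' @param mode "scorer-only" or "full-predictor".
#' @param objective metric name: scorer-only "macroF1" or "rmse"
#'   (defaulted from the task); full-predictor "observedFuzziness",
#'   "medianWidth" or "cappedRMSE".
#' @param targetEpsilon significance level at which width-type objectives
#'   are evaluated (default 0.2).
#' @param scheme validation scheme as in \code{\link{runValidation}}.
#' @param spec full-predictor specification (ncm, strategy, pconfig) as in
#'   \code{\link{runValidation}}; ignored in scorer-only mode.
#' @param seed integer seed.
#' @return list with \code{results} (data.frame, ranked) and \code{best}
#'   (the winning \code{scorerConfig}).
#' @export
gridSearch <- function(data, baseScorer, grid,
                       mode = c("scorer-only", "full-predictor"),
                       objective = NULL, targetEpsilon = 0.2,
                       scheme = list(kind = "kfold", k = 10),
                       spec = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(data, "SparseFeatureSet"), length(grid) > 0)
  task <- data@task
  known <- names(formals(scorerConfig))
  bad <- setdiff(names(grid), known)
  if (length(bad)) .stopf("unknown tuning parameter(s): %s",
                          paste(bad, collapse = ", "))
  if (is.null(objective))
    objective <- if (mode == "scorer-only") {
      if (task == "classification") "macroF1" else "rmse"
    } else {
      if (task == "classification") "observedFuzziness" else "medianWidth"
    }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- numeric(nrow(combos))
  maximize <- objective == "macroF1"
  for (i in seq_len(nrow(combos))) {
    cfg <- baseScorer
    for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][i]
    scores[i] <- if (mode == "scorer-only")
      .scorerObjective(data, cfg, objective, scheme, seed)
    else .predictorObjective(data, cfg, spec, objective, targetEpsilon,
                             scheme, seed)
  }
  ord <- order(if (maximize) -scores else scores)  # stable: ties keep order
  results <- cbind(combos, objective = scores)[ord, , drop = FALSE]
  rownames(results) <- NULL
  bestIdx <- ord[1]
  best <- baseScorer
  for (nm in names(combos)) best[[nm]] <- combos[[nm]][bestIdx]
  list(results = results, best = best, objectiveName = objective)
}

# Bare-scorer cross-validated objective; trains no calibration store.
.scorerObjective <- function(data, cfg, objective, scheme, seed) {
  n <- nrow(data@x)
  folds <- .validationFolds(scheme, n, data@y,
                            stratified = is.factor(data@y), seed, 1L)
  preds <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    testIdx <- folds[[f]]
    sc <- trainScorer(cfg, data[-testIdx])
    if (data@task == "classification") {
      d <- decisionScores(sc, data@x[testIdx, , drop = FALSE])
      preds[[f]] <- data.frame(truth = as.character(data@y[testIdx]),
                               pred = colnames(d)[max.col(d, "first")])
    } else {
      preds[[f]] <- data.frame(truth = data@y[testIdx],
        pred = decisionScores(sc, data@x[testIdx, , drop = FALSE]))
    }
  }
  all <- do.call(rbind, preds)
  if (objective == "macroF1") {
    f1 <- vapply(levels(data@y), function(cl) {
      tp <- sum(all$pred == cl & all$truth == cl)
      fp <- sum(all$pred == cl & all$truth != cl)
      fn <- sum(all$pred != cl & all$truth == cl)
      if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    mean(f1)
  } else if (objective == "rmse") {
    sqrt(mean((all$truth - all$pred)^2))
  } else .stopf("unknown scorer-only objective '%s'", objective)
}

.predictorObjective <- function(data, cfg, spec, objective, targetEpsilon,
                                scheme, seed) {
  spec <- spec %||% list()
  spec$scorer <- cfg
  if (is.null(spec$ncm))
    spec$ncm <- if (data@task == "classification") classificationNCM()
                else regressionNCM()
  if (is.null(spec$strategy)) spec$strategy <- samplingStrategy(seed = seed)
  grid <- if (objective == "cappedRMSE") significanceGrid(data@task)
          else targetEpsilon
  val <- runValidation(data, spec, scheme = scheme, seed = seed, grid = grid)
  if (objective == "observedFuzziness") {
    if (data@task != "classification")
      .stopf("observedFuzziness needs a classification task")
    return(unname(val$observedFuzziness["mean"]))
  }
  if (objective == "medianWidth") {
    s <- val$summary
    return(s$mean[s$metric == "medianWidth" & s$epsilon == targetEpsilon])
  }
  if (objective == "cappedRMSE") {
    s <- val$summary
    err <- s[s$metric == "errorRate", ]
    return(calibrationStats(err$mean, err$epsilon)$cappedRMSE)
  }
  .stopf("unknown full-predictor objective '%s'", objective)
}
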