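#' Per-feature contributions to one prediction
#'
#' Model-agnostic removal contributions: feature f's contribution is
#' \eqn{s(x) - s(x | x_f := 0)}, where s is the predicted midpoint
#' (regression) or the aggregated decision score of the predicted class
#' (the class with the highest p-value; classification). For a linear
#' scorer this equals \eqn{w_f x_f} exactly.
#'
#' @param model a \code{ConformalModel}.
#' @param x a single row (sparse vector / 1-row matrix).
#' @return named numeric vector: contribution per nonzero feature index.
#' @export
featureContributions <- function(model, x) {
  stopifnot(is(model, "ConformalModel"))
  if (is(x, "SparseFeatureSet")) x <- x@x
  x <- .asDgc(x)
  if (nrow(x) != 1L) .stopf("featureContributions: a single row is expected")
  if (ncol(x) != model@nFeatures)
    .stopf("featureContributions: feature dimensionality mismatch")
  nz <- which(x[1, ] != 0)
  if (!length(nz)) return(stats::setNames(numeric(0), character(0)))
  batch <- x[rep(1L, length(nz) + 1L), , drop = FALSE]
  for (k in seq_along(nz)) batch[k + 1L, nz[k]] <- 0
  s <- .interpretationScore(model, batch)
  stats::setNames(s[1] - s[-1], as.character(nz))
}

# Aggregated scalar score used for attribution: regression midpoint, or the
# decision score of the predicted class. Class choice is made on the first
# row of the batch (the unmodified object).
.interpretationScore <- function(model, batch) {
  aggFun <- if (model@aggregation == "mean") mean else stats::median
  if (model@task == "regression") {
    yh <- vapply(model@splits, function(sp) decisionScores(sp$scorer, batch),
                 numeric(nrow(batch)))
    if (nrow(batch) == 1L) yh <- matrix(yh, nrow = 1)
    return(apply(yh, 1, aggFun))
  }
  pv <- predictPValues(model, batch[1, , drop = FALSE])
  cls <- colnames(pv)[which.max(pv[1, ])]
  d <- vapply(model@splits,
              function(sp) decisionScores(sp$scorer, batch)[, cls],
              numeric(nrow(batch)))
  if (nrow(batch) == 1L) d <- matrix(d, nrow = 1)
  apply(d, 1, mean)
}

#' Atom-level contribution map
#'
#' Aggregates feature contributions back to the atoms they originate from:
#' each occurrence of a signature feature, rooted at atom a, credits a with
#' the feature's contribution divided by the feature's occurrence count
#' (alternatively spread uniformly over the occurrence's whole atom set).
#' Positive values push the prediction toward the predicted class
#' (classification) or increase the predicted value (regression). The
#' "significant signature" is the feature with the largest contribution
#' present in the molecule (ties: lexicographically smallest string).
#'
#' @param model a \code{ConformalModel}.
#' @param features a \code{\linkS4class{SignatureFeatures}} for the
#'   record(s), featurized under the model's vocabulary.
#' @param record which record of \code{features} to explain.
#' @param spread "root" (default) or "occurrence-set".
#' @return list with \code{atoms} (data.frame: \code{atom},
#'   \code{contribution}, \code{normalized}), \code{significantSignature},
#'   \code{significantAtoms} (list of occurrence atom-index sets) and
#'   \code{contributions} (the per-feature vector).
#' @export
atomGradient <- function(model, features, record = 1L,
                         spread = c("root", "occurrence-set")) {
  spread <- match.arg(spread)
  stopifnot(is(features, "SignatureFeatures"))
  x <- features@features@x[record, , drop = FALSE]
  amap <- features@atomMap[[record]]
  if (is.null(amap)) .stopf("atomGradient: no atom backmap for record %d", record)
  contrib <- featureContributions(model, x)
  nAtoms <- max(1L, vapply(amap, function(occs)
    max(vapply(occs, function(o) max(o$atoms), 0L)), 0L))
  atomVal <- numeric(nAtoms)
  for (fi in names(contrib)) {
    occs <- amap[[fi]]
    if (is.null(occs)) next  # external descriptor column: no atoms
    share <- contrib[[fi]] / length(occs)
    for (o in occs) {
      if (spread == "root") atomVal[o$root] <- atomVal[o$root] + share
      else atomVal[o$atoms] <- atomVal[o$atoms] + share / length(o$atoms)
    }
  }
  mx <- max(abs(atomVal))
  norm <- if (mx > 0) atomVal / mx else atomVal
  sigFeatures <- intersect(names(contrib), names(amap))
  sig <- NULL; sigAtoms <- list()
  if (length(sigFeatures)) {
    vals <- contrib[sigFeatures]
    strings <- signatureStrings(features@vocabulary)[as.integer(sigFeatures)]
    best <- which(vals == max(vals))
    if (length(best) > 1L)
      best <- best[order(strings[best], method = "radix")[1]]
    sig <- strings[best]
    sigAtoms <- lapply(amap[[sigFeatures[best]]], `[[`, "atoms")
  }
  list(atoms = data.frame(atom = seq_len(nAtoms), contribution = atomVal,
                          normalized = norm),
       significantSignature = sig, significantAtoms = sigAtoms,
       contributions = contrib)
}

#' Write an atom contribution map as JSON
#'
#' @param gradient result of \code{\link{atomGradient}}.
#' @param path output file.
#' @export
writeAtomContributions <- function(gradient, path) {
  jsonlite::write_json(list(
    atoms = gradient$atoms,
    significantSignature = gradient$significantSignature,
    significantAtoms = gradient$significantAtoms), path,
    digits = NA, auto_unbox = TRUE, dataframe = "rows", null = "null")
  invisible(path)
}
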