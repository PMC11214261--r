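#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t
#' @importClassesFrom Matrix dgCMatrix
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Sparse feature matrix with aligned labels
#'
#' Container for the numeric representation used throughout the package:
#' a sparse row-major matrix of per-record feature vectors (feature indices
#' are 1-based) together with the aligned label column and the task type.
#' Classification labels are stored as a factor whose level order is the
#' label domain (first-appearance order); regression labels are numeric.
#'
#' @slot x a \code{\link[Matrix]{dgCMatrix}} with one row per record.
#' @slot y labels aligned with rows: factor (classification), numeric
#'   (regression), or NULL for prediction-only data.
#' @slot task one of \code{"classification"}, \code{"regression"}.
#'
#' @export
setClass("SparseFeatureSet",
  representation(x = "dgCMatrix", y = "ANY", task = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@task %in% c("classification", "regression"))
      msg <- c(msg, "task must be 'classification' or 'regression'")
    if (!is.null(object@y)) {
      if (length(object@y) != nrow(object@x))
        msg <- c(msg, "length(y) must equal nrow(x)")
      if (object@task == "classification" && !is.factor(object@y))
        msg <- c(msg, "classification labels must be a factor")
      if (object@task == "regression" && !is.numeric(object@y))
        msg <- c(msg, "regression labels must be numeric")
    }
    if (length(object@x@x) && any(!is.finite(object@x@x)))
      msg <- c(msg, "feature values must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SparseFeatureSet
#'
#' @param x matrix-like object (coerced to sparse) or a dgCMatrix.
#' @param y labels: character/factor for classification, numeric for
#'   regression, or NULL for unlabeled data.
#' @param task "classification" or "regression".
#' @param labelDomain optional explicit class order (classification); by
#'   default the order of first appearance in \code{y}.
#' @return a \code{SparseFeatureSet}.
#' @examples
#' sfs <- sparseFeatureSet(matrix(1:6, 2), c("a", "b"), "classification")
#' @export
sparseFeatureSet <- function(x, y = NULL, task = c("classification", "regression"),
                             labelDomain = NULL) {
  task <- match.arg(task)
  if (!is(x, "dgCMatrix"))
    x <- as(as(as(Matrix(as.matrix(x), sparse = TRUE), "dMatrix"),
               "generalMatrix"), "CsparseMatrix")
  if (!is.null(y) && task == "classification" && !is.factor(y)) {
    if (is.null(labelDomain)) labelDomain <- unique(as.character(y))
    y <- factor(as.character(y), levels = labelDomain)
  }
  new("SparseFeatureSet", x = x, y = y, task = task)
}

#' @describeIn sparseFeatureSet the sparse matrix slot.
#' @param object a SparseFeatureSet.
#' @export
featureMatrix <- function(object) object@x

#' @describeIn sparseFeatureSet the aligned label column.
#' @export
labelValues <- function(object) object@y

#' @describeIn sparseFeatureSet the task string.
#' @export
taskType <- function(object) object@task

setMethod("show", "SparseFeatureSet", function(object) {
  cat("SparseFeatureSet:", nrow(object@x), "records x", ncol(object@x),
      "features;", object@task)
  if (object@task == "classification" && !is.null(object@y))
    cat(" [", paste(levels(object@y), collapse = ", "), "]", sep = "")
  cat("\n")
})

setMethod("dim", "SparseFeatureSet", function(x) dim(x@x))

#' Subset records of a SparseFeatureSet
#' @param x a SparseFeatureSet.
#' @param i row (record) indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SparseFeatureSet", function(x, i, j, ..., drop = FALSE) {
  new("SparseFeatureSet", x = x@x[i, , drop = FALSE],
      y = if (is.null(x@y)) NULL else x@y[i, drop = FALSE], task = x@task)
})

#' Molecule dataset
#'
#' Ordered collection of parsed molecule records with labels and optional
#' externally supplied per-record numeric descriptors. Structures are
#' molecular graphs as returned by \code{\link{parseStructure}}.
#'
#' @slot ids character record identifiers.
#' @slot structures list of molecular graphs (see \code{parseStructure}).
#' @slot labels factor (classification) / numeric (regression) / NULL.
#' @slot task "classification" or "regression".
#' @slot extra data.frame of external numeric descriptors (0 columns if none),
#'   one row per record; columns are appended after signature features
#'   during featurization, in column order.
#'
#' @export
setClass("ChemDataset",
  representation(ids = "character", structures = "list", labels = "ANY",
                 task = "character", extra = "data.frame"),
  validity = function(object) {
    n <- length(object@ids)
    msg <- NULL
    if (length(object@structures) != n)
      msg <- c(msg, "ids and structures lengths differ")
    if (!is.null(object@labels) && length(object@labels) != n)
      msg <- c(msg, "labels length differs from record count")
    if (!object@task %in% c("classification", "regression"))
      msg <- c(msg, "task must be 'classification' or 'regression'")
    if (nrow(object@extra) && nrow(object@extra) != n)
      msg <- c(msg, "extra descriptor rows differ from record count")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname ChemDataset-class
#' @param ids,structures,labels,task,extra see slots.
#' @export
chemDataset <- function(ids, structures, labels = NULL,
                        task = c("classification", "regression"),
                        extra = NULL) {
  task <- match.arg(task)
  if (!is.null(labels) && task == "classification" && !is.factor(labels))
    labels <- factor(as.character(labels), levels = unique(as.character(labels)))
  if (is.null(extra)) extra <- data.frame(row.names = seq_along(ids))
  new("ChemDataset", ids = as.character(ids), structures = structures,
      labels = labels, task = task, extra = extra)
}

#' @rdname ChemDataset-class
#' @param object a ChemDataset.
#' @export
recordIds <- function(object) object@ids

#' @rdname ChemDataset-class
#' @export
structures <- function(object) object@structures

#' @rdname ChemDataset-class
#' @export
datasetLabels <- function(object) object@labels

#' @rdname ChemDataset-class
#' @export
labelDomain <- function(object) {
  if (is.factor(object@labels)) levels(object@labels) else character(0)
}

setMethod("show", "ChemDataset", function(object) {
  cat("ChemDataset:", length(object@ids), "records;", object@task)
  if (is.factor(object@labels))
    cat(" [", paste(levels(object@labels), collapse = ", "), "]", sep = "")
  if (ncol(object@extra)) cat(";", ncol(object@extra), "external descriptors")
  cat("\n")
})

setMethod("length", "ChemDataset", function(x) length(x@ids))

#' @rdname ChemDataset-class
#' @param x a ChemDataset.
#' @param i record indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ChemDataset", function(x, i, j, ..., drop = FALSE) {
  new("ChemDataset", ids = x@ids[i], structures = x@structures[i],
      labels = if (is.null(x@labels)) NULL else x@labels[i, drop = FALSE],
      task = x@task, extra = x@extra[i, , drop = FALSE])
})

#' Signature vocabulary
#'
#' Injective mapping from canonical signature strings to 1-based feature
#' indices, assigned in first-encounter order during featurization.
#' Frozen at prediction time: signatures absent from the vocabulary are
#' dropped, never appended.
#'
#' @slot strings character vector; feature index = position.
#' @slot hMin,hMax the signature height range.
#' @export
setClass("SignatureVocabulary",
  representation(strings = "character", hMin = "integer", hMax = "integer"),
  validity = function(object) {
    msg <- NULL
    if (anyDuplicated(object@strings)) msg <- c(msg, "signature strings must be unique")
    if (object@hMin < 0L || object@hMax < object@hMin)
      msg <- c(msg, "require 0 <= hMin <= hMax")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname SignatureVocabulary-class
#' @param object a SignatureVocabulary.
#' @export
signatureStrings <- function(object) object@strings

#' @rdname SignatureVocabulary-class
#' @export
heightRange <- function(object) c(object@hMin, object@hMax)

setMethod("length", "SignatureVocabulary", function(x) length(x@strings))

setMethod("show", "SignatureVocabulary", function(object) {
  cat("SignatureVocabulary:", length(object@strings), "signatures, heights",
      object@hMin, "..", object@hMax, "\n")
})

#' Featurization result
#'
#' Bundles the vocabulary, the sparse count matrix (signature counts, with
#' any external descriptor columns appended), and the per-record
#' atom-occurrence backmap used for interpretation.
#'
#' @slot vocabulary a \code{SignatureVocabulary}.
#' @slot features a \code{SparseFeatureSet}; the first
#'   \code{length(vocabulary)} columns are signature counts.
#' @slot atomMap per-record list: names are feature indices (as character),
#'   values are lists of occurrences, each \code{list(root =, atoms =)}
#'   with 1-based atom indices.
#' @slot externalNames names of appended external descriptor columns.
#' @slot dropped integer per-record count of prediction-time signatures not
#'   in the frozen vocabulary (all zero in training mode).
#' @export
setClass("SignatureFeatures",
  representation(vocabulary = "SignatureVocabulary", features = "SparseFeatureSet",
                 atomMap = "list", externalNames = "character",
                 dropped = "integer"))

setMethod("show", "SignatureFeatures", function(object) {
  cat("SignatureFeatures:", nrow(object@features@x), "records,",
      length(object@vocabulary), "signature features")
  if (length(object@externalNames))
    cat(" +", length(object@externalNames), "external")
  cat("\n")
})

#' Data sampling strategy
#'
#' Describes how training data are split into proper-training and
#' calibration parts: one or several random (optionally stratified)
#' splits, disjoint folds, or explicit predefined partitions.
#'
#' @slot kind "random", "random-stratified", "predefined" or "fold".
#' @slot calibrationRatio fraction of records used for calibration
#'   (random kinds).
#' @slot nSplits number of splits (ACP repetitions) or folds (CCP k).
#' @slot seed integer RNG seed; splits are pure functions of
#'   (data, strategy).
#' @slot partitions for kind "predefined": list of
#'   \code{list(properTrain =, calibration =)} index vectors.
#' @export
setClass("SamplingStrategy",
  representation(kind = "character", calibrationRatio = "numeric",
                 nSplits = "integer", seed = "integer", partitions = "list"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("random", "random-stratified", "predefined", "fold"))
      msg <- c(msg, "unknown sampling kind")
    if (object@kind %in% c("random", "random-stratified") &&
        (object@calibrationRatio <= 0 || object@calibrationRatio >= 1))
      msg <- c(msg, "calibrationRatio must lie in (0,1)")
    if (object@nSplits < 1L) msg <- c(msg, "nSplits must be >= 1")
    if (object@kind == "predefined" && !length(object@partitions))
      msg <- c(msg, "predefined kind requires explicit partitions")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname SamplingStrategy-class
#' @param kind,calibrationRatio,nSplits,seed,partitions see slots.
#' @export
samplingStrategy <- function(kind = c("random", "random-stratified",
                                      "predefined", "fold"),
                             calibrationRatio = 0.2, nSplits = 1L,
                             seed = 1L, partitions = list()) {
  kind <- match.arg(kind)
  new("SamplingStrategy", kind = kind, calibrationRatio = calibrationRatio,
      nSplits = as.integer(nSplits), seed = as.integer(seed),
      partitions = partitions)
}

setMethod("show", "SamplingStrategy", function(object) {
  cat("SamplingStrategy:", object@kind,
      if (object@kind %in% c("random", "random-stratified"))
        sprintf("(ratio %.2f, %d split%s)", object@calibrationRatio,
                object@nSplits, if (object@nSplits > 1) "s" else "")
      else sprintf("(%d parts)", max(object@nSplits, length(object@partitions))),
      "\n")
})

#' Fitted scorer
#'
#' Uniform wrapper over the underlying scoring algorithms (libsvm SVC/SVR,
#' ridge-stabilized logistic regression) exposing decision scores and,
#' where supported, class probabilities.
#'
#' @slot fit the fitted model object.
#' @slot config the \code{\link{scorerConfig}} used.
#' @slot task "classification" or "regression".
#' @slot classes class labels in label-domain order (classification).
#' @slot nFeatures training dimensionality.
#' @slot platt sigmoid calibration coefficients (SVC probability mode).
#' @slot standardization list(cols, center, scale) for external columns.
#' @export
setClass("Scorer",
  representation(fit = "ANY", config = "list", task = "character",
                 classes = "character", nFeatures = "integer",
                 platt = "ANY", standardization = "ANY"))

setMethod("show", "Scorer", function(object) {
  cat("Scorer:", object@config$algorithm,
      if (object@config$algorithm != "logistic") paste0("(", object@config$kernel, ")"),
      object@task, "on", object@nFeatures, "features\n")
})

#' Conformal predictor model
#'
#' A fitted mondrian conformal classifier or conformal regressor: one
#' (scorer, calibration store) pair per data split, the nonconformity
#' measure, the p-value calculator configuration and the aggregation rule
#' for multi-split (ACP/CCP) models.
#'
#' @slot task "classification" or "regression".
#' @slot splits list; per split, \code{list(scorer =, calibration =,
#'   errorModel =)}. Classification calibration is a per-class list of
#'   sorted nonconformity values; regression a single sorted vector.
#' @slot ncm the nonconformity-measure descriptor.
#' @slot pconfig the p-value calculator configuration.
#' @slot aggregation "mean" or "median" (classification p-values);
#'   regression bound aggregation is "median" or "mean".
#' @slot classes label domain (classification).
#' @slot nFeatures training dimensionality.
#' @export
setClass("ConformalModel",
  representation(task = "character", splits = "list", ncm = "list",
                 pconfig = "list", aggregation = "character",
                 classes = "character", nFeatures = "integer"))

setMethod("show", "ConformalModel", function(object) {
  kind <- if (length(object@splits) == 1L) "ICP"
          else paste0(if (identical(object@ncm$sampling, "fold")) "CCP" else "ACP",
                      "(", length(object@splits), ")")
  cat("ConformalModel:", object@task, kind, "ncm =", object@ncm$kind, "\n")
  if (object@task == "classification") {
    ns <- vapply(object@splits[[1]]$calibration, length, 0L)
    cat("  calibration sizes (split 1):",
        paste(sprintf("%s=%d", object@classes, ns), collapse = ", "), "\n")
  } else {
    cat("  calibration size (split 1):",
        length(object@splits[[1]]$calibration), "\n")
  }
})

#' Venn-ABERS model
#'
#' One fitted scorer plus (score, binary label) calibration pairs per fold;
#' a single fold is an inductive Venn-ABERS predictor (IVAP), several folds
#' a cross Venn-ABERS predictor (CVAP).
#'
#' @slot folds list of \code{list(scorer =, scores =, labels01 =)}.
#' @slot classes the two class labels; the second is the "positive" class
#'   whose probability is reported.
#' @slot nFeatures training dimensionality.
#' @export
setClass("VennAbersModel",
  representation(folds = "list", classes = "character", nFeatures = "integer"))

setMethod("show", "VennAbersModel", function(object) {
  cat("VennAbersModel:", length(object@folds),
      if (length(object@folds) == 1L) "fold (IVAP);" else "folds (CVAP);",
      "positive class =", object@classes[2], "\n")
})
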