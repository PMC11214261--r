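# Model persistence: a single self-describing tar archive holding a JSON
# manifest (version, task, configuration, label domain, descriptor setup,
# seeds) plus an RDS payload with the fitted components. Predictions after
# a save/load round trip are identical to pre-save predictions.

.ARCHIVE_VERSION <- 1L

#' Save / load a model archive
#'
#' The archive bundles everything needed to predict new structures:
#' the descriptor configuration and frozen signature vocabulary, any
#' external-descriptor column schema, the fitted conformal or Venn-ABERS
#' model (scorers, calibration stores, NCM and p-value calculator
#' configuration), the task metadata and label domain, and creation
#' provenance. The format version is checked on load.
#'
#' @param model a \code{ConformalModel} or \code{VennAbersModel}.
#' @param path archive file path.
#' @param vocabulary optional \code{SignatureVocabulary} (chemistry
#'   pipelines).
#' @param meta optional named list merged into the manifest (e.g. heights,
#'   external descriptor names, seeds).
#' @return \code{path}, invisibly.
#' @export
saveModelArchive <- function(model, path, vocabulary = NULL, meta = list()) {
  stopifnot(is(model, "ConformalModel") || is(model, "VennAbersModel"))
  dir <- tempfile("archive")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  manifest <- c(list(
    format = "conformalsig-archive",
    version = .ARCHIVE_VERSION,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    tool = as.character(utils::packageVersion("conformalsig")),
    modelClass = class(model)[1],
    task = if (is(model, "ConformalModel")) model@task else "classification",
    classes = if (is(model, "ConformalModel")) model@classes else model@classes,
    nFeatures = model@nFeatures), meta)
  if (is(model, "ConformalModel")) {
    manifest$ncm <- model@ncm[setdiff(names(model@ncm), "errorConfig")]
    manifest$pvalueMode <- model@pconfig$mode
    manifest$aggregation <- model@aggregation
    manifest$nSplits <- length(model@splits)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(list(model = model, vocabulary = vocabulary),
          file.path(dir, "payload.rds"), version = 2)
  if (is.null(vocabulary)) NULL
  else writeVocabulary(vocabulary, file.path(dir, "vocabulary.txt"))
  target <- file.path(normalizePath(dirname(path)), basename(path))
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  status <- utils::tar(target, files = list.files(dir),
                       compression = "none", tar = "internal")
  setwd(old)
  if (!identical(status, 0L) && !is.null(status) && status != 0)
    .stopf("failed to write archive %s", path)
  invisible(path)
}

#' @rdname saveModelArchive
#' @return \code{loadModelArchive}: list with \code{model},
#'   \code{vocabulary} (or NULL) and \code{manifest}.
#' @export
loadModelArchive <- function(path) {
  if (!file.exists(path)) .stopf("archive not found: %s", path)
  dir <- tempfile("unarchive")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::untar(path, exdir = dir, tar = "internal")
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) .stopf("not a model archive (no manifest): %s", path)
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$format, "conformalsig-archive"))
    .stopf("not a conformalsig archive: %s", path)
  if (manifest$version > .ARCHIVE_VERSION)
    .stopf("archive version %s is newer than this tool supports (%d)",
           manifest$version, .ARCHIVE_VERSION)
  payload <- readRDS(file.path(dir, "payload.rds"))
  list(model = payload$model, vocabulary = payload$vocabulary,
       manifest = manifest)
}
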