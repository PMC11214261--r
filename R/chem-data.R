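#' Parse a SMILES string into a molecular graph
#'
#' Structures are parsed and normalized by OpenBabel (via \pkg{ChemmineOB});
#' aromaticity comes from OpenBabel's perception model. The returned graph
#' holds heavy atoms only: implicit hydrogens are never instantiated and
#' explicit hydrogens are removed. Atom indices are 1-based and stable for
#' the lifetime of the record.
#'
#' @param smiles a single non-empty SMILES string.
#' @return an object of class \code{"MolGraph"}: a list with
#'   \code{atoms} (data.frame: \code{element}, \code{charge},
#'   \code{aromatic}) and \code{bonds} (data.frame: \code{from}, \code{to},
#'   \code{order} in 1:3, \code{aromatic}).
#' @examples
#' benzene <- parseStructure("c1ccccc1")
#' nrow(benzene$atoms)  # 6
#' @export
parseStructure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    .stopf("parseStructure: need a single non-empty SMILES string")
  if (grepl("[[:space:]]", smiles))
    .stopf("parseStructure: SMILES may not contain whitespace: '%s'", smiles)
  conv <- .obConvertSmiles(smiles)
  if (is.null(conv))
    .stopf("parseStructure: unparseable SMILES: '%s'", smiles)
  .molFromBlocks(conv$sdf, conv$mol2)
}

# OpenBabel conversion of one SMILES to both SDF (elements, charges, bond
# orders) and MOL2 (aromatic bond flags). OpenBabel signals failure by
# returning empty output, and a batch conversion stops at the first bad
# record, hence one molecule per call. Returns NULL on failure.
.obConvertSmiles <- function(smiles) {
  inp <- paste0(smiles, " mol\n")
  sdf <- tryCatch(suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat("SMI", "SDF", inp))), error = function(e) "")
  if (!nzchar(sdf)) return(NULL)
  mol2 <- tryCatch(suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat("SMI", "MOL2", inp))), error = function(e) "")
  if (!nzchar(mol2)) return(NULL)
  list(sdf = sdf, mol2 = mol2)
}

# Same for one SDF entry (text including terminal $$$$): normalize via
# OpenBabel so that old-style charge codes are present and V3000 input is
# reduced to V2000, plus a MOL2 rendering for aromaticity.
.obConvertSDFEntry <- function(entry) {
  sdf <- tryCatch(suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat("SDF", "SDF", entry))), error = function(e) "")
  if (!nzchar(sdf)) return(NULL)
  mol2 <- tryCatch(suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat("SDF", "MOL2", entry))), error = function(e) "")
  if (!nzchar(mol2)) return(NULL)
  list(sdf = sdf, mol2 = mol2)
}

# V2000 old-style charge codes, positions 0..7.
.chargeFromCode <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)

# Build the MolGraph from an OpenBabel-normalized V2000 block and the
# matching MOL2 text (same atom/bond order). Heavy atoms only.
.molFromBlocks <- function(sdf, mol2) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  nAtoms <- as.integer(substr(counts, 1, 3))
  nBonds <- as.integer(substr(counts, 4, 6))
  if (is.na(nAtoms) || nAtoms < 1L) .stopf("malformed SDF counts line")
  atomLines <- lines[5:(4 + nAtoms)]
  element <- trimws(substr(atomLines, 32, 34))
  code <- as.integer(trimws(substr(atomLines, 37, 39)))
  charge <- .chargeFromCode[pmin(pmax(code, 0L), 7L) + 1L]
  # M CHG overrides the old-style codes when present
  for (ml in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ml)), "[[:space:]]+")[[1]])
    k <- f[1]
    for (e in seq_len(k)) charge[f[2 * e]] <- f[2 * e + 1]
  }
  if (nBonds > 0L) {
    bondLines <- lines[(5 + nAtoms):(4 + nAtoms + nBonds)]
    from <- as.integer(substr(bondLines, 1, 3))
    to <- as.integer(substr(bondLines, 4, 6))
    order <- as.integer(substr(bondLines, 7, 9))
  } else from <- to <- order <- integer(0)
  aromatic <- .mol2AromaticBonds(mol2, from, to)
  aromatic <- aromatic | order == 4L
  order[order == 4L] <- 1L  # nominal order for aromatic bonds; token is "p"
  # drop explicit hydrogens
  keep <- element != "H" & element != "D" & element != "T"
  if (!all(keep)) {
    newIdx <- cumsum(keep)
    bKeep <- keep[from] & keep[to]
    from <- newIdx[from[bKeep]]; to <- newIdx[to[bKeep]]
    order <- order[bKeep]; aromatic <- aromatic[bKeep]
    element <- element[keep]; charge <- charge[keep]
  }
  atomArom <- logical(length(element))
  atomArom[from[aromatic]] <- TRUE
  atomArom[to[aromatic]] <- TRUE
  structure(list(
    atoms = data.frame(element = element, charge = charge,
                       aromatic = atomArom, stringsAsFactors = FALSE),
    bonds = data.frame(from = from, to = to, order = order,
                       aromatic = aromatic)),
    class = "MolGraph")
}

# Extract the aromatic flags of the @<TRIPOS>BOND table; bond order in the
# MOL2 output matches the SDF bond block of the same OpenBabel parse. No
# installed R package reads MOL2, so this one table is read here.
.mol2AromaticBonds <- function(mol2, from, to) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  start <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
  n <- length(from)
  ar <- logical(n)
  if (!length(start) || n == 0L) return(ar)
  i <- start[1] + 1L
  got <- 0L
  while (i <= length(lines) && got < n && !startsWith(lines[i], "@")) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) >= 4L) {
      got <- got + 1L
      a1 <- as.integer(f[2]); a2 <- as.integer(f[3])
      if (identical(f[4], "ar")) {
        hit <- which((from == a1 & to == a2) | (from == a2 & to == a1))
        if (length(hit)) ar[hit[1]] <- TRUE
      }
    }
    i <- i + 1L
  }
  ar
}

#' @export
print.MolGraph <- function(x, ...) {
  cat("MolGraph:", nrow(x$atoms), "heavy atoms,", nrow(x$bonds), "bonds",
      if (any(x$atoms$aromatic)) sprintf("(%d aromatic atoms)", sum(x$atoms$aromatic)),
      "\n")
  invisible(x)
}

#' Read a chemical dataset from CSV or SDF
#'
#' CSV files need a header and a SMILES column; SDF files carry the label
#' as a named property. Records whose structure fails to parse are skipped
#' (the skip count is reported via \code{message}), not fatal.
#' Classification labels enter the label domain in first-appearance order.
#' Duplicate canonical structures are kept but reported with a warning.
#'
#' @param path input file.
#' @param format "csv" or "sdf".
#' @param labelColumn CSV column / SDF property holding the label.
#' @param smilesColumn CSV column holding SMILES (csv only).
#' @param task "classification" or "regression".
#' @param idColumn optional CSV column / SDF property used as record id;
#'   default: molecule title or running number.
#' @param delimiter CSV field delimiter.
#' @return a \code{\link{chemDataset}}.
#' @export
readChemDataset <- function(path, format = c("csv", "sdf"), labelColumn,
                            smilesColumn = "smiles",
                            task = c("classification", "regression"),
                            idColumn = NULL, delimiter = ",") {
  format <- match.arg(format)
  task <- match.arg(task)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "csv") {
    tab <- utils::read.csv(path, sep = delimiter, check.names = FALSE,
                           stringsAsFactors = FALSE)
    for (col in c(smilesColumn, labelColumn, idColumn))
      if (!col %in% names(tab))
        .stopf("column '%s' not found in %s", col, path)
    smiles <- as.character(tab[[smilesColumn]])
    rawLabels <- tab[[labelColumn]]
    ids <- if (is.null(idColumn)) as.character(seq_along(smiles))
           else as.character(tab[[idColumn]])
    mols <- vector("list", length(smiles))
    ok <- logical(length(smiles))
    canon <- character(length(smiles))
    for (i in seq_along(smiles)) {
      conv <- .obConvertSmiles(smiles[i])
      if (!is.null(conv)) {
        mols[[i]] <- .molFromBlocks(conv$sdf, conv$mol2)
        canon[i] <- .canonicalSmiles(conv$sdf)
        ok[i] <- TRUE
      }
    }
  } else {
    entries <- .splitSDFEntries(readLines(path, warn = FALSE))
    n <- length(entries)
    smilesNA <- NULL
    mols <- vector("list", n); ok <- logical(n)
    canon <- character(n); ids <- character(n); rawLabels <- rep(NA, n)
    for (i in seq_len(n)) {
      txt <- paste0(paste(entries[[i]], collapse = "\n"), "\n$$$$\n")
      props <- .sdfProperties(entries[[i]])
      if (!labelColumn %in% names(props)) next  # unlabeled entry -> skip
      conv <- .obConvertSDFEntry(txt)
      if (is.null(conv)) next
      mols[[i]] <- .molFromBlocks(conv$sdf, conv$mol2)
      canon[i] <- .canonicalSmiles(conv$sdf)
      rawLabels[i] <- props[[labelColumn]]
      ids[i] <- if (!is.null(idColumn) && idColumn %in% names(props))
        props[[idColumn]] else {
          ttl <- trimws(entries[[i]][1])
          if (nzchar(ttl)) ttl else as.character(i)
        }
      ok[i] <- TRUE
    }
  }
  nSkipped <- sum(!ok)
  if (!any(ok)) .stopf("no valid records in %s", path)
  if (nSkipped > 0L)
    message(sprintf("readChemDataset: skipped %d unparseable record(s)", nSkipped))
  labels <- rawLabels[ok]
  if (task == "regression") {
    labels <- suppressWarnings(as.numeric(labels))
    if (anyNA(labels)) .stopf("non-numeric regression label(s) in %s", path)
  }
  dup <- unique(canon[ok][duplicated(canon[ok]) & nzchar(canon[ok])])
  if (length(dup))
    warning(sprintf("duplicate structures kept as distinct records: %s",
                    paste(dup, collapse = ", ")), call. = FALSE)
  chemDataset(ids = ids[ok], structures = mols[ok], labels = labels,
              task = task)
}

.canonicalSmiles <- function(sdfText) {
  out <- tryCatch(suppressWarnings(suppressMessages(
    ChemmineOB::convertFormat("SDF", "CAN", sdfText))), error = function(e) "")
  trimws(strsplit(out, "[\t\n ]")[[1]][1])
}

.splitSDFEntries <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (k in seq_along(ends)) {
    block <- lines[starts[k]:max(starts[k], ends[k] - 1L)]
    if (any(nzchar(trimws(block)))) out[[length(out) + 1L]] <- block
  }
  out
}

.sdfProperties <- function(entryLines) {
  idx <- grep("^> *<", entryLines)
  props <- list()
  for (i in idx) {
    nm <- sub("^> *<([^>]*)>.*$", "\\1", entryLines[i])
    val <- if (i + 1L <= length(entryLines)) trimws(entryLines[i + 1L]) else ""
    props[[nm]] <- val
  }
  props
}

#' Attach external numeric descriptors to a dataset
#'
#' External per-record descriptors are appended after the signature
#' features during featurization, in the column order given here.
#'
#' @param dataset a \code{ChemDataset}.
#' @param table data.frame of numeric columns; record ids in a column named
#'   \code{id} or in \code{rownames}.
#' @param policy "strict" (every dataset id must be present) or
#'   "drop-missing" (records without descriptor rows are dropped).
#' @return the dataset with populated external descriptors.
#' @export
attachDescriptors <- function(dataset, table, policy = c("strict", "drop-missing")) {
  policy <- match.arg(policy)
  if (NROW(table) == 0L || NCOL(table) == 0L) return(dataset)
  if ("id" %in% names(table)) {
    rn <- as.character(table$id)
    table <- table[, setdiff(names(table), "id"), drop = FALSE]
  } else rn <- rownames(table)
  for (cn in names(table))
    if (!is.numeric(table[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(table[[cn]])))))[1]
      .stopf("attachDescriptors: non-numeric value in column '%s' (row %s)",
             cn, if (is.na(bad)) "?" else bad)
    }
  hit <- match(dataset@ids, rn)
  if (anyNA(hit)) {
    if (policy == "strict")
      .stopf("attachDescriptors: id(s) missing from descriptor table: %s",
             paste(utils::head(dataset@ids[is.na(hit)], 5), collapse = ", "))
    dataset <- dataset[!is.na(hit)]
    hit <- hit[!is.na(hit)]
  }
  extra <- table[hit, , drop = FALSE]
  rownames(extra) <- NULL
  initialize(dataset, extra = extra)
}

#' Split data into proper-training and calibration parts
#'
#' Realizes a \code{\link{samplingStrategy}} over \code{n} records:
#' random or stratified-random splits (ACP repetitions), disjoint folds
#' whose calibration parts partition the data (CCP), or predefined
#' partitions. Pure function of (strategy, n, labels).
#'
#' @param strategy a \code{SamplingStrategy}.
#' @param n number of records.
#' @param labels class labels, required for stratified splits.
#' @return list of splits, each \code{list(properTrain =, calibration =)}
#'   of disjoint 1-based indices whose union is \code{1:n}.
#' @examples
#' sp <- splitSampling(samplingStrategy("random", 0.2, seed = 7), 100)
#' length(sp[[1]]$calibration)  # 20
#' @export
splitSampling <- function(strategy, n, labels = NULL) {
  stopifnot(is(strategy, "SamplingStrategy"))
  if (n < 2L) .stopf("splitSampling: need at least 2 records")
  kind <- strategy@kind
  if (kind == "predefined") return(strategy@partitions)
  if (kind == "fold") {
    k <- strategy@nSplits
    if (k < 2L || k > n) .stopf("fold sampling: need 2 <= k <= n")
    perm <- withSeed(strategy@seed, sample.int(n))
    fold <- rep(seq_len(k), length.out = n)
    return(lapply(seq_len(k), function(i) {
      cal <- sort(perm[fold == i])
      list(properTrain = setdiff(seq_len(n), cal), calibration = cal)
    }))
  }
  ratio <- strategy@calibrationRatio
  lapply(seq_len(strategy@nSplits), function(s) {
    cal <- withSeed(strategy@seed + s - 1L, {
      if (kind == "random-stratified") {
        if (is.null(labels)) .stopf("stratified sampling requires labels")
        labels <- as.factor(labels)
        unlist(lapply(levels(labels), function(lv) {
          idx <- which(labels == lv)
          m <- round(length(idx) * ratio)
          if (m < 1L || m >= length(idx))
            .stopf("stratification impossible for class '%s' at ratio %.2f",
                   lv, ratio)
          sample(idx, m)
        }), use.names = FALSE)
      } else {
        m <- round(n * ratio)
        if (m < 1L || m >= n) .stopf("calibration ratio %.2f infeasible for n=%d",
                                     ratio, n)
        sample.int(n, m)
      }
    })
    cal <- sort(cal)
    list(properTrain = setdiff(seq_len(n), cal), calibration = cal)
  })
}

#' Write / read the sparse text dialect
#'
#' One record per line: \code{label idx:value idx:value ...} with strictly
#' ascending 1-based feature indices (the de facto sparse SVM-file
#' convention). The round trip is exact on labels, indices and printed
#' values.
#'
#' @param object a \code{SparseFeatureSet}.
#' @param path output / input file.
#' @export
writeSparseMatrix <- function(object, path) {
  stopifnot(is(object, "SparseFeatureSet"))
  m <- object@x
  y <- object@y
  lab <- if (is.null(y)) rep("0", nrow(m))
         else if (is.factor(y)) as.character(y)
         else sprintf("%.17g", y)
  if (any(grepl("[[:space:]:]", lab)))
    .stopf("labels must not contain whitespace or ':' in the sparse dialect")
  mt <- Matrix::t(m)  # column-slice per record
  p <- mt@p; iAll <- mt@i + 1L; xAll <- mt@x
  lines <- vapply(seq_len(nrow(m)), function(r) {
    if (p[r + 1L] == p[r]) return(lab[r])
    sel <- (p[r] + 1L):p[r + 1L]
    paste(lab[r], paste(sprintf("%d:%.17g", iAll[sel], xAll[sel]),
                        collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSparseMatrix
#' @param task task of the stored labels.
#' @param nFeatures total vocabulary size; default: largest index seen.
#' @param labelDomain optional explicit class order (classification).
#' @return \code{readSparseMatrix}: a \code{SparseFeatureSet}.
#' @export
readSparseMatrix <- function(path, task = c("classification", "regression"),
                             nFeatures = NULL, labelDomain = NULL) {
  task <- match.arg(task)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .stopf("empty sparse file: %s", path)
  ii <- jj <- integer(0); xx <- numeric(0)
  labs <- character(length(lines))
  for (r in seq_along(lines)) {
    tok <- strsplit(trimws(lines[r]), "[[:space:]]+")[[1]]
    labs[r] <- tok[1]
    if (length(tok) > 1L) {
      kv <- strsplit(tok[-1], ":", fixed = TRUE)
      idx <- as.integer(vapply(kv, `[`, "", 1L))
      val <- as.numeric(vapply(kv, `[`, "", 2L))
      if (anyNA(idx) || anyNA(val))
        .stopf("malformed sparse entry on line %d of %s", r, path)
      if (is.unsorted(idx, strictly = TRUE))
        .stopf("non-ascending feature indices on line %d of %s", r, path)
      ii <- c(ii, rep.int(r, length(idx))); jj <- c(jj, idx); xx <- c(xx, val)
    }
  }
  d <- c(length(lines), if (is.null(nFeatures)) max(jj, 1L) else nFeatures)
  m <- sparseMatrix(i = ii, j = jj, x = xx, dims = d)
  y <- if (task == "classification") labs else as.numeric(labs)
  sparseFeatureSet(m, y, task, labelDomain = labelDomain)
}
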