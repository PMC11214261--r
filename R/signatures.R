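#' Canonical atom signature
#'
#' The circular Signatures descriptor: a breadth-limited tree expansion of
#' the molecular graph rooted at one atom. At every node the expansion
#' visits all neighbors except the atom the node was reached from, so ring
#' atoms re-appear at deeper levels up to the height bound (a pure tree,
#' no ring-closure markers). The rendering grammar is
#' \code{[El]} atom tokens (formal charge appended as repeated \code{+}/\code{-}),
#' children wrapped in \code{(...)}, each child prefixed by its bond token
#' ("" single, \code{=} double, \code{#} triple, \code{p} aromatic), and
#' children sorted lexicographically (C locale) by their full rendering.
#' The height-0 signature of any atom is its bare atom token; benzene's
#' height-1 carbon signature is \code{"[C](p[C]p[C])"}.
#'
#' @param mol a \code{MolGraph} from \code{\link{parseStructure}}.
#' @param root 1-based atom index.
#' @param height non-negative expansion height.
#' @param withAtoms also return the set of visited atom indices.
#' @return the signature string, or (withAtoms) \code{list(string, atoms)}.
#' @examples
#' atomSignature(parseStructure("c1ccccc1"), 1, 1)  # "[C](p[C]p[C])"
#' @export
atomSignature <- function(mol, root, height, withAtoms = FALSE) {
  nA <- nrow(mol$atoms)
  if (root < 1L || root > nA) .stopf("invalid atom index %s", root)
  if (height < 0L) .stopf("height must be >= 0")
  adj <- .molAdjacency(mol)
  tokens <- .atomTokens(mol)
  visited <- rep(FALSE, nA)
  render <- function(atom, parent, depth) {
    visited[atom] <<- TRUE
    s <- tokens[atom]
    if (depth > 0L) {
      nb <- adj[[atom]]
      keep <- nb$to != parent
      if (any(keep)) {
        kids <- sort(paste0(nb$token[keep],
                            vapply(nb$to[keep], render, "", atom, depth - 1L)),
                     method = "radix")
        s <- paste0(s, "(", paste(kids, collapse = ""), ")")
      }
    }
    s
  }
  s <- render(root, 0L, as.integer(height))
  if (withAtoms) list(string = s, atoms = which(visited)) else s
}

# Adjacency list with bond tokens, cached on the MolGraph via attribute.
.molAdjacency <- function(mol) {
  adj <- attr(mol, ".adjacency")
  if (!is.null(adj)) return(adj)
  nA <- nrow(mol$atoms)
  b <- mol$bonds
  tok <- ifelse(b$aromatic, "p",
                c("", "=", "#")[pmin(pmax(b$order, 1L), 3L)])
  adj <- lapply(seq_len(nA), function(a) {
    sel1 <- which(b$from == a); sel2 <- which(b$to == a)
    list(to = c(b$to[sel1], b$from[sel2]), token = c(tok[sel1], tok[sel2]))
  })
  adj
}

.atomTokens <- function(mol) {
  ch <- mol$atoms$charge
  suffix <- ifelse(ch > 0, strrep("+", pmax(ch, 0)),
                   strrep("-", pmax(-ch, 0)))
  paste0("[", mol$atoms$element, suffix, "]")
}

#' All signatures of one record with their atom occurrences
#'
#' Computes, for every atom and every height in \code{hMin..hMax}, the
#' canonical signature and the set of atoms its expansion visits. This is
#' the backmap used by prediction interpretation: each (atom, height) pair
#' yields exactly one occurrence, rooted at that atom.
#'
#' @param mol a \code{MolGraph}.
#' @param hMin,hMax height range, \code{0 <= hMin <= hMax}.
#' @return named list: signature string -> list of occurrences
#'   \code{list(root =, atoms =)}.
#' @export
mapOccurrences <- function(mol, hMin = 1L, hMax = 3L) {
  stopifnot(hMin >= 0L, hMax >= hMin)
  out <- list()
  for (a in seq_len(nrow(mol$atoms)))
    for (h in hMin:hMax) {
      sig <- atomSignature(mol, a, h, withAtoms = TRUE)
      occ <- list(root = a, atoms = sig$atoms)
      if (is.null(out[[sig$string]])) out[[sig$string]] <- list(occ)
      else out[[sig$string]][[length(out[[sig$string]]) + 1L]] <- occ
    }
  out
}

#' Featurize a dataset with the Signatures descriptor
#'
#' Feature value = number of atoms whose signature at some height in
#' \code{hMin..hMax} equals the feature's string. In training mode
#' (\code{vocabulary = NULL}) the vocabulary is built in first-encounter
#' order (record, then atom, then height); in prediction mode the given
#' vocabulary is frozen and unknown signatures are dropped (counted per
#' record in \code{@dropped}). External descriptors attached to the
#' dataset are appended after the signature features in declared column
#' order.
#'
#' @param dataset a \code{ChemDataset}.
#' @param hMin,hMax signature height range (default 1..3).
#' @param vocabulary optional frozen \code{SignatureVocabulary}.
#' @return a \code{\linkS4class{SignatureFeatures}}.
#' @examples
#' ds <- chemDataset("m1", list(parseStructure("CCO")), 1.2, "regression")
#' sf <- featurize(ds, 0, 0)
#' signatureStrings(sf@vocabulary)  # "[C]" "[O]"
#' @export
featurize <- function(dataset, hMin = 1L, hMax = 3L, vocabulary = NULL) {
  stopifnot(is(dataset, "ChemDataset"))
  n <- length(dataset)
  if (n == 0L) .stopf("featurize: empty dataset")
  hMin <- as.integer(hMin); hMax <- as.integer(hMax)
  stopifnot(hMin >= 0L, hMax >= hMin)
  frozen <- !is.null(vocabulary)
  if (frozen) {
    vocab <- vocabulary@strings
    lookup <- new.env(parent = emptyenv())
    for (k in seq_along(vocab)) assign(vocab[k], k, envir = lookup)
  } else {
    vocab <- character(0)
    lookup <- new.env(parent = emptyenv())
  }
  ii <- jj <- integer(0); xx <- numeric(0)
  atomMap <- vector("list", n)
  dropped <- integer(n)
  for (r in seq_len(n)) {
    occ <- mapOccurrences(dataset@structures[[r]], hMin, hMax)
    sigs <- names(occ)
    idx <- integer(length(sigs))
    for (k in seq_along(sigs)) {
      hit <- get0(sigs[k], envir = lookup, inherits = FALSE)
      if (is.null(hit)) {
        if (frozen) { idx[k] <- NA_integer_; next }
        vocab <- c(vocab, sigs[k])
        hit <- length(vocab)
        assign(sigs[k], hit, envir = lookup)
      }
      idx[k] <- hit
    }
    keep <- !is.na(idx)
    dropped[r] <- sum(vapply(occ[!keep], length, 0L))
    cnt <- vapply(occ[keep], length, 0L)
    ii <- c(ii, rep.int(r, sum(keep))); jj <- c(jj, idx[keep])
    xx <- c(xx, as.numeric(cnt))
    am <- occ[keep]
    names(am) <- as.character(idx[keep])
    atomMap[[r]] <- am
  }
  nSig <- length(vocab)
  extNames <- colnames(dataset@extra)
  nExt <- length(extNames)
  if (nExt) {
    for (cidx in seq_len(nExt)) {
      v <- as.numeric(dataset@extra[[cidx]])
      nz <- which(v != 0)
      ii <- c(ii, nz); jj <- c(jj, rep.int(nSig + cidx, length(nz)))
      xx <- c(xx, v[nz])
    }
  }
  m <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, nSig + nExt))
  voc <- if (frozen) vocabulary
         else new("SignatureVocabulary", strings = vocab, hMin = hMin, hMax = hMax)
  feats <- sparseFeatureSet(m, dataset@labels, dataset@task,
                            labelDomain = labelDomain(dataset))
  new("SignatureFeatures", vocabulary = voc, features = feats,
      atomMap = atomMap, externalNames = as.character(extNames),
      dropped = dropped)
}

#' Persist / load a signature vocabulary
#'
#' Two-column tab-separated text: feature index, signature string.
#'
#' @param vocabulary a \code{SignatureVocabulary}.
#' @param path file path.
#' @export
writeVocabulary <- function(vocabulary, path) {
  stopifnot(is(vocabulary, "SignatureVocabulary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# heights\t%d\t%d", vocabulary@hMin, vocabulary@hMax), con)
  writeLines(sprintf("%d\t%s", seq_along(vocabulary@strings),
                     vocabulary@strings), con)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 3L || hdr[1] != "# heights")
    .stopf("malformed vocabulary file: %s", path)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  idx <- as.integer(vapply(body, `[`, "", 1L))
  strings <- vapply(body, `[`, "", 2L)
  if (!identical(idx, seq_along(strings)))
    .stopf("vocabulary indices must be 1..n in order: %s", path)
  new("SignatureVocabulary", strings = strings,
      hMin = as.integer(hdr[2]), hMax = as.integer(hdr[3]))
}
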