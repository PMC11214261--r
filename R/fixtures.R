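# Deterministic synthetic-data generators. The numeric generators draw
# i.i.d. samples, so any split of their output is exchangeable — the
# assumption under which conformal validity is guaranteed — making them the
# reference inputs for the validity test suites.

#' Synthetic two-class Gaussian data
#'
#' A two-class Gaussian mixture with configurable class means, a shared
#' diagonal covariance and an exact class allocation (the minority count is
#' \code{round(n * imbalance)}). Rows are shuffled so the sample is
#' exchangeable. With unit variance and means \eqn{\pm 1} on one dimension
#' the Bayes error is \eqn{\Phi(-1) \approx 0.159}.
#'
#' @param n sample size.
#' @param means list of two mean vectors (equal length = dimensionality).
#' @param sd shared per-dimension standard deviation.
#' @param imbalance fraction of the second class.
#' @param classes the two labels.
#' @param seed integer seed; the sample is a pure function of the
#'   arguments.
#' @return a classification \code{SparseFeatureSet}.
#' @export
genNumericClassification <- function(n, means = list(c(-1, 0), c(1, 0)),
                                     sd = 1, imbalance = 0.5,
                                     classes = c("neg", "pos"), seed = 1L) {
  stopifnot(n >= 2, length(means) == 2, imbalance > 0, imbalance < 1)
  d <- length(means[[1]])
  n2 <- round(n * imbalance); n1 <- n - n2
  withSeed(seed, {
    x1 <- matrix(stats::rnorm(n1 * d, sd = sd), n1, d, byrow = TRUE) +
      matrix(means[[1]], n1, d, byrow = TRUE)
    x2 <- matrix(stats::rnorm(n2 * d, sd = sd), n2, d, byrow = TRUE) +
      matrix(means[[2]], n2, d, byrow = TRUE)
    perm <- sample.int(n)
    x <- rbind(x1, x2)[perm, , drop = FALSE]
    y <- c(rep(classes[1], n1), rep(classes[2], n2))[perm]
    sparseFeatureSet(x, y, "classification", labelDomain = classes)
  })
}

#' Synthetic linear regression data
#'
#' \eqn{y = w \cdot x + noise \cdot scale(x) \cdot e}, \eqn{e \sim N(0,1)},
#' with \eqn{scale(x) = 1} or, heteroscedastic, \eqn{scale(x) = 1 + |x_1|}
#' so the residual spread grows with the first feature — the setting in
#' which error-model-normalized nonconformity measures pay off.
#'
#' @param n sample size.
#' @param w true weight vector (length = dimensionality).
#' @param noise noise standard deviation at scale 1.
#' @param heteroscedastic use \eqn{scale(x) = 1 + |x_1|}.
#' @param seed integer seed.
#' @return a regression \code{SparseFeatureSet}.
#' @export
genNumericRegression <- function(n, w = c(2, -1), noise = 1,
                                 heteroscedastic = FALSE, seed = 1L) {
  stopifnot(n >= 2, length(w) >= 1)
  d <- length(w)
  withSeed(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    scale <- if (heteroscedastic) 1 + abs(x[, 1]) else rep(1, n)
    y <- as.numeric(x %*% w) + noise * scale * stats::rnorm(n)
    sparseFeatureSet(x, y, "regression")
  })
}

# Fragment inventory for toy molecule assembly. "Middle" fragments keep an
# open attachment point at both their first and last atom, so plain SMILES
# concatenation yields valence-valid molecules; "terminal" fragments close
# the chain. The nitro terminal is the planted substructure of the
# classification rule.
.toyMiddle <- c("C", "CC", "CCC", "CO", "CN", "COC", "CCO", "CCN",
                "C(C)", "C(F)", "C(Cl)", "CC(C)", "CC(=O)", "C(=O)",
                "CS", "CC(F)", "COCC", "CCCC", "C(Br)", "CC(Cl)",
                "c1ccccc1", "Cc1ccccc1", "c1ccccc1C", "Cc1ccccc1C")
.toyTerminal <- c("Cl", "F", "Br", "O", "N", "S", "C#N", "C(=O)O",
                  "C(=O)N", "C=C", "OC", "NC")
.toyNitro <- "[N+](=O)[O-]"

#' Toy molecule sets with a planted structure-activity rule
#'
#' Assembles molecules by concatenating valence-safe SMILES fragments from
#' a fixed inventory (~30 fragments), so every generated structure parses.
#' Rules: \code{"substructure"} - the binary label marks the presence of a
#' planted nitro group (with optional label-flip noise);
#' \code{"aromatic-count"} - the regression label is the aromatic-atom
#' count of the parsed structure plus Gaussian noise.
#'
#' @param n number of molecules.
#' @param rule "substructure" or "aromatic-count".
#' @param noise label-flip probability (classification) or Gaussian label
#'   noise SD (regression).
#' @param seed integer seed.
#' @return a \code{\link{chemDataset}}; classification label domain is
#'   \code{c("inactive", "active")}.
#' @export
genToyMolecules <- function(n, rule = c("substructure", "aromatic-count"),
                            noise = 0, seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(n >= 1)
  smiles <- withSeed(seed, vapply(seq_len(n), function(i) {
    k <- sample(2:4, 1)
    parts <- sample(.toyMiddle, k, replace = TRUE)
    tail <- stats::runif(1)
    end <- if (tail < 0.45) .toyNitro
           else if (tail < 0.75) sample(.toyTerminal, 1)
           else ""
    paste0(paste(parts, collapse = ""), end)
  }, character(1)))
  mols <- lapply(smiles, parseStructure)
  if (rule == "substructure") {
    active <- grepl(.toyNitro, smiles, fixed = TRUE)
    lab <- withSeed(seed + 1L, {
      flip <- stats::runif(n) < noise
      xor(active, flip)
    })
    labels <- factor(ifelse(lab, "active", "inactive"),
                     levels = c("inactive", "active"))
  } else {
    counts <- vapply(mols, function(m) sum(m$atoms$aromatic), 0L)
    labels <- withSeed(seed + 1L, counts + noise * stats::rnorm(n))
  }
  ds <- chemDataset(ids = sprintf("toy%04d", seq_len(n)), structures = mols,
                    labels = labels,
                    task = if (rule == "substructure") "classification"
                           else "regression")
  attr(ds, "smiles") <- smiles
  ds
}

#' Emit a toy dataset as CSV (SMILES + label)
#'
#' @param dataset a dataset from \code{\link{genToyMolecules}} (carries its
#'   SMILES as an attribute).
#' @param path output CSV.
#' @export
writeToyCSV <- function(dataset, path) {
  smiles <- attr(dataset, "smiles")
  if (is.null(smiles)) .stopf("dataset carries no SMILES attribute")
  labs <- dataset@labels
  utils::write.csv(data.frame(id = dataset@ids, smiles = smiles,
                              label = if (is.factor(labs)) as.character(labs)
                                      else labs),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
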