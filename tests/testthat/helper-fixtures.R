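# Shared fixtures, built in code. Heavier objects are created once per
# test run and memoized here.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- build()
  .fixtureCache[[name]]
}

toyClassification <- function() fixture("toyClf", function()
  genNumericClassification(400, seed = 11))

toyRegression <- function() fixture("toyReg", function()
  genNumericRegression(300, c(2, -1), noise = 0.5, seed = 12))

toyMolecules <- function() fixture("toyMols", function()
  genToyMolecules(60, "substructure", seed = 13))

# Linearly separable 2-class data: class decided by sign of x1 with margin.
separableData <- function(n = 20, seed = 3) {
  x <- withSeed(seed = seed, {
    x1 <- c(stats::runif(n / 2, 1, 2), stats::runif(n / 2, -2, -1))
    cbind(x1, stats::rnorm(n))
  })
  sparseFeatureSet(x, ifelse(x[, 1] > 0, "up", "down"), "classification",
                   labelDomain = c("down", "up"))
}

withSeed <- conformalsig:::withSeed

# Random valence-safe toy molecule graphs with atom order permuted:
# relabels atoms/bonds of a MolGraph under a permutation.
permuteMolGraph <- function(mol, perm) {
  inv <- order(perm)  # inv[old] = new position
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$from <- inv[bonds$from]
  bonds$to <- inv[bonds$to]
  structure(list(atoms = atoms, bonds = bonds), class = "MolGraph")
}

# Closed-form weights of a fitted linear SVM/SVR: w = t(SV) %*% coefs.
# e1071 stores support vectors as a SparseM matrix for sparse input.
linearWeights <- function(scorer) {
  sv <- scorer@fit$SV
  if (inherits(sv, "matrix.csr")) sv <- SparseM::as.matrix(sv)
  as.numeric(crossprod(as.matrix(sv), scorer@fit$coefs))
}

# Exhaustive isotonic oracle: optimal monotone least-squares fit found by
# enumerating all partitions of the sequence into consecutive blocks
# (block means must be non-decreasing to be feasible).
exhaustiveIsotonic <- function(y, w) {
  n <- length(y)
  best <- NULL; bestSSE <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- if (n > 1) which(bitwAnd(mask, 2^(0:(n - 2))) > 0) else integer(0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    means <- numeric(length(bounds) - 1)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- sum(w[idx] * y[idx]) / sum(w[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < bestSSE - 1e-12) { bestSSE <- sse; best <- fit }
  }
  best
}

# string -> count mapping of a whole molecule at one height range
signatureCounts <- function(mol, hMin, hMax) {
  occ <- mapOccurrences(mol, hMin, hMax)
  counts <- vapply(occ, length, 0L)
  counts[order(names(counts))]
}
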