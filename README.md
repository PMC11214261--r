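# conformalsig

Confidence-calibrated QSAR modeling in R: mondrian conformal prediction
and Venn-ABERS probabilistic calibration on top of the circular molecular
**Signatures** descriptor, with atom-level interpretation of individual
predictions and conformal-specific evaluation and tuning machinery.

## Who this is for

Cheminformaticians and modelers who need predictions with *error-rate
guarantees* rather than bare point estimates: prediction **sets** for
classification and prediction **intervals** for regression that are valid
at a user-chosen significance level ε under the exchangeability
assumption, plus well-calibrated probabilities for binary endpoints.
Everything also works on plain numeric matrices (sparse SVM-file dialect),
so the conformal machinery is usable without any chemistry.

## The method

A **nonconformity measure** α = h(x, y), built on an underlying scoring
model (SVM with linear or RBF kernel, or logistic regression), scores how
strange an observation is. An inductive conformal predictor splits the
training data into a *proper training* part (fits the scorer) and a
*calibration* part (collects α₁, …, αₙ). A test object's p-value for a
candidate label is its rank among the calibration nonconformities, the
test instance included:

    p = |{ j = 1..n+1 : α_j ≥ α_{n+1} }| / (n + 1)

Calibration is **mondrian** (class-conditional): the test α is ranked only
against calibration examples of the same class, which gives per-class
validity and handles imbalanced data without balancing tricks. The
prediction set at significance ε contains every label with p ≥ ε and may
be empty, single- or multi-label; the error rate is guaranteed ≤ ε.
Variants: smoothed p-values (tie-splitting τ), linearly interpolated
p-values (smooths the staircase of small calibration sets), aggregated
(ACP) and cross (CCP) predictors over several splits, and a transductive
predictor (TCP) that retrains per test label. For regression the interval
is ŷ ± α₍ₖ₎·σ(x) with k = ⌈(1−ε)(n+1)⌉ and σ(x) an optional difficulty
scale from an error model trained on residuals (`normalized`,
`log-normalized` with smoothing factor β = 0.01). **Venn-ABERS**
predictors (IVAP/CVAP) return a calibrated probability pair (p₀, p₁) via
isotonic regression with the test object tentatively labeled 0 and 1.

Molecules are represented by the **Signatures** descriptor: canonical
atom-rooted subgraph strings up to a height bound (benzene's height-1
carbon signature is `[C](p[C]p[C])`); feature values are occurrence
counts, and every feature maps back to the atoms it is rooted at, which is
what makes per-atom interpretation of predictions possible.

## Worked example

```r
library(conformalsig)

ds    <- genToyMolecules(300, "substructure", seed = 42)   # planted nitro rule
sf    <- featurize(ds, 1, 3)                               # Signatures, heights 1..3
model <- fitConformalClassifier(sf@features, scorerConfig("svc", cost = 10),
           classificationNCM(), samplingStrategy("random-stratified", 0.2, seed = 1))

newMols <- genToyMolecules(5, "substructure", seed = 99)
sfNew   <- featurize(newMols, 1, 3, vocabulary = sf@vocabulary)
pv      <- predictPValues(model, sfNew@features@x)
round(pv, 3)
#>      inactive active
#> [1,]    0.419  0.032
#> [2,]    0.613  0.032
#> [3,]    0.032  0.419
#> [4,]    0.032  0.129
#> [5,]    0.032  0.839
predictionSet(pv, 0.2)
#> [[1]] "inactive"   [[2]] "inactive"   [[3]] "active"
#> [[4]] character(0) [[5]] "active"
```

Each row holds one p-value per class; at ε = 0.2 a label enters the
prediction set when its p-value is at least 0.2. Molecules 1–3 and 5 get
confident single-label sets (all matching their true labels here); for
molecule 4 both labels look strange (both p < 0.2), so the set is empty —
the conformal way of saying "no label is supported at this confidence".
`atomGradient(model, sfNew, record = 1)` then attributes the prediction to
atoms and names the most influential ("significant") signature.

The same workflow is available from a shell via the installed CLI wrapper
(`system.file("cli", "conformalsig.R", package = "conformalsig")`) with
subcommands `precompute`, `crossvalidate`, `tune`, `tune-scorer`, `train`,
`validate`, `predict` and `explain`.

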