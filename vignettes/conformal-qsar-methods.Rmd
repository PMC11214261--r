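---
title: "Methods: conformal QSAR modeling with molecular Signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformal QSAR modeling with molecular Signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the methods it implements: the
models and their assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, and the limits of what
the test suite demonstrates.

## The conformal model

All predictors in this package are built from the same three ingredients:

1. an **underlying scorer** — a libsvm SVC/SVR (linear or RBF kernel) or a
   logistic regression — fitted on a *proper training* set;
2. a **nonconformity measure (NCM)** α = h(x, y) derived from scorer
   outputs, with higher α meaning "stranger";
3. a **calibration set**, disjoint from the proper training set, whose
   sorted nonconformities α₁…αₙ turn a test nonconformity into a rank
   p-value: p = |{j = 1..n+1 : αⱼ ≥ αₙ₊₁}| / (n+1), the test instance
   included in the count.

The single substantive assumption is **exchangeability** of calibration
and test data. Under it the p-value of the true label is (super-)uniform,
so the prediction set {y : p_y ≥ ε} errs with probability at most ε.
Classification calibration is always **mondrian** (class-conditional):
each class keeps its own calibration store and the guarantee holds per
class, which is what makes imbalanced endpoints workable without
rebalancing. Non-mondrian pooling is deliberately not offered.

Classification NCMs: `negative-distance-to-hyperplane` (default; −d_y(x)),
`positive-distance-to-hyperplane` (+d_y(x)), `inverse-probability`
(1 − P̂(y|x)) and `probability-margin`
(0.5·(1 − P̂(y|x) + max_{y'≠y} P̂(y'|x))). Conformal validity does not
depend on the NCM being "good" — only efficiency (set sizes) does — and
the validity suite therefore runs over every NCM with both scorer
families.

Regression intervals are ŷ(x) ± α₍ₖ₎·σ(x) with k = ⌈(1−ε)(n+1)⌉; when
k > n the interval is (−∞, ∞), so with n calibration instances the
smallest informative significance level is 1/(n+1) — with five instances,
intervals become finite from ε = 1/6 ≈ 0.17. The difficulty scale σ(x) is
1 (`abs-diff`), ê(x) + β (`normalized`, error model ê trained on absolute
proper-training residuals) or exp(ĝ(x)) + β (`log-normalized`, ĝ trained
on ln(|residual| + β)). β defaults to 0.01; it stabilizes the scaling and
removes any possibility of division by zero.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| signature heights h_min..h_max | 1..3 | subgraph radius of the descriptor (graph bonds) |
| calibration ratio | 0.2 | fraction of training data held out for calibration |
| n splits / folds | 1 | >1 gives ACP (random splits) or CCP (folds) |
| SVM cost C | 1 | error penalty; the RBF tuning grid spans 2⁻⁶…2¹² |
| RBF γ | 1/n_features | kernel width; grid spans 2⁻¹⁴…2⁻⁴ |
| NCM β | 0.01 | smoothing floor of the difficulty scale |
| p-value mode | standard | `smoothed` (τ, default random per object/class) or `linear-interpolated` |
| significance grid | 0.01–0.30 (clf), 0.05–0.30 (reg), step 0.01 | range over which calibration/efficiency are reported |

The default C and γ are deliberately neutral; the sanctioned way to match
a tuned reference is `gridSearch()` with `defaultRBFGrid()` (60
combinations). `tune-scorer` mode cross-validates the bare scorer (macro
F1 / RMSE) and provably never trains a calibration store, which is the
cheap option when the final model aggregates many splits or is a TCP.

## Numerical and design choices

* **Signature grammar.** Atom tokens are `[El]` with formal charge as
  repeated `+`/`-`; child renderings carry a bond token ("" single, `=`
  double, `#` triple, `p` aromatic) and are sorted bytewise (C locale,
  radix sort) so canonicalization is locale-independent. The expansion is
  a pure breadth-limited tree: at each node all neighbors except the atom
  it was reached from are expanded, so rings re-appear at deeper levels
  and there are no ring-closure markers. This is simpler than Faulon's
  canonical scheme; at large heights distinct ring/chain environments can
  in principle collide, which is accepted and documented — heights 1..3
  are the intended operating range. Hydrogens never appear; isotopes and
  stereo flags are ignored. Aromaticity is perceived by OpenBabel and
  encoded on bonds, not by lowercase atom tokens.
* **Frozen vocabulary.** Prediction-time featurization never extends the
  vocabulary; unknown signatures are dropped and counted per molecule as a
  diagnostic.
* **Ties.** P-value counting handles ties exactly by definition (a fully
  degenerate calibration store yields p = 1 for any test α at or below the
  common value, with no special-casing). The interpolated calculator
  places knots at the unique calibration values, is clamped to 1 below the
  smallest and to 1/(n+1) above the largest, and coincides with the
  standard p-value at every knot; the "within one step of standard"
  property holds for distinct calibration values and relaxes to k/(n+1)
  at a knot with k ties.
* **Smoothed τ.** In `random` mode one τ ~ U(0,1) is drawn per (test
  object, class) from an explicit seed and shared across splits, so
  repeated predictions are reproducible.
* **Multi-split aggregation.** ACP/CCP p-values aggregate by arithmetic
  mean (median configurable); regression bounds and midpoints by median
  (mean configurable). Mean-aggregated p-values trade a little worst-case
  validity for stability; the validity suite checks the realized error
  rates directly.
* **SVC probabilities.** libsvm's internal CV-based Platt calibration is
  not reproducible (its RNG cannot be seeded from R), so the package fits
  its own in-sample Platt sigmoid on training decision values (pairwise,
  averaged and renormalized for multiclass). In-sample fitting can be
  overconfident relative to CV-based calibration; for conformal purposes
  only the ordering of α matters, so validity is unaffected.
* **Logistic scorer.** Implemented as glmnet with a small fixed ridge
  (λ = 10⁻⁴ default): signature matrices routinely have more features
  than molecules and an unpenalized fit would be rank-deficient.
* **Error-model floor.** For the `normalized` NCM the error model's
  prediction is clamped at zero before adding β (an SVR trained on
  non-negative targets can still predict slightly negative values).
* **Isotonic regression.** Venn-ABERS needs weighted isotonic fits with
  tied scores pooled, so the package carries a small weighted PAVA,
  oracle-tested against exhaustive monotone least squares. IVAP merges
  (p0, p1) as p1/(1 − p0 + p1); CVAP merges fold pairs by the
  geometric-mean rule and reports fold-wise min/max as (p0, p1).
* **Interpretation.** Contributions are feature-removal finite differences
  s(x) − s(x with x_f = 0) on the decision score of the predicted class
  (regression: midpoint) — model-agnostic and exact (w_f·x_f) for linear
  scorers. Raw scores rather than p-values are attributed, for
  determinism. Each occurrence credits its root atom with
  contribution/occurrence-count; spreading over the whole occurrence atom
  set is available behind a flag. Ties for the significant signature break
  to the lexicographically smallest string.
* **Persistence.** A model archive is one tar file (R's internal tar, no
  external tools) holding a JSON manifest — format version (checked on
  load), task, label domain, NCM and calculator configuration, descriptor
  heights, seeds — plus the fitted components; save/load round trips
  reproduce predictions byte-identically.
* **Atom indices** are 1-based everywhere in the R API and in JSON
  outputs, following R convention.

## What the synthetic generators emulate

`genNumericClassification` (two-class Gaussian mixture, exact class
allocation, shuffled rows) and `genNumericRegression` (linear signal,
optional heteroscedastic noise scale 1 + |x₁|) produce i.i.d. samples, so
any split is exchangeable — they are the reference inputs for the
validity suites, at the package's standard study sizes of 2500 training
(calibration ratio 0.2) and 2000 test records. `genToyMolecules`
assembles valence-safe SMILES from a fixed ~30-fragment inventory with a
planted structure–activity rule (a nitro substructure for classification;
aromatic-atom count for regression), so chemistry tests need no external
files and the "right answer" is known by construction.

What passing these suites shows: the conformal machinery is valid and
efficient *when exchangeability holds*. What it does not show: behavior
under the distribution shift, assay drift, scaffold-split structure and
activity-cliff phenomena of real chemical data — there the guarantee can
degrade, which is precisely why calibration curves and capped RMSE are
first-class outputs of `runValidation`.

Two statistical facts the test suite accounts for explicitly:

* An *observed* error rate at level ε fluctuates with both the test draw
  (binomial, variance ε(1−ε)/m) and the calibration draw (the conditional
  error probability is Beta-distributed, variance ≈ ε(1−ε)/(n_cal+2));
  validity checks use three standard errors of the combined distribution.
* Under 1 + |x₁| Gaussian heteroscedasticity, difficulty scaling narrows
  the *median* interval at equal coverage but not the *mean* — the mean is
  dominated by the (correctly) widened difficult tail, a property
  verifiable in closed form with a perfect error model. Width comparisons
  in the tests therefore use the median.

## Known limitations

No stereochemistry, 3D conformers, tautomer standardization or descriptor
catalogue beyond Signatures (external numeric descriptors can be attached
per record and are appended after the signature block). TCP is
classification-only and retrains per test object and label — quadratic
cost, small datasets only. Venn-ABERS is binary-only and, unlike mondrian
conformal classification, may need balanced data to perform well. Spline
p-value interpolation is not implemented (linear only). SDF reading
targets V2000; V3000 entries are normalized through OpenBabel's
converter.
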