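---
title: "Representation uncertainty for ionic-liquid property screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representation uncertainty for ionic-liquid property screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ionic liquids (ILs) — salts of an organic cation and an anion that are
liquid near ambient temperature — are candidate CO2 absorbents, but the
space of cation–anion combinations is astronomically large. Screening it
with quantitative structure–property relationship (QSPR) models is fast,
yet a regression model asked about a molecule far from its training data
(outside its *applicability domain*) returns a number that looks as
confident as any other. A screening pipeline that cannot tell those numbers
apart will happily rank garbage.

`ilscreen` quantifies that risk with two spread-based uncertainties:

* **Model uncertainty (MU)** — the sample standard deviation of the
  predictions of four models that share one molecular representation and
  differ only in hyperparameters.
* **Representation uncertainty (RU)** — the sample standard deviation of
  the predictions of four models built on four *different* representations
  of the same ion pair.

The premise: hyperparameter variants of one representation tend to agree
even where they are all wrong, because they see the molecule through the
same features. Models built on genuinely different representations agree
where the data supported learning and disagree in extrapolation, so their
spread is a sharper out-of-distribution signal.

## The four representations

Each ion pair (validated `cation.anion` SMILES, net charges +1/−1 by
default) is featurised four ways:

* **C-MF** — a hashed circular substructure *count* fingerprint. Every
  heavy atom contributes one environment per radius 0–2, built from the
  atom invariant (element, degree, formal charge, ring membership) and the
  sorted (bond order, neighbour id) multiset; environments are hashed into
  1024 buckets per ion, cation and anion hashed separately and
  concatenated (2048 features). The binary variant **B-MF**
  (`min(count, 1)`) is kept as a baseline; the count variant carries
  occurrence multiplicity and supersedes it.
* **MD** — 18 physicochemical and constitutional descriptors per ion
  (OpenBabel MW, logP, TPSA, molar refractivity, H-bond donor/acceptor
  counts, fluorine count; atom/bond/ring/element counts, net charge,
  maximum degree), concatenated across the two ions (36 features).
  Undefined descriptors impute to 0.
* **MI** — the pair's 2D depiction, both ions on one 128 × 128 grayscale
  canvas rendered by OpenBabel's depiction engine, expressed as ink
  (0 = blank).
* **MG** — the molecular graph: nodes are heavy atoms (element one-hot,
  degree, formal charge, ring membership), edges are bonds with a
  bond-order one-hot; no edge crosses the cation/anion boundary.

Measurement conditions (temperature for viscosity; temperature and
pressure for CO2 capacity; none for refractive index and log EC50) are
standardized — (T − 298.15)/30, (P − 101.325)/100 — and appended to the
vector representations, or concatenated to the pooled penultimate features
of the image/graph models. Featurizers are pure functions of (pair,
config); a `scheme_tag` stored in every model blocks train/predict
featurizer mismatches.

## The regressors

* Vector representations use gradient-boosted trees (xgboost, histogram
  method, single-threaded and seeded, hence bit-reproducible).
* The image model is a convolutional random-feature ridge regressor: two
  fixed seeded filter banks (12 px patches at stride 6, 6 px patches at
  stride 3), ReLU activations mean-pooled over a 3 × 3 spatial grid, plus
  coarse row/column ink profiles and an 8-fold mean-pooled copy of the raw
  canvas as a skip connection; the readout is closed-form ridge
  regression. Optional 4-fold right-angle rotation augmentation
  (`featurizer_config(image_augment = "rotations")`) quadruples the
  training views at training time only; it is off by default because its
  gain is modest relative to its cost on the synthetic benchmark.
* The graph model is a message-passing random-feature ridge regressor:
  node features are projected to a hidden width, passed through 2–3 tanh
  message-passing rounds over the bond graph, sum- and mean-pooled per ion
  component, and read out by ridge regression.

The random-feature designs were chosen because they retain the inductive
biases of convolutional and message-passing architectures while training
deterministically in seconds on one CPU; only the readout is fitted.

Each representation carries a four-variant hyperparameter grid (trees:
depth × learning rate; image: filter count × ridge penalty; graph: hidden
width × depth × penalty). `train_suite()` scores the four variants on an
internal 80/20 validation split of the training set, refits all four on
the full training set (these are the MU quartet), and promotes the
internally-best variant's full refit to the representation's best model.
Variant grids deliberately keep all members at comparable capacity: an
internal validation split of a few hundred records is noisy, and a grid
mixing strong and degenerate settings can promote a variant that
underperforms when refit on the full data.

## Uncertainty, thresholds, flags

Both MU and RU use the sample standard deviation (divisor n − 1) of the
four member predictions; the population convention is available and, being
a fixed rescaling of every uncertainty, does not change any flag once the
threshold is calibrated under the same convention (scale equivariance is
property-tested).

Reliability thresholds are calibrated on training-set uncertainties:

* **Threshold I** — the maximum: every training prediction is reliable.
* **Threshold II** — the Tukey upper fence Q3 + 1.5 × IQR, with quartiles
  by linear interpolation of order statistics (R type 7): outlying training
  uncertainties are already treated as unreliable. This is the default
  throughout.

A prediction is flagged unreliable iff its uncertainty *strictly* exceeds
the threshold; ties are reliable, so threshold I never flags its own
calibration set. Thresholds remember which uncertainty kind (MU/RU) they
were calibrated on and refuse to be applied across kinds without an
explicit override.

## Ensemble and evaluation

The ensemble prediction is the equal-weight arithmetic mean of the four
best models (weights configurable, default ¼ each); it equals the `mean`
stored in each RU profile. By convexity of the square, per sample
(ensemble error)² ≤ mean member squared error, so ensemble MSE can never
exceed the mean member MSE — the suite asserts this exactly, along with
RMSE ≥ MAE. `evaluate_predictions()` reports RMSE, MAE and R²
(undefined, and reported as `NA`, when the truth has zero variance);
`stratified_rmse()` bins the observed values into half-open ranges (last
bin closed) for range-resolved error. `global_importance()` gives seeded
permutation importance (mean RMSE increase over repeats) for the vector
models, with the sign of the feature–prediction correlation as a
direction heuristic — a reading aid, not a causal claim.

## The out-of-distribution benchmark and the screen

`assemble_benchmark()` mirrors a "non-IL" probe: replicate groups, each
the full cross product of a seeded sub-sample (default 5 groups of
100 × 100 = 10 000 candidates) drawn from pools of arbitrary neutral
molecules, with charge validation deliberately relaxed and reference
conditions (298.15 K, 101.325 kPa) applied uniformly.
`evaluate_discrimination()` counts, per uncertainty method and group, the
candidates flagged unreliable.

`run_sequential_screen()` chains property stages (default order: viscosity
→ toxicity → CO2 capacity, configurable); each stage computes RU and the
ensemble prediction for the surviving candidates, drops RU-unreliable ones,
applies a percentile or absolute cutoff in the stated direction, and passes
the survivors on. Counts are conserved exactly (inputs = unreliable +
failed + survivors), loosening a cutoff can only grow the survivor set, and
with absolute cutoffs the final set is order-independent — all three are
tested.

## The synthetic generator

Real IL property sets (viscosity and CO2 uptake compilations, refractive
index, log EC50) are not redistributable here, so every experiment runs on
a synthetic family with known ground truth:

* *In-domain*: tetraalkylammonium cations (four arms from a 9-arm
  alkyl/hydroxyethyl/fluoroalkyl alphabet; net charge +1 by construction)
  paired with simple organic anions (carboxylates, sulfonates, carbonates,
  halides, dicyanamide; net charge −1).
* *OOD*: substituted fused aromatics and related neutral scaffolds
  (naphthalene, quinoline, anthracene, biphenyl, styrene, dibenzofuran ×
  18 substituents). The in-domain grammar produces no aromatic atoms, so
  the two families share no canonical SMILES — a structural, not
  statistical, domain shift, like pairing arbitrary screening-library
  molecules as pseudo-ions.

Ground truth is linear in SMARTS substructure counts plus linear condition
terms plus Gaussian noise (default sd 0.1 on the linear scale); CO2-style
targets pass through a logistic squash to stay in [0, 1]. Condition ranges
are T ∈ [283, 343] K and P ∈ [50, 500] kPa — plausible laboratory ranges,
chosen once and documented. Default coefficients point in chemically
expected directions (chain length raises viscosity and toxicity; oxygen
and fluorine content raise CO2 uptake). The generator is a test harness
with retrievable noiseless truth, not a chemistry model: it reproduces the
*mechanism* the package exploits (representations agreeing in-domain and
diverging on a disjoint alphabet), not the quantitative distributions of
real IL data. Tests passing on it demonstrate the machinery, thresholds and
invariants — they do not certify accuracy on laboratory measurements.

## Problem sizes and numerical choices

The bundled experiments use 500 in-domain records (80/20 split: 400 train,
100 test), 200 OOD candidates (a 20 × 10 cross product), suites of 4
representations × 4 variants, and three fixed seeds — sizes at which the
full pipeline trains in a few minutes per seed on one CPU while leaving
all effects far from sampling noise. Ridge systems are solved in closed
form on centred, scaled designs (constant columns kept with zero weight);
tree fits are exactly reproducible via single-threaded histogram mode with
a recorded seed; variant selection breaks ties toward the first-listed
variant; permutation importance skips constant (never-set) fingerprint
columns, whose importance is identically zero.

## Known limitations

* On the synthetic benchmark the graph model is close to exact — its
  sum-pooled element one-hots span linear count functions, which is what
  the generator's ground truth is — so its test RMSE sits at the noise
  floor and the equal-weight ensemble, which averages in weaker members,
  beats the *mean* member on every seed but does not generally come within
  10% of this best member. With real, nonlinear property surfaces no
  single representation is exact and the members are more nearly
  interchangeable.
* The depiction engine auto-scales molecules to the canvas, which erases
  much of the molecular-size signal; the image model is therefore the
  weakest member on count-driven synthetic targets (test R² ≈ 0.6–0.85
  against ≥ 0.9 for the others), and on some sampled libraries markedly
  so.
* RU needs four trained model families; it costs roughly four times an MU
  workflow, which is the price of the sharper out-of-distribution signal.
* Charge validation accepts only 1:1 ion pairs by default; multivalent
  salts require the permissive mode and are untested territory for the
  shipped featurizers.
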