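---
title: "Fatty-acid chemometrics for salmon origin: models, calibration and design notes"
author: "fameclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fatty-acid chemometrics for salmon origin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the statistical
model behind each stage, the parameters that matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the design choices made where the design was
genuinely open.

## 1. The measurement and the data model

GC-FID analysis of fatty acid methyl esters (FAMEs) reports, per
chromatogram, each identified acid's peak area as a percentage of the
summed identified peaks.  The result is *compositional*: 17 non-negative
numbers summing to 100.  Two of the 17 features are co-eluting peak pairs
quantified as one ("22:1n11+22:1n9", "20:3n3+20:4n6").

A study fish ("sample") contributes up to six replicate chromatograms —
three independent lipid extractions, each injected twice.  Replicates of
one fish are far more alike than two fish of the same group, so the fish
*block* is the exchangeable unit.  `FameExperiment` (a
`SummarizedExperiment`) therefore stores the per-instance block id, class
label and replicate index, and every resampling operation in the package
(holdout split, cross-validation fold) moves whole blocks.  Validity
enforces label consistency within blocks, replicate indices in 1..6, and
— for canonical 17-feature data — values in [0, 100] with sum-closure to
100 within a tolerance (default 0.5 percentage points; published
composition tables themselves miss 100 by up to ~0.5 through rounding,
and a hard equality would reject them).

The four classes follow a fixed code order (0 Norway farmed, 1 Chile
farmed, 2 Canada farmed, 3 Canada wild) so confusion matrices and
scatter plots are comparable across analyses.

## 2. The synthetic-data generator

No raw chromatograms are publicly deposited for this kind of study; the
generator exists so that every downstream stage is testable against data
with the *published group statistics*.  Its parameter table
(`defaultParameters()`) is the published per-group mean ± SD of each
acid, with group sizes 25/24/25/26 and 6 replicates per fish; four
chromatograms are dropped at random, leaving the 596 usable instances of
the emulated design.

The specimen-level model for fish $i$ in group $g$ is, per feature $f$:

$$x_{if} = \mu_{gf} + \sigma_{gf}\left(\sqrt{\rho}\, t_i +
\sqrt{1-\rho}\,\epsilon_{if}\right),
\qquad t_i, \epsilon_{if} \sim N(0,1),$$

where $t_i$ is a single latent "feed composition / fat content" factor
shared by all features of one fish.  The loading $\sqrt\rho$ keeps every
marginal mean and SD exactly at the table values (the moment-recovery
tests exploit this) while inducing an inter-feature correlation of
$\rho$.  Replicate chromatograms multiply the specimen vector with
independent relative noise of SD `replicateCv`, negatives are truncated
at 0, and each profile is renormalized to sum exactly 100.

### Why the latent factor is strong ($\rho = 0.9$ by default)

The published study separates all four groups essentially perfectly with
a distance-weighted 3-NN on raw features.  That is only geometrically
possible if within-group specimen variation is close to low-rank: the
published SDs are large (e.g. 4.42 percentage points for oleic acid in
Canada-farmed fish), and if that variation were *independent* per acid,
the Chile-farmed and Canada-farmed clouds would irreducibly interpenetrate
— no classifier, let alone kNN, could reach 99% accuracy (we measured
specimen-level kNN error of 4–6% under independence; even the Bayes
error is far above 1%).  Real compositional lipid data behaves
differently: within a farm, fish vary mostly along one axis (overall fat
deposition driven by feed ration and fish size), which moves many acids
together.  The one-factor model with $\rho = 0.9$ encodes exactly that:
marginals match the table, but the conditional spread around the latent
axis is small, so groups are separable in 17-D while still overlapping
in any 2-D linear projection — the published picture.  The factor is
applied to the Chile-farmed and Canada-farmed groups (the pair the study
reports as overlapping); the other two groups are either internally
tight (Norway) or far from everything (wild), so their treatment is not
load-bearing, and `correlatedGroups` can change it.

`replicateCv = 0.02` is a free knob: studies of this kind never report
within-fish replicate variance.  2% relative noise is small enough not
to distort the table moments and large enough that replicates are not
identical.

### What the generator does not emulate

Gaussian marginals have no skew or outliers; real peak-area data do.
Consequences we have measured and accept: the gain-ratio *scores* and
the fine order of similarly-informative features differ from the
published ranking (20:2n6, with tiny SDs and a well-offset Chile mean,
ranks top-3 here but 7th in the study); and the prefix-accuracy curve of
the feature search crosses the 99% threshold earlier and more noisily
than the study's reported six features (see the search section below).  Passing tests on this
generator demonstrate correctness of the machinery and reproduction of
the headline separability structure — not that the generator is a
substitute for real chromatograms.  Chromatographic drift, retention
times, co-elution changes and diet covariates are out of scope.

## 3. Feature ranking: gain ratio over MDL discretization

Continuous features are discretized by Fayyad–Irani recursive entropy
partitioning: the candidate boundary minimizing class-conditional
entropy is accepted iff its information gain exceeds
$(\log_2(N-1) + \Delta)/N$, with
$\Delta = \log_2(3^k-2) - (kE - k_1E_1 - k_2E_2)$, then both halves are
processed recursively.  This discretizer is the standard companion of
entropy-based ranking criteria, is deterministic, and needs no
hyperparameters.  A feature yielding no accepted cut is uninformative
and scores 0 (the SplitInfo = 0 rule — 0, not NaN, so rankings remain
total).  All logarithms are base 2; the ratio itself is base-invariant
but reported intermediates are in bits.  Ties in the ranking are broken
by canonical feature order, making `rankFeatures()` invariant to
instance order.

Exact reproduction of published gain-ratio values is not attempted: they
depend on the raw data's distribution shape, which group means and SDs
do not determine.

## 4. Minimal-feature search

`minimalFeatureSearch()` bisects over the length of the ranked-feature
prefix.  Two corrections to the published pseudocode are deliberate and
documented in the function help:

* the success predicate is *accuracy ≥ threshold* — the printed strict
  `>`/`<` pair leaves accuracy exactly at the threshold driving neither
  branch;
* on termination the reported count is $R + 1$, the smallest prefix
  whose accuracy met the threshold among those evaluated.  A literal
  trace of the printed loop on the worked example
  (accuracies 0.50, 0.70, 0.80, 0.95, 0.992, …, threshold 0.99) stops at
  the midpoint $m = 3$ and would report four features, whose accuracy
  (0.95) fails the threshold; returning $R+1$ yields the correct five.

Bisection assumes the prefix-accuracy curve is non-decreasing.  The
returned prefix is always re-verified against the memoized accuracies
(warning on failure), and `linearSweep = TRUE` switches to the
exhaustive scan, which is also exported separately
(`linearScanMinimal()`) and serves as the ground-truth oracle in the
tests.  The evaluator is memoized — at most one evaluation per prefix
length, $O(\log n)$ calls plus the initial full-set call — and seeded
once per search so repeated evaluations are coherent.  Whether
"accuracy" means holdout or cross-validated accuracy is not fixed by the
published description; the evaluator is injected, and the default
(`prefixEvaluator()`) uses leave-one-sample-out cross-validation, the
scheme the study used for validation-driven choices.

## 5. Embeddings

**Standardization.**  The 17 features share a unit (%) but span two
orders of magnitude, so an unscaled covariance PCA is dominated by the
few most abundant acids.  With centering only, PC1+PC2 of the default
synthetic data capture ≈ 98% of variance; with unit-variance scaling,
87.5–89% across seeds — matching the published 87.8% almost exactly.
We read that as strong evidence the original analysis normalized
features, and make `standardize = TRUE` the default for both PCA and the
t-SNE stage (a flag restores centering-only behavior).  Component signs
are canonicalized (largest-magnitude loading positive) so scores are
platform-stable.

**t-SNE.**  Hyperparameters are not published; the package uses
perplexity 30, 1000 iterations, exact (non-Barnes–Hut) gradients and PCA
initialization scaled to SD $10^{-4}$.  With deterministic
initialization the embedding is reproducible from the seed alone.  When
the instance count cannot support the perplexity it is shrunk with a
warning.

**The transductive stage.**  `tsneFeatureStage()` embeds *all*
instances jointly and hands the 2-D coordinates to the classifiers;
train/test splitting happens afterwards.  This mirrors the published
pipeline — t-SNE has no natural out-of-sample extension — but it is
information leakage in the strict inductive sense: test instances shape
the embedding of training instances.  Downstream accuracies on the
t-SNE regime must be read as transductive.  Labels, blocks and instance
order pass through the stage untouched (asserted by tests).

## 6. The classifier bench

The seven families carry the published hyperparameters as defaults.
Backend mapping, where an R implementation choice had to be made:

* **kNN** — implemented in-package: 3 neighbors, Euclidean,
  inverse-distance vote weights; an exact distance-0 match decides
  alone.  No installed package provides distance-weighted kNN.
* **Decision tree** — `rpart` with `minsplit = 2`, `minbucket = 3`,
  `cp = 0`; `rpart` caps depth at 30 versus the nominal limit of 100 —
  immaterial, trees on 596 instances stay far shallower.
* **SVM** — `e1071::svm`, C = 15, RBF, $\gamma = 1/n_\text{features}$
  ("auto"), no internal rescaling.
* **Random forest** — `randomForest`, 15 trees; the "do not split
  subsets smaller than 5" rule has no direct equivalent and is mapped to
  `nodesize = 3`.
* **ANN** — implemented in-package: one hidden layer of 300 ReLU units,
  softmax output, full-batch Adam (lr 0.01, 400 epochs), cross-entropy
  with L2 penalty $\alpha/(2n)\lVert W\rVert^2$, $\alpha = 0.02$;
  inputs are standardized internally for optimization stability.  The
  published configuration (ReLU + Adam) has no counterpart in the
  installed R stack, so the trainer is written here.
* **Naive Bayes** — `e1071::naiveBayes`, Gaussian class-conditionals.
* **AdaBoost** — implemented in-package: SAMME.R over 80 depth-1
  `rpart` stumps, learning rate 0.7, probability estimates clipped at
  $10^{-10}$; the base learner is unstated in the source material and
  depth-1 stumps are the conventional default.

**Validation.**  "20:80" is read as 20% test / 80% train, assigned at
the block level and stratified by class (5 test blocks per class under
the default design); the published leave-one-sample-out scheme shows
block awareness was intended, and stratification preserves the
near-balanced design in a 20-block test set.  Block disjointness is
asserted on every split and fold.  The multi-class F1 is
class-frequency-weighted (the groups are near-balanced, so weighted and
macro averaging differ negligibly; both are available).  Wall-clock
prediction time is logged in reports and excluded from the
byte-deterministic pipeline artifacts; it is hardware-dependent and
never asserted.

## 7. Composition statistics

The analysis unit is the fish: replicates are averaged per sample before
any test, matching the published table's per-group n and avoiding
pseudo-replication.  Derived sums are never generated or stored — they
are recomputed from the 17 base features per sample (ΣSFA =
14:0 + 16:0 + 18:0; ΣMUFA = the six monounsaturated peaks; ΣPUFA = the
remainder; together they partition the closed composition exactly).  The
n3/n6 ratio is computed per sample and then summarized (mean of ratios,
consistent with reporting an SD for the ratio).  The co-eluting
20:3n3 + 20:4n6 peak mixes an n3 and an n6 acid; the default excludes it
from both sums, `apportionCoeluting = "half"` splits it 50/50 — neither
convention exactly recovers the published wild-group ratio, so neither
is asserted numerically.

Tukey HSD pairwise p-values feed an insert-and-absorb compact-letter
display (letters assigned from the lowest group mean upward); groups
share a letter iff their comparison is non-significant at α = 0.05,
a property the tests check directly.  Exact ties (zero within-group
variance) make the F statistic degenerate; they are reported as fully
significant with a warning rather than silently producing NaNs.

## 8. Pipeline, seeds and problem sizes

`runPipeline()` derives one seed per stage from the master seed
(affine map mod $2^{31}-1$), so changing one stage's options never
perturbs another stage's randomness, and every report is reproducible
from the configuration alone.  No global RNG state is relied upon
anywhere; every stochastic function takes an explicit seed.

Problem sizes used throughout the test suite are the emulated design
itself (596 chromatograms, 100 blocks) for pipeline-level checks;
10,000 specimens per group for generator moment recovery; 1,000 random
monotone curves for the search-oracle equivalence; and 200–600-instance
constructions for property tests.

## 9. Known limitations

* The generator reproduces first and second marginal moments and a
  plausible low-rank correlation structure — not distribution shape.
  Quantities that depend on shape (exact gain-ratio scores, the exact
  crossing point of the prefix-accuracy curve, hence the exact minimal
  feature count) vary across seeds and differ from the published values;
  the tests assert them as specified and report the measured values when
  they fail.
* The t-SNE classifier regime is transductive by design (above); do not
  quote its accuracies as out-of-sample performance.
* `anovaTukey()` assumes homoscedastic Gaussians at the sample level; no
  Welch or non-parametric fallback is provided.
* The bench fixes the published hyperparameters; there is deliberately
  no tuning machinery.
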