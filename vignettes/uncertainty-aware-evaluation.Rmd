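---
title: "Uncertainty-aware evaluation of One-vs-All classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware evaluation of One-vs-All classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovaUQ)
```

## Scope and model

`ovaUQ` evaluates how well a multi-class classifier expresses its own
uncertainty. The multi-class problem with labels in `{0, ..., C-1}` is
decomposed One-vs-All: `C` independent binary tasks, each trained to
separate one class from the rest, each with its own predictor. This mirrors
the common practice for image classifiers built on extracted feature
vectors (for example DenseNet features of chest X-rays), where per-class
binary heads with logistic outputs are trained independently.

Every evaluated predictor satisfies one contract: given a feature matrix it
yields a `T x n` matrix of positive-class probabilities, one row per
stochastic forward pass (`ProbabilitySample`). Everything downstream — the
predictive mean, the predictive entropy, the certainty partition, both
confusion matrices, calibration — consumes only that contract, so any
stochastic classifier can be plugged in through
`probabilitySample()` / `readProbabilityTable()` without using the bundled
networks at all.

### Reference predictors

The bundled stochastic predictors realise four standard uncertainty
quantification schemes on a shared backbone: a fully connected rectifier
network with hidden widths 128/64/32, dropout rate 0.5 after each hidden
layer and a single logistic output. With the default 150 inputs the
parameter total is 29,697 (layer-wise 19,328 / 8,256 / 2,080 / 33), and a
five-member ensemble carries 148,485. Training is minibatch Adam
(learning rate 0.001, batch size 64, 15 epochs) on binary cross-entropy,
implemented directly in base-R matrix code — the problem sizes here
(thousands of instances, a few hundred input dimensions) make anything
heavier unnecessary.

- **MC dropout** keeps dropout masks active at inference; each pass is one
  mask realisation (inverted dropout, so the deterministic pass needs no
  rescaling).
- **Deep ensemble**: `M` members differing only in initialisation seed and
  shuffle seed (no bagging); one deterministic pass each.
- **Ensemble MC dropout** pools `T/M` dropout passes from each member into
  a single sample.
- **Ensemble Bayesian network**: members carry an independent Gaussian
  posterior per weight (mean plus softplus-parameterised spread), trained
  variationally — one reparameterised weight draw per minibatch, a
  standard-normal prior, and the KL term reweighted by 1/(number of
  minibatches). Sampling draws a full weight realisation per pass. We use
  plain per-pass weight sampling rather than a variance-reduction scheme
  such as Flipout: the evaluation layer only consumes the sampled
  probabilities, and full sampling keeps the predictor transparent and
  dependency-free. Posterior spreads start at softplus(-5) (about 0.007) so
  early training is near-deterministic; `paramCount()` reports the weight
  means, the conventional "trainable parameters" figure, with the equal
  number of spread parameters noted in the class documentation.

## The evaluation layer

For per-pass probabilities `p_t(i)` the predictive mean is their arithmetic
average `mu(i)`, the hard label is positive iff `mu >= 0.5` (ties positive
— the boundary case must land somewhere and the positive class is the
clinically salient one), and the predictive entropy is the Shannon entropy
of the two-point distribution `(mu, 1 - mu)` in nats with `0 log 0 = 0`.
Entropy is thresholded on its normalised form, entropy divided by `log C`
(`log 2` per binary task): the conventional 0.30 threshold then means "30%
of maximal entropy" regardless of class count or logarithm base. Boundary
instances (normalised entropy exactly equal to the threshold) count as
certain — strict inequality defines "uncertain".

Crossing correctness with certainty yields the uncertainty confusion
matrix (TC, TU, FC, FU) and its metrics UAcc, USen, USpe, UPre; UF1 is
defined as the harmonic mean of UPre and USen, the exact analogue of the
traditional F1. Two limits pin the semantics down and are tested exactly:
threshold 1 makes every instance certain and UAcc collapses to plain
accuracy; a threshold below the smallest normalised entropy makes every
instance uncertain and UAcc collapses to 1 - accuracy.

Any metric ratio with a zero denominator returns 0 and raises a
`degenerate` flag in the report instead of erroring, so parameter sweeps
never abort on an edge case; the flag makes silent 0/0 conventions visible.

**Calibration.** Confidence is `max(mu, 1 - mu)`. The expected calibration
error uses `M = 10` equal-width bins on `[0, 1]` — the ubiquitous default —
with the first bin closed on the left and the rest left-open; empty bins
contribute zero. The Brier score is the mean squared gap between `mu` and
the outcome. AUC-ROC uses the rank (Mann–Whitney) formulation with ties
counted 1/2, and errors explicitly when only one class is present. The
uncertainty-aware AUC is the AUC of the stochastic predictive mean against
the true labels: it is the quantity that a delta against the baseline AUC
makes comparable, which is how the package (and its delta tables) use it.

**Percentage uncertainty.** For a metric reported in percent, the delta
between the uncertainty-free baseline and the uncertainty-aware value is
the *absolute* difference in percentage points, reported at one decimal;
internal values keep full precision. The absolute value matters: an
uncertainty-aware metric can exceed its baseline (the shipped
published-values fixture contains such a cell), and a signed difference
would make the tables incomparable. The shipped fixtures
(`inst/extdata/published_ova_metrics.csv`, `published_ova_deltas.csv`)
carry the printed values of the published chest X-ray study this layout
follows; one printed delta cell is internally inconsistent with its two
printed operands and is flagged `consistent = FALSE`, and the tests assert
agreement on the consistent cells only.

## The synthetic generator

`makeFeatures()` draws class-conditional spherical Gaussians: class `k`'s
mean sits at `separation / sqrt(2)` along coordinate axis `k`, so all
pairwise mean distances equal `separation`, and `separation / sigma` is an
analytic dial for aleatoric overlap — 0 removes all signal (AUC 0.5 by
construction), 10 gives near-perfect separability. Defaults are 732/619/526
instances over three classes and 150 features, the shape of a moderately
imbalanced extracted-feature table, with `separation = 3` chosen so that a
trained reference network lands in the realistic low-90s accuracy band
rather than saturating. `makeCalibrated()` draws `mu` uniform on `[0, 1]`
and `y ~ Bernoulli(mu)`, a fixture that is perfectly calibrated by
construction and pins the ECE implementation down at large `n`.

What the generator does **not** emulate: the covariance structure, heavy
tails and manifold geometry of real pretrained-network features, label
noise, or distribution shift between splits. Passing tests therefore
demonstrate the correctness of the evaluation machinery and the qualitative
behaviour of the samplers, not clinical-grade performance numbers; the
published headline values depend on real images and pretrained features and
are out of reach of a synthetic rig by design.

## Pipeline choices

- **Oversampling before splitting.** Minority classes are topped up to the
  majority count by duplicating their own rows (never synthesising new
  ones), before the train/test split. This matches dataset-level balancing
  as usually described, but it lets duplicates of one row straddle the
  split — a mild optimistic leakage. We keep it for fidelity and flag it
  here; balance after splitting if unbiased test estimates matter.
- **Stratified 80/20 split**, seeded, with at least one instance of each
  stratum on each side. The source study does not state its split; 80/20 is
  the field default.
- **Per-task independence**: each OvA task trains its own predictor(s);
  nothing is shared across tasks, matching the C-classifiers description.
- **Seeding**: every function that touches randomness takes an explicit
  seed; `runTask` derives split/init/train/sample sub-seeds from its master
  seed, and ensemble members get consecutive derived seeds (which also
  makes a single-member ensemble MC sample reduce bit-exactly to plain MC
  dropout). A `runManifest` therefore replays to byte-identical tables.

## Numerical notes

- Probabilities are clipped to `[1e-12, 1 - 1e-12]` inside the
  cross-entropy only; reported probabilities are unclipped.
- Weight initialisation is variance-scaled Gaussian (2/fan-in for rectifier
  layers, 1/fan-in for the output unit), seed-controlled.
- `predictiveEntropy()` validates distributions to a sum-to-one tolerance
  of 1e-8; the brute-force oracle comparisons in the tests run at 1e-12.
- Divergent training (non-finite or grossly increasing loss) warns and
  returns the predictor rather than erroring.
- A posterior spread of exactly zero is representable
  (`scalePosterior(net, 0)`) and collapses the Bayesian sampler to its
  deterministic mean pass.

## Problem sizes used in the test suite

Unit and property tests run on datasets of tens-to-hundreds of instances
with 4–20 features and small networks; the calibration-recovery check uses
50,000 calibrated points; the end-to-end check runs the full study shape —
three classes oversampled to 732 each, 150 features, all four techniques,
`T = 50`, `M = 5`, threshold 0.30 — which completes in about 90 seconds on
one CPU. These sizes were chosen as the smallest that exercise every code
path at the study's actual shape.

## Known limitations

- The aleatoric/epistemic decomposition is not separated out: predictive
  entropy mixes both sources, and no variance-based or mutual-information
  split is provided.
- Joint multi-class calibration (softmax heads) is out of scope; every
  guarantee is per OvA task.
- The uncertainty metrics at threshold 0.30 are sensitive to how saturated
  a sampler's predictive means are; dropout-based samplers on synthetic
  Gaussians keep means well inside (0, 1), which depresses UAcc relative to
  what heavily saturated real-feature models report. The threshold is a
  parameter precisely because this trade-off is data-dependent.
- Reliability diagrams are emitted as per-bin tables, not plots.
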