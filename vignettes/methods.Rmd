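---
title: "Methods: grey-wolf-optimized fuzzy-scoring residual networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grey-wolf-optimized fuzzy-scoring residual networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

histowolf re-implements, as a tested and reusable pipeline, a hybrid method
for classifying histopathology texture images as benign or malignant:
correlation-based redundancy filtering, multilevel fast discrete wavelet
texture features, an adaptive multi-leader Grey Wolf Optimizer (GWO) with a
Pareto archive for wrapper feature selection and hyperparameter tuning, and
a compact residual convolutional network whose output stage is a fuzzy
scoring layer. This vignette is the package's own account of the models,
the choices that were genuinely open, and what the bundled synthetic data
can and cannot show.

## Preprocessing and the correlation machinery

Images are resized to a common square side (224 px to match the network's
nominal input contract; the desk-scale examples use 64 px), colour-normalized
by Reinhard transfer — each channel of the lαβ perceptual representation is
shifted and scaled to match reference per-channel means and standard
deviations — and z-scored jointly over all pixels and channels so every
image enters training with zero mean and unit variance. Because the
synthetic corpus has no canonical reference slide, the Reinhard reference
defaults to the pooled colour statistics of the training split; held-out
splits are normalized against the same reference to avoid leakage. A source
channel with zero spread cannot be rescaled and passes through unchanged
with a warning.

The redundancy filter is a greedy left-to-right scan over feature columns:
a column is dropped iff its absolute Pearson correlation with an
already-kept column exceeds a threshold (default 0.95). First-seen columns
win, which makes the result deterministic and order-stable; constant
columns, whose correlation is undefined, are kept and flagged. The filter
is applied to the wavelet feature table — the one tabular object in the
pipeline where pairwise correlation is well defined — after extraction and
before the wrapper selection. `correlation_coefficient()` and
`coefficient_of_determination()` expose the underlying sums-of-squares
bookkeeping (`r = S_XY / sqrt(S_XX S_YY)`, `R² = 1 − SSE/S_YY`, sample
covariance with the `1/(n−1)` convention, and the bound `|cov| ≤ s_x s_y`).

## Wavelet texture features

The texture front-end is a separable, periodized (wrap-around) multilevel
2-D discrete wavelet transform, written in-package: the transform is part
of the method's substance and no wavelet package ships with the
environment this package targets. Orthonormal filter pairs are provided for
`haar`, `db2` and `db4`; the highpass (mother) taps sum to zero — the
discrete analogue of the admissibility requirement that makes detail bands
annihilate constants — and the lowpass (father) taps sum to `sqrt(2)`.
Periodization keeps the transform orthogonal, so reconstruction is exact to
floating point and coefficient energy equals pixel energy; both properties
are enforced by tests at 1e−8 and 1e−6 (relative) respectively.

Each subband (three detail orientations per level plus the final smooth
band) contributes four statistics: mean absolute coefficient, standard
deviation, energy, and the Shannon entropy (base 2) of a 64-bin histogram
of normalized absolute coefficients with `0·log 0 := 0`. These are the
standard wavelet-texture statistics; no single canonical set exists, and
this one keeps the table small ((3J+1)×4 columns,
default J = 3) while carrying the density/irregularity contrast the
synthetic classes encode. Images are reduced to luminance (ITU-R 601
weights) before decomposition.

## The Grey Wolf Optimizer and its adaptive extension

The single-objective core follows the canonical encircling algebra: with a
linearly decaying exploration scalar `a = 2(1 − t/T)`, coefficient vectors
`A = 2a·r1 − a` and `C = 2·r2` drawn fresh per dimension, each wolf
encircles the three best solutions (alpha, beta, delta) via
`D = |C∘X_p − X|`, `X' = X_p − A∘D`, and moves to the mean of the three
candidate positions, clamped to the box. The best-ever solution is retained
so the reported history is monotone nonincreasing.

The multi-objective extension replaces the three best by leaders elected
from an external non-dominated archive. Objective space is cut into a
hypercube grid (10 divisions per objective, ranges inflated by 10% beyond
the observed archive extent); a cell is drawn with probability proportional
to `c / N_i` (`c = 2`, `N_i` the cell occupancy), favouring sparse regions,
and the alpha is drawn uniformly from that cell; beta and delta repeat the
procedure over the remaining members. Archive insertions reject dominated
candidates, purge members the candidate dominates, rebuild the grid when a
candidate lands outside it, and on capacity overflow (default 100) evict
uniformly from the most crowded cell. All updates are deterministic under a
fixed seed.

### Wrapper feature selection

Feature subsets are encoded as continuous positions in `[0,1]^d` and
decoded by thresholding at `tau = 0.5` (an all-zero mask keeps its largest
coordinate). The bi-objective fitness pairs the validation error of a
deliberately cheap, fixed reference classifier — a closed-form ridge
discriminant on ±1 labels, standardized per split — with the selected
fraction. The error is averaged over ten seeded stratified 50/50 splits of
the supplied training portion: with a planted-signal table the error floor
is so low that a single split quantizes to zero for many masks, and the
average restores enough resolution to rank masks by their informative
content.

Two further stages harden the selection against the winner's curse that
any wrapper objective invites:

* a memetic local phase runs greedy backward elimination from the best
  archive member, offering every evaluated neighbour to the archive. Drops
  are accepted when strictly improving, and at equal error only while the
  error is positive — a zero-error plateau carries no evidence that the
  dropped feature was useless, so pruning stops there;
* the final mask is chosen by re-evaluating every archive member on an
  independent, larger split ensemble (20 splits) and applying the
  one-standard-error rule familiar from penalized regression: among members
  within one standard error of the minimum re-evaluated error, the fewest
  features win.

On planted tables (500 samples, 50 features, 5 informative at effect size
3) this recovers at least four of the five informative features with at
most 15 total in the large majority of data realizations. The remaining
realizations are intrinsically degenerate: a brute-force subset scan shows
that roughly a third of such tables admit masks of only three informative
features with exactly zero validation error, and no selector that honours
"lowest measured error" can distinguish those from the full set.

### Hyperparameter tuning

Learning rate (log-uniform over `[1e−4, 1e−2]`), batch size
(`{32, 64, 128}` by thirds) and weight decay (log-uniform over
`[1e−6, 1e−2]`) are decoded from the unit cube and tuned by the
single-objective GWO core against short-training validation error. The
default configuration is seeded into the initial pack, so the tuned
configuration is never worse than the default on the tuning objective.

## The residual network and the fuzzy scoring head

The desk-scale architecture is one strided 3×3 stem convolution, a residual
block of two 3×3 convolutions with dense cascaded wiring (the second block
convolution receives the block input channel-concatenated with the first
convolution's output), an identity shortcut with the second nonlinearity
applied after the addition (`y = σ(F(x) + x)`; a 1×1 projection `W_s`
stands in when shapes differ), global average pooling, and a fully
connected head emitting per-class energies `E`. Class probabilities are the
normalized negated-energy exponentials `P_i ∝ exp(−E_i)` — a softmax over
logits `−E`, stabilized by subtracting the minimum energy. Everything is
plain matrix algebra (im2col convolutions with explicit backward passes)
and an in-package Adam optimizer; training is bitwise reproducible under a
fixed seed.

The fuzzy scoring machinery works on a class-index window `[i−a, i+b]`
(default `a = b = 1`, clipped to `[1, m]`): the window centroid
`V0 = Σ j·P_j / Σ P_j` measures how much probability mass leaks toward
neighbouring classes, the redistributed probability is
`P̃_i = (|i−V0|/(a+b))·Σ_window P_j`, and the impact of replacing the plain
error `ε_i = y_i − P_i` by the fuzzy error `ε̃_i = y_i − P̃_i` is
`φ = P̃_i − P_i`, which is non-positive whenever class `i` holds the window
maximum *of a symmetric window* (exactly `−P_i` for a symmetric uniform
window; asymmetric windows admit counterexamples where mass piled on the
long side pushes `P̃_i` above `P_i`, so the reduced-impact guarantee is
stated — and tested — for `a = b`). The window width
`a + b` is used as the normalizer so the bound `0 ≤ |i−V0|/(a+b) < 1` holds
for every valid window, including asymmetric ones where a difference-based
normalizer would vanish.

**How the fuzzy error enters training.** The usual formulations of the
modified backpropagation error are mutually inconsistent about its sign,
and substituting `ε̃` verbatim as the output-layer delta is unstable by
construction: that error never vanishes, breaks the zero-sum structure of
the softmax gradient, and in practice collapses the network into a
one-class attractor (misclassified samples receive *weaker* updates than
correct ones). The package therefore implements the reading that realizes
the mechanism's described behaviour — the modified error *reduces the
impact* of confidently classified samples and grades borderline ones — by
using `φ` as a per-sample modulation of the output error:

```
dlogits = (1 + φ) · (P − y),   φ = P̃_i − P_i  for the true class i.
```

With class `i` at the window maximum, `φ ≤ 0` shrinks the update toward
zero as confidence grows; for ambiguous samples the update is graded up
(up to 1.5×); and `φ = 0` (i.e. `P̃ = P`) recovers the plain
softmax/cross-entropy gradient exactly, so the fuzzy and plain heads differ
only in this output-layer term. Hidden layers backpropagate the modulated
signal unchanged. `fuzzy_errors()` continues to report `ε`, `ε̃` and `φ`
as defined, independently of how training consumes them.

**Memberships and thresholds.** After training, each class's Gaussian
membership is fitted on the training samples' pooled penultimate
activations projected onto that class's output weight row (mean and
standard deviation, spread floored at 1e−3). At prediction time the class
distribution is reweighted by the membership degrees and renormalized; the
binary decision thresholds this adjusted malignant score. A validation grid
search tunes the spread scaling over `{0.5, 1, 2, 4}` and the threshold
over candidates derived from the validation scores themselves (midpoints
between adjacent sorted unique scores, plus 0.5), maximizing balanced
accuracy with deterministic tie-breaks (larger spread, then lower
threshold). Score-derived thresholds matter because the fuzzy-trained
scores, while ranking the classes well, need not be calibrated around 0.5.
An optional per-epoch threshold refit exists but is off by default; the
validation grid search is the documented calibration path. The continuous
report `S̃ = V0` accompanies every prediction, along with an `uncertain`
flag for samples on the decision boundary.

## The synthetic corpus

The generator renders Poisson-placed elliptical blobs with low-order
radial-harmonic boundary perturbations on a tinted background plus additive
high-frequency noise — a deliberate cartoon of nuclear density and
pleomorphism. Benign-like tissue (class 0) is sparse, round and smooth
(6 blobs per 1e4 px², radii 3–6 px, irregularity 0.15, noise 0.02);
malignant-like tissue (class 1) scales with the separability control `s`:
density `6 + 10s`, radii `3−s` to `6−s`, irregularity `0.15 + 0.6s`, noise
`0.02 + 0.08s`. At `s = 0` the classes are identical by construction; at
`s = 1` wavelet band energies separate the classes almost perfectly. The
tabular generator plants class-shifted Gaussian features among standard
Gaussian noise, with optional noisy redundant copies and a truth mask.

What passing tests on this corpus show: that every stage implements its
contract — the transform is exact, the optimizer converges and keeps a
clean archive, the fuzzy head trains stably and calibrates, selection
recovers planted structure, and the pipeline is leak-free (chance accuracy
at zero separability). What they do not show: performance on real
histology. Real slides carry stain physics, magnification effects, tissue
architecture and label noise that a blob cartoon does not emulate; the
published headline numbers for this family of methods depend on large
external corpora and full-scale training and are out of scope here.

## Problem sizes and numerical choices

The examples and tests run at desk scale on one CPU: 64×64 images,
100 per class for the end-to-end runs (60/20/20 stratified split), 15
training epochs with 8 filters; the ablation uses 32×32 images, 40 per
class and 8 epochs over five replicate seeds; wrapper selection uses 24
wolves and 40 iterations over 50 features. The default Adam learning rate
is 1e−2 — the top of the tuned search range — because at these sample
sizes an epoch contains only a handful of optimizer steps and smaller rates
under-train the head within the configured epochs. Tolerances: 1e−8
reconstruction, 1e−6 relative energy, 1e−12 for closed-form oracles;
degenerate inputs (constant images, zero-variance vectors, empty archives,
single-class folds) raise errors with named causes rather than propagating
NaNs. Two definitional choices worth knowing: a sometimes-seen variant of
the accuracy formula adds false positives to its numerator — the standard
formula is implemented; and the window centroid is the probability-weighted
mean class index (a naive factoring of the defining ratio collapses it to
the true class index, which would make the centroid distance vacuous).

## Limitations

The residual network is intentionally small; depth and width are
configurable but the architecture is not the 152-layer design its family
name evokes. The fuzzy window machinery generalizes to `m > 2` classes, but
the pipeline and its calibration are exercised for the binary task only.
Wrapper selection on finite tables can tie genuinely different masks at
zero validation error; the one-standard-error selection makes the choice
parsimonious, not oracular. The CLI is a thin veneer over the package
functions — the functions, not the CLI, are the tested interface.
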