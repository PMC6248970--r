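---
title: "Methods: radiomic signatures for predicting plan adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic signatures for predicting plan adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsig)
```

## The problem and the model

During concurrent chemoradiation for stage-III NSCLC, a substantial
fraction of tumours (the literature puts it around 30–40%) shrink enough
that the treatment plan is redone mid-course. `radsig` implements a
binary classification pipeline that predicts this *adaptive* vs
*non-adaptive* outcome from the pre-treatment planning CT and clinical
scores. The statistical model is deliberately simple — a Random Forest on
a small selected feature set — and the scientific content lies in (a) the
fixed 251-feature representation of the tumour, (b) the
selection-frequency protocol that distils it into a signature, and (c)
the evaluation suite (pooled LOO ROC, prevalence-adjusted predictive
values, .632+ bootstrap) appropriate to a 91-patient cohort.

This vignette documents the modelling assumptions, every tunable that
matters, the numerical conventions, and what the synthetic-data tests do
and do not establish. It states no empirical result that the test suite
or the acceptance script does not itself compute.

## Feature representation

### Quantization

Texture features need a gray-level alphabet. Intensities inside the ROI
are binned equal-width over the ROI's own range into `G` levels,
`level(v) = min(G, 1 + floor(G(v − min)/(max − min)))`, with a constant
ROI mapping to level 1. The default `G = 32` follows common radiomics
practice: it keeps a 32×32 co-occurrence matrix reasonably dense for
ROIs of a few thousand voxels. First-order statistics are computed on
*raw* intensities (quantization exists only to serve the co-occurrence
and pattern alphabets); their histogram uses `n_bins = 64`, chosen so
that the relative-maxima count is non-trivial on 10³-voxel ROIs. No
resampling or cross-patient intensity normalization is applied — the
pipeline works on the voxel grid as given, and voxel spacing is carried
as metadata only.

### First-order statistics (12)

Moments use population normalization; skewness is m₃/m₂^1.5 and kurtosis
the raw m₄/m₂² (a Gaussian scores 3, not 0 — the convention is ambiguous
in the field, so the choice is documented here and in `?firstorder_features`).
Peak-based descriptors are defined on the unsmoothed histogram:
a relative maximum is a run of equal probabilities strictly higher than
both flanking runs (boundary runs compare one side); a plateau counts
once, at its left edge. "Energy around the maximum" uses a ±2-bin
window — the smallest symmetric neighbourhood that distinguishes peak
sharpness. Constant input is degenerate: skewness, kurtosis and width
are reported as 0.

### GLCM (130)

The 26 unit displacements of a voxel form 13 ± classes; opposite
displacements give exactly transposed matrices under the
both-ends-in-ROI pairing rule, so only one representative per class is
kept (the one whose last nonzero component is negative, which reproduces
the direction labels of the published signature, e.g. `(0,-1,0)` and
`(-1,1,-1)`). Matrices are unsymmetrized and normalized by pair count.

Keeping one matrix per ± pair is only information-preserving if every
statistic is transpose-invariant. Nine of the ten are as usually
written; the marginal variance Σ(i−μₓ)²p is not, and the property test
caught this. The package therefore defines `variance` as the symmetrized
(σₓ² + σᵧ²)/2, which equals the usual definition whenever the matrix is
symmetric and makes the 13-direction collapse exact. Cluster shade,
sometimes suspected of sign-flipping under transposition, is in fact
invariant ((i+j) is symmetric in i and j).

A ROI too thin along a displacement yields a zero matrix; its statistics
are reported as 0 and flagged `degenerate` rather than NA, so feature
vectors stay complete and tree-based learners see a constant, harmless
column.

### LBP-TOP (100)

Local binary patterns with 8 neighbours are computed in the three
orthogonal planes through each ROI voxel, on the quantized levels (same
alphabet as the GLCM, for determinism). Neighbours sit at angles 2πk/8
and radius R, sampled by bilinear interpolation; offsets within 1e-9 of
an integer are snapped so axis-aligned neighbours are read exactly. The
comparison is `neighbour ≥ center − 1e-9`: the tolerance is part of the
stated convention because on integer-valued levels the interpolated
value can equal the center *exactly in real arithmetic* (e.g. corners
c+1, c+1, c+1, c−1 at a 45° offset), and without a tolerance the bit
would be decided by floating-point evaluation order. Real, non-tied
differences on quantized levels are orders of magnitude above 1e-9, so
the tolerance only stabilizes genuine ties.

A voxel is coded in a plane iff its full sampling circle fits inside the
volume bounds in that plane; out-of-ROI voxels may be sampled as
neighbours (their level is 0), which keeps the coding rule local and
oracle-checkable. Per-plane histograms are compressed by the mapping
(u2: 59 bins, ri: 36, riu2: 10, raw: 256), normalized to 1/3 each and
concatenated in plane order XY, XZ, YZ. The 10-configuration grid —
radii {1,2,3} × {raw, u2, ri} plus riu2 at radius 3 — is forced by the
printed family size (100 = 10 × 10); "LBP3" is read as radius 3, since
the three orthogonal planes are intrinsic to the construction rather
than a parameter. Summary statistics treat the concatenated histogram
as a distribution over 1-based bin positions; "range" is pattern
diversity (count of occupied bins), not max−min of positions.

### Semantic features (9)

Integer-coded, not one-hot: the downstream learner is tree-based, and
the published signature treats items like "histology" as single
features. The nine fields are age, sex, smoking, T, N, stage, histology,
and the two mutation axes EGFR and ALK — the source material names eight
items plus a plural "gene mutations evaluation", and splitting mutations
into the two clinically standard axes is the most plausible completion
to nine. `unknown` is an explicit category (sentinel −1 where it is not
a natural ordinal level), never a missing value.

## Signature selection

The wrapper embeds the classifier in the subset search. Per outer
leave-one-out fold, a greedy forward best-first search starts from the
empty set; each step scores every candidate addition by the mean
accuracy of a Random Forest over one stratified 2-fold CV split of the
fold's training rows (the split is drawn once per search; all candidates
in a step share the same forest seed so comparisons are paired), accepts
the best candidate, and stops after 5 consecutive expansions that fail
to improve on the best subset found (the backtracking limit of
best-first search as commonly configured). The baseline to beat is the
majority-class rate, so a pure-noise fold can return an empty subset.
Ties everywhere break by registry order, and every random element is
seeded per fold (`seed + fold`), so reruns reproduce per-fold subsets
exactly.

The inner forest uses 100 trees (vs 500 in the final model) purely as a
cost decision. The search strategy and inner metric are choices the
protocol leaves open; greedy-forward-with-backtracking and accuracy are
the defaults of the wrapper ecosystems this protocol originated in.

The signature keeps features selected in at least τ = 10% of the outer
folds (so 10 of 91 folds ≈ 0.110 is in, 8 of 91 ≈ 0.088 is out), ordered
by frequency. τ is monotone by construction: raising it can only shrink
the signature.

## Classifier and evaluation

The final Random Forest grows 500 CART trees on bootstrap samples with
m = ⌊√p⌋ split candidates per node (the constraint m < p is enforced for
p > 1); the predicted probability is the fraction of trees voting
positive, and 0.5 is the decision threshold (ties ≥ count positive). No
installed R package provides a random forest in this environment, so the
package carries its own compact implementation (Rcpp) with a
self-contained seeded RNG — results are reproducible across sessions and
platforms compiled with the same standard library.

Evaluation pools the n out-of-fold LOO probabilities into one ROC; the
AUC is the trapezoidal/Mann–Whitney value with midpoint tie handling.
Proportion metrics carry Wald 95% intervals with n = the number of
pooled predictions; the AUC uses the Hanley–McNeil standard error. Two
predictive-value flavours are reported: raw precision TP/(TP+FP), and
prevalence-adjusted PPV/NPV at an assumed prevalence π (default 0.40,
matching the literature adaptation rate). At π equal to the sample
prevalence the adjusted PPV provably equals raw precision (the Bayes
identity; asserted numerically in the tests). On the published
Proposed-system row, the π = 0.40 reconstruction reproduces the printed
PPV/NPV (.657/.869) and the Wald interval reproduces the printed
accuracy CI exactly; the printed sensitivity CI is not a Wald interval
at any defensible n, and the package makes no attempt to match it.

The .632+ bootstrap draws B = 200 row resamples; the leave-one-out
bootstrap error averages, per row, the error over replicates where the
row is out-of-bag (never-out-of-bag rows are excluded; single-class
resamples are skipped). The no-information rate γ uses observed and
resubstitution-predicted class proportions. The blend is
R = (ε̂₀ − err̄)/(γ − err̄) clipped to [0,1] (0 when the denominator is
non-positive), w = 0.632/(1 − 0.368R), estimate
(1−w)·err̄ + w·min(ε̂₀, γ) — which degrades gracefully to the classical
.632 rule when ε̂₀ = err̄.

## Synthetic data: what it emulates, what it does not

`generate_phantom()` states a world matching the cohort the protocol was
built for: 50/41 class sizes; semantic categories at the published
Total-column proportions (male 0.76, stage IIIB 0.40, histology
0.43/0.47/0.07/0.03, age ≈ N(71, 9.6²)); vocabularies the cohort table
does not give (smoking, T, N, EGFR, ALK) use fixed plausible stage-III
distributions chosen once: smoking 0.15/0.45/0.35/0.05
(never/former/current/unknown), T 0.10/0.25/0.35/0.30, N
0.10/0.15/0.50/0.25, EGFR 0.10/0.60/0.30 (mutated/wild-type/unknown),
ALK 0.05/0.60/0.35. Volumes are 48³ with lung-like Gaussian background
(N(−750, 40²) HU), an ellipsoidal ROI with semi-axes 8–14 voxels, and a
tumour interior at ~30 HU: homogeneous (one smoothed component) for
non-adaptive, a two-component mixture (±20 HU, arranged in blobs
smoothed at scale 2.5 voxels) for adaptive. The contrast was fixed once
so that texture families separate the classes clearly (the suite checks
the direction of the GLCM-inertia difference, not a tuned magnitude).

The phantoms emulate *texture contrast with known ground truth*; they do
not emulate CT physics (beam hardening, partial volume), anatomical
context, inter-feature correlation structure, or scanner variability. A
green phantom test therefore establishes that the pipeline recovers
planted signal and orders feature families sensibly — not that the
published clinical effect sizes would replicate. The published
performance numbers require the original extracted dataset; the package
offers `validate_external_arff()` and `scripts/s1_validation.R` to
re-run selection and evaluation on such a deposit side by side, without
asserting equality (the original tool's search internals and forest
hyperparameters are unspecified).

`generate_feature_table()` plants `k` informative columns at mean
separation `d` among standard normal noise, at the 50/91 class balance,
with names drawn from the real registry. The planted-recovery
acceptance check runs at n = 60, p = 50, k = 5, d = 1.5 over seeds 1–10
and requires every informative feature to outrank every noise feature in
at least 8 of 10 seeds; the no-signal (d = 0) and strong-signal (d = 3)
ends are checked through the full selection + LOO pipeline (AUC within
[0.3, 0.7], above 0.9 respectively). Note the d = 0 run evaluates the
signature on the same table that selected it, so its AUC drifts above
0.5 by selection optimism — the [0.3, 0.7] band is what "no usable
signal" means under that protocol, not an unbiasedness claim.

## Numerical choices and degenerate inputs

* Equal-width binning maps the range maximum into the top bin
  (`min(G, ...)`), so histograms never drop mass.
* Constant ROI: first-order moments report 0 for skewness/kurtosis;
  GLCM collapses to a single diagonal cell (inertia = absolute = 0,
  energy = idm = 1); every LBP plane concentrates in the image of code
  255.
* Masks are coerced to binary by `value > 0`; a mask with fewer than 2
  foreground voxels is a hard error (texture is undefined).
* ARFF round-trips preserve feature names byte-for-byte (names with
  commas, e.g. `glcm_absolute_-1,1,-1`, are single-quoted) and values to
  better than 1e-9; nominal attributes are integer-coded 0-based in
  declaration order with the coding recorded as an attribute.
* All seeds are 32-bit; per-fold and per-replicate seeds are derived
  additively from the master seed.

## Known limitations

* The exact inventory of the original 10 GLCM statistics and the
  original wrapper's search/stopping rule are not recoverable from the
  source material; the package's choices are pinned by the printed
  family sizes (130 = 13 × 10, 100 = 10 × 10) and documented above.
  Changing either grid would change feature totals and is deliberately
  not configurable past the registry invariant.
* Fixed-bin-count quantization over the ROI range makes texture features
  invariant to affine intensity shifts but not comparable across
  absolute-HU protocols; fixed-bin-width quantization is out of scope.
* The in-package Random Forest implements the standard CART/bagging
  algorithm but is not a drop-in reimplementation of any particular
  library's forest; published numbers obtained with other forests will
  differ within normal stochastic-classifier variation.
* DICOM series and RT-STRUCT parsing are out of scope; convert to
  NIfTI/NRRD upstream.
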