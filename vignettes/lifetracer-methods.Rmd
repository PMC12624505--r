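---
title: "Methods: peak detection, feature alignment and classification for GC×GC-HRTOF-MS biosignature screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak detection, feature alignment and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifetracer)
```

## The problem and the model

Comprehensive two-dimensional gas chromatography with high-resolution
time-of-flight mass spectrometry (GC×GC-HRTOF-MS) characterizes each analyte
by two retention times — RT1 on the long primary column (minutes scale) and
RT2 on the short secondary column (seconds scale) — and a fragment mass
spectrum. An untargeted run of a complex natural extract produces hundreds
of millions of scans. The question this package answers is whether the
*distributional* pattern of such an organic inventory is abiotic
(meteoritic) or biotic (terrestrial), without relying on any single named
biomarker.

The model is deliberately simple: samples are represented by a binary
presence/absence matrix over *features* — (m/z bin, RT1, RT2) triplets that
proxy single fragment-ion species — and a regularized linear classifier on
that matrix provides both the class decision and, through its signed
coefficients, a ranking of the fragment families that drive it. Everything
upstream of the classifier exists to make that matrix trustworthy at a
sample size of n = 18 (8 abiotic, 10 biotic in the emulated study design).

## Pipeline stages and their assumptions

### Quantization and total ion images

Scans are assigned to integer m/z bins 30–700 with half-open windows
[v − 0.5, v + 0.5). The half-open convention is a deliberate departure from
a closed-interval description: closed windows would count a boundary scan in
two adjacent bins and break intensity conservation, which the test suite
asserts exactly (the sum over all images of a sample equals the sum of the
retained scan areas).

Each bin's scans are accumulated on a fixed grid: RT1 from 2200 s in 3.5 s
steps, RT2 from 0 s in 8 ms steps (439 rows). The inclusive RT1 range gives
2646 columns; the instrument vendor's printed figure of 2643 cannot be
derived from the same range and step, so the full inclusive grid is used —
no downstream computation depends on the column count, only on the spacing.
Entries snap to the nearest axis point with ties toward the lower index
(the acquisition's phase relative to the grid is unknown; a fixed, symmetric
convention keeps the operation deterministic and order-independent). Cells,
rows and columns with no scans are zero — zero imputation is the correct
semantic for "no ions detected", unlike missing-at-random imputation.

### Peak detection

The image standard deviation σ is the *population* SD over all cells,
zeros included. Real images are overwhelmingly zero, so σ is essentially a
robust scale for the noise floor; computing it on nonzero cells only would
make the threshold λ₁σ depend on how much of the image a compound occupies.

Pixels above λ₁σ (strict inequality; default λ₁ = 5) are clustered with
DBSCAN on their integer (row, column) coordinates, Euclidean metric,
eps = 5 pixels, min_samples = 20 with the point itself counted in its own
neighbourhood (the sklearn convention). Isolated supra-threshold pixels are
therefore discarded as noise — this acts as the zeroth denoising filter.
Cluster bounding boxes wider than 50 s in RT1 or taller than 1 s in RT2 are
bisected at the geometric midpoint of the offending axis (RT1 checked
first) and both pixel subsets are re-checked recursively; each half's
extent is at most half the parent's, so termination is guaranteed. Midpoint
splitting was chosen over valley-finding because the split rule exists to
bound feature extent for alignment, not to deconvolve overlapping analytes
— deconvolution is explicitly out of scope.

A peak reports its apex (maximum-intensity pixel; first in scan order on
ties) and `Irect`, the intensity sum over the bounding rectangle of the
*thresholded* image, matching the stated processing order.

### The denoising cascade

Three filters run in fixed order, each only removing peaks:

1. **Whole-image rejection**: if more than 10 % (strict) of the thresholded
   image is nonzero, the image is uniform noise and all its peaks are
   dropped.
2. **Local intensity**: peaks with `Irect < λ₂σ` are dropped (default
   λ₂ = 100), with σ the original pre-threshold image SD — the threshold is
   meant as "how many noise SDs of signal does this rectangle hold".
3. **Strip regions**: full-height column bands and full-width row bands
   centred on a peak's apex (half-width 5 pixels, matching eps) are scored
   by their nonzero-pixel ratio; a peak on a band exceeding its configured
   threshold is dropped. The original per-region thresholds are not public,
   so the thresholds are mandatory configuration with a deliberately
   permissive default of 0.5 — users with bleed-prone columns should
   tighten them.

### Feature alignment

Filtered peaks from all samples are sorted by descending `Irect` (ties:
rt1, rt2, sample id) and greedily assigned: a peak joins an existing
feature if it shares the m/z bin and its apex lies within RT1thrsh = 50 s
and RT2thrsh = 0.8 s of the feature's *seed* apex; otherwise it seeds a new
feature. Anchoring distances to the seed rather than a running centroid
keeps clustering deterministic and idempotent (a centroid drifts with
insertion order). When several features qualify, the smallest combined
normalized distance (|ΔRT1|/50 + |ΔRT2|/0.8, ties to the lower feature id)
wins. Intensity-first ordering means the most intense occurrence of a
compound defines its canonical position. A consequence the tests assert: no
two seeds of one bin are mutually within tolerance, so the greedy pass is
exhaustive.

### Calibration

λ₁ and λ₂ are not free knobs: they are selected by grid search
(λ₁ ∈ 1…20, λ₂ ∈ {1, 10, 20, …, 200}) against a reference compound list
with known presence patterns, scoring the fraction of expected
(compound, sample) occurrences recovered within ±50 s RT1 / ±1 s RT2. Among
cells with accuracy strictly above 0.90, the largest λ₁ wins (maximal noise
rejection), then the median of its passing λ₂ values (lower of two middles)
— neither the most permissive nor the most restrictive surviving setting.
The RT clustering thresholds come from reference dispersions (max − min of
matched apexes across samples, maximized over compounds): RT1 is rounded
*up* to the whole second — the printed outcome 49.056 → 50 contradicts a
"nearest second" description, and ceiling is also the conservative choice
for a tolerance — while RT2 uses round-half-even to 0.1 s (0.816 → 0.8
matches the printed value). Zero dispersion floors at one grid unit
(1 s, 0.1 s).

### Classification

Class encoding: abiotic = 1, biotic = 0, so positive coefficients and
scores mean abiotic-enriched. Two nested schemes are provided:

* **9-fold / leave-one-out** (the preferred scheme at n = 18): per seed,
  shuffle, split into folds of two; inside each fold's 16 training samples
  a LOO loop scores every hyperparameter grid point by mean validation
  accuracy; the winner is refit and scored on the held-out pair. Accuracy
  averages over folds and seeds; AUC pools decision scores across folds
  within a seed (a two-sample fold has no within-fold AUC) and averages
  over seeds.
* **Stratified 6-fold with inner 5-fold**: round-robin stratified outer
  folds (every fold holds both classes); the remaining five folds serve in
  turn as validation folds; selection by mean validation AUC.

Validation ties break toward stronger regularization (smaller C, larger
naive-Bayes α, fewer trees): at 15-sample training sets many grid points
tie at accuracy 1, and the conservative end of the tie is the defensible
choice. Seeds are fixed to 0…9 for the ten repetitions.

Model families: L1/L2 logistic regression via glmnet with
λ = 1/(C·n) mapping C onto the sklearn-style objective the field's tooling
uses; a kernel SVM (linear, polynomial, RBF, sigmoid; simplified SMO,
entirely adequate at n ≤ 18) and a Gini random forest on binary features
are implemented in-package because no R implementation is available in the
target environment; Bernoulli naive Bayes with Lidstone smoothing is
closed-form. Degenerate training sets — a class with fewer than two
members, which only arise in leave-one-out loops over very small synthetic
designs — fall back to a ridge-IRLS fit with the same objective (glmnet
refuses them), or to a constant-score model when a class is absent
entirely. The deployed model is L2 logistic regression with C = 0.1,
selected by leave-one-out over the full matrix.

### Feature groups and the artifact check

Coeluting fragment ions of one parent compound share retention times but
differ in m/z, so coefficient-ranked features are greedily grouped within
50 s / 0.8 s *regardless of m/z*: the highest-|coefficient| unassigned
feature anchors a group, absorbs every unassigned feature within tolerance
of *it* (chains are not merged transitively — membership is always measured
from the anchor), and represents the group. Groups whose representative
appears in fewer than two samples are set aside as unreplicated.

Compound identification is manual and out of scope; instead the package
ships the robustness check used to argue the classifier does not lean on
instrument artifacts: given a user-supplied list of artifact group ids, the
coefficients of all their member features are zeroed and all samples are
re-scored. If artifacts are genuinely inert, accuracy changes by exactly
zero. The synthetic construction that guarantees this — artifact features
present in every sample — is also the physically meaningful one: a
contaminant like column-bleed siloxane shows up everywhere, carries no
class information, and an unpenalized intercept absorbs it, leaving its L2
coefficient exactly zero.

### Distributional statistics

Peak attributes (m/z, RT1, RT2) are compared between the abiotic and biotic
peak populations with the two-sample Kolmogorov–Smirnov statistic (exact
sup-distance of the empirical CDFs, computed directly; p-value from the
asymptotic approximation, adequate at thousands of peaks per class) and
one-sided Mann–Whitney U tests whose alternatives mirror the scientific
directions of interest (abiotic RT1 stochastically lower — more volatile
compounds elute earlier; m/z lower and RT2 higher as the complementary
checks). Retention times are grid-quantized and therefore tied; the U test
uses the tie-corrected normal approximation, switching to the exact
distribution below n = 50 when no ties are present.

## The synthetic world

`generate_dataset()` emits the instrument's 7-column scan-table dialect
with known ground truth. Its defaults state the emulated world once:

| parameter | default | why |
|---|---|---|
| n_abiotic / n_biotic | 8 / 10 | the emulated study design |
| rt1_jitter_sd | 8 s | 8-sample dispersions (≈ 2.8–6 sd of range) stay below the 50 s clustering threshold, matching the calibrated reference dispersion of ~49 s |
| rt2_jitter_sd | 0.1 s | same logic against the 0.8 s threshold (reference dispersion ~0.8 s) |
| amplitude | 1e5 | a planted blob's ~60 supra-threshold pixels dwarf λ₁σ ≈ 1.2 % of amplitude on the 439 × 2646 grid |
| footprint_sd | 1.5 px | isotropic Gaussian truncated at 3 sd — the smallest shape on which every pixel is a DBSCAN core point at eps = 5 / min_samples = 20 |
| background_rate | 200 scans per occupied bin | diffuse floor; exponential intensities (mean 30) sit orders of magnitude below λ₁σ, so > 99 % are removed by thresholding alone |

Fragments of one compound share a single jittered centre per sample —
coelution is exact, as it is physically. Strip noise emits dense bands of
configurable width, density and intensity.

What the generator does **not** emulate: physically realistic fragmentation
(isotope patterns, electron-impact rules), intensity correlations between
fragments, RT warping that varies along the gradient (jitter is a single
offset per compound), duplicate injections, and vendor binary formats. A
green end-to-end test therefore establishes the pipeline's bookkeeping and
statistical machinery, not chromatographic realism: conclusions about real
data still require the calibration stage against real reference compounds.

## Numerical choices and degenerate inputs

* Boundary comparisons follow the stated inequalities exactly: threshold
  survival is `> λ₁σ`, whole-image rejection is `> 10 %`, peak retention is
  `Irect ≥ λ₂σ`, calibration passing is `accuracy > 0.90`.
* σ = 0 (all-zero image) keeps every peak in the Irect filter and produces
  no detections upstream anyway.
* Axis snapping ties go to the lower index; apex ties to the first pixel in
  column-major order; coefficient ties in grouping anchor the lower feature
  id; validation-accuracy ties pick the stronger regularization. Every tie
  in the system has a stated, tested resolution — determinism is a design
  requirement, not an accident.
* An empty peak set, an empty bin, a single-class matrix, or a λ₁ so large
  that nothing survives all degrade gracefully to empty outputs rather than
  errors; genuinely contradictory inputs (duplicate sample ids, unknown
  labels, unknown group ids, missing strip thresholds) error with named
  causes.

## Known limitations

* The permutation-null behaviour of the 9-fold/LOO scheme is pessimistic at
  the 8/10 class imbalance (mean accuracy ≈ 0.40 over random label
  permutations, not 0.50): leave-one-out majority voting is anti-correlated
  with held-out labels. This is a property of the scheme, shared with the
  original design, and is why the acceptance check estimates the null over
  ten independent permutations.
* eps = 5 is interpreted in pixel units, where one RT1 pixel is 3.5 s and
  one RT2 pixel is 8 ms — the metric is anisotropic in time, which matches
  an image-processing reading of the method but means the clustering radius
  is not a physical time.
* Strip-filter thresholds default to 0.5 in the absence of the original
  calibrated values; they are configuration, not truth.
* The in-package SVM and random forest are sized for n ≤ a few dozen
  samples; they are not general-purpose implementations.
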