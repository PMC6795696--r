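---
title: "Habitat mapping of soft-tissue sarcoma from multi-parametric MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatmap)
```

## The problem

Soft-tissue sarcomas (STS) are spatially heterogeneous: a single tumor can
contain strongly vascularized cellular regions, poorly perfused cellular
regions, necrotic or cystic cavities and macroscopic fat. Treatment response
is often invisible to size-based criteria, because radiotherapy changes the
*composition* of the tumor more than its outline. Habitat mapping addresses
this by classifying every voxel of the tumor into a tissue sub-type from
co-aligned quantitative MRI maps, and then tracking the volume and diffusion
properties of each sub-type over time.

`habitatmap` implements that pipeline end to end for three voxel-wise
features:

* **ADC** (apparent diffusion coefficient, mm²/s), inversely related to
  cellularity;
* **FF** (Dixon fat fraction), \(FF = S_{fat} / (S_{fat} + S_{water}) \times 100\%\);
* **EF** (enhancement fraction), \(EF = (S_{post} - S_{pre}) / (S_{post} +
  S_{pre}) \times 100\%\), a normalized measure of gadolinium uptake.

Each feature is mapped onto \([0,1]\) by fixed linear transforms —
\(ADC / 3\times10^{-3}\,\mathrm{mm^2/s}\) (clipped), \((EF + 100)/200\),
\(FF/100\) — so that every voxel becomes a point in the unit cube. Five
classes are distinguished: (1) enhancing cellular tumor, (2) non-enhancing
cellular tumor, (3) necrotic/cystic tissue, (4) fat, and (5) a synthetic
"novelty" class that captures feature combinations unlike any training
tissue, so that atypical voxels are flagged rather than silently forced into
the nearest tissue class.

## Classification model

The reference classifier is Gaussian naive Bayes (NB), implemented natively
in the package: per class \(c\) and feature \(d\) it stores the sample mean
\(\mu_{cd}\) and variance \(\sigma^2_{cd}\) of the training voxels, plus a
class prior \(\pi_c\), and scores a voxel \(x\) as

\[ P(c \mid x) \propto \pi_c \prod_{d=1}^{3}
   \mathcal{N}(x_d;\, \mu_{cd},\, \sigma^2_{cd}). \]

Design choices around this model:

* **Priors** default to the empirical class frequencies of the training set
  (the conventional default when nothing else is known); a uniform prior is
  available via `fit_gaussian_nb(..., priors = "uniform")`. Because the
  novelty class contributes many synthetic voxels, its empirical prior is
  substantial, which is precisely what makes it an effective catch-all.
* **Variance floor.** Variances are floored at \(10^{-9}\) times the largest
  per-feature total variance, so a constant feature in a small ROI cannot
  collapse a density to a point mass.
* **Posterior computation** is done in log space with a max-shift before
  exponentiation; a brute-force density-product oracle in the test suite
  bounds the discrepancy below \(10^{-9}\).

Seven further families (logistic regression, RBF support vector machine, a
20-node three-layer neural network, random forest, k-nearest-neighbor,
kernel density estimation, and KDE with an automatic bandwidth) implement
the same probability-output contract for the model-comparison study. They
are deliberately thin wrappers over established implementations
(`nnet::multinom`, `e1071::svm` with Platt-style probability calibration,
`nnet::nnet`, `randomForest::randomForest`), while kNN and KDE are
implemented natively because no installed package exposes per-class
probability outputs in the exact form required. Two deviations from an
idealized description are worth recording: the neural network uses the
logistic sigmoid activation of `nnet` (not rectified-linear units) with the
BFGS quasi-Newton optimizer, and logistic regression maps the
inverse-regularization hyperparameter \(C\) onto `nnet::multinom`'s weight
decay as \(decay = 1/C\). Both are documented model-family conventions, not
tuning knobs.

The automatic KDE variant selects its bandwidth by Silverman's
rule-of-thumb, \(h = \hat\sigma \,(4 / ((d+2)n))^{1/(d+4)}\), with
\(\hat\sigma\) the mean of the per-dimension sample standard deviations and
a floor of \(10^{-4}\) (the lower end of the bandwidth search range) for
degenerate samples. A scalar bandwidth shared across dimensions was chosen
over a per-dimension vector because the three features live on a common
\([0,1]\) scale; the bandwidth is computed per class, so sharper classes
receive sharper kernels.

## Training data and the novelty class

Expert training ROIs are square patches of 1–2 cm² (45–100 voxels) placed
far from visible tissue boundaries; `extract_roi_samples()` warns (rather
than errors) when a count falls outside that range, because phantom ROIs
may legitimately be smaller. The novelty class is synthesized by
`synthesize_novelty_rois()`: 15 ROIs by default, each with a uniformly drawn
voxel count in \([45, 100]\) (the expert-ROI size range, reused for
symmetry), sampled uniformly over the intrinsic parameter ranges
\(EF \in [-100, 100]\,\%\), \(FF \in [0, 100]\,\%\),
\(ADC \in [0, 3]\times10^{-3}\,\mathrm{mm^2/s}\) and passed through the
standard normalization, so each normalized component is exactly
Uniform(0, 1). The synthesis is seeded; without a recorded seed the training
set would be irreproducible.

## Cross-validation and model selection

Model selection uses an exhaustive one-ROI-per-class scheme: every element
of the Cartesian product of the per-class ROI lists is a validation tuple;
the classifier is fitted on all remaining ROIs and scored on the pooled
voxels of the tuple, and accuracy is the percentage of voxels classified
correctly (pooled, not macro-averaged over ROIs — matching the definition
of accuracy as a voxel percentage). The hyperparameter with the highest
*median* accuracy over cycles wins; ties resolve to the smallest value on
the grid, favoring the smoother model. Default search grids are 25
log-spaced points across each family's documented range.

A class contributing exactly one ROI poses a dilemma: excluding it from
training while it is validated would break the five-class model. The package
keeps such ROIs in the training set even while they are validated and flags
the affected cycles in a `leaky` column, so the optimistic bias is visible
rather than hidden. Family comparisons use Welch's unequal-variance t-test
(two-sided); the plain-variance variant is a special case and the unequal
variance form is the safer default when one family saturates at 100%.

## MRF label de-noising

Voxel-wise classification ignores spatial correlation and produces
salt-and-pepper label noise. The package removes it by minimizing the
energy

\[ E(\ell) = \sum_v -\log \max(p_v(\ell_v), \varepsilon)
   \;+\; \beta \sum_{(v,u) \in \mathcal{N}} \mathbf{1}[\ell_v \neq \ell_u], \]

the negative log of the classifier's per-voxel probabilities plus a Potts
penalty on discordant neighbor pairs (each unordered pair counted once).
Inference is iterated conditional modes (ICM): starting from the argmax
labeling, voxels are swept in fixed raster order and each label is set to
the local-energy minimizer, with ties broken toward the lowest class id.
Sequential (not synchronous) updates guarantee the energy is non-increasing
and that the algorithm terminates; the per-sweep count of changed voxels is
returned as a convergence trace.

Numerical and structural choices:

* \(\beta = 1\) by default, exposed everywhere; \(\beta = 0\) reduces the
  output exactly to the argmax labeling (a tested invariant).
* The default neighborhood is 8-connected *within each axial slice*, so each
  slice is an independent MRF with its own trace, and the study-level
  summary reports the median iteration count over slices; a 6-connected 3-D
  neighborhood is available as an option.
* The probability floor \(\varepsilon = 10^{-12}\) keeps the data term
  finite when a classifier emits an exact zero.
* The sweep kernel is compiled (Rcpp); the energy function used by the
  test-suite monotonicity checks is an independent vectorized R
  implementation, so the two code paths cross-validate each other.

## Habitat quantification

`summarize_habitats()` reports, per class, the voxel count, volume (voxel
count × voxel volume), volume fraction and mean ADC in native units. The
mean (not median) ADC is used; voxels with invalid ADC are excluded from
the mean but still counted in the volume. The class-4 (fat) mean ADC is
computed but flagged non-interpretable, because ADC from fat-suppressed
diffusion imaging is noise-dominated in fat. Spie-chart geometry encodes
the volume fraction as segment angle (summing to 360°) and the mean ADC as
segment radius, normalized to the largest interpretable class mean across
the timepoints being compared so that pre- and post-treatment charts share
one radial scale; pre-treatment radii appear as dashed reference arcs on
post-treatment charts. Longitudinal comparison reports per-class changes in
fraction and mean ADC plus the total volume change
\(100\,(V_{post} - V_{pre})/V_{pre}\), computed on the radiologist VOI.

## The phantom: what it emulates and what it does not

Because no patient data ship with the package, every stage is validated on
a synthetic phantom with known ground truth. The default phantom is a
64×64×16 grid at 2 mm isotropic spacing — a desk-scale study of roughly
1.8×10⁴ tumor voxels that keeps the full pipeline under a few seconds —
containing nested compartments: an enhancing-tumor ellipsoid enclosing a
non-enhancing ellipsoid, a necrotic ellipsoid and a fat block. Compartments
are painted in list order with later entries overriding earlier ones, which
is how nesting is expressed; the VOI is their union.

Per-class parameters are drawn as clipped Gaussians with defaults chosen to
respect the decision-tree contrasts while remaining realistic for STS
tissue: classes 1/2/3 at ADC 0.9/1.0/2.4 ×10⁻³ mm²/s (SD 0.1×10⁻³), EF
60/5/5 % (SD 8), FF 5/5/5 % (SD 4); class 4 at FF 85 % (SD 4), EF 0 and a
deliberately noisy ADC (SD 0.6×10⁻³) mimicking the unreliability of
fat-suppressed diffusion in fat. Classes 1 and 2 are separated almost
exclusively by enhancement (≈7 SD in EF), necrosis by ADC (≈15 SD), and fat
by FF (≈20 SD). Raw Dixon and pre/post-contrast signal pairs are
synthesized as exact pre-images of the target FF/EF under the defining
equations (total signal fixed at 200 a.u.), so the map-computation stage is
exercised on the same code path as real data. Training ROIs are placed by
eroding each compartment so that a square ROI plus a one-voxel margin lies
entirely inside one class — the phantom analogue of drawing ROIs "far from
visible boundaries".

The phantom deliberately omits coil bias fields, Rician noise, motion,
partial-volume gradients at boundaries (unless the blur option is used) and
mis-registration between maps. Passing phantom tests therefore demonstrates
the correctness of the algorithms under their own assumptions — Gaussian
class-conditional features, aligned grids — not robustness to real
acquisition artifacts. The Gaussian noise model intentionally matches the
NB model family so that classifier-correctness tests are clean; a
`label_noise` option draws a fraction of voxels' parameters from a wrong
class to stress the MRF stage.

Longitudinal phantoms apply a designed response model to the baseline
geometry — converting a chosen fraction of one class's voxels to another
class (e.g. 30% of enhancing tumor devascularizing) and shifting class ADC
means — with independent post-treatment draws, and record the designed
deltas so recovery can be asserted within sampling error.

## Problem sizes and tolerances used in the validation suite

The test suite and the acceptance script run entirely on seeded phantoms:
the default 64×64×16 study for end-to-end recovery (volume fractions within
±2 percentage points, class ADC means within 2 standard errors), 16×16
single-slice random probability fields for ICM energy monotonicity over
\(\beta \in \{0, 0.5, 1, 2\}\), 200 random queries for the NB-vs-oracle
bound of \(10^{-9}\), \(10^{5}\) random signal pairs for the FF/EF range
invariants, 50 randomized per-class count configurations for the
cross-validation combinatorics, and 2×10⁴ uniform queries (those at
normalized distance ≥ 0.3 from every tissue mean) for the ≥ 90% novelty
capture requirement. These sizes were chosen so the whole suite completes
in well under a minute while keeping every statistical tolerance at the
2-standard-error level or tighter.

## Known limitations

* Grid equality is a hard precondition: volumes on different grids are
  rejected, never resampled. Registration is out of scope.
* Only the Gaussian NB model serializes to JSON; other families live in
  memory for the comparison study.
* The singleton-ROI leak in cross-validation (above) is flagged but not
  avoidable without dropping a class.
* ADC values above the intrinsic ceiling of 3×10⁻³ mm²/s are clipped to 1
  after normalization rather than excluded, keeping features inside the
  trained domain at the cost of a small pile-up at 1.0 in extreme voxels.
* The novelty prior inherits the (large) sample share of the synthetic
  ROIs; users who want a less aggressive novelty class can reduce
  `n_novelty_rois` or switch to uniform priors.
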