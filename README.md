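# habitatmap

Voxel-wise tumor "habitat" mapping for soft-tissue sarcoma (STS) from
co-aligned multi-parametric MRI. The package classifies every voxel of a
tumor volume into one of five tissue sub-types, cleans the label map with a
Markov-random-field prior, and quantifies how each habitat changes across
treatment — for imaging scientists who need composition-based (rather than
size-based) response readouts.

## What it computes

Three quantitative features per voxel, each rescaled to [0, 1]:

* **ADC** — apparent diffusion coefficient (mm²/s), normalized as
  `ADC / 3e-3` (clipped);
* **FF** — Dixon fat fraction, `FF = S_fat / (S_fat + S_water) × 100 %`,
  normalized as `FF / 100`;
* **EF** — enhancement fraction, `EF = (S_post − S_pre) / (S_post + S_pre) × 100 %`,
  normalized as `(EF + 100) / 200`.

Classes: **1** enhancing cellular tumor (red), **2** non-enhancing cellular
tumor (green), **3** necrotic/cystic (blue), **4** fat (yellow), **5**
"novelty" (gray) — a catch-all trained on uniform samples of the whole
feature cube so atypical voxels are flagged instead of mis-assigned.

The reference classifier is a natively implemented Gaussian naive Bayes,

    P(c | x) ∝ π_c · Π_d N(x_d ; μ_cd, σ²_cd),

with seven further families (LR, SVM, NN, RF, kNN, KDE, automatic-bandwidth
KDE) behind the same probability contract for model comparison via
exhaustive one-ROI-per-class cross-validation (every Cartesian combination
of one held-out ROI per class; optimum = highest median voxel accuracy).
Label de-noising minimizes

    E(ℓ) = Σ_v −log max(p_v(ℓ_v), ε) + β · Σ_(v,u) 1[ℓ_v ≠ ℓ_u]

by iterated conditional modes (8-connected within each axial slice by
default), and habitat summaries report per-class volume fractions and mean
ADC, rendered as Spie charts (angle = volume fraction, radius = mean ADC).

A synthetic phantom module generates full seeded studies (parameter
volumes, raw signal pairs, VOI, training ROIs, ground-truth labels) so the
entire pipeline is testable without patient data.

## Worked example

A complete phantom study — generate, compute maps, train (tissue ROIs plus
the synthesized novelty class), classify, MRF-smooth, summarize:

```r
library(habitatmap)
report <- run_study(study_config(mode = "phantom",
                                 phantom = phantom_spec(seed = 42),
                                 seed = 42))
print(report)
```

```
habitat-mapping study report
  stages: load-inputs -> compute-maps -> make-training -> train -> predict -> mrf-smooth -> summarize
  classifier: NB
  MRF: median 2 iteration(s), all slices converged
  phantom recovery: raw 98.77%, MRF 100.00%
  class_id                         name voxels volume_mm3   fraction
1        1     enhancing cellular tumor  15988     127904 0.87812380
2        2 non-enhancing cellular tumor    771       6168 0.04234635
3        3              necrotic/cystic    603       4824 0.03311913
4        4                          fat    845       6760 0.04641072
5        5                      novelty      0          0 0.00000000
      mean_adc adc_interpretable
1 0.0008995871              TRUE
2 0.0010016648              TRUE
3 0.0023990424              TRUE
4 0.0010282809             FALSE
5           NA              TRUE
```

Reading this: voxel-wise NB alone labels 98.77 % of tumor voxels correctly
against the phantom's ground truth; the MRF pass removes the residual
salt-and-pepper noise (100 %), converging after a median of 2 ICM sweeps
per axial slice. The recovered volume fractions and class mean ADCs match
the phantom design (classes 1/2/3 generated at 0.9/1.0/2.4 ×10⁻³ mm²/s; the
class-4 ADC is flagged non-interpretable, as it would be in fat-suppressed
diffusion imaging). `spie_geometry()` / `plot_spie()` turn such summaries
into Spie charts, and `compare_timepoints()` quantifies pre/post-treatment
change.

A command-line front end over the same functions is installed at
`inst/cli/habitatmap.R` (subcommands `simulate`, `compute-maps`, `train`,
`predict`, `mrf-smooth`, `summarize`, `compare`, `crossval`, `run-study`).

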