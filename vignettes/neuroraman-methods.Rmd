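---
title: "Methods: label-free chemometric assessment of neuronal activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free chemometric assessment of neuronal activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroraman)
```

# The problem and the analysis model

A spiral-scanning Raman microscope integrates one spectrum per cell (or per
ganglion) over a circular region in a few seconds. Ligand-evoked neuronal
activity does not produce a new band; it shifts the relative intensities of
existing bands — nucleic-acid, phosphate, ribose and lipid vibrations at
740, 994, 1121 and 2848 cm⁻¹ are the strongest markers, with a weaker
contribution from the amide I / C=C region (1592–1668 cm⁻¹). Detecting
activity is therefore a small-effect, high-dimensional classification
problem: ~1200 correlated intensity channels, a few dozen spectra per
condition, and an effect that lives in a handful of narrow bands on top of
a fluorescence background several times larger than any band.

The analysis chain implemented here mirrors standard chemometric practice
for that regime:

1. **Preprocess** each spectrum into a comparable, scale-free form
   (smooth, remove background, vector-normalize a fixed window).
2. **Reduce** to five latent dimensions, unsupervised (PCA) for
   exploration and cross-validated classification, supervised (PLS-DA) for
   the activity read-out.
3. **Binomialize** the five PLS scores with a Mahalanobis nearest-centroid
   rule so binary metrics (sensitivity, specificity, accuracy, ROC/AUC)
   are defined.
4. **Dose–response**: per-dose AUC against the 0 µM control, and a
   Williams-type monotone trend test on a scalar response.

Because no measured spectra are deposited, every statistical property of
this chain is validated against a synthetic generator whose ground truth is
known exactly. The generator is first-class, tested code, not a fixture.

# The synthetic generator: what it emulates

`syntheticDesign()` encodes the study conditions:

- **Bands.** Lorentzian (Cauchy) unit-height profiles at the band positions
  observed in cultured neurons (748, 1000/1001, 1126, 1301, 1337, 1447,
  1585, 1660, 2930 cm⁻¹) plus the response markers (740, 994, 1121,
  2848 cm⁻¹). A Lorentzian is the standard lineshape for an isolated Raman
  band; no instrument broadening model is layered on top. Widths are
  10–40 cm⁻¹ FWHM (narrow fingerprint bands, broad CH-stretch region);
  amplitudes are arbitrary units chosen so the strongest bands
  (phenylalanine 1001, CH₂ 2930) dominate, as in cell spectra.
- **Ligand effect.** Multiplicative: at full effect a marker band's
  amplitude is scaled by its `effect_multiplier` (default 1.5 for the four
  markers, 1.2 for the amide-region band, 1.0 elsewhere). The fractional
  effect at dose c follows a Hill curve E_max·cʰ/(EC₅₀ʰ + cʰ) with defaults
  E_max = 1, EC₅₀ = 0.5 µM, h = 1, chosen once so that the experimental
  dose grid (0, 0.05, 0.5, 5, 50, 500 µM) spans from ~9% effect at
  0.05 µM to saturation at ≥5 µM — reproducing the qualitative finding that
  doses of 5 µM and above are maximally discriminable from control. The
  magnitude 1.5 is an assumption (intensity-scale effect sizes are not
  published), fixed before any test was run and not revisited.
- **Background and noise.** An order-4 polynomial fluorescence baseline
  (positive, slowly varying, ~5× the band scale) — deliberately inside the
  model class of the baseline corrector so recovery tests have a clean
  oracle. Noise is Gaussian with standard deviation
  `noise_scale · sqrt(signal + 1)`, a shot-noise proxy (variance grows with
  intensity, floor of 1 count); default `noise_scale = 0.02`.
- **Cosmic rays.** Poisson-counted single-pixel positive spikes
  (`spike_rate` per spectrum, amplitude 5–50 a.u.). The default rate is 0:
  the default conditions model a clean acquisition, and despiking is
  correspondingly off by default; both are exposed for robustness
  experiments.
- **Group sizes.** 30 spectra per condition (`n_per_group`), matching the
  reported experiments; ganglion mode averages `k_cells = 10` single-cell
  draws per spectrum, which shrinks residual noise by ~1/√10 and emulates a
  population measurement.
- **Calcium traces** (`calciumDesign()`): frames at 0.8 s⁻¹, stimulation at
  80 s, 20 cells, a post-stimulus rise whose fold size is
  1 + (peak_fold − 1)·effect with log-normal cell-to-cell variability
  (sdlog 0.25), exponential decay (τ = 60 s), and 2% frame noise.
  `calcium_present = FALSE` forces zero effect — the calcium-free null in
  which the ligand response must vanish. Peak fold at full effect defaults
  to 2.5 so that saturating doses drive nearly all cells past the strict
  1.5-fold responder threshold while the null stays near zero responders.

What the generator does **not** emulate: band-position shifts, Fano or
asymmetric lineshapes, correlated (pink) detector noise, water/medium
background structure, focus drift, cell-to-cell biological covariance
beyond independent amplitude noise, or photobleaching of the fluorescence
background within an exposure. Passing tests therefore demonstrate that
the analysis chain is correct and calibrated under its stated assumptions,
not that real spectra will separate this cleanly; with real data the
preprocessing residuals and the effect size, not the machinery, become the
limiting factors.

# Preprocessing: parameters and numerical choices

`preprocessConfig()` defaults, in pipeline order:

| stage | parameter | default | rationale |
|---|---|---|---|
| despike | `despike`, `despike_z`, `despike_window` | off, z = 8, 5 pt | single-pixel spikes are orders of magnitude above shot noise; z = 8 on a running-median residual (robust SD = 1.4826·MAD) never triggers on band shoulders when noise is present |
| smoothing | `sg_window`, `sg_polyorder` | 11 pt, order 2 | order 2 is the stated protocol; the window is unstated, 11 points (~20 cm⁻¹) smooths noise without flattening the narrowest ~10 cm⁻¹ bands |
| baseline | `baseline_order`, `baseline_max_iter`, `baseline_tol` | 4, 100, 1e-4 | order 4 is the stated protocol; see below for the iteration scheme |
| normalize | `norm_range_cm1` | 600–2980 cm⁻¹ | stated protocol; L2 ("vector") norm over the cropped range, and all downstream analysis uses only that range |

**Iterative baseline.** A plain order-4 least-squares fit is biased upward
by the bands, so the corrector uses the clipped-refit (ModPoly-style)
scheme: fit, clip the working spectrum to the fit, refit, repeat. The fit
uses an orthonormal polynomial basis (QR of the Vandermonde matrix on the
grid mapped to [−1, 1]) for conditioning. Convergence is declared when the
baseline changes by less than `baseline_tol` (relative to the spectrum
maximum) in one iteration. The per-iteration change of this scheme decays
roughly harmonically, so a very tight tolerance is unreachable in any
reasonable iteration budget; 1e-4 stops when the baseline is stable to
0.01% of the spectrum scale, which is far below the normalization noise
floor, and a second pass over corrected output changes it by less than
1e-13 of scale when run to depth (the idempotence property the tests
check). Non-convergence yields the last iterate with a warning, never an
error, so one stubborn spectrum cannot abort a batch.

**Order of operations.** Smooth → baseline → crop+normalize is fixed; the
protocol source does not state whether normalization precedes cropping, so
this package defines the norm over the cropped window (the alternative is a
configuration away via `norm_range_cm1`). The whole pipeline is invariant
to uniform intensity rescaling of the input, which the tests assert.

**Degenerate inputs.** A spectrum that is identically zero over the
normalization window is an error (not a silent NaN row); despiking that
wants to alter more than 5% of points is an error (a broken spectrum, not
cosmic rays); pipeline errors are annotated with the failing row index.

# Chemometrics: conventions and honesty guarantees

- **PCA** is a column-mean-centred SVD. Signs are fixed (largest-magnitude
  loading element positive) so results are platform-reproducible.
  Explained variance ratios are non-increasing and sum to ≤1 by
  construction; the degenerate all-identical-rows case returns zero EVR
  rather than NaN.
- **Cross-validated classification** (`kfoldPCAClassify`) is fold-honest:
  the PCA is fitted per fold on training rows only and both partitions are
  projected through that fold's model. The per-fold PCA centres are
  returned so tests can audit that no all-data fit leaked in. The
  classifier on the scores is a linear-kernel SVM (a delegated
  maximum-margin solver); its contract — linear decision function trained
  on training scores only — is what the tests pin down. Folds are
  stratified by class; a fold whose training set loses a class is an
  explicit stratification error.
- **PLS-DA** is NIPALS PLS1 on a {0, 1} indicator (second factor level
  codes 1), five components by default. With a univariate response each
  weight vector is the deflated cross-covariance X'y, normalised — no inner
  iteration is needed, and successive score vectors are exactly orthogonal
  in exact arithmetic (asserted to 1e-6 relative). Components whose weight
  norm falls below 1e-12 are truncated rather than fitted as noise.
- **Mahalanobis binomialization** uses the pooled within-class covariance
  of the five training-score dimensions plus a ridge (default
  1e-6·trace/5). With as few as 16 spectra per class and 5 dimensions a
  per-class covariance is unstable, and an exactly singular pooled
  covariance (e.g. scores confined to a subspace) must fail loudly: with
  `ridge_lambda = 0` a singular matrix raises an error instructing a
  positive ridge. Distances are reported unsquared; the continuous ROC
  score is d(class₀) − d(class₁), the canonical distance-difference score
  (the binary rule never names a continuous score, so this is this
  package's explicit choice). Ties in the binary call go to the first
  class.
- **ROC/AUC** sweeps thresholds over the unique scores; tied scores move
  the curve diagonally so the trapezoidal AUC equals the Mann–Whitney
  statistic P(s₊ > s₋) + ½P(tie), which the tests verify against brute
  force to 1e-12 and against an independent implementation (pROC).
- **Evaluation protocols.** The protocol source mentions three
  inconsistent schemes — ten-fold cross-validation, five repeats, and a
  single 80/20 split. All are available rather than one being guessed:
  `plsdaEvaluate(train_fraction = 0.8)` for the split (an 80/20 split that
  loses a class is redrawn once, then errors), `kfoldPCAClassify(k = ...)`
  for k-fold, and both are seeded so repeats are a loop away. The reported
  five PC contributions are returned in full; selecting which PC axes to
  display is left to the user.

# Dose–response statistics

ΔF/F uses the pre-stimulation frames as baseline F, reports per-frame
(F(t) − F)/F and the peak post-stimulation fold max F(t)/F; the responder
rule is strictly greater than 1.5-fold. The two-group test is Student's
pooled-variance t (as named in the protocol, not Welch); multi-group
comparisons use classical one-way ANOVA with Tukey HSD delegated to the
standard implementation.

The trend test is a Williams-type step-down procedure: isotonic
(pool-adjacent-violators, n-weighted) estimates of the treated-group means,
the statistic t̄ᵢ = (µ̂ᵢ − ȳ₀)/√(s²(1/nᵢ + 1/n₀)) with s² the pooled ANOVA
variance, and significance at dose i only if every higher dose is also
significant (closed testing). Critical values are obtained by seeded
Monte-Carlo simulation of the matching null design (same n-structure, same
isotonic procedure, variance re-estimated per replicate) rather than from
printed tables: tables cover few (k, n, df) combinations, while simulation
generalises to any design and is itself testable — the suite checks that
the null rejection rate at the top dose sits within Monte-Carlo error of
α = 0.05. The t̄ (amalgamated-mean) variant was chosen over ū; the source
protocol does not say which was used. Default 10 000 null replicates per
critical value; zero pooled variance is an explicit error.

# Reproducibility machinery

Every generator is a pure function of (design, seed): the RNG state is
saved, seeded and restored around each draw, so generation never perturbs
the caller's stream. `runPipeline()` fans one global seed out to stage
seeds via a deterministic string hash (`stageSeed`), writes metrics JSON,
score CSVs and a manifest (config echo, config hash, seeds, timings), and
re-running a config reproduces all numeric outputs byte-identically — the
tests compare the emitted files. Configs round-trip losslessly through
YAML, and validation reports the offending field by name.

# Problem sizes used by the test suite

The suite exercises the full study designs at their native sizes — 30 + 30
spectra on the 1533-point instrument grid for the two-class experiments and
6 × 30 for the dose series — across 10 generator seeds, with 20 000
Monte-Carlo replicates behind the Williams critical value and 2000
replicates for its calibration check; the whole suite completes in well
under a minute on one core. These sizes are the package's chosen balance
between statistical resolution and a suite a developer will actually run;
the same code paths accept arbitrarily larger designs.

# Known limitations

- Binary classification only; the dose series is handled one-vs-control,
  not as multi-class PLS-DA, and VIP-style variable selection is out of
  scope.
- The calibration map is a degree-≤2 polynomial, monotone over the anchor
  span (±10%); strong nonlinear axis distortions outside that span are
  extrapolated and unchecked.
- The JCAMP-DX reader covers the uncompressed (X++(Y..Y)) AFFN dialect with
  XFACTOR/YFACTOR only — no SQZ/DIF packing, no vendor binary formats, no
  hyperspectral cubes.
- The despiker assumes shot noise is present; on strictly noiseless input
  its robust scale collapses and band shoulders can be flagged, which is
  why it is off by default and errors beyond 5% flagged points.
- The geometry module is closed-form bookkeeping (θ = D/2L, spot size);
  it does not simulate the spiral trajectory, laser power or detector
  physics, and the number of spiral passes per exposure is not derivable
  from the published parameters.
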