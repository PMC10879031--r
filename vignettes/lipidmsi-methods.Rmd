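---
title: "Methods: spatial lipidomics analysis of arterial MALDI-MSI data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial lipidomics analysis of arterial MALDI-MSI data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmsi)
```

# Scope and model

`lipidmsi` analyses MALDI mass spectrometry imaging (MSI) data of arterial
cross-sections: centroid spectra acquired per pixel (typically 45 um
pixels over m/z 300-1200, one imzML file per section and ionization mode),
together with histology-derived segmentation masks (myocardium,
periadventitial adipose tissue, artery; within advanced plaque: necrotic
core and inflammatory-cell regions). The pipeline runs: peak picking and
deisotoping; cross-section feature consolidation with a prevalence
filter; exact-mass lipid annotation with adducts; landmark-based
registration of the histology masks onto the MSI grid; per-segment mean
and 99th-percentile ("p99") spectra; non-negative matrix factorization
(NMF) of the pixel-by-feature matrix; OPLS-DA discrimination of disease
stages with a cross-validation/permutation validation suite; and a
top-intensity-pixel colocalization statistic between ion images and
histological regions.

Because arterial MSI studies rarely deposit raw data, the package ships a
ground-truth phantom generator. All quantitative guarantees in the test
suite and in `scripts/acceptance.R` are statements about these phantoms,
not about any instrument dataset.

# The synthetic phantom and what it does (and does not) emulate

`make_phantom()` builds an arterial cross-section at toy scale (36 x 36
pixels by default) from concentric annuli: a TAG/DAG-rich tunica media, a
PC/SM-rich intima/plaque, and, in advanced disease, an eccentric
necrotic-core ellipse plus small inflammatory blobs. In negative mode the
wall carries a PI(38:4)-driven signature and the core a
CerPE(36:1)-driven one. Each region plants a fixed set of (species,
adduct, intensity) triples; pixel spectra are the region signature times a
spatial weight (1 inside, a `bleed` fraction, default 0.1, in the
one-pixel neighbourhood), plus isotopologue peaks and noise, clipped at
zero. Three modelling choices matter downstream:

* **Isotopes.** Two isotopologues per species: M+1 at `0.0109 x carbon
  count` relative abundance and M+2 at half its square. This is the
  first-order binomial approximation for carbon; it is adequate to
  exercise deisotoping and deliberately not a full isotope-pattern
  computation.
* **Noise.** Relative Gaussian noise on every peak intensity (sd =
  `noise_sd` times the peak's clean intensity, default 0.05) plus
  spurious chemical-noise peaks with uniform m/z and bounded uniform
  intensity (mean 10 per pixel, max 5 units against planted bases of
  40-120). `noise_sd = 0` switches all noise off. The instrument noise of
  real TOF acquisitions is not characterized quantitatively anywhere we
  could anchor to, so these levels are free parameters chosen once to be
  plausible: strong enough to create false peaks for the SNR filter,
  weak enough that region signatures stay identifiable.
* **Replacement semantics.** A necrotic core replaces the plaque
  signature at its pixels (necrosis destroys the underlying tissue), so
  pure-core pixels exist and the core pattern is a recoverable NMF
  component. Inflammatory foci share the advanced signature at spatial
  weight 0.7 — small cell-scale structures carry weaker signal, which
  reproduces their lower colocalization percentages.

`make_cohort()` emulates a 17-section study graded healthy (6), mild (6)
and advanced (5). Healthy and mild differ only in intimal thickness;
advanced sections add the core/inflammatory regions whose species
intensities scale with `effect_size`. At `effect_size = 0` the advanced
lesion is absent altogether and an "advanced" section degenerates to the
mild phenotype, making the classes exactly exchangeable — the degenerate
case the calibration tests rely on. Per-section log-normal species
multipliers (`section_cv = 0.15`) provide within-class biological
variability. The phantoms do **not** emulate ionization suppression,
matrix clusters, profile-mode peak shapes, mass-calibration drift or 3-D
tissue effects; passing tests therefore demonstrate the correctness of
the algorithms under known ground truth, not robustness to every artefact
of real acquisitions.

# Spectral processing

**Peak picking** retains local maxima (within half a resolution element,
`mz / 20000` by default) whose intensity reaches `max(intensity_min,
snr_min x noise)`, with the noise level estimated as the median absolute
deviation of the spectrum's intensities scaled by 1.4826. The default
`snr_min = 3` keeps the false-positive rate on pure chemical noise below
5% per spectrum under the generator's bounded-intensity noise model.

**Deisotoping** walks the peak list in ascending m/z and removes any peak
sitting at 1-3 C13 spacings (1.00335 Da, tolerance `iso_tol_da = 0.01`)
above a retained peak, provided its intensity does not exceed the
retained peak's isotope ceiling `I x r^k / k!` with `r = 0.0109 x
carbons` and carbons estimated as `0.066 x m/z`; a `margin` factor
(default 1.5) absorbs intensity noise. The intensity ceiling is what
protects genuine neighbours — e.g. a CE(18:1) monoisotopic peak lies only
9 mDa off the M+2 position of CE(18:2), but is far too intense to be its
isotope. The operation is idempotent.

**Consolidation** pools all sections' peaks and forms features by
single-linkage gap clustering at `mz_tol_ppm = 20` (chosen for a
resolution-20,000 TOF; configurable), with each feature's m/z the
intensity-weighted mean of its members. "Present in a section" means the
cluster contains at least one peak of that section; a pixel with no
matching peak contributes intensity 0 (no imputation). The **prevalence
filter** then keeps features present in at least `min_sections` sections
(default 5, the "5 of 17" design rule).

Spectra are not normalized by default (TIC or otherwise); intensities
enter downstream statistics as stored, and any normalization is left to
the caller before assembly.

# Annotation

Features are matched against a reference table by exact mass under each
polarity's adduct set ([M+H]+, [M+Na]+, [M+K]+ positive; [M-H]- negative;
singly charged only, the lipid MALDI regime) within `ppm_max = 15`. All
candidates are reported ranked by |ppm error| — sum-composition
annotation cannot resolve isobars (e.g. LPC(16:0) and PC(O-16:0) share an
elemental formula), so no winner is forced. An optional confirmation pass
(`confirm_with_high_accuracy()`, default 3 ppm) emulates follow-up
high-resolution measurements. The bundled table
(`inst/extdata/lipid_reference_synthetic.csv`) is synthetic: ~170
sum-composition species across the sterol, glycerolipid,
glycerophospholipid and sphingolipid classes seen in arterial lipidomics,
generated from class composition templates (`lipid_formula()`) and
verified against textbook masses; it stands in for a database download
and is regenerated in code by `build_reference_table()`. Which adducts a
class actually forms is matrix-dependent and not modelled; the default
adduct sets are a recorded assumption.

# Registration and segment spectra

Histology masks are registered by a similarity transform restricted to
translation and scaling (`fit_similarity_transform()`), the closed-form
least-squares solution on landmark pairs; rotation is available behind a
flag but off by default. Labels are projected onto the MSI grid by
nearest-neighbour lookup through the inverse transform — labels are
categorical, so no interpolation — and out-of-field pixels become
background. Per segment, the package computes the mean and the 99th
percentile of pixel intensities per feature. The percentile uses linear
interpolation between order statistics (R type 7; intensities 1..100 give
p99 = 99.01); the convention is recorded in the output because several
conventions exist. The p99 statistic is read here as "the 99th percentile
of per-pixel intensities per feature within the segment", the natural
robust-maximum reading of a "99th percentile max spectrum".

# NMF and rank selection

`run_nmf()` factorizes the non-negative pixels x features matrix with
Lee-Seung multiplicative updates (MU) by default, chosen because the
Frobenius objective is provably non-increasing — a property the test
suite asserts numerically. MU converges slowly near exact factorizations
and can stall in poor local minima, so a HALS (hierarchical alternating
least squares) update is available via `method = "hals"` together with
`n_restarts`; on noiseless phantoms HALS reaches relative reconstruction
errors at machine precision where MU plateaus around 1e-5. Initialization
is uniform random scaled by `sqrt(mean(X)/k)`, fully seeded. On return, H
rows are scaled to unit maximum with the scale moved into W, leaving the
product unchanged.

The rank is chosen by a K-means criterion (`select_rank()`): K-means
(k-means++ seeding, 10 restarts) on L2-row-normalized pixel spectra for
each candidate rank, keeping the rank with the highest mean silhouette;
ties resolve to the smallest rank. Silhouette was chosen as the K-means
quality measure because it is bounded, scale-free and penalizes both
merged and split clusters; elbow and gap statistics are reasonable
alternatives but need extra conventions. Factorization is run jointly
over the concatenated pixels of all sections, and separately for
whole-tissue and artery-only pixel sets; the silhouette computation
subsamples to 2000 pixels (deterministically, per seed) to bound the
distance matrix.

# OPLS-DA and its validation suite

The two-class discriminant model is OPLS in the Trygg-Wold formulation:
`n_ortho` components of class-orthogonal variation are deflated from X,
then a single predictive component is fitted against the dummy-coded
response. With `n_ortho = 0` the predictive scores equal the first PLS1
component — asserted to 1e-8 against an independent NIPALS implementation
in the tests. Observations are the per-segment p99 intensities,
unit-variance scaled after mean centring (the common chemometrics
default; Pareto and centring-only are available). Multi-class tissue
models (myocardium / PVAT / artery) are one-vs-rest wrappers, and
myocardium-specific features can be excluded from subsequent artery
models via the coefficients of the myocardium-vs-rest model
(`exclude_features_by_coefficient()`, empirical quantile of the positive
coefficients, so the exclusion set shrinks to empty as q approaches 1).

Model quality is reported as R2Y (training explained class variance) and
Q2 from sevenfold cross-validation with stratified venetian-blind folds:
observations are ordered by class and seed-permuted index and dealt
cyclically into folds, so the assignment is deterministic given the seed
and every training set keeps both classes (violations raise an error
rather than silently re-stratifying). `Q2 = 1 - PRESS / SS_tot` with the
total corrected sum of squares of the dummy response. The number of
orthogonal components can be chosen automatically as the largest value
whose marginal Q2 gain is at least 0.01.

**CV-ANOVA** tests the model by an F statistic on the cross-validated
residuals: `F = ((SS_tot - PRESS)/df1) / (PRESS/df2)` with `df1` the
number of model components and `df2 = n - df1 - 1`; `PRESS >= SS_tot`
yields p = 1 by definition. A consequence worth stating plainly: under
the null hypothesis the cross-validated Q2 is negative most of the time
(that is exactly what "no predictive ability" looks like), so the null
distribution of this p-value has a large atom at 1 and is *not* uniform —
the test is conservative, never anticonservative. The test suite measures
this honestly: the null rejection rate at the 5% level is about 1.5%, and
the measured atom mass (~0.87) is reported by the acceptance script. The
**permutation test** refits the model under `n_perm` label permutations
and reports `p = (1 + #{Q2_perm >= Q2_obs}) / (1 + n_perm)`, bounded
below by `1/(1+n_perm)`.

**VIP** is computed over the predictive component only,
`VIP_j = sqrt(p) |w_j| / ||w||`, whose squares average to exactly 1;
features with VIP > 1.0 are flagged influential. The predictive-only
variant is used because orthogonal components are, by construction,
unrelated to class separation; a total-model VIP would dilute the
discrimination signal.

# Colocalization

For each feature, the top 10% most intense pixels *within the artery
segmentation of the section under study* are selected — exactly
`ceiling(fraction x n)` pixels, ties broken by row-major pixel order so
the mask is deterministic — and, for each histological region, the
percentage of region pixels inside that mask is reported. The fraction is
taken per section over artery pixels (whether the original procedure
thresholded over artery or all tissue pixels is not stated; artery-only
is our recorded default, consistent with plaque-focused questions). An
empirical null places an equal-sized random pixel set inside the same
mask (`n_null` draws, default 1000), giving a baseline expectation of
about `100 x fraction` percent and an empirical p-value. Two exact
identities are asserted in the tests: overlap is invariant under
monotone intensity transforms, and over any partition of the mask the
region-size-weighted overlaps sum to the top-mask size.

# Pipeline, determinism and problem sizes

`run_pipeline()` executes the stages in study order (ingest, peaks,
deisotope, consolidate, prevalence filter, annotate, register, segment,
NMF whole-tissue then artery-only, tissue OPLS-DA and
myocardium-feature exclusion, artery PCA and two-group OPLS-DA with the
validation suite, colocalization) and writes CSV/JSON artifacts plus a
provenance log of all parameters and seeds. Defaults equal the
study-convention values (SNR 3, 20 ppm, 5-section prevalence, 15 ppm
annotation, 10% fraction, 7 folds, VIP 1.0). Every random step is seeded
from the config, and reruns produce byte-identical numeric artifacts (a
test asserts this).

The bundled analyses run at deliberately small problem sizes — 36 x 36 to
36 x 48 pixel sections, 16-30 planted species, cohorts of 4-17 sections,
200-500 Monte-Carlo draws — chosen so the whole suite and the acceptance
script each complete in minutes on a single core while still exercising
every code path at the study's design (17 sections, 6/6/5 classes, 12 vs
5 grouping).

# Known limitations

* Exact-mass annotation reports candidates, not identifications; isobaric
  overlaps are flagged, not resolved, and MS/MS is out of scope.
* The imzML writer always stores 64-bit uncompressed arrays; compressed
  or 32-bit files are read but not written.
* CV-ANOVA p-values are conservative under the null (see above); treat
  them as a significance screen, not as calibrated tail probabilities.
* The rank-selection silhouette is computed on a pixel subsample for
  large images; pathological cases where the optimal rank hinges on a few
  pixels could in principle be missed.
* No batch/section normalization is implemented; section-to-section
  intensity drift must be handled upstream or absorbed by the
  unit-variance scaling of the observation matrix.
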