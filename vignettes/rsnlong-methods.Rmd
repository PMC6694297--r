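---
title: "Longitudinal resting-state network analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal resting-state network analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `rsnlong`, the tunable
parameters and their defaults, what the synthetic cohort generator does and
does not emulate, and the numerical decisions taken where the design was
genuinely open. It states no empirical result beyond what the package's
test suite and `scripts/acceptance.R` themselves compute.

## The analysis model

The pipeline targets a two-group (control vs transgenic), five-timepoint
longitudinal rs-fMRI design. Each acquisition is a 4D volume series on a
common reference grid with a brain mask and a six-column rigid-body motion
table; registration and distortion correction are assumed already done.

**Preprocessing** is applied in a fixed order: discard the first
`n_discard = 5` volumes (magnetisation steady state), per-volume Gaussian
smoothing at `fwhm_mm = 1.2`, OLS removal of a linear trend and the six
motion regressors, voxelwise z-scoring, and a 0.01–0.1 Hz zero-phase FIR
band-pass built from a Hamming window. Only mask voxels are ever touched.
The band-pass comes after z-scoring and the series is not re-standardised
afterwards, so later amplitude measurements retain the filter's effect.

**Group ICA.** All preprocessed acquisitions are concatenated along time
(per-voxel, per-block variance normalisation on by default — standard for
temporal concatenation, preventing any acquisition from dominating). The
concatenated matrix is reduced by PCA (eigendecomposition of the smaller
Gram matrix) to a fixed order and unmixed by fixed-point ICA with the
logcosh contrast and symmetric decorrelation, treating voxels as samples so
the estimated sources are spatial maps. Maps are z-scored over mask voxels;
signs are fixed so map skewness is non-negative; components are ordered by
explained variance. Component labels come from Dice overlap between the
`|z| > 2.3` thresholded maps and labelled templates, assigned greedily
(ties to the lower component index), with a configurable per-label quota —
the somatosensory system classically takes two components.

**Dual regression** maps the group components back to individuals: stage 1
fits each volume's voxel vector on the group maps (plus intercept), giving
a `T x K` time-series matrix; stage 2 fits each voxel's series on those
time-series (plus intercept), giving subject beta maps that are spatially
standardised into z-maps. Design normalisation of the stage-1 series before
stage 2 is off by default, so the amplitude metric and stage 2 read the
same series; the normalised variant is available by flag. Subject z-maps
are spatial standardisations of the beta maps rather than per-voxel
t-to-z conversions: the downstream shape metric uses a pooled z > 2.3 cut,
and no per-voxel inference is performed anywhere in the pipeline.

**Metrics.** Amplitude is the sample SD (denominator `T−1`) of a network's
stage-1 series; shape is the mean of the subject z-map values strictly
above `z_thresh = 2.3`, and is *missing* (never zero) when no voxel
qualifies — missing shapes propagate by row-wise exclusion, never
imputation. Between-network connectivity is the Pearson correlation of
stage-1 series pairs. Thresholding for shape uses the subject's own map
(the closest reading of the method); masking by the group map instead is
available by flag.

**Subnetworks.** A second ICA at high order decomposes the cohort; a
high-order component is assigned to a parent network (typically the DMN)
iff its concatenated group time-course correlates with the parent's above
`r_thresh = 0.4` *and* the two `z > 2.3` maps share more than
`overlap_thresh = 250` voxels — both criteria jointly. Matching is done
once at cohort level (the group time-courses), since components are
identified once for the whole cohort, not per subject. Signed correlation
is used ("high temporal correlation" is read as positive co-activation);
absolute-value matching is a flag. Within-network cohesion is the mean of
all pairwise correlations of a subject's subnetwork series.

**Statistics.** For each network and metric the mixed model

\[ y_s = \beta_0 + \beta_1\,\mathrm{group} + \beta_2\,\mathrm{age} +
\beta_3\,\mathrm{group}\times\mathrm{age} + \beta_{4,s} + \xi \]

is fitted by REML with a subject random intercept; group is coded 0/1
(control/transgenic) and age is in months, uncentered by default (centering
changes only the intercept and group-term interpretation and is available
as an option). When the interaction is significant (p < 0.05) the groups
are refitted separately with age as the only fixed effect. Per-timepoint
group differences use Kruskal–Wallis tests with Benjamini–Hochberg
correction *across timepoints within one network-by-metric family* — the
family matching the per-network presentation of such results; the family is
configurable since other choices are defensible. Tiers follow adjusted
p < 0.05 (significant) and < 0.1 (tendency). Brain–behaviour association
uses Spearman rank correlation within group-by-timepoint strata, two-sided,
flagged at uncorrected p < 0.05, skipping strata under 4 subjects.
Correlation-valued responses are Fisher-z transformed before mixed-model
fitting and back-transformed for reporting (raw-r mode available).

### Fixed-effect p-values

Wald z tests are the simplest choice for mixed-model fixed effects, but at
these cohort sizes (6–10 subjects per group) they run anticonservative.
The default is therefore Satterthwaite degrees of freedom via `lmerTest`,
whose type-I calibration at exactly this design is verified by Monte-Carlo
in the test suite; `df = "wald"` remains available for comparison.

## The synthetic cohort generator

The generator exists so that every stage has a recoverable answer. Its
defaults *are* the study conditions: per-timepoint group sizes
(6, 10, 9, 9, 9 controls / 8, 9, 9, 9, 6 transgenics; 84 acquisitions),
per-group mean ages from ~5 to ~18 months with matching jitter SDs,
TR = 2 s. Ages are drawn with a single per-subject jitter scalar (clipped
at ±3 SD) so each subject's ages stay strictly increasing; they are stored
in months, the unit the mixed models use.

Signal model per acquisition:

* **Networks** are compact plateau blobs (a logistic radial profile
  truncated at 5% so support is finite), peak-normalised, placed by
  rejection sampling until pairwise spatial correlation is below 0.5. A
  plateau rather than a Gaussian peak keeps the whole blob core above a
  z-threshold after map standardisation, which is what makes voxel-count
  overlap criteria meaningful.
* **Sources** are band-limited Gaussian time courses built in the frequency
  domain (unit coefficients on DFT bins inside 0.01–0.08 Hz), standardised
  to zero mean, unit SD — so planted sources survive the pipeline's
  band-pass.
* **Amplitudes** follow `a = intercept + slope·age + b_{s,k} + η`, with a
  per-subject, per-network random intercept (`subject_sd = 0.1`) and a
  per-acquisition, per-network session fluctuation (`amp_resid_sd = 0.08`)
  — the generative counterparts of the mixed model's β4,s and ξ. Default
  trajectories: somatosensorial I/II rise at +0.03 units/month in controls
  and fall at −0.03 in transgenics (amplitude 1 at mid-cohort age);
  sensorimotor and DMN are flat in both groups, serving as null networks.
* **Motion** is a smoothed random walk in 6 rigid-body parameters; a rank-6
  spatio-temporal term couples it into the voxel signal
  (`motion_coupling = 0.1`) using the same motion table later regressed
  out, so nuisance regression is testable.
* **Noise** is voxelwise white Gaussian, `noise_sd = 0.5` against a mean
  planted amplitude of 1.
* **Behaviour**: a score that is a weighted sum of planted network
  amplitudes (default: somatosensorial I only) plus noise, mapped affinely
  to a positive trial count and a correct-response ratio clipped to [0, 1].
* **DMN subnetworks** (optional): the DMN is generated as several compact
  subcomponents whose courses share a common parent signal with weight
  0.8, so a low-order decomposition sees one merged DMN while a high-order
  one resolves the parts, with pairwise subnetwork correlation 0.64 and
  parent correlation ≈ 0.8 — comfortably above the 0.4 assignment
  threshold.

### Grid scale and voxel size

The default grid is 20 × 20 × 10 with 200 volumes — a desk-scale stand-in
for the native 64 × 64 × 34 × 600 protocol, which is available by passing
those dimensions. Voxel size is derived from the acquisition field of view
(25.6 × 25.6 × 20.4 mm), so the desk grid means *coarser voxels over the
same brain*: 1.28 × 1.28 × 2.04 mm, at which the 1.2 mm smoothing kernel is
sub-voxel, exactly as the native resolution makes it a 3-voxel kernel. This
consistency matters: at fine voxel sizes, heavy smoothing of a small grid
drives the local noise floor so low that voxelwise z-scoring saturates wide
skirts around each planted network, the sources lose their spatial sparsity
and no decomposition — this package's or any other's — can separate them.
The generator's validity range therefore requires a realistic noise floor
(`noise_sd` of roughly half the planted amplitude or more).

### What the generator does not emulate

No hemodynamic response convolution, no physiological noise spectra
(cardiac/respiratory), no scanner drift beyond the polynomial trend, no
anatomically shaped networks, no registration error. Passing tests
demonstrate that the pipeline's machinery recovers known structure under
this model; they cannot certify performance on real data with structured
noise and anatomical variability.

## Numerical choices

* **Band-pass design**: linear-phase FIR, Hamming window, length
  `4 / (transition width)` with the transition width taken as the lower
  band edge, capped at `T/3` taps and forced odd; applied centred
  (delay-compensated) with reflection padding, and the taps re-centred so
  the DC gain is exactly zero. Zero-phase behaviour matters because stage-1
  time-series are later correlated across networks.
* **Smoothing** is separable Gaussian convolution with edge
  renormalisation, restricted to the mask by normalised convolution
  (`G*(x·m) / G*(m)`), so no signal bleeds across the mask boundary.
  An edge-preserving intensity-weighted variant was deliberately not
  implemented: brightness-threshold heuristics add parameters the rest of
  the pipeline never exercises, and the Gaussian at the same FWHM preserves
  the testable surface.
* **Detrending order** is 1 (linear) by default; configurable.
* **Zero-variance voxels** are zeroed and flagged rather than propagating
  NaN into the decomposition.
* **ICA convergence**: strict tolerance 1e-6 with up to 1000 iterations and
  4 deterministic restarts. When the order exceeds the number of
  non-Gaussian sources, the Gaussian directions have no stable fixed point
  and the strict criterion is unattainable; the best iterate is then
  accepted at a relaxed tolerance of 1e-3 with a warning. A genuine failure
  (no iterate below 1e-3) is an error reporting the iteration count and
  tolerance.
* **Greedy matching ties** (template labelling): higher Dice wins; equal
  Dice goes to the lower component index.
* **Degenerate rank tests**: all-identical values give H = 0, p = 1,
  flagged.
* **Seeds**: every stochastic step takes an integer seed; child streams are
  derived arithmetically and kept below 2^31. Per-cohort quantities
  (session fluctuations) are drawn from a single stream per cohort rather
  than per-acquisition derived seeds — first draws from many linearly
  spaced seeds are measurably correlated, enough to bias Monte-Carlo
  calibration.

## Problem sizes used by the validation suite

Monte-Carlo validation runs at sizes chosen for a single desk CPU and
documented here as the package's own choices: OLS oracle equivalence on 100
random instances (V, T ≤ 50); ICA recovery over 20 seeds at V = 1500,
T = 200, 3–5 sources, SNR 2; mixed-model recovery on 100 metric-level
cohorts at the full reference group sizes and its type-I error on 500;
end-to-end detection over 25 imaging cohorts at half group sizes on the
20 × 20 × 10 grid with 150 volumes; subnetwork recovery on one
single-timepoint cohort at 52 × 52 × 24 — the scale at which a 250-voxel
overlap criterion is geometrically meaningful (on the 20 × 20 × 10 desk
grid, with ~1300 mask voxels, no pair of z-thresholded maps can share 250
voxels, so the absolute threshold from the native resolution forces the
larger mask).

## Known limitations

* The spatial ICA assumes sparsity-driven non-Gaussianity of network maps;
  heavily saturated or dense spatial sources (see the voxel-size note
  above) defeat it.
* Satterthwaite p-values are approximate; for very small groups (n < 4)
  the per-timepoint rank tests are more trustworthy than the mixed model.
* The subnetwork overlap criterion counts voxels, so its meaning scales
  with resolution; analyses at non-native grids should scale it or work at
  subnetwork scale.
* Checksums gate pipeline re-execution per stage; editing outputs in place
  while keeping byte length identical to a previous run defeats staleness
  detection only if the md5 also collides, which is not a realistic
  concern.
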