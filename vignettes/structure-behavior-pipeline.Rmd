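---
title: "Linking motor sequence learning to white-matter microstructure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking motor sequence learning to white-matter microstructure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmstdti)
```

# Overview

`tmstdti` implements a complete structure–behavior analysis for temporal
motor sequence learning: scoring of a temporal motor sequence task (TMST),
diffusion-tensor scalar maps, skeletonized voxelwise permutation inference
with threshold-free cluster enhancement (TFCE), radial/axial diffusivity
decomposition, and waypoint-constrained probabilistic tractography. Because
studies of this kind rarely deposit raw data, the package ships a
synthetic-data generator that emulates the task design and produces
crossing-fiber diffusion phantoms with known ground truth, so the entire
pipeline is testable end to end.

This vignette is the package's methodological record: the models, the
tunable parameters and their defaults, what the simulations do and do not
emulate, and the numerical choices made where the design was genuinely
open.

# The behavioral task and its scores

In the TMST a participant presses and releases a mouse button in synchrony
with a visually presented sequence of 10 elements — 5 short (300 ms) and 5
long (600 ms) blocks separated by a 300 ms inter-stimulus interval, in the
order S L L S L S S L S L. Practice is organized as 4 sequences per block,
4 blocks per run, 3 runs per day over 5 days: 240 trials and 15 runs in
total. Two scores are computed per run:

* **PCOR** (percent correct): the percentage of stimulus elements whose
  matched key press was initiated between 300 ms before stimulus onset and
  stimulus end, with a press duration under M + 2SD for short elements or
  over M − 2SD for long elements. M and SD are per-subject, per-day norms
  computed from that day's first (training) run, using the sample SD.
* **PSYN** (percent synchronization): per matched element, the absolute
  press–onset lag plus absolute release–offset lag, divided by the element
  duration; 100 minus the mean of these normalized lags.

Scoring operates on a response *stream*: responses are re-matched to
elements greedily in presentation order, each element taking the
still-unmatched response whose press time is nearest its onset among those
inside the admissible window. Per subject, **final performance** is the
score of the last run of day 5, and the **slope of improvement** is the
Pearson r between run index and run-mean score over the 15 runs (the
least-squares slope in score units per run is also reported, as the two
readings of an "r-value of the best-fit line" differ).

Aggregation conventions the original description leaves open, fixed here:

* PSYN is averaged per element, then per trial, then per run; unmatched
  elements contribute the maximal normalized lag of 100 (run scores are
  floored at 0). Matched-element lags are *not* capped, so any lag
  increase strictly lowers the score.
* Duration-criterion boundaries are strict (a duration exactly at
  M + 2SD fails). One guard exists for the degenerate perfect performer:
  with zero-SD norms, a duration exactly equal to the class mean passes —
  otherwise exact reproduction of every stimulus would score 0 rather
  than 100, contradicting what the scores are meant to measure. Whenever
  SD > 0 the guard is a no-op.
* "Training trials at the beginning of each day" is taken to be the first
  run of that day.
* A zero-variance run series has an undefined correlation; the slope is
  defined as 0 there (a flat learner neither improves nor worsens), with
  a warning.

## The behavioral generator

`generate_behavior_log()` simulates one subject's complete log. Responses
equal stimulus times plus Gaussian jitter whose SD follows the classic
exponential approach to asymptote in run index `k`:
`sd_k = sd_inf + (sd_1 - sd_inf) * exp(-rate * (k - 1))`. The asymptotic
jitter `sd_inf` is solved numerically from the profile's `asymptote_psyn`
so that the *expected* PSYN at convergence equals the asymptote, including
the contributions of key-press duration noise and of occasional
mis-ordered elements (the response reproduces the wrong duration class)
whose rate decays toward `1 - asymptote_pcor/100`. This makes the
generator's asymptote a calibrated quantity: at low jitter the recovered
final PSYN matches it to a fraction of a point, which the tests exploit.

The exponential form itself is a modeling choice — the original behavioral
report does not characterize individual learning curves — chosen because it
is the standard skill-acquisition law and its early segment is close to
linear, which is what the slope-of-improvement measure implicitly assumes.
Default profile values place cohorts near the reported group means (final
PSYN ≈ 70 ± 11, final PCOR ≈ 93 ± 7, ages 19–35, n = 13).

All draws are reproducible from `(seed, subject_id)`; the generator
restores the caller's RNG state.

# Diffusion phantoms

`simulate_dwi()` uses the standard multi-tensor forward model: per voxel,

    S(g, b) = S0 * ( sum_i f_i * exp(-b g' D_i g) + f_iso * exp(-b d_iso) )

with axially symmetric compartments `D_i = ad * u u' + rd * (I - u u')`.
The default phantom (`default_phantom()`) is a 16³ grid (2 mm voxels) with
two orthogonal tubes crossing near the center: a dominant "CST-like"
bundle along z (peak volume fraction 0.75) and a weaker "SLF-like" bundle
along y (peak 0.55), each with a Gaussian radial fraction profile
(SD = radius/1.5) so FA has a well-defined ridge at the tube center. The
remaining volume is isotropic (0.8 × 10⁻³ mm²/s); compartment diffusivities
default to ad = 1.7 × 10⁻³, rd = 0.3 × 10⁻³ mm²/s. The acquisition scheme
is one b = 0 volume plus 32 spherical-Fibonacci directions at
b = 1000 s/mm²; noise is Gaussian at SNR 30 by default (Rician available;
at this SNR the Gaussian approximation keeps the log-linear fit unbiased,
which the recovery tests rely on).

Cohorts (`generate_dwi_cohort()`) inject a structure–behavior association
through a latent per-subject `integrity` parameter: by default the target
bundle's radial compartment diffusivity is a linear function of integrity
(0.6 × 10⁻³ mm²/s per unit integrity), and the same integrity drives the
behavioral asymptotes — mirroring the hypothesis that synchronization
skill tracks association-fiber integrity expressed as radial diffusivity.
Setting the slope to 0 yields null cohorts in which structure varies only
by measurement noise.

A second link route scales the target bundle's volume *fraction*. Here a
subtlety discovered during development matters: the link must trade
fraction against the *other crossing bundle* (`preserve_total`), not
against the isotropic background — removing isotropic volume raises FA and
inverts the expected pattern. Moreover, at fraction parity the fitted FA
of an orthogonal crossing is at its *minimum*, so a linear perturbation of
relative fraction has no first-order FA effect; the fraction route
produces the expected signs only when the linked bundle is the weaker
population. That is also the anatomically relevant regime (an association
bundle crossing the dominant projection pathway), and it is the condition
the corresponding test constructs.

`crossing_fraction_sweep()` quantifies the underlying mechanism in a
single voxel: as the second orthogonal compartment grows from 0 to 0.5 of
the anisotropic volume, fitted FA falls strictly and fitted RD rises —
the core of the argument that a *negative* FA–behavior association can
reflect *greater* integrity of a crossing fiber population.

# Tensor fitting and scalar maps

`fit_tensor()` is ordinary log-linear least squares on `log(S/S0)` with
`S0` the mean of the b = 0 volumes and b = 0 rows excluded from the design;
a weighted (S²) variant is available. The estimator is exact for noiseless
data, which gives the test suite sharp oracles (round-trip recovery to
1 × 10⁻⁹ relative error). Non-positive samples are replaced by a small
epsilon before the log and flagged; negative eigenvalues are clamped to 0
after decomposition and flagged. FA is the normalized eigenvalue
dispersion; AD = λ₁ (diffusivity along the axis of greatest diffusion);
RD = (λ₂ + λ₃)/2 (mean of the two perpendicular axes); MD ≡ (AD + 2 RD)/3.

Eigendecomposition uses a vectorized analytic routine for symmetric 3×3
matrices (trigonometric solution of the characteristic cubic; eigenvectors
from products of shifted matrices), cross-checked against LAPACK in the
tests. This keeps whole-cohort fits at interactive speed, which the
permutation calibration (thousands of voxel-fits per cohort, hundreds of
cohorts) depends on. Exactly degenerate spectra fall back to a canonical
basis — irrelevant for rotation-invariant scalars and documented for
tractography determinism.

# Skeletonized permutation inference

`build_skeleton()` thins the group-mean FA map (threshold FA > 0.25, the
conventional cut restricting analysis to major tracts present in all
subjects) by directional non-maximum suppression. The suppression
direction is the offset of the FA-weighted center of gravity of the 3×3×3
neighborhood; where that offset vanishes — the voxel already sits at the
local center — the direction of strongest negative curvature of the
lightly presmoothed FA surface is used, and for tube-like ridges (both
perpendicular curvatures comparably negative) suppression is applied along
both, so a cylindrical bundle thins to its center line. A pure
Hessian-direction rule was tried first and rejected: beyond a Gaussian
ridge's inflection radius the most negative curvature turns tangential and
rim voxels survive as spurious sheet fragments. A small tolerance (10⁻³)
in the comparisons keeps plateau ties — a ridge running between voxel
centers — from being suppressed by interpolation asymmetry.

`project_to_skeleton()` samples each subject's map along the stored
perpendicular direction (half-voxel steps within ±`search_mm`, default
2 mm) and takes the maximum, absorbing small misalignments of the
subject's tract core; the argmax location is kept so AD/RD can be sampled
at the same place (`extract_roi(..., projections=)`). Both
provenance-based and plain-mask ROI extraction are provided, since either
reading of "extract from the same skeleton regions" is defensible.

`permutation_correlate()` computes, per voxel, the t statistic of the
regressor of interest in a GLM with nuisance covariates (age, optionally
gender), and performs Freedman–Lane permutation: residuals of the
nuisance-only model are row-permuted and the statistic map recomputed.
Freedman–Lane is the de-facto standard for GLM permutation with nuisance
covariates in this framework. Each map is TFCE-enhanced,

    tfce(v) = sum_h h^H * e(h, v)^E * dh,

with the canonical H = 2, E = 0.5, dh = max/100, and 26-connectivity
restricted to the analysis voxels (which *is* the skeleton neighborhood
for skeleton data). Family-wise corrected p-values come from the
permutation distribution of the image-wide maximum enhanced statistic,
with the never-zero convention p = (1 + #{null ≥ observed})/(1 + n_perm).
Defaults are 5000 permutations and α = 0.05; the tail is configurable
(two-sided by default; one-sided tails enhance the correspondingly signed
statistic). Zero-variance voxels are excluded and flagged; rank-deficient
designs are errors.

`gaussian_smooth()` (for VBM-style gray-matter analyses, which enter the
same permutation engine) is separable discrete Gaussian convolution
truncated at 4σ with boundary renormalization (a constant map is exactly
preserved; an interior impulse integrates to 1 within ~10⁻⁴). The σ = 4 mm
default corresponds to ≈ 9.4 mm FWHM.

## Calibration

The package's central statistical claim is that the engine controls the
family-wise error rate. `null_cohort_fwer()` measures it: 200 simulated
null cohorts (n = 13, link slope 0, 16³ phantom, 500 permutations each),
full skeleton + projection + permutation pipeline per cohort, fraction of
cohorts with any corrected p < 0.05. The regressor for these null cohorts
is the generative behavioral endpoint (the profile's asymptotic PSYN plus
run-level noise) — exchangeable with respect to the maps by construction,
which is the only property FWER depends on; this keeps 200-cohort
calibration at desk scale. Measured rates sit within binomial error of the
nominal 0.05 (the acceptance script recomputes this from scratch).

Problem sizes used throughout (16³ grids, 13 subjects, 500 permutations
for calibration, hundreds to thousands of streamline samples in tests) are
the package's chosen desk-scale study conditions; the defaults users see
(5000 permutations, 10,000 samples per seed voxel) match field practice.

# Probabilistic tractography

`track()` propagates streamline samples from every seed voxel (default
10,000 per voxel), bidirectionally (two opposite initial directions whose
combined trajectory forms one streamline), in steps of half a voxel,
along directions drawn from an angular dispersion model centered on the
local principal eigenvector, sign-aligned with the previous step. The
dispersion is a projected-Gaussian perturbation with concentration
`kappa * FA` — uncertainty grows where anisotropy is low — with
κ = ∞ tracking deterministically. Termination: grid exit, FA below 0.1,
curvature over 80° per step, or 2000 steps. A streamline is retained only
if it crosses *every* waypoint mask and touches *no* exclusion mask
(exclusion takes precedence in the bookkeeping, so launched =
retained + excluded + waypoint-failed exactly); retained streamlines
increment each visited voxel once, matching "particle count" semantics.
In voxels known from phantom ground truth to carry a second fiber
population, the propagation axis is drawn from either compartment with
probability proportional to volume fraction — reproducing crossing-region
branching without estimating a multi-fiber model, which is deliberately
out of scope.

`planar_mask()` builds the one-voxel-thick inclusion/exclusion planes;
mask placements are given as phantom-grid indices (a named configuration
replaces the original standard-space coordinates, since no registration
exists in a common-grid simulation). `average_and_threshold()` averages
visitation maps across subjects and zeroes voxels below 10% of the
maximum mean count, the conventional cut for anatomically plausible
tracts. On the crossing phantom, axial (superior/inferior) versus lateral
(anterior/posterior) target schemes recover visitation maps confined to
the correct respective bundles — the qualitative dissociation of
projection from association pathways.

# A worked cohort

```{r cohort, eval = FALSE}
spec <- default_phantom()
profiles <- simulate_cohort_profiles(n = 13, seed = 7)
cohort <- generate_dwi_cohort(spec, profiles, seed = 7)
behavior <- vapply(profiles, function(p) p$asymptote_psyn, 0)
ages <- vapply(profiles, function(p) p$age, 0)

ana <- cohort_skeleton_correlation(cohort$volumes, behavior, ages,
                                   n_permutations = 1000, seed = 7)
sum(ana$result$significant)   # voxels surviving corrected p < 0.05

sms <- ana$scalar_maps
fa <- extract_roi(lapply(sms, `[[`, "fa"), cohort$crossing_mask)
rd <- extract_roi(lapply(sms, `[[`, "rd"), cohort$crossing_mask)
partial_correlation(behavior, rd, ages)  # positive
partial_correlation(behavior, fa, ages)  # negative
```

With the default radial-diffusivity link, the skeleton voxels surviving
correction lie on the SLF-like bundle, the FA–behavior partial correlation
in the crossing region is negative and the RD–behavior partial correlation
positive — the qualitative pattern the pipeline exists to detect. (The
chunk is not evaluated at build time; the same computation runs in the
test suite.)

# What the simulations do not emulate

* No scanner artifacts: eddy currents, motion, susceptibility distortion,
  and their corrections are absent; subjects share one grid, so the
  registration and template-building stages of skeleton/VBM workflows are
  out of scope by design.
* Phantom anatomy is two straight orthogonal tubes, not brain geometry;
  bundle curvature, fanning, partial-volume with CSF, and multi-shell
  acquisition are not modeled.
* The behavioral generator draws independent Gaussian jitter per element;
  it does not model serial dependence, anticipation strategies, or missed
  responses beyond mis-ordered durations.
* Passing tests therefore demonstrate correctness of the *methods* under
  known ground truth — not that effect sizes from any particular empirical
  cohort would replicate; group-level statistics from real studies are
  outside what these simulations can certify.

# Known limitations

* The skeleton is a ridge heuristic faithful at phantom scale; it is not
  the published TBSS algorithm and makes no attempt at its distance-map
  projection machinery.
* The tractography orientation model is single-tensor plus dispersion
  (with optional ground-truth crossing information); it is not a Bayesian
  multi-fiber fit, so its uncertainty estimates are schematic.
* Permutation p-values are exact only with respect to the chosen scheme
  (Freedman–Lane, max-TFCE null); no attempt is made to numerically
  replicate any specific external implementation.
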