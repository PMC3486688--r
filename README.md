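# tmstdti

Structure–behavior analysis for temporal motor sequence learning with
diffusion MRI, as a tested, self-contained R package.

## The problem

Skilled motor performance varies widely across people, and part of that
variation tracks the microstructure of the white-matter pathways linking
sensorimotor regions. A standard way to study this is to correlate
behavioral measures from a temporal motor sequence task (TMST) — where
participants press and release a button in synchrony with a sequence of
short (300 ms) and long (600 ms) visual elements over 5 days of practice —
with voxelwise diffusion-tensor measures: fractional anisotropy (FA) on a
white-matter skeleton, decomposed into axial diffusivity (AD = λ₁) and
radial diffusivity (RD = (λ₂+λ₃)/2). Interpreting such correlations is
complicated by crossing fibers: where a second fiber population crosses a
tract, *greater* integrity of the crossing population can *lower* FA and
*raise* RD, so a negative FA–behavior correlation may actually signal
better-organized association fibers. Probabilistic tractography with
waypoint and exclusion masks is then needed to establish which pathways
cross the region.

`tmstdti` implements this entire analysis chain for researchers who want
to run it, teach it, or validate it against ground truth:

* **Behavior** — scoring of trial-level key-press logs into percent
  correct (PCOR: presses initiated within [onset − 300 ms, offset] with
  durations inside the M ± 2SD class criteria) and percent
  synchronization (PSYN: 100 − duration-normalized absolute onset/offset
  lags), plus final performance and slope-of-improvement (Pearson r of
  run means against run index across 15 runs).
* **Tensor** — log-linear tensor fitting, FA/MD/AD/RD maps, run averaging,
  NIfTI + FSL-dialect bval/bvec I/O.
* **Stats** — mean-FA skeletonization (FA > 0.25), perpendicular
  projection, voxelwise permutation partial-correlation (Freedman–Lane,
  nuisance covariates, threshold-free cluster enhancement, family-wise
  corrected p from the max-TFCE null), ROI extraction and partial
  correlations, Gaussian smoothing for VBM-style maps.
* **Tractography** — probabilistic streamline tracking with waypoint and
  exclusion planes, per-voxel particle counts, cross-subject averaging
  thresholded at 10% of maximum.
* **Synthetic data** — the full task design (10-element S L L S L S S L S L
  sequence; 4 × 4 × 3 × 5 = 240 trials) and multi-tensor crossing-fiber DWI
  phantoms with a latent per-subject `integrity` parameter that links
  structure to behavior with known ground truth.

## Worked example

Score a simulated learner, then run the skeletonized FA–behavior analysis
on a 13-subject phantom cohort in which the SLF-like bundle's radial
diffusivity increases with the subjects' latent skill:

```r
library(tmstdti)

design  <- tmst_design()
profile <- subject_profile("sub01", age = 24, asymptote_psyn = 78,
                           asymptote_pcor = 96)
log  <- generate_behavior_log(design, profile, seed = 42)
runs <- score_runs(log)
head(runs[, c("day", "run", "pcor", "psyn")], 3)
#>  day run   pcor     psyn
#>    1   1  98.75 39.64908
#>    1   2 100.00 46.56252
#>    1   3 100.00 55.63156
summarize_subject(runs)[, 1:5]
#>  subject final_pcor final_psyn pcor_slope psyn_slope
#>    sub01     94.375    77.4898 -0.7370883  0.8830942
```

The subject improves from PSYN ≈ 40 toward its asymptote of 78 (the
psyn_slope of 0.88 is the r-value of the best-fit line through the 15 run
means; PCOR starts near ceiling, so its slope is uninformative).

```r
spec     <- default_phantom()
profiles <- simulate_cohort_profiles(n = 13, seed = 7)
cohort   <- generate_dwi_cohort(spec, profiles, seed = 7)   # RD-behavior link
behavior <- vapply(profiles, function(p) p$asymptote_psyn, 0)
ages     <- vapply(profiles, function(p) p$age, 0)

ana <- cohort_skeleton_correlation(cohort$volumes, behavior, ages,
                                   n_permutations = 1000, seed = 7)
sum(ana$result$significant)
#> 24        # skeleton voxels with corrected p < 0.05, all on the SLF-like bundle

sms <- ana$scalar_maps
rd <- extract_roi(lapply(sms, `[[`, "rd"), cohort$crossing_mask)
fa <- extract_roi(lapply(sms, `[[`, "fa"), cohort$crossing_mask)
partial_correlation(behavior, rd, ages)$r   #  0.92
partial_correlation(behavior, fa, ages)$r   # -0.92
```

Behavior correlates *negatively* with FA and *positively* with RD in the
crossing region — the signature of a structure–behavior association
carried by the crossing association bundle — and the permutation engine
localizes it to the correct tract. Tractography then dissociates the two
pathways through the crossing:

```r
fit <- fit_tensor(cohort$volumes[[1]])
seed_mask <- array(FALSE, fit$dims); seed_mask[8:9, 8:9, 8:9] <- TRUE
vm <- track(fit, list(seed = seed_mask,
                      waypoints = list(planar_mask(fit$dims, "z", 3),
                                       planar_mask(fit$dims, "z", 14))),
            tracking_settings(samples_per_seed_voxel = 1000, seed = 1))
tract <- average_and_threshold(list(vm), fraction = 0.10)
```

See `vignettes/structure-behavior-pipeline.Rmd` for the full methods
account.

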