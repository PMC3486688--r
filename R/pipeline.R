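#' Skeletonized FA-behavior correlation pipeline for a simulated cohort
#'
#' Runs the full structure-behavior analysis on a cohort of DWI volumes:
#' per-subject tensor fit and scalar maps, group mean FA, skeleton
#' construction, projection of each subject's map onto the skeleton, and
#' voxelwise permutation partial-correlation with TFCE family-wise
#' correction.
#'
#' @param volumes list of `dwi_volume` objects (one per subject).
#' @param behavior per-subject regressor of interest (e.g. final PSYN).
#' @param covariates nuisance covariates (e.g. age), or `NULL`.
#' @param metric which scalar map to test (`"fa"`, `"rd"`, `"ad"`, `"md"`).
#' @param n_permutations,alpha,tail passed to [design_spec()].
#' @param fa_threshold skeleton threshold.
#' @param search_mm projection search half-width (mm).
#' @param seed integer seed for the permutation draws.
#' @return list with `result` (a `stat_result`), `skeleton`, `scalar_maps`
#'   (per subject), `projections`, and `mean_fa`.
#' @export
cohort_skeleton_correlation <- function(volumes, behavior, covariates = NULL,
                                        metric = "fa", n_permutations = 5000,
                                        alpha = 0.05, tail = "two-sided",
                                        fa_threshold = 0.25, search_mm = 2,
                                        seed = 1L) {
  sms <- lapply(volumes, function(v) scalar_maps(fit_tensor(v)))
  fa_maps <- lapply(sms, `[[`, "fa")
  mean_fa <- Reduce(`+`, fa_maps) / length(fa_maps)
  skel <- build_skeleton(mean_fa, fa_threshold = fa_threshold)
  voxel_mm <- volumes[[1]]$voxel_mm
  proj_fa <- project_cohort(fa_maps, skel, search_mm = search_mm,
                            voxel_mm = voxel_mm)
  Y <- if (identical(metric, "fa")) proj_fa$values else {
    do.call(rbind, lapply(seq_along(sms), function(s) {
      pts <- proj_fa$projections[[s]]$positions
      .interp3(sms[[s]][[metric]], pts)
    }))
  }
  des <- design_spec(behavior, covariates, n_permutations = n_permutations,
                     alpha = alpha, tail = tail)
  res <- permutation_correlate(Y, des, coords = skel$coords,
                               dims = skel$dims, seed = seed)
  list(result = res, skeleton = skel, scalar_maps = sms,
       projections = proj_fa$projections, mean_fa = mean_fa)
}

#' Family-wise error calibration on null cohorts
#'
#' Simulates cohorts with no structure-behavior link (`link slope = 0`),
#' runs the full skeleton + permutation-correlation pipeline on each, and
#' reports whether any voxel survived the corrected threshold. The
#' fraction of cohorts with any significant voxel estimates the empirical
#' family-wise false-positive rate of the engine at level `alpha`.
#'
#' @param n_cohorts number of simulated null cohorts.
#' @param n_subjects subjects per cohort.
#' @param n_permutations permutations per analysis.
#' @param alpha corrected level.
#' @param spec phantom specification (default crossing phantom).
#' @param scheme acquisition scheme.
#' @param seed integer base seed; cohort `i` derives its own seeds from it.
#' @param metric scalar map tested.
#' @return list with `any_significant` (logical per cohort), `fwer`, and
#'   `n_cohorts`.
#' @export
null_cohort_fwer <- function(n_cohorts = 200, n_subjects = 13,
                             n_permutations = 500, alpha = 0.05,
                             spec = default_phantom(),
                             scheme = default_scheme(), seed = 1L,
                             metric = "fa") {
  any_sig <- logical(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    cseed <- .seed_combine(seed, paste0("null-cohort-", i))
    profiles <- simulate_cohort_profiles(n_subjects, seed = cseed,
                                         behavior_link = 0)
    cohort <- generate_dwi_cohort(spec, profiles, scheme,
                                  link = list(bundle = "slf", param = "rd",
                                              slope = 0, ref = 0.5),
                                  seed = cseed)
    behavior <- .latent_final_psyn(profiles, seed = cseed)
    ages <- vapply(profiles, `[[`, 0, "age")
    ana <- cohort_skeleton_correlation(cohort$volumes, behavior, ages,
                                       metric = metric,
                                       n_permutations = n_permutations,
                                       alpha = alpha, seed = cseed)
    any_sig[i] <- any(ana$result$significant)
  }
  list(any_significant = any_sig, fwer = mean(any_sig), n_cohorts = n_cohorts)
}

# behavioral endpoint drawn from the generative model: the profile's
# asymptotic PSYN plus run-level measurement noise (the final run is one
# noisy realization of the asymptote)
.latent_final_psyn <- function(profiles, seed = 1L, run_noise_sd = 3) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.seed_combine(seed, "final-psyn"))
  vapply(profiles, function(p)
    p$asymptote_psyn + rnorm(1, 0, run_noise_sd), 0)
}

#' Linked-cohort association recovery
#'
#' Simulates a cohort in which the SLF-like bundle's radial compartment
#' diffusivity increases with the subjects' latent integrity (which also
#' drives behavioral skill), then measures the partial correlation
#' (controlling age) between behavior and mean FA / mean RD extracted from
#' the true crossing region. Recovers the qualitative headline pattern:
#' behavior negatively associated with FA and positively with RD in the
#' crossing region.
#'
#' @param seed integer seed.
#' @param n_subjects cohort size.
#' @param spec phantom specification.
#' @param scheme acquisition scheme.
#' @param link structure-behavior link passed to [generate_dwi_cohort()].
#' @return list with `r_fa`, `r_rd`, `p_fa`, `p_rd`, `behavior`,
#'   `fa_roi`, `rd_roi`.
#' @export
linked_cohort_associations <- function(seed = 1L, n_subjects = 13,
                                       spec = default_phantom(),
                                       scheme = default_scheme(),
                                       link = list(bundle = "slf", param = "rd",
                                                   slope = 0.6e-3, ref = 0.5)) {
  profiles <- simulate_cohort_profiles(n_subjects, seed = seed,
                                       behavior_link = 1)
  cohort <- generate_dwi_cohort(spec, profiles, scheme, link = link,
                                seed = seed)
  behavior <- .latent_final_psyn(profiles, seed = seed)
  ages <- vapply(profiles, `[[`, 0, "age")
  sms <- lapply(cohort$volumes, function(v) scalar_maps(fit_tensor(v)))
  roi <- cohort$crossing_mask
  fa_roi <- extract_roi(lapply(sms, `[[`, "fa"), roi)
  rd_roi <- extract_roi(lapply(sms, `[[`, "rd"), roi)
  pc_fa <- partial_correlation(behavior, fa_roi, ages)
  pc_rd <- partial_correlation(behavior, rd_roi, ages)
  list(r_fa = pc_fa$r, r_rd = pc_rd$r, p_fa = pc_fa$p, p_rd = pc_rd$p,
       behavior = behavior, fa_roi = fa_roi, rd_roi = rd_roi)
}
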