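#' Simulate a trial-level key-press log for one subject
#'
#' Generates every trial of the practice schedule (all days and runs) for a
#' subject. Response press/release times equal stimulus onset/offset plus
#' Gaussian jitter whose SD shrinks from `timing_jitter_sd` toward the level
#' implied by `asymptote_psyn` as an exponential function of run index.
#' Occasional mis-ordered key-press durations (the response reproduces the
#' wrong element class) occur at a rate that decays toward
#' `1 - asymptote_pcor/100`.
#'
#' @param design a [tmst_design()].
#' @param profile a [subject_profile()].
#' @param seed integer; any value accepted, reproducibility is per
#'   `(seed, subject_id)`.
#' @return data.frame with one row per stimulus element and columns
#'   `subject`, `day`, `run`, `trial`, `element_index`, `label`,
#'   `stim_onset_ms`, `stim_offset_ms`, `resp_press_ms`, `resp_release_ms`.
#'   `trial` counts within run; `run` counts within day.
#' @export
generate_behavior_log <- function(design = tmst_design(), profile = subject_profile(),
                                  seed = 1L) {
  if (!inherits(design, "tmst_design")) stop("design must be a tmst_design")
  if (!inherits(profile, "tmst_profile")) stop("profile must be a tmst_profile")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.seed_combine(seed, profile$subject_id))

  tl <- stimulus_timeline(design)
  n_el <- nrow(tl)
  trials_per_run <- design$sequences_per_block * design$blocks_per_run
  n_runs <- n_total_runs(design)

  p_inf <- 1 - profile$asymptote_pcor / 100
  p0 <- min(1, p_inf + 0.25)
  sd_inf <- .psyn_to_jitter_sd(profile$asymptote_psyn, design,
                               dur_sd = profile$duration_error_sd,
                               err_rate = p_inf)

  wrong_dur <- ifelse(tl$label == "S", design$long_ms, design$short_ms)

  out <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    decay <- exp(-profile$learning_rate * (k - 1))
    sd_k <- sd_inf + (profile$timing_jitter_sd - sd_inf) * decay
    sd_k <- max(sd_k, 0)
    p_k <- p_inf + (p0 - p_inf) * decay
    if (p_inf == 0 && profile$duration_error_sd == 0 &&
        profile$timing_jitter_sd == 0 && profile$asymptote_psyn == 100) {
      p_k <- 0  # fully noiseless subject reproduces stimuli exactly
    }
    m <- trials_per_run * n_el
    press_jit <- rnorm(m, 0, sd_k)
    rel_jit <- rnorm(m, 0, sd_k)
    dur_noise <- if (profile$duration_error_sd > 0) rnorm(m, 0, profile$duration_error_sd) else 0
    err <- runif(m) < p_k
    press <- rep(tl$onset_ms, trials_per_run) + press_jit
    release <- rep(tl$offset_ms, trials_per_run) + rel_jit + dur_noise
    # mis-ordered element: duration of the other class, preserving press time
    release[err] <- press[err] + rep(wrong_dur, trials_per_run)[err] +
      (if (length(dur_noise) > 1) dur_noise[err] else 0)
    release <- pmax(release, press + 1)  # a press is always released after it

    day <- (k - 1) %/% design$runs_per_day + 1L
    run <- (k - 1) %% design$runs_per_day + 1L
    out[[k]] <- data.frame(
      subject = profile$subject_id, day = day, run = run,
      trial = rep(seq_len(trials_per_run), each = n_el),
      element_index = rep(tl$element_index, trials_per_run),
      label = rep(tl$label, trials_per_run),
      stim_onset_ms = rep(tl$onset_ms, trials_per_run),
      stim_offset_ms = rep(tl$offset_ms, trials_per_run),
      resp_press_ms = press, resp_release_ms = release,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a cohort of subject profiles
#'
#' Draws `n` subjects whose latent `integrity` determines their behavioral
#' asymptotes, emulating the inter-individual spread of final scores seen in
#' small motor-learning cohorts (final PSYN roughly 70 +/- 11, final PCOR
#' roughly 93 +/- 7). With `behavior_link = 0`, integrity and behavior are
#' drawn independently (a null cohort).
#'
#' @param n number of subjects (default 13).
#' @param seed integer seed.
#' @param behavior_link strength of the integrity -> asymptote mapping;
#'   1 is the default full coupling, 0 decouples them.
#' @return list of [subject_profile()] objects.
#' @export
simulate_cohort_profiles <- function(n = 13, seed = 1L, behavior_link = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.seed_combine(seed, "cohort-profiles"))
  integrity <- runif(n, 0.05, 0.95)
  skill <- if (behavior_link > 0) {
    behavior_link * (integrity - 0.5) + (1 - behavior_link) * runif(n, -0.45, 0.45)
  } else runif(n, -0.45, 0.45)
  ages <- round(runif(n, 19, 35))
  lapply(seq_len(n), function(i) {
    subject_profile(
      subject_id = sprintf("s%02d", i), age = ages[i],
      asymptote_psyn = min(98, max(30, 70 + 24 * skill[i] + rnorm(1, 0, 2))),
      asymptote_pcor = min(100, max(50, 93 + 14 * skill[i] + rnorm(1, 0, 1.5))),
      learning_rate = exp(rnorm(1, log(0.3), 0.25)),
      timing_jitter_sd = runif(1, 100, 150),
      duration_error_sd = runif(1, 10, 30),
      integrity = integrity[i])
  })
}

#' Write / read behavior logs and cohort covariates as TSV
#'
#' The log dialect has one row per stimulus element:
#' `subject day run trial element_index label stim_onset_ms stim_offset_ms
#' resp_press_ms resp_release_ms`.
#'
#' @param log data.frame as produced by [generate_behavior_log()].
#' @param path file path.
#' @export
write_behavior_log <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_log
#' @export
read_behavior_log <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname write_behavior_log
#' @param profiles list of [subject_profile()].
#' @export
write_cohort_covariates <- function(profiles, path) {
  df <- data.frame(
    subject = vapply(profiles, `[[`, "", "subject_id"),
    age = vapply(profiles, `[[`, 0, "age"),
    gender = rep_len(c("F", "M"), length(profiles)),
    integrity = vapply(profiles, `[[`, 0, "integrity"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
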