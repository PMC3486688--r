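#' Temporal motor sequence task design
#'
#' Describes the stimulus structure of the temporal motor sequence task
#' (TMST): an ordered sequence of short (S) and long (L) visual elements that
#' the participant reproduces by pressing and releasing a mouse button in
#' synchrony with element onsets and offsets.
#'
#' The default is the standard learning sequence: 10 elements (5 short at
#' 300 ms, 5 long at 600 ms) separated by a 300 ms inter-stimulus interval,
#' practised 4 sequences per block, 4 blocks per run, 3 runs per day over
#' 5 days (240 trials, 15 runs).
#'
#' @param element_labels character vector over `c("S", "L")` giving the
#'   element order of one sequence.
#' @param short_ms,long_ms stimulus durations (ms) for S and L elements.
#' @param isi_ms inter-stimulus interval (ms).
#' @param sequences_per_block,blocks_per_run,runs_per_day,days practice
#'   structure counts.
#' @return An object of class `tmst_design`.
#' @export
#' @examples
#' d <- tmst_design()
#' n_total_trials(d)  # 240
tmst_design <- function(element_labels = c("S", "L", "L", "S", "L", "S", "S", "L", "S", "L"),
                        short_ms = 300, long_ms = 600, isi_ms = 300,
                        sequences_per_block = 4, blocks_per_run = 4,
                        runs_per_day = 3, days = 5) {
  stopifnot(all(element_labels %in% c("S", "L")), length(element_labels) >= 1)
  if (short_ms <= 0 || long_ms <= 0 || isi_ms < 0)
    stop("element durations must be positive and ISI non-negative")
  counts <- c(sequences_per_block, blocks_per_run, runs_per_day, days)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("block/run/day structure counts must be positive integers")
  structure(list(
    element_labels = element_labels,
    short_ms = short_ms, long_ms = long_ms, isi_ms = isi_ms,
    sequences_per_block = as.integer(sequences_per_block),
    blocks_per_run = as.integer(blocks_per_run),
    runs_per_day = as.integer(runs_per_day),
    days = as.integer(days)
  ), class = "tmst_design")
}

#' @rdname tmst_design
#' @param design a `tmst_design`.
#' @export
n_total_trials <- function(design) {
  with(design, sequences_per_block * blocks_per_run * runs_per_day * days)
}

#' @rdname tmst_design
#' @export
n_total_runs <- function(design) design$runs_per_day * design$days

#' Element durations of a design (ms)
#' @param design a `tmst_design`.
#' @return numeric vector, one duration per element.
#' @export
element_durations <- function(design) {
  ifelse(design$element_labels == "S", design$short_ms, design$long_ms)
}

#' Stimulus timeline of one trial
#'
#' Element onsets/offsets relative to trial start, with the design ISI
#' between consecutive elements.
#'
#' @param design a `tmst_design`.
#' @return data.frame with `element_index`, `label`, `onset_ms`, `offset_ms`.
#' @export
stimulus_timeline <- function(design) {
  dur <- element_durations(design)
  n <- length(dur)
  onset <- cumsum(c(0, head(dur, -1) + design$isi_ms))
  data.frame(element_index = seq_len(n), label = design$element_labels,
             onset_ms = onset, offset_ms = onset + dur,
             stringsAsFactors = FALSE)
}

#' Synthetic subject profile
#'
#' Latent parameters controlling one simulated participant: behavioral skill
#' (asymptotic PSYN/PCOR and learning rate), motor noise (timing jitter and
#' key-press duration noise), and a unitless structural `integrity` parameter
#' in \[0, 1\] through which diffusion phantoms can be linked to behavior.
#'
#' `asymptote_psyn` sets the synchronization level the subject converges to;
#' `timing_jitter_sd` is the press/release timing jitter (ms, SD) at the
#' start of training, which decays exponentially in run index toward the
#' jitter level implied by `asymptote_psyn`.
#'
#' @param subject_id character identifier.
#' @param age years.
#' @param asymptote_psyn,asymptote_pcor asymptotic scores in \[0, 100\].
#' @param learning_rate per-run exponential approach rate (> 0 learns).
#' @param timing_jitter_sd initial timing jitter SD (ms).
#' @param duration_error_sd extra SD (ms) on key-press durations.
#' @param integrity latent structural parameter in \[0, 1\].
#' @return An object of class `tmst_profile`.
#' @export
subject_profile <- function(subject_id = "s01", age = 25,
                            asymptote_psyn = 70, asymptote_pcor = 93,
                            learning_rate = 0.3,
                            timing_jitter_sd = 120, duration_error_sd = 20,
                            integrity = 0.5) {
  if (asymptote_psyn < 0 || asymptote_psyn > 100 ||
      asymptote_pcor < 0 || asymptote_pcor > 100)
    stop("asymptotic scores must lie in [0, 100]")
  if (timing_jitter_sd < 0 || duration_error_sd < 0)
    stop("jitter/duration error SDs must be >= 0")
  if (integrity < 0 || integrity > 1) stop("integrity must lie in [0, 1]")
  structure(list(
    subject_id = as.character(subject_id), age = age,
    asymptote_psyn = asymptote_psyn, asymptote_pcor = asymptote_pcor,
    learning_rate = learning_rate,
    timing_jitter_sd = timing_jitter_sd,
    duration_error_sd = duration_error_sd,
    integrity = integrity
  ), class = "tmst_profile")
}

#' A noiseless profile: exact reproduction of every stimulus
#' @inheritParams subject_profile
#' @export
noiseless_profile <- function(subject_id = "s01", age = 25) {
  subject_profile(subject_id, age, asymptote_psyn = 100, asymptote_pcor = 100,
                  timing_jitter_sd = 0, duration_error_sd = 0)
}

# timing jitter SD (ms) whose expected normalized absolute lag yields the
# given PSYN score. Press lag ~ N(0, s); release lag ~ N(0,
# sqrt(s^2 + dur_sd^2)) for clean elements (duration noise adds to the
# release) and ~ |wrong - right duration| for mis-ordered elements at rate
# err_rate; E|N(0, s)| = s * sqrt(2/pi). Solved numerically for s.
.psyn_to_jitter_sd <- function(psyn, design, dur_sd = 0, err_rate = 0) {
  d <- element_durations(design)
  A <- sqrt(2 / pi) * mean(1 / d) * 100          # expected lag%, per ms of SD
  wrong <- ifelse(design$element_labels == "S", design$long_ms, design$short_ms)
  P <- mean(abs(wrong - d) / d) * 100            # mis-order release penalty
  target <- 100 - psyn
  f <- function(s) s * A + (1 - err_rate) * sqrt(s^2 + dur_sd^2) * A +
    err_rate * P - target
  if (f(0) >= 0) return(0)
  stats::uniroot(f, c(0, target / A + dur_sd + 1), tol = 1e-8)$root
}
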