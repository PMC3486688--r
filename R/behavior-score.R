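#' Split a behavior log into trial records
#'
#' A trial record pairs the trial's ordered stimulus elements with its
#' response stream. The generator writes responses aligned to elements;
#' the scorer nevertheless treats responses as an unlabeled time-sorted
#' stream and re-derives the element-response matching.
#'
#' @param log behavior-log data.frame (see [generate_behavior_log()]).
#' @return list of trial records, each a list with `subject`, `day`, `run`,
#'   `trial`, `elements` (data.frame `onset_ms`, `offset_ms`, `label`) and
#'   `responses` (data.frame `press_ms`, `release_ms`, sorted by press).
#' @export
trial_records <- function(log) {
  key <- interaction(log$subject, log$day, log$run, log$trial, drop = TRUE)
  lapply(split(seq_len(nrow(log)), key), function(i) {
    rows <- log[i, ]
    rows <- rows[order(rows$element_index), ]
    resp <- rows[!is.na(rows$resp_press_ms), c("resp_press_ms", "resp_release_ms")]
    resp <- resp[order(resp$resp_press_ms), ]
    list(subject = rows$subject[1], day = rows$day[1], run = rows$run[1],
         trial = rows$trial[1],
         elements = data.frame(onset_ms = rows$stim_onset_ms,
                               offset_ms = rows$stim_offset_ms,
                               label = rows$label, stringsAsFactors = FALSE),
         responses = data.frame(press_ms = resp$resp_press_ms,
                                release_ms = resp$resp_release_ms))
  })
}

#' Match responses to stimulus elements
#'
#' A response is admissible for an element if its press time lies in
#' `[onset - window_pre_ms, offset]` (a press may anticipate the stimulus by
#' up to 300 ms, or occur any time before stimulus end). Elements are
#' matched greedily in presentation order; each takes the still-unmatched
#' admissible response whose press time is nearest its onset (ties go to
#' the earlier response).
#'
#' @param trial a trial record (see [trial_records()]).
#' @param window_pre_ms anticipation window before onset (ms).
#' @return the trial with `matching` added: integer vector, one entry per
#'   element, index into `responses` or `NA` if unmatched.
#' @export
match_responses <- function(trial, window_pre_ms = 300) {
  el <- trial$elements
  rs <- trial$responses
  n_el <- nrow(el)
  matching <- rep(NA_integer_, n_el)
  used <- logical(nrow(rs))
  for (i in seq_len(n_el)) {
    lo <- el$onset_ms[i] - window_pre_ms
    hi <- el$offset_ms[i]
    ok <- which(!used & rs$press_ms >= lo & rs$press_ms <= hi)
    if (length(ok)) {
      j <- ok[which.min(abs(rs$press_ms[ok] - el$onset_ms[i]))]
      matching[i] <- j
      used[j] <- TRUE
    }
  }
  trial$matching <- matching
  trial
}

.ensure_matched <- function(trials, window_pre_ms = 300) {
  lapply(trials, function(tr) {
    if (is.null(tr$matching)) match_responses(tr, window_pre_ms) else tr
  })
}

#' Daily duration norms
#'
#' Mean and SD of matched key-press durations (release minus press), split
#' by element class, from a set of training trials. The SD is the sample SD
#' (n - 1 denominator). These norms feed the PCOR duration criteria.
#'
#' @param training_trials list of (matched) trial records.
#' @return list with `short_mean_ms`, `short_sd_ms`, `long_mean_ms`,
#'   `long_sd_ms`, `n_short`, `n_long`.
#' @export
duration_norms <- function(training_trials) {
  training_trials <- .ensure_matched(training_trials)
  durs <- list(S = numeric(0), L = numeric(0))
  for (tr in training_trials) {
    m <- tr$matching
    ok <- which(!is.na(m))
    if (!length(ok)) next
    d <- tr$responses$release_ms[m[ok]] - tr$responses$press_ms[m[ok]]
    lab <- tr$elements$label[ok]
    durs$S <- c(durs$S, d[lab == "S"])
    durs$L <- c(durs$L, d[lab == "L"])
  }
  for (cls in c("S", "L")) {
    if (!length(durs[[cls]]))
      stop(sprintf("no matched responses for %s elements; cannot compute duration norms",
                   if (cls == "S") "short" else "long"))
  }
  list(short_mean_ms = mean(durs$S),
       short_sd_ms = if (length(durs$S) > 1) sd(durs$S) else 0,
       long_mean_ms = mean(durs$L),
       long_sd_ms = if (length(durs$L) > 1) sd(durs$L) else 0,
       n_short = length(durs$S), n_long = length(durs$L))
}

#' Percent correct (PCOR)
#'
#' The percentage of stimulus elements whose matched key-press was initiated
#' between `window_pre_ms` before stimulus onset and stimulus end, and whose
#' duration satisfies the class criterion: strictly less than M + 2SD for
#' short elements, strictly greater than M - 2SD for long elements (M, SD
#' from [duration_norms()]). The denominator is the total element count, so
#' unmatched elements count as incorrect.
#'
#' @param trials list of trial records.
#' @param norms output of [duration_norms()].
#' @param window_pre_ms anticipation window (ms).
#' @return percentage in \[0, 100\].
#' @export
score_pcor <- function(trials, norms, window_pre_ms = 300) {
  trials <- .ensure_matched(trials, window_pre_ms)
  n_total <- 0L
  n_pass <- 0L
  for (tr in trials) {
    n_total <- n_total + nrow(tr$elements)
    m <- tr$matching
    ok <- which(!is.na(m))
    if (!length(ok)) next
    dur <- tr$responses$release_ms[m[ok]] - tr$responses$press_ms[m[ok]]
    lab <- tr$elements$label[ok]
    # strict criterion boundaries (a tie at M +/- 2SD fails); a press whose
    # duration equals the class mean always passes, which keeps the
    # degenerate zero-SD norms of a perfectly consistent performer scorable
    pass <- ifelse(lab == "S",
                   dur < norms$short_mean_ms + 2 * norms$short_sd_ms |
                     abs(dur - norms$short_mean_ms) < 1e-9,
                   dur > norms$long_mean_ms - 2 * norms$long_sd_ms |
                     abs(dur - norms$long_mean_ms) < 1e-9)
    n_pass <- n_pass + sum(pass)
  }
  if (n_total == 0L) stop("no stimulus elements to score")
  100 * n_pass / n_total
}

#' Percent synchronization (PSYN)
#'
#' Per matched element, the absolute press-onset lag plus the absolute
#' release-offset lag, divided by the stimulus element duration, as a
#' percentage; unmatched elements take the maximal penalty of 100. A trial
#' scores 100 minus the mean normalized lag over its elements; the returned
#' score is the mean over trials, floored at 0.
#'
#' @param trials list of trial records.
#' @param window_pre_ms anticipation window used if matching is absent (ms).
#' @return percentage, `0 <= psyn <= 100`.
#' @export
score_psyn <- function(trials, window_pre_ms = 300) {
  trials <- .ensure_matched(trials, window_pre_ms)
  trial_scores <- vapply(trials, function(tr) {
    el <- tr$elements
    dur <- el$offset_ms - el$onset_ms
    if (any(dur <= 0)) stop("zero-duration stimulus element")
    lagpct <- rep(100, nrow(el))
    ok <- which(!is.na(tr$matching))
    if (length(ok)) {
      j <- tr$matching[ok]
      lag <- abs(tr$responses$press_ms[j] - el$onset_ms[ok]) +
        abs(tr$responses$release_ms[j] - el$offset_ms[ok])
      lagpct[ok] <- 100 * lag / dur[ok]
    }
    100 - mean(lagpct)
  }, 0)
  max(0, mean(trial_scores))
}

#' Slope of improvement
#'
#' Pearson correlation between run index and run-mean score across practice
#' runs: the r-value of the best-fit line through a subject's run averages.
#' A zero-variance score series returns 0 with a warning (a flat learner
#' neither improves nor worsens). The least-squares slope coefficient (score
#' units per run) is attached as attribute `"beta"` for transparency.
#'
#' @param run_scores numeric vector of run-mean scores, in run order.
#' @return r in \[-1, 1\].
#' @export
slope_of_improvement <- function(run_scores) {
  run_scores <- as.numeric(run_scores)
  if (length(run_scores) < 3 || any(!is.finite(run_scores)))
    stop("need >= 3 finite run scores")
  idx <- seq_along(run_scores)
  if (sd(run_scores) == 0) {
    warning("zero-variance score series; returning r = 0")
    return(structure(0, beta = 0))
  }
  r <- cor(idx, run_scores)
  beta <- r * sd(run_scores) / sd(idx)
  structure(r, beta = beta)
}

#' Score every run of a behavior log
#'
#' Computes run-level PCOR and PSYN for each subject in a log. Duration
#' norms are recomputed for each subject and day from that day's training
#' trials, defined as the first run of the day.
#'
#' @param log behavior-log data.frame.
#' @param window_pre_ms anticipation window (ms).
#' @return data.frame `subject, day, run, run_index, pcor, psyn, n_trials`.
#' @export
score_runs <- function(log, window_pre_ms = 300) {
  out <- list()
  for (subj in unique(log$subject)) {
    slog <- log[log$subject == subj, ]
    days <- sort(unique(slog$day))
    runs_per_day <- max(slog$run)
    for (d in days) {
      dlog <- slog[slog$day == d, ]
      first_run <- min(dlog$run)
      training <- .ensure_matched(
        trial_records(dlog[dlog$run == first_run, ]), window_pre_ms)
      norms <- duration_norms(training)
      for (r in sort(unique(dlog$run))) {
        trials <- if (r == first_run) training else
          .ensure_matched(trial_records(dlog[dlog$run == r, ]), window_pre_ms)
        out[[length(out) + 1L]] <- data.frame(
          subject = subj, day = d, run = r,
          run_index = (d - 1L) * runs_per_day + r,
          pcor = score_pcor(trials, norms, window_pre_ms),
          psyn = score_psyn(trials, window_pre_ms),
          n_trials = length(trials), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Per-subject behavioral summary
#'
#' Final performance (PCOR and PSYN of the last run of the last day) and
#' slope-of-improvement r-values over the full run series.
#'
#' @param run_scores data.frame from [score_runs()] (one subject), or a
#'   behavior log (scored first).
#' @param expected_runs required run count (default 15); `NULL` disables
#'   the check.
#' @return data.frame `subject, final_pcor, final_psyn, pcor_slope,
#'   psyn_slope, pcor_beta, psyn_beta`.
#' @export
summarize_subject <- function(run_scores, expected_runs = 15) {
  if (!is.null(run_scores$stim_onset_ms)) run_scores <- score_runs(run_scores)
  out <- lapply(split(run_scores, run_scores$subject), function(df) {
    df <- df[order(df$run_index), ]
    if (!is.null(expected_runs) && nrow(df) != expected_runs)
      stop(sprintf("subject %s has %d runs; expected %d",
                   df$subject[1], nrow(df), expected_runs))
    pslope <- suppressWarnings(slope_of_improvement(df$pcor))
    sslope <- suppressWarnings(slope_of_improvement(df$psyn))
    data.frame(subject = df$subject[1],
               final_pcor = df$pcor[nrow(df)], final_psyn = df$psyn[nrow(df)],
               pcor_slope = as.numeric(pslope), psyn_slope = as.numeric(sslope),
               pcor_beta = attr(pslope, "beta"), psyn_beta = attr(sslope, "beta"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
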