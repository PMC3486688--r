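test_that("responses at stimulus times give the identity matching", {
  tr <- make_trial(c(0, 600, 1500), c(300, 1200, 1800), c("S", "L", "S"),
                   press = c(0, 600, 1500), release = c(300, 1200, 1800))
  m <- match_responses(tr)
  expect_equal(m$matching, 1:3)
})

test_that("a press preceding the window leaves the element unmatched", {
  tr <- make_trial(1000, 1300, "S", press = 650, release = 950)
  expect_true(is.na(match_responses(tr)$matching))
  # exactly at the window edge is admissible
  tr2 <- make_trial(1000, 1300, "S", press = 700, release = 1000)
  expect_equal(match_responses(tr2)$matching, 1)
})

test_that("greedy matching picks the nearest admissible press and keeps the rest available", {
  # two elements, two responses, press times swept over a grid; check the
  # documented rule directly: element 1 takes the unmatched admissible
  # response nearest its onset, then element 2
  onsets <- c(0, 600)
  offsets <- c(300, 900)
  for (p1 in seq(-250, 850, by = 100)) for (p2 in seq(-250, 850, by = 100)) {
    if (p1 == p2) next
    tr <- make_trial(onsets, offsets, c("S", "S"),
                     press = c(p1, p2), release = c(p1, p2) + 300)
    m <- match_responses(tr)$matching
    press_sorted <- sort(c(p1, p2))
    admissible <- function(p, i) p >= onsets[i] - 300 & p <= offsets[i]
    # oracle: independent enumeration of the rule
    exp1 <- NA_integer_
    cand1 <- which(admissible(press_sorted, 1))
    if (length(cand1))
      exp1 <- cand1[which.min(abs(press_sorted[cand1] - onsets[1]))]
    exp2 <- NA_integer_
    cand2 <- setdiff(which(admissible(press_sorted, 2)), exp1)
    if (length(cand2))
      exp2 <- cand2[which.min(abs(press_sorted[cand2] - onsets[2]))]
    expect_equal(m, c(exp1, exp2))
    ok <- !is.na(m)
    expect_true(!anyDuplicated(m[ok]))   # injective
  }
})

test_that("duration norms use the sample SD per element class", {
  tr <- make_trial(c(0, 600, 1500, 2700), c(300, 900, 2100, 3300),
                   c("S", "S", "L", "L"),
                   press = c(0, 600, 1500, 2700),
                   release = c(280, 920, 2100, 3300))
  n <- duration_norms(list(tr))
  expect_equal(n$short_mean_ms, 300)
  expect_equal(n$short_sd_ms, sqrt(((280 - 300)^2 + (320 - 300)^2) / 1))
  expect_equal(n$long_mean_ms, 600)
  expect_equal(n$long_sd_ms, 0)
})

test_that("missing long-element matches raise an informative error", {
  tr <- make_trial(c(0, 600), c(300, 1200), c("S", "L"),
                   press = 0, release = 300)
  tr <- match_responses(tr)
  expect_error(duration_norms(list(tr)), "long")
})

test_that("perfect reproduction scores 100 on both measures", {
  d <- tmst_design()
  tl <- stimulus_timeline(d)
  tr <- make_trial(tl$onset_ms, tl$offset_ms, tl$label,
                   press = tl$onset_ms, release = tl$offset_ms)
  norms <- duration_norms(list(tr))
  expect_equal(score_pcor(list(tr), norms), 100)
  expect_equal(score_psyn(list(tr)), 100)
})

test_that("PCOR applies the M +/- 2SD duration criteria strictly", {
  # 10 short elements far apart; presses at onset; 9 durations of 300,
  # one of 400 against norms M = 280, SD = 40 -> 400 >= 360 fails -> 90
  onsets <- seq(0, by = 2000, length.out = 10)
  offsets <- onsets + 300
  durs <- c(rep(300, 9), 400)
  tr <- make_trial(onsets, offsets, rep("S", 10),
                   press = onsets, release = onsets + durs)
  norms <- list(short_mean_ms = 280, short_sd_ms = 40,
                long_mean_ms = 600, long_sd_ms = 50)
  expect_equal(score_pcor(list(tr), norms), 90)
  # boundary tie fails: duration exactly M + 2SD = 360
  tr2 <- make_trial(onsets[1], offsets[1], "S", press = onsets[1],
                    release = onsets[1] + 360)
  expect_equal(score_pcor(list(tr2), norms), 0)
  # long element shorter than M - 2SD fails: 480 <= 500
  tr3 <- make_trial(0, 600, "L", press = 0, release = 480)
  expect_equal(score_pcor(list(tr3), norms), 0)
  tr4 <- make_trial(0, 600, "L", press = 0, release = 520)
  expect_equal(score_pcor(list(tr4), norms), 100)
})

test_that("PSYN normalizes summed lags by element duration", {
  tr <- make_trial(0, 600, "L", press = 60, release = 660)
  expect_equal(score_psyn(list(tr)), 100 - 120 / 600 * 100)
  # unmatched element takes the maximal penalty
  tr2 <- make_trial(0, 600, "L")
  expect_equal(score_psyn(list(tr2)), 0)
})

test_that("PSYN strictly decreases as any lag grows and under uniform delay", {
  d <- tmst_design()
  tl <- stimulus_timeline(d)
  base <- make_trial(tl$onset_ms, tl$offset_ms, tl$label,
                     press = tl$onset_ms, release = tl$offset_ms)
  s0 <- score_psyn(list(base))
  prev <- s0
  for (delta in c(10, 25, 60)) {
    tr <- make_trial(tl$onset_ms, tl$offset_ms, tl$label,
                     press = tl$onset_ms + delta,
                     release = tl$offset_ms + delta)
    s <- score_psyn(list(tr))
    expect_lt(s, prev)
    prev <- s
  }
  # single-lag increase, all else fixed
  pr <- tl$onset_ms; pr[4] <- pr[4] + 50
  tr <- make_trial(tl$onset_ms, tl$offset_ms, tl$label,
                   press = pr, release = tl$offset_ms)
  expect_lt(score_psyn(list(tr)), s0)
})

test_that("scores are invariant under a global time translation", {
  d <- tmst_design()
  tl <- stimulus_timeline(d)
  jit <- c(20, -15, 8, 0, 30, -22, 14, 6, -9, 11)
  for (shift in c(0, 1234.5, -800)) {
    tr <- make_trial(tl$onset_ms + shift, tl$offset_ms + shift, tl$label,
                     press = tl$onset_ms + jit + shift,
                     release = tl$offset_ms + jit + shift)
    if (shift == 0) {
      ref_psyn <- score_psyn(list(tr))
      ref_pcor <- score_pcor(list(tr), duration_norms(list(tr)))
    } else {
      expect_equal(score_psyn(list(tr)), ref_psyn)
      expect_equal(score_pcor(list(tr), duration_norms(list(tr))), ref_pcor)
    }
  }
})

test_that("slope of improvement equals the Pearson r of score on run index", {
  expect_equal(as.numeric(slope_of_improvement(seq(50, 92, by = 3))), 1)
  x <- c(60, 62, 61, 65, 64, 66, 68, 67, 70, 71, 69, 73, 74, 76, 75)
  r <- slope_of_improvement(x)
  expect_equal(as.numeric(r), pearson_oracle(seq_along(x), x), tolerance = 1e-12)
  expect_equal(as.numeric(slope_of_improvement(rev(x))), -as.numeric(r),
               tolerance = 1e-12)
  expect_warning(r0 <- slope_of_improvement(rep(80, 15)), "zero-variance")
  expect_equal(as.numeric(r0), 0)
  expect_error(slope_of_improvement(c(1, 2)), ">= 3")
})

test_that("subject summaries take final scores from the last run and check run count", {
  log <- generate_behavior_log(tmst_design(), noiseless_profile(), seed = 1)
  rs <- score_runs(log)
  expect_equal(nrow(rs), 15)
  s <- suppressWarnings(summarize_subject(rs))
  expect_equal(s$final_pcor, 100)
  expect_equal(s$final_psyn, 100)
  expect_equal(s$pcor_slope, 0)
  expect_error(summarize_subject(rs[-15, ]), "expected 15")
})

test_that("recovered final PSYN approaches the generator asymptote at low noise", {
  d <- tmst_design()
  p <- subject_profile("lowjit", asymptote_psyn = 80, asymptote_pcor = 100,
                       learning_rate = 0.6, timing_jitter_sd = 40,
                       duration_error_sd = 0)
  s <- summarize_subject(score_runs(generate_behavior_log(d, p, seed = 9)))
  expect_equal(s$final_psyn, 80, tolerance = 0.05)
  expect_gt(s$psyn_slope, 0.5)
})

test_that("final PSYN rank order follows generator asymptotes across a cohort", {
  d <- tmst_design()
  asym <- seq(45, 93, length.out = 13)
  finals <- vapply(seq_along(asym), function(i) {
    p <- subject_profile(sprintf("r%02d", i), asymptote_psyn = asym[i],
                         asymptote_pcor = 100, learning_rate = 0.5,
                         timing_jitter_sd = 60, duration_error_sd = 5)
    rs <- score_runs(generate_behavior_log(d, p, seed = 11))
    rs$psyn[15]
  }, 0)
  expect_gt(cor(asym, finals, method = "spearman"), 0.9)
})
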