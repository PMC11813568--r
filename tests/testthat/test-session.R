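test_that("schedules carry the designed trial counts per condition", {
  d1 <- session_design(experiment = 1)
  s1 <- make_schedule(d1, seed = 1)
  expect_equal(nrow(s1), 108)
  expect_setequal(unique(s1$condition), c("Cold", "ColdTouch"))

  d3 <- session_design(experiment = 3)
  s3 <- make_schedule(d3, seed = 1)
  expect_equal(nrow(s3), 162)
  counts <- table(s3$condition, s3$signal_present)
  expect_true(all(counts == 27))
  expect_setequal(unique(s3$grid_location), 0:8)
})

test_that("no grid location repeats within the revisit window", {
  for (seed in 1:20) {
    s <- make_schedule(session_design(experiment = 3), seed = seed)
    loc <- s$grid_location
    w <- 3
    for (i in 2:length(loc)) {
      recent <- loc[max(1, i - w):(i - 1)]
      expect_false(loc[i] %in% recent)
    }
  }
})

test_that("four locations with window three force a round-robin cycle", {
  d <- session_design(experiment = 1, n_locations = 4)
  s <- make_schedule(d, seed = 8)
  loc <- s$grid_location
  # after the opening permutation every position is forced: the cycle of the
  # first four locations repeats exactly
  expect_equal(loc, rep_len(loc[1:4], length(loc)))
  expect_error(make_schedule(session_design(n_locations = 3)),
               "unsatisfiable")
})

test_that("simulate_cooling produces a monotone trace that stops at target", {
  d <- session_design(target_delta_t = -0.8)
  set.seed(4)
  for (i in 1:20) {
    cool <- simulate_cooling(-0.8, d)
    expect_true(all(diff(cool$trace$temp_degC) < 0))
    if (!cool$failed) {
      expect_lte(cool$achieved_delta_t, -0.8)
      expect_equal(cool$duration_s,
                   cool$trace$time_s[nrow(cool$trace)])
      # every earlier sample was still above target
      pre <- head(cool$trace$temp_degC, -1)
      expect_true(all(pre > -0.8))
    } else {
      expect_equal(cool$duration_s, d$timeout_s)
    }
  }
  expect_error(simulate_cooling(0.5), "negative")
})

test_that("an unreachable target always fails at the time-out", {
  d <- session_design(target_delta_t = -1.9,
                      thermal = thermal_params(asymptote_degC = 1.0))
  set.seed(6)
  for (i in 1:10) {
    cool <- simulate_cooling(-1.9, d)
    expect_true(cool$failed)
    expect_equal(cool$duration_s, 10)
  }
  expect_equal(thermal_fail_prob(-1.9, thermal_params(asymptote_degC = 1)), 1)
})

test_that("simulated failure rate matches the analytic model rate", {
  d <- session_design(target_delta_t = -1.0)
  p_ref <- thermal_fail_prob(-1.0, d$thermal, d$timeout_s)
  expect_lt(p_ref, 0.1) # defaults keep failures rare
  set.seed(12)
  n <- 4000
  fails <- sum(replicate(n, simulate_cooling(-1.0, d)$failed))
  se <- sqrt(p_ref * (1 - p_ref) / n)
  # the sampling grid can only delay threshold detection, so the simulated
  # rate sits at or slightly above the continuous-time reference
  expect_gt(fails / n, p_ref - 3 * se)
  expect_lt(fails / n, p_ref + 5 * se + 0.01)
})

test_that("detection sessions classify outcomes per the contingency table", {
  d <- session_design(experiment = 1, target_delta_t = -1.0)
  # near-perfect observer: all signals hit, all noise correctly rejected
  obs <- observer_params(gain = 50, criterion = 25)
  tr <- run_detection_session(obs, d, seed = 2)
  ok <- tr[!tr$failed, ]
  expect_true(all(ok$outcome_class[ok$signal_present] == "hit"))
  expect_true(all(ok$outcome_class[!ok$signal_present] == "correct_rejection"))
  expect_true(all(is.na(tr$outcome_class[tr$failed])))
  # per condition, exactly the designed number of analysable trials
  for (cond in d$conditions) {
    cc <- ok[ok$condition == cond, ]
    expect_equal(sum(cc$signal_present), 27)
    expect_equal(sum(!cc$signal_present), 27)
  }
})

test_that("outcome labels cross signal presence with the response", {
  d <- session_design(experiment = 1)
  obs <- observer_params(gain = 1.5, criterion = 1)
  tr <- run_detection_session(obs, d, seed = 9)
  ok <- tr[!tr$failed, ]
  expect_equal(ok$outcome_class,
               ifelse(ok$signal_present,
                      ifelse(ok$response, "hit", "miss"),
                      ifelse(ok$response, "false_alarm",
                             "correct_rejection")))
})

test_that("noise-trial durations replay recorded signal durations", {
  d <- session_design(experiment = 1, target_delta_t = -1.0)
  obs <- observer_params(gain = 2, criterion = 1)
  tr <- run_detection_session(obs, d, seed = 33)
  sig_durs <- tr$cooling_duration[tr$signal_present & !tr$failed]
  noise <- tr[!tr$signal_present, ]
  # after the first successful signal trial, every noise duration must be a
  # replay of an earlier recorded one
  first_sig <- min(tr$trial_index[tr$signal_present & !tr$failed])
  late <- noise[noise$trial_index > first_sig, ]
  for (i in seq_len(nrow(late))) {
    earlier <- tr$cooling_duration[tr$signal_present & !tr$failed &
                                     tr$trial_index < late$trial_index[i]]
    expect_true(any(abs(earlier - late$cooling_duration[i]) < 1e-12))
  }
})

test_that("session timeline is strictly increasing with full trial spans", {
  d <- session_design(experiment = 1)
  obs <- observer_params(gain = 2, criterion = 1)
  tr <- run_detection_session(obs, d, seed = 14)
  expect_true(all(diff(tr$onset_time) > 0))
  spans <- tr$end_time - tr$onset_time
  expect_true(all(spans >= d$baseline_s + d$lead_s + tr$cooling_duration +
                    d$response_s - 1e-9))
  # trials are separated by the inter-trial interval, plus any recovery
  # pause before a repeated cooling trial
  gaps <- tr$onset_time[-1] - tr$end_time[-nrow(tr)]
  expect_true(all(gaps >= d$iti_s - 1e-9))
})

test_that("same-location cooling events are separated by at least 30 s", {
  d <- session_design(experiment = 1, target_delta_t = -1.2)
  set.seed(20)
  mins <- vapply(1:5, function(i) {
    obs <- observer_params(gain = 2, criterion = 1)
    tr <- run_detection_session(obs, d, seed = 100 + i)
    min_same_location_interval(tr, d)
  }, 0)
  expect_true(all(mins >= 30))
})

test_that("failed trials are repeated and replacements enter the analysis", {
  # a slow thermal model at a deep target produces frequent failures
  d <- session_design(experiment = 1, target_delta_t = -1.9,
                      thermal = thermal_params(asymptote_degC = 2.0,
                                               tau_s = 6, rate_sdlog = 0.6))
  obs <- observer_params(gain = 2, criterion = 1)
  tr <- run_detection_session(obs, d, seed = 55)
  expect_gt(sum(tr$failed), 0)
  ok <- tr[!tr$failed, ]
  for (cond in d$conditions) {
    expect_equal(sum(ok$condition == cond & ok$signal_present), 27)
    expect_equal(sum(ok$condition == cond & !ok$signal_present), 27)
  }
  # repetitions keep the revisit window: thermal recovery holds throughout
  expect_gte(min_same_location_interval(tr, d), 30)
})

test_that("sessions are reproducible under a fixed seed", {
  d <- session_design(experiment = 3)
  obs <- observer_params(gain = 2, criterion = 1)
  expect_identical(run_detection_session(obs, d, seed = 8),
                   run_detection_session(obs, d, seed = 8))
})

test_that("session design validates its inputs", {
  expect_error(session_design(experiment = 4), "1, 2 or 3")
  expect_error(session_design(target_delta_t = -2.5), "-2.0")
  expect_error(session_design(target_delta_t = 0.3), "-2.0")
  expect_error(session_design(n_signal = 0), "positive")
})
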