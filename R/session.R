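#' Design of one detection session
#'
#' Experiments 1 and 2 compare Cold against ColdTouch; Experiment 3 adds
#' ColdSound. Each condition contributes 27 signal (cooling present) and 27
#' noise (cooling absent) trials, fully interleaved. Cooling is delivered at
#' one of nine grid locations (3 x 3, 1 cm spacing), and a location is only
#' revisited after at least `min_intervening_locations` other locations, so
#' that each site gets at least 30 s of thermal recovery between cooling
#' events.
#'
#' @param experiment 1, 2 or 3; fixes the condition set.
#' @param target_delta_t Cooling target in degC (negative), normally the
#'   staircase-estimated per cent-correct point. Must lie in [-2.0, -0.2].
#' @param n_signal,n_noise Signal and noise trials per condition. Default 27.
#' @param n_locations Number of grid locations. Default 9.
#' @param min_intervening_locations Minimum number of other locations visited
#'   between successive trials at the same location. Default 3.
#' @param baseline_s Baseline temperature-sampling window at trial start (s).
#' @param lead_s Pre-stimulus lead of the alerting/tactile/auditory signal
#'   before cooling onset (s).
#' @param timeout_s Cooling time-out; a signal trial that has not reached the
#'   target by then is marked failed (s).
#' @param iti_s Inter-trial interval (s).
#' @param response_s Nominal time from end of cooling to the spoken/keyed
#'   response; affects only the timeline (s).
#' @param min_recovery_s Minimum elapsed time between the end of one cooling
#'   exposure and the start of the next at the same location (s). The
#'   schedule's revisit constraint satisfies this by construction; the
#'   session additionally waits out any remainder before a repeated failed
#'   trial whose slot could not be separated far enough. Default 30.
#' @param sampling_hz_mean,sampling_hz_sd Thermal-camera sampling-loop rate
#'   (Hz): jittered per sample, truncated positive.
#' @param thermal A [thermal_params()] list for the cooling-dynamics model.
#' @return An object of class `session_design`.
#' @export
session_design <- function(experiment = 1, target_delta_t = -1.0,
                           n_signal = 27, n_noise = 27,
                           n_locations = 9, min_intervening_locations = 3,
                           baseline_s = 0.5, lead_s = 2, timeout_s = 10,
                           iti_s = 8, response_s = 1.5, min_recovery_s = 30,
                           sampling_hz_mean = 7.24, sampling_hz_sd = 1.44,
                           thermal = thermal_params()) {
  if (!experiment %in% 1:3) stop("experiment must be 1, 2 or 3")
  if (!(target_delta_t >= -2.0 && target_delta_t <= -0.2)) {
    stop("target_delta_t must lie in [-2.0, -0.2] degC")
  }
  if (n_signal < 1 || n_noise < 1) stop("trial counts must be positive")
  conditions <- if (experiment == 3) {
    c("Cold", "ColdTouch", "ColdSound")
  } else {
    c("Cold", "ColdTouch")
  }
  structure(
    list(experiment = as.integer(experiment), conditions = conditions,
         target_delta_t = target_delta_t,
         n_signal = as.integer(n_signal), n_noise = as.integer(n_noise),
         n_locations = as.integer(n_locations),
         min_intervening_locations = as.integer(min_intervening_locations),
         baseline_s = baseline_s, lead_s = lead_s, timeout_s = timeout_s,
         iti_s = iti_s, response_s = response_s,
         min_recovery_s = min_recovery_s,
         sampling_hz_mean = sampling_hz_mean, sampling_hz_sd = sampling_hz_sd,
         thermal = thermal),
    class = "session_design"
  )
}

#' Parameters of the exponential-approach cooling model
#'
#' Skin temperature under the stimulator is modelled as
#' T(t) = -A * (1 - exp(-t / (tau / m))), with a per-trial lognormal rate
#' multiplier m (meanlog 0, sdlog `rate_sdlog`) standing in for trial-to-trial
#' variation in nozzle distance and local skin thermodynamics. The trial
#' fails when the target is not reached within the time-out. With the
#' defaults, targets near -1 degC take a median of about 2 s (most durations
#' in ~1-8 s) and a few percent of trials fail.
#'
#' @param asymptote_degC Asymptotic temperature decrease A (> 0, degC).
#' @param tau_s Nominal time constant tau (s).
#' @param rate_sdlog sdlog of the lognormal per-trial rate multiplier.
#' @return Named list of class `thermal_params`.
#' @export
thermal_params <- function(asymptote_degC = 2.4, tau_s = 4, rate_sdlog = 0.6) {
  stopifnot(asymptote_degC > 0, tau_s > 0, rate_sdlog >= 0)
  structure(list(asymptote_degC = asymptote_degC, tau_s = tau_s,
                 rate_sdlog = rate_sdlog),
            class = "thermal_params")
}

#' Analytic failure probability of the cooling model
#'
#' Probability that the deterministic crossing time tau/m * -log(1 - |x|/A)
#' exceeds the time-out, under the lognormal rate multiplier. Ignores the
#' finite sampling grid (which only delays detection of the crossing by less
#' than one sample), so it slightly underestimates the simulated rate; used
#' as the reference value in calibration checks.
#'
#' @param target_delta_t Cooling target in degC (negative).
#' @param thermal A [thermal_params()] list.
#' @param timeout_s Time-out in seconds.
#' @return Failure probability.
#' @export
thermal_fail_prob <- function(target_delta_t, thermal = thermal_params(),
                              timeout_s = 10) {
  frac <- abs(target_delta_t) / thermal$asymptote_degC
  if (frac >= 1) return(1)
  base_t <- thermal$tau_s * -log(1 - frac)
  # fail iff m < base_t / timeout
  stats::plnorm(base_t / timeout_s, 0, thermal$rate_sdlog)
}

#' Generate the trial schedule of a session
#'
#' Conditions and signal/noise trials are fully interleaved in uniform random
#' order. Grid locations are assigned so that no location repeats within a
#' window of `min_intervening_locations` trials: the first `n_locations`
#' trials visit every location once in random order, and each later trial
#' draws uniformly from the locations not used in the preceding window. This
#' construction guarantees the revisit constraint for cooling events and uses
#' all locations.
#'
#' @param design A [session_design()].
#' @param seed Optional integer seed.
#' @return Data frame with columns `condition`, `signal_present`,
#'   `grid_location` (0-based), one row per scheduled trial.
#' @export
make_schedule <- function(design, seed = NULL) {
  stopifnot(inherits(design, "session_design"))
  k <- design$n_locations
  w <- design$min_intervening_locations
  if (k <= w) {
    stop("revisit constraint unsatisfiable: need more than ",
         w, " locations, have ", k)
  }
  with_seed(seed, {
    cond <- rep(design$conditions, each = design$n_signal + design$n_noise)
    sig <- rep(rep(c(TRUE, FALSE), c(design$n_signal, design$n_noise)),
               length(design$conditions))
    ord <- sample.int(length(cond))
    cond <- cond[ord]; sig <- sig[ord]
    n <- length(cond)
    loc <- integer(n)
    first <- sample.int(k) - 1L
    m <- min(k, n)
    loc[seq_len(m)] <- first[seq_len(m)]
    if (n > k) {
      for (i in (k + 1L):n) {
        recent <- loc[(i - w):(i - 1L)]
        choicesv <- setdiff(0:(k - 1L), recent)
        loc[i] <- if (length(choicesv) == 1) choicesv else sample(choicesv, 1)
      }
    }
    data.frame(condition = cond, signal_present = sig, grid_location = loc)
  })
}

#' Simulate one cooling exposure
#'
#' Samples the exponential-approach temperature trace at jittered intervals
#' (per-sample rate drawn from Normal(`sampling_hz_mean`, `sampling_hz_sd`),
#' truncated positive) and closes the shutter at the first sample at or below
#' the target. If the target is not reached within the time-out the trial is
#' failed and the exposure lasts the full time-out.
#'
#' @param target_delta_t Cooling target in degC (negative).
#' @param design A [session_design()] supplying the thermal parameters,
#'   sampling rate and time-out.
#' @return List with `trace` (data frame `time_s`, `temp_degC`), `duration_s`,
#'   `achieved_delta_t` (trace value at shutter close, or at time-out when
#'   failed) and `failed`.
#' @export
simulate_cooling <- function(target_delta_t, design = session_design()) {
  if (!(is.numeric(target_delta_t) && target_delta_t < 0)) {
    stop("target_delta_t must be negative (a cooling)")
  }
  th <- design$thermal
  m <- stats::rlnorm(1, 0, th$rate_sdlog)
  tau_eff <- th$tau_s / m
  # jittered sampling instants out to the time-out
  n_max <- ceiling(design$timeout_s * (design$sampling_hz_mean +
                                         4 * design$sampling_hz_sd)) + 2
  rates <- stats::rnorm(n_max, design$sampling_hz_mean, design$sampling_hz_sd)
  rates <- pmax(rates, 0.5)
  t_k <- cumsum(1 / rates)
  t_k <- t_k[t_k <= design$timeout_s]
  temp <- -th$asymptote_degC * (1 - exp(-t_k / tau_eff))
  hit <- which(temp <= target_delta_t)
  if (length(hit) > 0) {
    i <- hit[1]
    list(trace = data.frame(time_s = t_k[seq_len(i)],
                            temp_degC = temp[seq_len(i)]),
         duration_s = t_k[i], achieved_delta_t = temp[i], failed = FALSE)
  } else {
    nT <- length(t_k)
    list(trace = data.frame(time_s = t_k, temp_degC = temp),
         duration_s = design$timeout_s,
         achieved_delta_t = if (nT > 0) temp[nT] else 0, failed = TRUE)
  }
}

# nominal (median) crossing time used for noise trials before any signal
# trial has recorded a duration
nominal_duration <- function(design) {
  th <- design$thermal
  frac <- min(abs(design$target_delta_t) / th$asymptote_degC, 0.99)
  min(th$tau_s * -log(1 - frac), design$timeout_s)
}

classify_outcome <- function(signal_present, response) {
  ifelse(signal_present,
         ifelse(response, "hit", "miss"),
         ifelse(response, "false_alarm", "correct_rejection"))
}

# Insert a repeated (failed) trial at a random later queue position that
# keeps the location-revisit window intact on both sides; falls back to the
# first feasible position, scanning from a random start.
reinsert_failed <- function(queue, row, recent_locs, w) {
  npos <- nrow(queue) + 1L
  feasible <- function(pos) {
    before <- c(recent_locs, queue$grid_location[seq_len(pos - 1L)])
    before <- utils::tail(before, w)
    after <- queue$grid_location[seq(pos, length.out = min(w, npos - pos))]
    !(row$grid_location %in% c(before, after))
  }
  start <- sample.int(npos, 1)
  for (off in 0:(npos - 1L)) {
    pos <- ((start - 1L + off) %% npos) + 1L
    if (feasible(pos)) {
      return(rbind(queue[seq_len(pos - 1L), , drop = FALSE], row,
                   queue[seq(pos, length.out = npos - pos), , drop = FALSE]))
    }
  }
  rbind(queue, row) # no feasible slot (tiny grids only); append regardless
}

#' Run one simulated detection session
#'
#' Executes the schedule trial by trial. Signal trials draw a cooling
#' exposure from [simulate_cooling()] and the observer responds to the
#' achieved temperature change; noise trials deliver no cooling, last as long
#' as a duration resampled from the successful signal exposures recorded so
#' far (the matched-duration replay), and the observer responds at its
#' false-alarm rate for the condition. Failed signal trials (time-out) are
#' recorded with `failed = TRUE`, do not enter the analysis, and are repeated
#' at a random later point of the session that still respects the
#' location-revisit window.
#'
#' @param obs An [observer_params()] observer.
#' @param design A [session_design()].
#' @param seed Optional integer seed for the whole session.
#' @param participant_id Identifier copied into each record.
#' @return Data frame of trial records: `participant_id`, `experiment`,
#'   `condition`, `trial_index`, `grid_location`, `signal_present`,
#'   `target_delta_t`, `achieved_delta_t`, `cooling_duration`, `onset_time`,
#'   `end_time`, `response`, `outcome_class`, `failed`.
#' @export
run_detection_session <- function(obs, design, seed = NULL,
                                  participant_id = 1L) {
  stopifnot(inherits(obs, "observer_params"),
            inherits(design, "session_design"))
  with_seed(seed, {
    queue <- make_schedule(design)
    w <- design$min_intervening_locations
    sig_durations <- numeric(0)
    executed_locs <- integer(0)
    last_cool_end <- rep(-Inf, design$n_locations)
    records <- vector("list", 0)
    t_now <- 0
    idx <- 0L
    while (nrow(queue) > 0) {
      row <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      idx <- idx + 1L
      if (row$signal_present) {
        # wait out whatever remains of the site's thermal-recovery window
        # (only ever positive for repeats of failed trials squeezed near the
        # end of the session)
        deficit <- last_cool_end[row$grid_location + 1L] +
          design$min_recovery_s -
          (t_now + design$baseline_s + design$lead_s)
        if (is.finite(deficit) && deficit > 0) t_now <- t_now + deficit
      }
      onset <- t_now
      cool_start <- onset + design$baseline_s + design$lead_s
      if (row$signal_present) {
        cool <- simulate_cooling(design$target_delta_t, design)
        dur <- cool$duration_s
        achieved <- cool$achieved_delta_t
        failed <- cool$failed
        resp <- simulate_response(obs, row$condition,
                                  min(achieved, -1e-9))
      } else {
        dur <- if (length(sig_durations) > 0) {
          sig_durations[sample.int(length(sig_durations), 1)]
        } else {
          nominal_duration(design)
        }
        achieved <- NA_real_
        failed <- FALSE
        resp <- simulate_response(obs, row$condition, NA_real_)
      }
      end_t <- cool_start + dur + design$response_s
      records[[idx]] <- data.frame(
        participant_id = participant_id, experiment = design$experiment,
        condition = row$condition, trial_index = idx,
        grid_location = row$grid_location,
        signal_present = row$signal_present,
        target_delta_t = if (row$signal_present) design$target_delta_t
                         else NA_real_,
        achieved_delta_t = achieved, cooling_duration = dur,
        onset_time = onset, end_time = end_t,
        response = resp,
        outcome_class = if (failed) NA_character_
                        else classify_outcome(row$signal_present, resp),
        failed = failed)
      if (row$signal_present) {
        if (!failed) sig_durations <- c(sig_durations, dur)
        last_cool_end[row$grid_location + 1L] <- cool_start + dur
      }
      executed_locs <- c(executed_locs, row$grid_location)
      if (failed) {
        queue <- reinsert_failed(queue, row, executed_locs, w)
      }
      t_now <- end_t + design$iti_s
    }
    do.call(rbind, records)
  })
}

#' Minimum same-location interval between cooling events
#'
#' Scans the trial records of one session for successive cooling exposures
#' (signal trials, including failed ones) at the same grid location and
#' returns the minimum elapsed time from the end of one exposure to the onset
#' of the next. This is the thermal-recovery window the schedule must keep
#' at or above 30 s.
#'
#' @param trials Trial records from [run_detection_session()].
#' @param design The [session_design()] the session was run with (supplies
#'   the baseline/lead/response timing needed to place the cooling window
#'   inside each trial).
#' @return Minimum interval in seconds (`Inf` if no location is revisited).
#' @export
min_same_location_interval <- function(trials, design = session_design()) {
  sig <- trials[trials$signal_present, , drop = FALSE]
  if (nrow(sig) < 2) return(Inf)
  cool_start <- sig$onset_time + design$baseline_s + design$lead_s
  cool_end <- cool_start + sig$cooling_duration
  best <- Inf
  for (loc in unique(sig$grid_location)) {
    i <- which(sig$grid_location == loc)
    if (length(i) < 2) next
    gaps <- cool_start[i[-1]] - cool_end[i[-length(i)]]
    best <- min(best, gaps)
  }
  best
}
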