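#' Configuration of one 3-down/1-up weighted staircase branch
#'
#' Levels are skin-temperature decreases from baseline, so they are negative;
#' "weaken" moves the level toward zero (down step, after three consecutive
#' yes responses once the rule is armed) and "strengthen" moves it away from
#' zero (up step, after a single no). The unequal steps (+0.1 vs -0.14 degC)
#' make this a weighted staircase whose asymptotic convergence point is the
#' level detected with probability (0.14/0.24)^(1/3), about 0.84 - in
#' practice the procedure tracks the ~80% per cent-correct point.
#'
#' @param down_step Step toward zero after the required run of yes responses,
#'   in degC (> 0). Default +0.1.
#' @param up_step Step away from zero after a no, in degC (< 0).
#'   Default -0.14.
#' @param upper_bound Weakest allowed level in degC (closest to zero).
#'   Default -0.2.
#' @param lower_bound Strongest allowed level in degC. Default -2.0.
#' @param start_level Starting level in degC: -0.2 for the branch that grows
#'   progressively colder, -1.2 for the branch that grows progressively less
#'   cold.
#' @param n_reversals_stop Number of recorded reversals that terminates the
#'   branch. Default 12.
#' @param n_reversals_ignore Leading reversals discarded by
#'   [estimate_threshold()]. Default 3.
#' @param max_trials Safety cap on trials per branch for degenerate response
#'   patterns that never produce 12 reversals. Default 200.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(down_step = 0.1, up_step = -0.14,
                             upper_bound = -0.2, lower_bound = -2.0,
                             start_level = -0.2, n_reversals_stop = 12,
                             n_reversals_ignore = 3, max_trials = 200) {
  if (!(lower_bound < upper_bound && upper_bound < 0)) {
    stop("need lower_bound < upper_bound < 0")
  }
  if (start_level < lower_bound || start_level > upper_bound) {
    stop("start_level must lie within [lower_bound, upper_bound]")
  }
  if (!(down_step > 0 && up_step < 0)) stop("need down_step > 0 > up_step")
  if (n_reversals_ignore >= n_reversals_stop) {
    stop("n_reversals_ignore must be < n_reversals_stop")
  }
  structure(
    list(down_step = down_step, up_step = up_step,
         upper_bound = upper_bound, lower_bound = lower_bound,
         start_level = start_level,
         n_reversals_stop = as.integer(n_reversals_stop),
         n_reversals_ignore = as.integer(n_reversals_ignore),
         max_trials = as.integer(max_trials)),
    class = "staircase_config"
  )
}

#' Initial state of a staircase branch
#'
#' @param cfg A [staircase_config()].
#' @return An object of class `staircase_state` holding the current level,
#'   the yes-run counter, reversal levels, the per-trial log and termination
#'   flags.
#' @export
staircase_init <- function(cfg) {
  stopifnot(inherits(cfg, "staircase_config"))
  structure(
    list(current_level = cfg$start_level,
         consecutive_yes = 0L,
         first_no_seen = FALSE,
         last_move_direction = "none",  # weaken | strengthen | none
         reversal_levels = numeric(0),
         trial_levels = numeric(0),
         trial_responses = logical(0),
         trial_reversal = logical(0),
         finished = FALSE,
         termination_reason = NA_character_),
    class = "staircase_state"
  )
}

# Execute a proposed move with boundary clamping (carry-on rule) and reversal
# bookkeeping. A move clamped into a non-move records neither a direction nor
# a reversal; the run simply continues at the bound.
apply_move <- function(state, cfg, direction) {
  step <- if (direction == "weaken") cfg$down_step else cfg$up_step
  proposed <- state$current_level + step
  new_level <- clamp(proposed, cfg$lower_bound, cfg$upper_bound)
  if (new_level == state$current_level) return(state) # clamped non-move
  reversal <- state$last_move_direction != "none" &&
    state$last_move_direction != direction
  if (reversal) {
    # the reversal is logged at the level where the turn happens (pre-move)
    state$reversal_levels <- c(state$reversal_levels, state$current_level)
    state$trial_reversal[length(state$trial_reversal)] <- TRUE
  }
  state$current_level <- new_level
  state$last_move_direction <- direction
  state$consecutive_yes <- 0L
  state
}

#' Advance a staircase branch by one trial
#'
#' Implements the 3-down/1-up rule armed by the first "no": before the first
#' no, every yes weakens the stimulus by one down step (1-down lead-in) and
#' the first no both arms the full rule and strengthens the stimulus. From
#' then on a single no strengthens, and three consecutive yes responses
#' weaken. Proposed levels beyond the bounds are clamped to the bound and the
#' run carries on. A reversal is recorded whenever an executed move changes
#' direction relative to the previous executed move; the branch finishes at
#' `n_reversals_stop` reversals or at the `max_trials` safety cap.
#'
#' @param state A [staircase_init()] state (not yet finished).
#' @param cfg The branch's [staircase_config()].
#' @param response `TRUE` for "yes" (cooling detected), `FALSE` for "no".
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, cfg, response) {
  stopifnot(inherits(state, "staircase_state"),
            inherits(cfg, "staircase_config"),
            is.logical(response), length(response) == 1, !is.na(response))
  if (state$finished) stop("cannot update a finished staircase")

  state$trial_levels <- c(state$trial_levels, state$current_level)
  state$trial_responses <- c(state$trial_responses, response)
  state$trial_reversal <- c(state$trial_reversal, FALSE)

  if (response) {
    if (!state$first_no_seen) {
      state <- apply_move(state, cfg, "weaken")
    } else {
      state$consecutive_yes <- state$consecutive_yes + 1L
      if (state$consecutive_yes >= 3L) {
        state <- apply_move(state, cfg, "weaken")
      }
    }
  } else {
    state$first_no_seen <- TRUE
    state <- apply_move(state, cfg, "strengthen")
  }

  if (length(state$reversal_levels) >= cfg$n_reversals_stop) {
    state$finished <- TRUE
    state$termination_reason <- "reversals"
  } else if (length(state$trial_levels) >= cfg$max_trials) {
    state$finished <- TRUE
    state$termination_reason <- "trial_cap"
  }
  state
}

#' Threshold estimate from reversal levels
#'
#' Arithmetic mean of the reversal levels after discarding the first
#' `n_ignore`. The `"no_trials"` method instead averages the levels of "no"
#' trials after discarding the first three "no" trials, an alternative
#' reading of how reversal-based procedures are sometimes summarised; the
#' reversal-mean is the default and the one used by the pipeline.
#'
#' @param reversal_levels Numeric vector of reversal levels in degC (for the
#'   default method), or a finished `staircase_state` (either method).
#' @param n_ignore Number of leading reversals (or "no" trials) to discard.
#' @param method `"reversals"` (default) or `"no_trials"`.
#' @return Threshold estimate in degC.
#' @export
estimate_threshold <- function(reversal_levels, n_ignore = 3,
                               method = c("reversals", "no_trials")) {
  method <- match.arg(method)
  if (inherits(reversal_levels, "staircase_state")) {
    state <- reversal_levels
    if (method == "no_trials") {
      lv <- state$trial_levels[!state$trial_responses]
      if (length(lv) <= n_ignore) {
        stop("too few 'no' trials to estimate a threshold (have ",
             length(lv), ", need > ", n_ignore, ")")
      }
      return(mean(lv[-seq_len(n_ignore)]))
    }
    reversal_levels <- state$reversal_levels
  }
  if (length(reversal_levels) <= n_ignore) {
    stop("too few reversals to estimate a threshold (have ",
         length(reversal_levels), ", need > ", n_ignore, ")")
  }
  mean(reversal_levels[-seq_len(n_ignore)])
}

#' Average the two interleaved branch estimates
#'
#' @param t_desc,t_asc Branch threshold estimates in degC; `NA` if a branch
#'   failed to terminate by reversals.
#' @return Arithmetic mean, or `NA` if either branch estimate is undefined.
#' @export
combine_branches <- function(t_desc, t_asc) {
  if (is.na(t_desc) || is.na(t_asc)) return(NA_real_)
  (t_desc + t_asc) / 2
}

#' Run the dual interleaved staircase on a simulated observer
#'
#' Two parallel branches - one starting weak at -0.2 degC and growing
#' progressively colder, one starting at -1.2 degC and growing progressively
#' less cold - are interleaved by choosing one unfinished branch uniformly at
#' random on each trial. Responses come from the observer in the Cold
#' condition (the threshold phase runs without touch). Each branch runs to
#' its own termination; branch thresholds are the reversal means (ignoring
#' the first `n_reversals_ignore`) and the final estimate averages the two
#' branches.
#'
#' @param obs An [observer_params()] observer.
#' @param cfg_desc,cfg_asc Branch configurations; defaults are the standard
#'   pair of [staircase_config()]s with starts -0.2 and -1.2 degC.
#' @param seed Optional integer seed for the run (interleaving order and
#'   observer responses).
#' @return List with `threshold` (degC, `NA` if undefined), `ok` (logical:
#'   both branches terminated by reversals), the per-branch estimates, and
#'   the two `staircase_state` logs (`desc`, `asc`).
#' @export
run_dual_staircase <- function(obs,
                               cfg_desc = staircase_config(start_level = -0.2),
                               cfg_asc = staircase_config(start_level = -1.2),
                               seed = NULL) {
  stopifnot(inherits(obs, "observer_params"))
  with_seed(seed, {
    states <- list(desc = staircase_init(cfg_desc),
                   asc = staircase_init(cfg_asc))
    cfgs <- list(desc = cfg_desc, asc = cfg_asc)
    repeat {
      open <- names(states)[!vapply(states, `[[`, TRUE, "finished")]
      if (length(open) == 0) break
      b <- if (length(open) == 1) open else sample(open, 1)
      resp <- simulate_response(obs, "Cold", states[[b]]$current_level)
      states[[b]] <- staircase_update(states[[b]], cfgs[[b]], resp)
    }
    est_one <- function(b) {
      st <- states[[b]]
      if (st$termination_reason != "reversals") return(NA_real_)
      estimate_threshold(st$reversal_levels, cfgs[[b]]$n_reversals_ignore)
    }
    t_desc <- est_one("desc")
    t_asc <- est_one("asc")
    list(threshold = combine_branches(t_desc, t_asc),
         ok = !is.na(t_desc) && !is.na(t_asc),
         threshold_desc = t_desc, threshold_asc = t_asc,
         desc = states$desc, asc = states$asc)
  })
}

#' Tidy per-trial log of one or two staircase branches
#'
#' @param x A `staircase_state`, or the result of [run_dual_staircase()].
#' @return A data frame with columns `trial_index`, `branch`, `level_degC`,
#'   `response`, `reversal_flag`.
#' @export
staircase_log <- function(x) {
  one <- function(st, branch) {
    n <- length(st$trial_levels)
    data.frame(trial_index = seq_len(n), branch = rep(branch, n),
               level_degC = st$trial_levels, response = st$trial_responses,
               reversal_flag = st$trial_reversal)
  }
  if (inherits(x, "staircase_state")) return(one(x, "single"))
  rbind(one(x$desc, "desc"), one(x$asc, "asc"))
}
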