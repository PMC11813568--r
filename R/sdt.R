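#' Tabulate detection outcomes for one condition
#'
#' Crosses signal presence with the yes/no response: hit = yes on a signal
#' trial, miss = no on a signal trial, false alarm = yes on a noise trial,
#' correct rejection = no on a noise trial. Failed (timed-out) trials are
#' dropped; their repetitions carry the analysable outcomes.
#'
#' @param trials Trial records of one participant (see
#'   [run_detection_session()]).
#' @param condition Condition label to tabulate.
#' @return Object of class `sdt_counts`: `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`, `n_signal`, `n_noise`, plus `accuracy`
#'   ((hits + correct rejections) / all trials) and `degenerate` (TRUE when
#'   no trials match).
#' @export
tabulate_counts <- function(trials, condition) {
  check_condition(condition)
  tr <- trials[!is.na(trials$condition) & trials$condition == condition &
                 !trials$failed, , drop = FALSE]
  hits <- sum(tr$signal_present & tr$response)
  misses <- sum(tr$signal_present & !tr$response)
  fas <- sum(!tr$signal_present & tr$response)
  crs <- sum(!tr$signal_present & !tr$response)
  n_s <- hits + misses
  n_n <- fas + crs
  structure(
    list(hits = hits, misses = misses, false_alarms = fas,
         correct_rejections = crs, n_signal = n_s, n_noise = n_n,
         accuracy = if (n_s + n_n > 0) (hits + crs) / (n_s + n_n) else NA_real_,
         degenerate = (n_s + n_n) == 0),
    class = "sdt_counts"
  )
}

#' Construct outcome counts directly
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative counts.
#' @return An `sdt_counts` object.
#' @export
sdt_counts <- function(hits, misses, false_alarms, correct_rejections) {
  cts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(cts < 0) || any(cts != round(cts))) {
    stop("counts must be non-negative integers")
  }
  n_s <- hits + misses
  n_n <- false_alarms + correct_rejections
  structure(
    list(hits = hits, misses = misses, false_alarms = false_alarms,
         correct_rejections = correct_rejections,
         n_signal = n_s, n_noise = n_n,
         accuracy = if (n_s + n_n > 0)
           (hits + correct_rejections) / (n_s + n_n) else NA_real_,
         degenerate = (n_s + n_n) == 0),
    class = "sdt_counts"
  )
}

#' Loglinear-corrected hit and false-alarm rates
#'
#' The loglinear correction adds 0.5 to the hit and false-alarm counts and 1
#' to each trial count before computing rates, keeping every rate strictly
#' inside (0, 1) even at 0 or n out of n. By default the correction is
#' applied to every cell uniformly (the standard form, which avoids biasing
#' comparisons between corrected and uncorrected participants); the
#' `"conditional"` variant corrects only when a raw rate is exactly 0 or 1.
#'
#' @param counts An `sdt_counts` object.
#' @param variant `"uniform"` (default) or `"conditional"`.
#' @return List with `hit_rate`, `fa_rate`, `correction_applied`.
#' @export
loglinear_rates <- function(counts, variant = c("uniform", "conditional")) {
  variant <- match.arg(variant)
  stopifnot(inherits(counts, "sdt_counts"))
  if (counts$n_signal == 0 || counts$n_noise == 0) {
    stop("cannot compute rates with zero signal or noise trials")
  }
  raw_h <- counts$hits / counts$n_signal
  raw_f <- counts$false_alarms / counts$n_noise
  extreme <- raw_h %in% c(0, 1) || raw_f %in% c(0, 1)
  if (variant == "uniform" || extreme) {
    list(hit_rate = (counts$hits + 0.5) / (counts$n_signal + 1),
         fa_rate = (counts$false_alarms + 0.5) / (counts$n_noise + 1),
         correction_applied = TRUE)
  } else {
    list(hit_rate = raw_h, fa_rate = raw_f, correction_applied = FALSE)
  }
}

check_rate <- function(r, name) {
  if (!(is.numeric(r) && length(r) == 1 && r > 0 && r < 1)) {
    stop(name, " must lie strictly in (0, 1); apply the loglinear ",
         "correction before computing d' or C")
  }
  r
}

#' Sensitivity index d'
#'
#' d' = z(hit rate) - z(false-alarm rate), z being the standard-normal
#' quantile. Rates must be strictly inside (0, 1) (see [loglinear_rates()]).
#'
#' @param hit_rate,fa_rate Corrected rates in (0, 1).
#' @return d' (dimensionless).
#' @export
d_prime <- function(hit_rate, fa_rate) {
  check_rate(hit_rate, "hit_rate")
  check_rate(fa_rate, "fa_rate")
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Response bias C
#'
#' C = (z(hit rate) + z(false-alarm rate)) / 2. Note the sign convention:
#' negative C indicates a tendency to respond "no" (conservative), positive C
#' a tendency to respond "yes" (liberal). This is the negative of the
#' textbook c = -(zH + zF)/2; the convention is chosen so that the sign of C
#' reads directly as the direction of the response tendency.
#'
#' @inheritParams d_prime
#' @return C (dimensionless).
#' @export
criterion_C <- function(hit_rate, fa_rate) {
  check_rate(hit_rate, "hit_rate")
  check_rate(fa_rate, "fa_rate")
  (stats::qnorm(hit_rate) + stats::qnorm(fa_rate)) / 2
}

#' Full SDT summary of one participant x condition cell
#'
#' @param counts An `sdt_counts` object.
#' @param variant Correction variant passed to [loglinear_rates()].
#' @return Object of class `sdt_result`: corrected `hit_rate` and `fa_rate`,
#'   `d_prime`, `criterion_C`, `accuracy` (raw), `correction_applied`.
#' @export
sdt_result <- function(counts, variant = "uniform") {
  rates <- loglinear_rates(counts, variant)
  structure(
    list(hit_rate = rates$hit_rate, fa_rate = rates$fa_rate,
         d_prime = d_prime(rates$hit_rate, rates$fa_rate),
         criterion_C = criterion_C(rates$hit_rate, rates$fa_rate),
         accuracy = counts$accuracy,
         correction_applied = rates$correction_applied),
    class = "sdt_result"
  )
}

#' Per-participant, per-condition SDT table for a whole experiment
#'
#' @param trials Trial records of one or more participants.
#' @param variant Correction variant passed to [loglinear_rates()].
#' @return Data frame with one row per participant x condition:
#'   `participant_id`, `condition`, counts, corrected rates, `d_prime`,
#'   `criterion_C`, `accuracy`.
#' @export
sdt_table <- function(trials, variant = "uniform") {
  out <- list()
  for (pid in unique(trials$participant_id)) {
    tr <- trials[trials$participant_id == pid, , drop = FALSE]
    for (cond in intersect(conditions_all(), unique(tr$condition))) {
      cts <- tabulate_counts(tr, cond)
      res <- sdt_result(cts, variant)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, condition = cond,
        hits = cts$hits, misses = cts$misses,
        false_alarms = cts$false_alarms,
        correct_rejections = cts$correct_rejections,
        hit_rate = res$hit_rate, fa_rate = res$fa_rate,
        d_prime = res$d_prime, criterion_C = res$criterion_C,
        accuracy = res$accuracy)
    }
  }
  do.call(rbind, out)
}
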