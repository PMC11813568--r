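#' Fast simulation of a cohort's SDT table at fixed stimulus levels
#'
#' Simulates the detection phase of a whole cohort by drawing hit and
#' false-alarm counts binomially at each observer's analytic yes-rates for a
#' given stimulus level, skipping the trial-by-trial session machinery
#' (scheduling, timing, failed-trial repetition - none of which alter the
#' response distribution of the equal-variance observer). This is the tool
#' for Monte-Carlo calibration studies (type-I error, power curves) that
#' need thousands of cohorts.
#'
#' @param observers List of [observer_params()] (e.g. from
#'   [sample_cohort()]).
#' @param delta_t Stimulus level in degC presented on signal trials; either a
#'   single value or one per observer (e.g. per-participant staircase
#'   thresholds).
#' @param conditions Condition labels to simulate. Default Cold + ColdTouch.
#' @param n_signal,n_noise Trials per condition. Default 27 each.
#' @param variant Correction variant for [loglinear_rates()].
#' @param seed Optional integer seed.
#' @return A data frame in [sdt_table()] format.
#' @export
simulate_cohort_sdt <- function(observers, delta_t,
                                conditions = c("Cold", "ColdTouch"),
                                n_signal = 27, n_noise = 27,
                                variant = "uniform", seed = NULL) {
  stopifnot(length(observers) >= 1)
  lv <- rep_len(delta_t, length(observers))
  with_seed(seed, {
    out <- list()
    for (i in seq_along(observers)) {
      obs <- observers[[i]]
      for (cond in conditions) {
        ph <- p_yes(obs, cond, lv[i])
        pf <- p_yes(obs, cond, NA_real_)
        hits <- stats::rbinom(1, n_signal, ph)
        fas <- stats::rbinom(1, n_noise, pf)
        cts <- sdt_counts(hits, n_signal - hits, fas, n_noise - fas)
        res <- sdt_result(cts, variant)
        out[[length(out) + 1L]] <- data.frame(
          participant_id = i, condition = cond,
          hits = cts$hits, misses = cts$misses,
          false_alarms = cts$false_alarms,
          correct_rejections = cts$correct_rejections,
          hit_rate = res$hit_rate, fa_rate = res$fa_rate,
          d_prime = res$d_prime, criterion_C = res$criterion_C,
          accuracy = res$accuracy)
      }
    }
    do.call(rbind, out)
  })
}

#' Monte-Carlo rejection rate of the planned gating comparison
#'
#' Repeatedly samples a cohort, simulates its SDT table at a fixed stimulus
#' level via [simulate_cohort_sdt()], and runs the one-tailed paired
#' Cold-vs-ColdTouch d' comparison. With `gating_mean = 1, gating_sd = 0`
#' this measures the empirical type-I error of the planned test; with gating
#' below 1 it measures power.
#'
#' @param hyper A [cohort_hyperparams()] template; its seed is re-split per
#'   replicate.
#' @param delta_t Signal level in degC.
#' @param n_cohorts Number of simulated cohorts.
#' @param alpha Significance level of the planned test.
#' @param exclude Apply the floor/ceiling exclusion rule. Default FALSE (the
#'   calibration concerns the test itself).
#' @param seed Integer seed.
#' @return List: `rejection_rate`, `mean_delta_d_prime` (Cold minus
#'   ColdTouch), `n_cohorts`.
#' @export
planned_comparison_mc <- function(hyper, delta_t = -1.0, n_cohorts = 1000,
                                  alpha = 0.05, exclude = FALSE, seed = 1L) {
  rej <- logical(n_cohorts)
  dd <- numeric(n_cohorts)
  for (r in seq_len(n_cohorts)) {
    h <- hyper
    h$seed <- split_seed(seed, r, 1L)
    cohort <- sample_cohort(h)
    tab <- simulate_cohort_sdt(cohort, delta_t,
                               seed = split_seed(seed, r, 2L))
    if (exclude) tab <- apply_exclusions(tab)$kept
    w <- wide_measure(tab, "d_prime")
    tt <- paired_t(w$Cold, w$ColdTouch, tail = "one")
    rej[r] <- tt$p_value < alpha
    dd[r] <- tt$mean_difference
  }
  list(rejection_rate = mean(rej), mean_delta_d_prime = mean(dd),
       n_cohorts = n_cohorts)
}
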