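#' Paired t-test with effect size
#'
#' Wraps the standard paired t-test (on the differences x - y) and attaches
#' Cohen's d. One-tailed tests use the pre-registered direction mean(x) >
#' mean(y); for the sensitivity comparison the convention throughout the
#' package is x = Cold d', y = ColdTouch d', so the gating hypothesis is the
#' one-tailed alternative.
#'
#' @param x,y Paired per-participant values (equal length >= 2).
#' @param tail `"one"` (alternative mean(x) > mean(y)) or `"two"`.
#' @param effect `"d_av"` (mean difference over the average of the two
#'   condition SDs; default) or `"d_z"` (mean difference over the SD of the
#'   differences).
#' @return List of class `t_test_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `tail`, `mean_difference`,
#'   `sd_of_differences`, `cohen_d`, `n`, `method`.
#' @export
paired_t <- function(x, y, tail = c("two", "one"), effect = "d_av") {
  tail <- match.arg(tail)
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must be paired vectors of equal length >= 2")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("degenerate input: all pairwise differences are identical")
  }
  alt <- if (tail == "one") "greater" else "two.sided"
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  structure(
    list(t_statistic = unname(tt$statistic),
         degrees_of_freedom = unname(tt$parameter),
         p_value = tt$p.value, tail = tail,
         mean_difference = mean(d), sd_of_differences = stats::sd(d),
         cohen_d = cohen_d_av(x, y, paired = TRUE, variant = effect),
         n = length(x), method = "paired t"),
    class = "t_test_result"
  )
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, two-tailed.
#' Used to compare pooled cohorts across experiments (e.g. tone vs LED
#' alerting signals).
#'
#' @param group_a,group_b Independent samples (each length >= 2).
#' @return A `t_test_result` (with `n1`, `n2` instead of `n`).
#' @export
welch_t <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("degenerate input: both groups have zero variance")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  structure(
    list(t_statistic = unname(tt$statistic),
         degrees_of_freedom = unname(tt$parameter),
         p_value = tt$p.value, tail = "two",
         mean_difference = mean(group_a) - mean(group_b),
         sd_of_differences = NA_real_,
         cohen_d = (mean(group_a) - mean(group_b)) /
           ((stats::sd(group_a) + stats::sd(group_b)) / 2),
         n1 = length(group_a), n2 = length(group_b), method = "Welch t"),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s: t(%.4g) = %.4f, %s-tailed p = %.4g, d = %.3f\n",
              x$method, x$degrees_of_freedom, x$t_statistic, x$tail,
              x$p_value, x$cohen_d))
  invisible(x)
}

#' Cohen's d for a two-condition comparison
#'
#' The default `d_av` divides the mean difference by the average of the two
#' condition SDs, the definition that reproduces the printed effect sizes of
#' the summary statistics this package targets. `d_z` (mean difference over
#' SD of differences, paired designs only) is available as a variant.
#'
#' @param x,y Condition values; paired when `paired = TRUE`.
#' @param paired Whether observations are paired (required for `d_z`).
#' @param variant `"d_av"` or `"d_z"`.
#' @return Effect size (dimensionless).
#' @export
cohen_d_av <- function(x, y, paired = TRUE, variant = c("d_av", "d_z")) {
  variant <- match.arg(variant)
  if (variant == "d_z") {
    if (!paired) stop("d_z requires paired observations")
    d <- x - y
    if (stats::sd(d) == 0) stop("degenerate input: zero SD of differences")
    return(mean(d) / stats::sd(d))
  }
  s_av <- (stats::sd(x) + stats::sd(y)) / 2
  if (s_av == 0) stop("degenerate input: zero average SD")
  (mean(x) - mean(y)) / s_av
}

#' Exact power of the paired t-test
#'
#' Power of the paired (one-sample-on-differences) t-test with effect size d,
#' n pairs and significance level alpha, from the noncentral t distribution
#' with df = n - 1 and noncentrality d * sqrt(n).
#'
#' @param n Number of pairs (>= 2).
#' @param effect_size_d Cohen's d on the differences (> 0).
#' @param alpha Significance level.
#' @param tail `"one"` or `"two"`.
#' @return Power in (0, 1).
#' @export
power_paired_t <- function(n, effect_size_d, alpha = 0.05,
                           tail = c("one", "two")) {
  tail <- match.arg(tail)
  stopifnot(n >= 2, effect_size_d > 0, alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- effect_size_d * sqrt(n)
  if (tail == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp)
  }
}

#' A-priori sample size for the paired t-test
#'
#' Smallest n such that [power_paired_t()] reaches the requested power,
#' found by exact noncentral-t evaluation over increasing n.
#'
#' @param effect_size_d Cohen's d on the differences (> 0).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param tail `"one"` or `"two"`.
#' @param n_max Search cap (error if exceeded).
#' @return List of class `power_spec`: the inputs plus `solved_n` and
#'   `achieved_power`.
#' @examples
#' required_n_paired_t(0.857, 0.05, 0.80, "one")$solved_n # 10
#' @export
required_n_paired_t <- function(effect_size_d, alpha = 0.05, power = 0.80,
                                tail = c("one", "two"), n_max = 10000) {
  tail <- match.arg(tail)
  stopifnot(effect_size_d > 0, alpha > 0, alpha < 1)
  if (!(power > 0 && power < 1)) stop("power must lie strictly in (0, 1)")
  for (n in 2:n_max) {
    pw <- power_paired_t(n, effect_size_d, alpha, tail)
    if (pw >= power) {
      return(structure(
        list(effect_size_d = effect_size_d, alpha = alpha, power = power,
             tail = tail, solved_n = n, achieved_power = pw),
        class = "power_spec"
      ))
    }
  }
  stop("no n <= ", n_max, " reaches the requested power")
}

#' @export
print.power_spec <- function(x, ...) {
  cat(sprintf(
    "paired t, d = %.3f, alpha = %.3f (%s-tailed), power %.2f -> n = %d (achieved %.3f)\n",
    x$effect_size_d, x$alpha, x$tail, x$power, x$solved_n, x$achieved_power))
  invisible(x)
}

#' Floor/ceiling exclusion of participants
#'
#' Applies the a-priori criterion that a participant whose overall response
#' accuracy in any condition exceeds 95% or falls below 50% is excluded from
#' the cohort analysis.
#'
#' @param sdt_tab Output of [sdt_table()] (must carry `accuracy`).
#' @param upper,lower Accuracy bounds. Defaults 0.95 and 0.50.
#' @return List: `kept` (filtered table), `excluded_ids`.
#' @export
apply_exclusions <- function(sdt_tab, upper = 0.95, lower = 0.50) {
  bad <- unique(sdt_tab$participant_id[
    sdt_tab$accuracy > upper | sdt_tab$accuracy < lower])
  list(kept = sdt_tab[!(sdt_tab$participant_id %in% bad), , drop = FALSE],
       excluded_ids = bad)
}

wide_measure <- function(sdt_tab, measure) {
  w <- stats::reshape(
    sdt_tab[, c("participant_id", "condition", measure)],
    idvar = "participant_id", timevar = "condition", direction = "wide")
  names(w) <- sub(paste0("^", measure, "\\."), "", names(w))
  w
}

#' Cohort-level summary and planned comparisons for one experiment
#'
#' Per-condition mean and SD of d' and C, plus the planned comparisons:
#' Cold vs ColdTouch d' with a one-tailed paired t (pre-registered gating
#' direction), Cold vs ColdTouch C two-tailed, and - when ColdSound is
#' present - Cold vs ColdSound two-tailed for both d' and C (no directional
#' prediction for sound).
#'
#' @param sdt_tab Output of [sdt_table()]: one row per participant x
#'   condition with `d_prime`, `criterion_C` (and `accuracy` if the
#'   exclusion rule is to be applied).
#' @param experiment Experiment number (1-3) recorded in the summary.
#' @param exclude Apply [apply_exclusions()] first. Default TRUE.
#' @return List of class `experiment_summary`: `experiment`, `n`,
#'   `excluded_ids`, `condition_stats` (data frame of mean/SD per condition),
#'   and `comparisons` (named list of `t_test_result`s).
#' @export
experiment_summary <- function(sdt_tab, experiment = NULL, exclude = TRUE) {
  if (exclude && "accuracy" %in% names(sdt_tab)) {
    ex <- apply_exclusions(sdt_tab)
    sdt_tab <- ex$kept
    excluded <- ex$excluded_ids
  } else {
    excluded <- integer(0)
  }
  conds <- intersect(conditions_all(), unique(sdt_tab$condition))
  per_participant <- table(sdt_tab$participant_id)
  if (any(per_participant != length(conds))) {
    stop("every participant must contribute every condition exactly once")
  }
  n <- length(unique(sdt_tab$participant_id))
  if (n < 2) stop("need at least 2 participants after exclusions")

  cstats <- do.call(rbind, lapply(conds, function(cc) {
    s <- sdt_tab[sdt_tab$condition == cc, , drop = FALSE]
    data.frame(condition = cc,
               d_prime_mean = mean(s$d_prime), d_prime_sd = stats::sd(s$d_prime),
               C_mean = mean(s$criterion_C), C_sd = stats::sd(s$criterion_C),
               n = nrow(s))
  }))

  dmat <- wide_measure(sdt_tab, "d_prime")
  cmat <- wide_measure(sdt_tab, "criterion_C")
  comparisons <- list(
    d_prime_touch = paired_t(dmat$Cold, dmat$ColdTouch, tail = "one"),
    C_touch = paired_t(cmat$Cold, cmat$ColdTouch, tail = "two")
  )
  if ("ColdSound" %in% conds) {
    comparisons$d_prime_sound <-
      paired_t(dmat$Cold, dmat$ColdSound, tail = "two")
    comparisons$C_sound <- paired_t(cmat$Cold, cmat$ColdSound, tail = "two")
  }
  structure(
    list(experiment = experiment, n = n, excluded_ids = excluded,
         condition_stats = cstats, comparisons = comparisons),
    class = "experiment_summary"
  )
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat(sprintf("Experiment %s summary (n = %d%s)\n",
              if (is.null(x$experiment)) "?" else x$experiment, x$n,
              if (length(x$excluded_ids))
                paste0(", excluded: ", paste(x$excluded_ids, collapse = ","))
              else ""))
  print(x$condition_stats, row.names = FALSE)
  for (nm in names(x$comparisons)) {
    cat(sprintf("  %-14s", nm)); print(x$comparisons[[nm]])
  }
  invisible(x)
}

#' Cross-experiment pooled and between-groups comparisons
#'
#' Pools participants across experiments for the Cold vs ColdTouch paired
#' comparison (one-tailed for d', two-tailed for C), and compares the
#' tone-alerted cohorts (Experiments 1 and 2) against the LED-alerted cohort
#' (Experiment 3) with Welch's t-tests on Cold and ColdTouch d' and C.
#'
#' @param sdt_tabs Named list of [sdt_table()] outputs, one per experiment,
#'   names `"1"`, `"2"`, `"3"` (any subset of size >= 2).
#' @return List with `pooled_d_prime`, `pooled_C` (paired
#'   `t_test_result`s) and, when both groups are present, `welch` (a named
#'   list of Welch `t_test_result`s by measure and condition).
#' @export
cross_experiment_comparison <- function(sdt_tabs) {
  stopifnot(is.list(sdt_tabs), length(sdt_tabs) >= 2)
  grab <- function(tab, cond, measure) {
    tab[tab$condition == cond, measure]
  }
  all_tab <- do.call(rbind, lapply(names(sdt_tabs), function(e) {
    t <- sdt_tabs[[e]]
    t$participant_id <- paste0("e", e, "_", t$participant_id)
    t
  }))
  dmat <- wide_measure(all_tab, "d_prime")
  cmat <- wide_measure(all_tab, "criterion_C")
  out <- list(
    pooled_d_prime = paired_t(dmat$Cold, dmat$ColdTouch, tail = "one"),
    pooled_C = paired_t(cmat$Cold, cmat$ColdTouch, tail = "two")
  )
  tone <- intersect(names(sdt_tabs), c("1", "2"))
  if (length(tone) > 0 && "3" %in% names(sdt_tabs)) {
    tone_tab <- do.call(rbind, sdt_tabs[tone])
    led_tab <- sdt_tabs[["3"]]
    out$welch <- list()
    for (m in c("d_prime", "criterion_C")) {
      for (cc in c("Cold", "ColdTouch")) {
        out$welch[[paste(m, cc, sep = "_")]] <-
          welch_t(grab(tone_tab, cc, m), grab(led_tab, cc, m))
      }
    }
  }
  out
}
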