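#' Generative parameters of one simulated detection observer
#'
#' An equal-variance Gaussian signal-detection observer with linear
#' transduction of cooling magnitude. On a signal trial the internal evidence
#' is Normal(gain * g * |dT|, 1), where g is `gating_factor` when concurrent
#' touch is present and 1 otherwise; on a noise trial it is Normal(0, 1). The
#' observer responds "yes" when the evidence exceeds the criterion; under
#' concurrent sound the criterion is lowered by `sound_bias_shift` (a liberal
#' shift). A lapse mixes in a uniformly random response.
#'
#' Touch is modelled as a pure multiplicative gain reduction (a sensitivity
#' effect) and sound as a pure criterion shift (a bias effect), so each
#' experimental effect direction maps onto exactly one parameter.
#'
#' @param gain Evidence units per degree Celsius of cooling magnitude
#'   (> 0). Maps |dT| to the mean of the signal evidence distribution.
#' @param criterion Decision cut-off in evidence units.
#' @param gating_factor Multiplier in (0, 1] applied to `gain` when touch
#'   accompanies cooling; 1 means no gating.
#' @param sound_bias_shift Evidence units subtracted from the criterion when
#'   sound accompanies the trial; positive values make the observer more
#'   liberal ("yes"-prone) under sound.
#' @param lapse Probability in [0, 0.1] that the observer responds at random
#'   (0.5 either way) regardless of the stimulus.
#' @param seed Optional integer seed identifying this observer's RNG stream.
#' @return An object of class `observer_params`.
#' @examples
#' obs <- observer_params(gain = 2, criterion = 1)
#' p_yes(obs, "Cold", -1)
#' @export
observer_params <- function(gain = 2, criterion = 1, gating_factor = 1,
                            sound_bias_shift = 0, lapse = 0, seed = NULL) {
  stopifnot(is.numeric(gain), length(gain) == 1, gain > 0,
            is.numeric(criterion), length(criterion) == 1,
            gating_factor > 0, gating_factor <= 1,
            lapse >= 0, lapse <= 0.1)
  structure(
    list(gain = gain, criterion = criterion, gating_factor = gating_factor,
         sound_bias_shift = sound_bias_shift, lapse = lapse, seed = seed),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n",
      sprintf("  gain: %.3f evidence units / degC\n", x$gain),
      sprintf("  criterion: %.3f\n", x$criterion),
      sprintf("  gating_factor (touch): %.3f\n", x$gating_factor),
      sprintf("  sound_bias_shift: %.3f\n", x$sound_bias_shift),
      sprintf("  lapse: %.3f\n", x$lapse), sep = "")
  invisible(x)
}

#' Condition labels understood by the observer
#' @return Character vector of the three condition labels.
#' @export
conditions_all <- function() c("Cold", "ColdTouch", "ColdSound")

check_condition <- function(condition) {
  if (!(is.character(condition) && length(condition) == 1 &&
        condition %in% conditions_all())) {
    stop("condition must be one of: ", paste(conditions_all(), collapse = ", "),
         call. = FALSE)
  }
  condition
}

#' Probability of a "yes" response
#'
#' Closed form of the observer model:
#' P(yes) = lapse/2 + (1 - lapse) * Phi(gain * g * |dT| - c_eff),
#' with g = `gating_factor` under ColdTouch (1 otherwise) and
#' c_eff = criterion - sound_bias_shift under ColdSound (criterion otherwise).
#' On a noise trial (`delta_t = NA`) the signal term is zero.
#'
#' @param obs An [observer_params()] object.
#' @param condition One of `"Cold"`, `"ColdTouch"`, `"ColdSound"`.
#' @param delta_t Skin-temperature change from baseline in degrees Celsius;
#'   must be <= 0 when a signal is present, or `NA` for a stimulus-absent
#'   (noise) trial.
#' @return Probability of responding "yes".
#' @examples
#' obs <- observer_params(gain = 2, criterion = 1)
#' p_yes(obs, "Cold", -1)        # pnorm(1)
#' p_yes(obs, "Cold", NA)        # false-alarm probability
#' @export
p_yes <- function(obs, condition, delta_t = NA_real_) {
  stopifnot(inherits(obs, "observer_params"))
  check_condition(condition)
  if (length(delta_t) != 1) stop("delta_t must be a single value")
  signal <- !is.na(delta_t)
  if (signal && delta_t > 0) {
    stop("delta_t on a signal trial must be <= 0 (a cooling, not a warming)")
  }
  g <- if (condition == "ColdTouch") obs$gating_factor else 1
  c_eff <- obs$criterion -
    (if (condition == "ColdSound") obs$sound_bias_shift else 0)
  mu <- if (signal) obs$gain * g * abs(delta_t) else 0
  obs$lapse / 2 + (1 - obs$lapse) * stats::pnorm(mu - c_eff)
}

#' Draw one yes/no response from the observer
#'
#' Bernoulli draw at [p_yes()]; advances the current RNG stream, so runs are
#' reproducible under [set.seed()].
#'
#' @inheritParams p_yes
#' @return `TRUE` for "yes", `FALSE` for "no".
#' @export
simulate_response <- function(obs, condition, delta_t = NA_real_) {
  stats::runif(1) < p_yes(obs, condition, delta_t)
}

#' Cohort-level hyperparameters for sampling observers
#'
#' Means and SDs of each observer parameter across participants. Sampled
#' values are truncated (clamped) to the parameter's legal range after
#' drawing. Defaults describe a cohort on the scale of a cold-detection
#' experiment with light-touch gating: mean Cold sensitivity near d' = 1.9 at
#' a detection threshold near -1 degC, with touch removing roughly a third of
#' the gain.
#'
#' @param n_participants Number of participants (>= 2). Default 12.
#' @param gain_mean,gain_sd Gain distribution (evidence units / degC).
#' @param criterion_mean,criterion_sd Criterion distribution.
#' @param gating_mean,gating_sd Touch gating-factor distribution; values are
#'   clamped into (0, 1].
#' @param sound_shift_mean,sound_shift_sd Sound criterion-shift distribution.
#' @param lapse_mean,lapse_sd Lapse distribution; clamped into [0, 0.1].
#' @param seed Integer seed for reproducible cohort sampling.
#' @return An object of class `cohort_hyperparams`.
#' @export
cohort_hyperparams <- function(n_participants = 12,
                               gain_mean = 2.0, gain_sd = 0.4,
                               criterion_mean = 1.06, criterion_sd = 0.25,
                               gating_mean = 0.65, gating_sd = 0.10,
                               sound_shift_mean = 0.2, sound_shift_sd = 0.1,
                               lapse_mean = 0.02, lapse_sd = 0.01,
                               seed = 1L) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  sds <- c(gain_sd, criterion_sd, gating_sd, sound_shift_sd, lapse_sd)
  if (any(sds < 0)) stop("all hyperparameter SDs must be >= 0")
  structure(
    list(n_participants = as.integer(n_participants),
         gain_mean = gain_mean, gain_sd = gain_sd,
         criterion_mean = criterion_mean, criterion_sd = criterion_sd,
         gating_mean = gating_mean, gating_sd = gating_sd,
         sound_shift_mean = sound_shift_mean, sound_shift_sd = sound_shift_sd,
         lapse_mean = lapse_mean, lapse_sd = lapse_sd,
         seed = as.integer(seed)),
    class = "cohort_hyperparams"
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample a cohort of observers
#'
#' Draws `n_participants` parameter sets from independent normals with the
#' hyperparameter means and SDs, then clamps each parameter to its legal
#' range (gain >= 0.01, gating factor in (0, 1], lapse in [0, 0.1]).
#' Reproducible under the hyperparameter seed; each observer also receives
#' its own child seed via [split_seed()].
#'
#' @param hyper A [cohort_hyperparams()] object.
#' @return List of [observer_params()] objects of length `n_participants`.
#' @export
sample_cohort <- function(hyper) {
  stopifnot(inherits(hyper, "cohort_hyperparams"))
  n <- hyper$n_participants
  with_seed(hyper$seed, {
    gain <- clamp(stats::rnorm(n, hyper$gain_mean, hyper$gain_sd), 0.01, Inf)
    crit <- stats::rnorm(n, hyper$criterion_mean, hyper$criterion_sd)
    gat <- clamp(stats::rnorm(n, hyper$gating_mean, hyper$gating_sd), 1e-6, 1)
    snd <- stats::rnorm(n, hyper$sound_shift_mean, hyper$sound_shift_sd)
    lap <- clamp(stats::rnorm(n, hyper$lapse_mean, hyper$lapse_sd), 0, 0.1)
    lapply(seq_len(n), function(i) {
      observer_params(gain = gain[i], criterion = crit[i],
                      gating_factor = gat[i], sound_bias_shift = snd[i],
                      lapse = lap[i], seed = split_seed(hyper$seed, i))
    })
  })
}

#' Analytic sensitivity and bias of an observer at a stimulus level
#'
#' For the equal-variance observer without lapse, d' = gain * g * |dT| and
#' (in the sign convention where positive C means a "yes" tendency)
#' C = gain * g * |dT| / 2 - c_eff. Used as the ground truth in
#' parameter-recovery checks.
#'
#' @inheritParams p_yes
#' @return Named list with `d_prime` and `criterion_C`.
#' @export
analytic_sdt <- function(obs, condition, delta_t) {
  stopifnot(inherits(obs, "observer_params"))
  check_condition(condition)
  g <- if (condition == "ColdTouch") obs$gating_factor else 1
  c_eff <- obs$criterion -
    (if (condition == "ColdSound") obs$sound_bias_shift else 0)
  mu <- obs$gain * g * abs(delta_t)
  list(d_prime = mu, criterion_C = mu / 2 - c_eff)
}

#' Serialize observer or cohort parameters
#'
#' Writes the parameter list to JSON or YAML (chosen by file extension);
#' fields are in the units documented in [observer_params()] /
#' [cohort_hyperparams()]. `read_params()` restores the object.
#'
#' @param x An `observer_params` or `cohort_hyperparams` object.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   the restored object.
#' @export
write_params <- function(x, path) {
  stopifnot(inherits(x, c("observer_params", "cohort_hyperparams")))
  payload <- c(list(.class = class(x)[1]), unclass(x))
  write_keyed_file(payload, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  payload <- read_keyed_file(path)
  cls <- payload$.class
  payload$.class <- NULL
  payload <- lapply(payload, function(v) if (is.null(v)) NULL else v)
  switch(cls,
    observer_params = do.call(observer_params, payload),
    cohort_hyperparams = do.call(cohort_hyperparams, payload),
    stop("unknown parameter class in file: ", cls)
  )
}

write_keyed_file <- function(payload, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(payload, path)
  } else {
    stop("unsupported extension '", ext, "': use .json, .yaml or .yml")
  }
}

read_keyed_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported extension '", ext, "': use .json, .yaml or .yml")
  }
}
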