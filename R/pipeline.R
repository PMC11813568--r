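#' Configuration of a full simulated experiment
#'
#' Bundles everything one run needs: the cohort hyperparameters, the
#' staircase pair, the session design and the analysis options, under one
#' master seed. The master seed determines all child seeds (per participant
#' and phase) through [split_seed()], so any participant can be re-simulated
#' in isolation.
#'
#' @param experiment 1, 2 or 3.
#' @param hyper A [cohort_hyperparams()].
#' @param cfg_desc,cfg_asc Staircase branch configurations.
#' @param design_args Named list of overrides for [session_design()]
#'   (`experiment` and `target_delta_t` are set by the pipeline).
#' @param correction_variant `"uniform"` or `"conditional"` loglinear
#'   correction.
#' @param effect_variant `"d_av"` or `"d_z"` effect size.
#' @param exclude Apply the floor/ceiling exclusion rule. Default TRUE.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = 1,
                            hyper = cohort_hyperparams(),
                            cfg_desc = staircase_config(start_level = -0.2),
                            cfg_asc = staircase_config(start_level = -1.2),
                            design_args = list(),
                            correction_variant = "uniform",
                            effect_variant = "d_av",
                            exclude = TRUE,
                            seed = 1L) {
  if (!experiment %in% 1:3) stop("experiment must be 1, 2 or 3")
  structure(
    list(experiment = as.integer(experiment), hyper = hyper,
         cfg_desc = cfg_desc, cfg_asc = cfg_asc,
         design_args = design_args,
         correction_variant = correction_variant,
         effect_variant = effect_variant,
         exclude = isTRUE(exclude), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Serialize / restore a pipeline configuration
#'
#' JSON or YAML by file extension; round-trips losslessly.
#'
#' @param config A [pipeline_config()].
#' @param path File ending in `.json`, `.yaml` or `.yml`.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  payload <- list(
    experiment = config$experiment,
    hyper = unclass(config$hyper),
    cfg_desc = unclass(config$cfg_desc),
    cfg_asc = unclass(config$cfg_asc),
    design_args = config$design_args,
    correction_variant = config$correction_variant,
    effect_variant = config$effect_variant,
    exclude = config$exclude,
    seed = config$seed)
  write_keyed_file(payload, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  p <- read_keyed_file(path)
  pipeline_config(
    experiment = p$experiment,
    hyper = do.call(cohort_hyperparams, p$hyper),
    cfg_desc = do.call(staircase_config, p$cfg_desc),
    cfg_asc = do.call(staircase_config, p$cfg_asc),
    design_args = if (length(p$design_args)) p$design_args else list(),
    correction_variant = p$correction_variant,
    effect_variant = p$effect_variant,
    exclude = p$exclude,
    seed = p$seed)
}

#' Run the full simulation-and-analysis pipeline
#'
#' For each simulated participant: (1) staircase phase - the dual interleaved
#' staircase estimates the per cent-correct cooling level (clamped into the
#' legal target range); (2) detection phase - a full session at that level;
#' (3) SDT analysis per condition; then (4) cohort-level planned comparisons.
#' When `out_dir` is given, writes one trial CSV per participant, the SDT
#' table, a JSON summary and a manifest recording the seed and the MD5 of
#' the serialized configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List of class `pipeline_result`: `summary`
#'   ([experiment_summary()]), `sdt` (the SDT table with a `threshold_degC`
#'   column), `trials` (all trial records), `thresholds` (per participant),
#'   `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hyper <- config$hyper
  hyper$seed <- split_seed(config$seed, 0L)
  cohort <- sample_cohort(hyper)

  trials <- list()
  thresholds <- numeric(length(cohort))
  for (i in seq_along(cohort)) {
    sc <- run_dual_staircase(cohort[[i]], config$cfg_desc, config$cfg_asc,
                             seed = split_seed(config$seed, i, 1L))
    if (!sc$ok) {
      stop("staircase phase failed to converge for participant ", i,
           " (degenerate observer)")
    }
    thr <- clamp(sc$threshold, config$cfg_desc$lower_bound,
                 config$cfg_desc$upper_bound)
    thresholds[i] <- thr
    design <- do.call(session_design, c(
      list(experiment = config$experiment, target_delta_t = thr),
      config$design_args))
    trials[[i]] <- run_detection_session(
      cohort[[i]], design, seed = split_seed(config$seed, i, 2L),
      participant_id = i)
  }
  all_trials <- do.call(rbind, trials)
  tab <- sdt_table(all_trials, variant = config$correction_variant)
  tab$threshold_degC <- thresholds[tab$participant_id]
  summary <- experiment_summary(tab, experiment = config$experiment,
                                exclude = config$exclude)

  result <- structure(
    list(summary = summary, sdt = tab, trials = all_trials,
         thresholds = thresholds, config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

summary_to_list <- function(s) {
  comp <- lapply(s$comparisons, function(tt) {
    tt <- unclass(tt)
    tt[!vapply(tt, is.function, TRUE)]
  })
  list(experiment = s$experiment, n = s$n,
       excluded_ids = s$excluded_ids,
       condition_stats = s$condition_stats,
       comparisons = comp)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(result$config, cfg_path)
  for (pid in unique(result$trials$participant_id)) {
    write_trials(result$trials[result$trials$participant_id == pid, ],
                 file.path(out_dir, sprintf("trials_p%02d.csv", pid)))
  }
  utils::write.csv(result$sdt, file.path(out_dir, "sdt_results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summary_to_list(result$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  manifest <- list(
    seed = result$config$seed,
    experiment = result$config$experiment,
    n_participants = length(result$thresholds),
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = c("config.json", "sdt_results.csv", "summary.json",
              sprintf("trials_p%02d.csv",
                      unique(result$trials$participant_id))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

trial_columns <- c("participant_id", "experiment", "condition", "trial_index",
                   "grid_location", "signal_present", "target_delta_t",
                   "achieved_delta_t", "cooling_duration", "onset_time",
                   "end_time", "response", "outcome_class", "failed")

#' Write / read trial records as CSV
#'
#' The CSV schema is the column set documented in
#' [run_detection_session()]; logical flags are written as TRUE/FALSE and
#' round-trip losslessly. Unknown extra columns are preserved on read.
#'
#' @param records Trial-record data frame.
#' @param path CSV path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   records.
#' @export
write_trials <- function(records, path) {
  missing_cols <- setdiff(trial_columns, names(records))
  if (length(missing_cols)) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols)) {
    stop("file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    df$response <- logical(0); df$signal_present <- logical(0)
    df$failed <- logical(0)
    return(df)
  }
  parse_flag <- function(col) {
    v <- df[[col]]
    if (is.logical(v)) return(v)
    u <- toupper(trimws(as.character(v)))
    bad <- which(!u %in% c("TRUE", "FALSE") & !is.na(u))
    if (length(bad)) {
      stop("malformed ", col, " value '", v[bad[1]], "' at row ", bad[1],
           " of ", path)
    }
    u == "TRUE"
  }
  df$signal_present <- parse_flag("signal_present")
  df$response <- parse_flag("response")
  df$failed <- parse_flag("failed")
  df
}
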