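#' Write / read the per-item response log CSV
#'
#' Interchange format: UTF-8, comma-delimited, header
#' `participant_id,assessment_id,scheduled_time,response_time,item_id,category,step_eap,step_se`
#' with ISO-8601 timestamps. The write/read round trip preserves all
#' fields (timestamps to 1 second, numerics to full double precision).
#'
#' @param log data frame in response-log layout (see [run_study()]).
#' @param path CSV path.
#' @return `path` invisibly (writer); the data frame (reader) with
#'   `POSIXct` timestamp columns.
#' @export
write_response_log <- function(log, path) {
  write_records(log, path,
                c("participant_id", "assessment_id", "scheduled_time",
                  "response_time", "item_id", "category",
                  "step_eap", "step_se"))
}

#' @rdname write_response_log
#' @export
read_response_log <- function(path) {
  read_records(path, c("scheduled_time", "response_time"))
}

#' Write / read the per-assessment summary CSV
#'
#' Interchange format with header
#' `participant_id,assessment_id,scheduled_time,response_time,theta_true,eap,se,ci_low,ci_high,n_items,termination_reason`
#' (`theta_true` present only for simulated studies).
#'
#' @param summaries data frame in assessment-summary layout.
#' @param path CSV path.
#' @return as for [write_response_log()].
#' @export
write_assessment_summaries <- function(summaries, path) {
  cols <- c("participant_id", "assessment_id", "scheduled_time",
            "response_time",
            intersect("theta_true", names(summaries)),
            "eap", "se", "ci_low", "ci_high", "n_items",
            "termination_reason")
  write_records(summaries, path, cols)
}

#' @rdname write_assessment_summaries
#' @export
read_assessment_summaries <- function(path) {
  read_records(path, c("scheduled_time", "response_time"))
}

#' Write a smoothed series CSV
#'
#' Layout `time,fit,se_band_low,se_band_high` (plus `se_fit`).
#'
#' @param smooth a `smoothed_series` from [loess_smooth()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_smoothed_series <- function(smooth, path) {
  df <- data.frame(time = smooth$time, fit = smooth$fit,
                   se_fit = smooth$se_fit,
                   se_band_low = smooth$band_low,
                   se_band_high = smooth$band_high)
  write_records(df, path, names(df))
}

write_records <- function(df, path, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, cols, drop = FALSE]
  for (j in seq_along(df))
    if (inherits(df[[j]], "POSIXct"))
      df[[j]] <- format(df[[j]], "%Y-%m-%dT%H:%M:%S%z")
  utils::write.csv(format_num_df(df), path, row.names = FALSE,
                   quote = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

read_records <- function(path, time_cols = character(0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  for (cl in intersect(time_cols, names(df))) {
    parsed <- as.POSIXct(df[[cl]], format = "%Y-%m-%dT%H:%M:%S%z",
                         tz = "UTC")
    if (any(is.na(parsed) & !is.na(df[[cl]]) & nzchar(df[[cl]]))) {
      bad <- which(is.na(parsed) & nzchar(df[[cl]]))[1]
      stop("malformed timestamp in column ", cl, ", row ", bad,
           ": ", df[[cl]][bad])
    }
    df[[cl]] <- parsed
  }
  df
}

#' Read an assessment configuration file
#'
#' YAML (or JSON) key-value configuration mapped onto [cat_control()]:
#' keys `estimator` (only `"EAP"` is supported), `criterion` (`"MEPV"`
#' or `"max_info"`), `randomesque_n`, `se_threshold`, `max_items`,
#' `min_items`, `prior_policy` (`"static"`/`"dynamic"`), `inflation`,
#' `grid_lower`, `grid_upper`, `grid_points`, `seed`. Missing keys
#' take the package defaults.
#'
#' @param path path to a YAML/JSON config file.
#' @return list with elements `control` (a [cat_control()]) and
#'   `seed`.
#' @export
read_cat_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping")
  known <- c("estimator", "criterion", "randomesque_n", "se_threshold",
             "max_items", "min_items", "prior_policy", "inflation",
             "grid_lower", "grid_upper", "grid_points", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$estimator) && toupper(cfg$estimator) != "EAP")
    stop("unsupported estimator: ", cfg$estimator, " (only EAP)")
  pick <- function(key, default) if (is.null(cfg[[key]])) default
                                 else cfg[[key]]
  control <- cat_control(
    criterion = select_criterion(pick("criterion", "MEPV"),
                                 pick("randomesque_n", 1L)),
    rule = stopping_rule(pick("se_threshold", 0.3),
                         pick("max_items", Inf),
                         pick("min_items", 1L)),
    grid = quad_grid(pick("grid_lower", -6), pick("grid_upper", 6),
                     pick("grid_points", 161)),
    prior_policy = pick("prior_policy", "dynamic"),
    inflation = pick("inflation", 0))
  list(control = control, seed = as.integer(pick("seed", 1L)))
}

#' Write a run manifest
#'
#' JSON record of one tool invocation: the configuration snapshot, the
#' master seed, the package version, the inventory of files written,
#' and start/end timestamps. Every listed output is checked to exist.
#'
#' @param path manifest path (JSON).
#' @param config list snapshot of the configuration used.
#' @param seed master seed of the run.
#' @param outputs character vector of files the run wrote.
#' @param started,finished `POSIXct` run timestamps.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs,
                           started, finished = Sys.time()) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing) > 0L)
    stop("manifest lists nonexistent output(s): ",
         paste(missing, collapse = ", "))
  jsonlite::write_json(
    list(tool = "promcat",
         version = as.character(utils::packageVersion("promcat")),
         seed = seed,
         config = config,
         outputs = outputs,
         started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
         finished = format(finished, "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a study configuration file
#'
#' YAML mapping for [run_study()] simulations: `bank` (CSV path,
#' optional — defaults to the shipped synthetic bank), `weeks`,
#' `start`, `n_per_regime` and `compliance` (mappings keyed by regime
#' kind), `full_length_weeks`, `seed`, plus any [read_cat_config()]
#' keys under `cat:`.
#'
#' @param path path to the YAML file.
#' @return list with `cohort`, `bank`, `control`, `full_length_weeks`,
#'   `seed`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pick <- function(key, default) if (is.null(cfg[[key]])) default
                                 else cfg[[key]]
  bank <- if (is.null(cfg$bank)) default_item_bank()
          else read_item_bank(cfg$bank)
  control <- if (is.null(cfg$cat)) cat_control() else {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(cfg$cat, tmp)
    read_cat_config(tmp)$control
  }
  npr <- unlist(pick("n_per_regime",
                     list(thrice_weekly = 12, daily = 15,
                          thrice_daily = 12)))
  cmp <- unlist(pick("compliance",
                     list(thrice_weekly = 0.63, daily = 0.93,
                          thrice_daily = 0.43)))
  if (!all(names(npr) %in% c("thrice_weekly", "daily", "thrice_daily")))
    stop("n_per_regime keys must be regime kinds")
  if (!all(names(npr) %in% names(cmp)))
    stop("compliance must cover every regime in n_per_regime")
  seed <- as.integer(pick("seed", 1L))
  cohort <- simulate_cohort(npr, cmp[names(npr)],
                            weeks = pick("weeks", 12),
                            start = as.Date(pick("start", "2022-07-18")),
                            seed = seed)
  list(cohort = cohort, bank = bank, control = control,
       full_length_weeks = unlist(pick("full_length_weeks", c(0, 6, 12))),
       seed = seed)
}
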