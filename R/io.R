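# Session-table and configuration file formats.
#
# Canonical session dialect: comma-delimited UTF-8, '.' decimal separator,
# header row, one row per trial, times in seconds from session start.
# Required columns: session_id, trial_time_s, label (Go|NoGo),
# outcome (food|water|miss|nogo). Optional numeric annotation columns are
# preserved.

session_required_cols <- c("session_id", "trial_time_s", "label", "outcome")

validate_sessions <- function(df, where = "session table") {
  missing <- setdiff(session_required_cols, names(df))
  if (length(missing))
    stop(where, ": missing required column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(!df$label %in% c("Go", "NoGo"))
  if (length(bad))
    stop(where, ": invalid label at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!df$outcome %in% c("food", "water", "miss", "nogo"))
  if (length(bad))
    stop(where, ": invalid outcome at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which((df$label == "NoGo") != (df$outcome == "nogo"))
  if (length(bad))
    stop(where, ": outcome inconsistent with label at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  for (sid in unique(df$session_id)) {
    tt <- df$trial_time_s[df$session_id == sid]
    if (any(diff(tt) <= 0)) {
      r <- which(df$session_id == sid)[which(diff(tt) <= 0)[1] + 1L]
      stop(where, ": trial times not strictly increasing in session '",
           sid, "' at row ", r)
    }
  }
  invisible(df)
}

#' Read a session table
#'
#' @param path path to a comma-delimited session file.
#' @return Validated session data frame.
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(session_id = "character"))
  # numeric columns are doubles in the canonical dialect
  for (j in seq_along(df)) if (is.integer(df[[j]])) {
    df[[j]] <- as.double(df[[j]])
  }
  validate_sessions(df, where = basename(path))
  df
}

#' Write a session table
#'
#' Numeric columns are written with enough digits to round-trip exactly.
#'
#' @param trials session data frame (validated before writing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(trials, path) {
  validate_sessions(trials)
  out <- trials
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]))
      out[[j]] <- trimws(formatC(out[[j]], digits = 17, format = "g"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

config_known_keys <- list(
  geometry = c("mu_other", "mu_water", "mu_food", "sigma2"),
  params = c("g", "n", "s", "preset"),
  sim = c("dt", "duration", "x0", "T0", "H0", "r_water", "r_food",
          "feedback_delay", "rng_seed", "miss_termination", "record_stride"),
  schedule = c("duration", "go_fraction", "iti_min", "iti_max",
               "trial_allowance", "rng_seed"),
  stim = c("onsets", "stim_duration", "stim_magnitude"),
  fit = c("batch_fraction", "batch_min", "lr", "max_epochs", "tol",
          "patience", "spacing", "seed", "satiation_threshold"),
  dataset = c("n_sessions", "T0_range", "H0_range", "rng_seed"))

#' Read a run configuration
#'
#' YAML configuration with sections `geometry`, `params`, `sim`, `schedule`,
#' `stim`, `fit`, `dataset` (all optional); unknown sections or keys are
#' rejected. The parsed list round-trips losslessly through
#' [write_config()].
#'
#' @param path path to a YAML file.
#' @return Named list of configuration sections.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(config_known_keys))
  if (length(unknown))
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), config_known_keys[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  cfg
}

#' Write a run configuration
#'
#' @param cfg configuration list as returned by [read_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

# resolve config sections into package objects (used by the CLI)
config_to_objects <- function(cfg) {
  geom <- do.call(well_geometry, cfg$geometry %||% list())
  params <- if (!is.null(cfg$params$preset)) {
    default_params(cfg$params$preset)
  } else if (!is.null(cfg$params)) {
    do.call(model_params, cfg$params)
  } else default_params("behavior")
  sim <- do.call(sim_config, cfg$sim %||% list())
  list(geom = geom, params = params, sim = sim,
       schedule_args = cfg$schedule %||% list(),
       stim = if (!is.null(cfg$stim)) do.call(stim_protocol, cfg$stim),
       fit = cfg$fit %||% list(),
       dataset = cfg$dataset %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
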