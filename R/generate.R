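#' Generate a Go/No-Go trial schedule
#'
#' Trial onsets are separated by i.i.d. uniform inter-trial intervals plus a
#' fixed per-trial allowance (the maximum odour sampling time), and labels are
#' i.i.d. Go with probability `go_fraction`, matching the statistics of the
#' behavioural assay.
#'
#' @param duration schedule length, seconds.
#' @param go_fraction probability that a trial is a Go trial.
#' @param iti_min,iti_max bounds of the uniform inter-trial interval, seconds.
#' @param trial_allowance fixed per-trial time added between intervals,
#'   seconds.
#' @param rng_seed optional integer seed.
#' @return A [trial_schedule()].
#' @export
generate_trial_schedule <- function(duration = 7200, go_fraction = 0.67,
                                    iti_min = 2, iti_max = 8,
                                    trial_allowance = 1.5,
                                    rng_seed = NULL) {
  if (go_fraction <= 0 || go_fraction >= 1)
    stop("'go_fraction' must be in (0, 1)")
  if (iti_min >= iti_max) stop("'iti_min' must be below 'iti_max'")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  # upper bound on trial count, then truncate to the session duration
  n_max <- ceiling(duration / (iti_min + trial_allowance)) + 1L
  gaps <- stats::runif(n_max, iti_min, iti_max) + trial_allowance
  times <- cumsum(gaps)
  times <- times[times < duration]
  labels <- ifelse(stats::runif(length(times)) < go_fraction, "Go", "NoGo")
  trial_schedule(times, labels)
}

#' Generate a synthetic behavioural dataset
#'
#' Wraps [simulate_session()] over `n_sessions` sessions with fresh random
#' schedules and initial needs, returning both the experiment-format view
#' (what fitting and the behavioural statistics see: one trial table with no
#' trajectory or true-need columns) and the hidden ground truth used by
#' parameter-recovery tests.
#'
#' @param n_sessions number of sessions.
#' @param geom a [well_geometry()].
#' @param params a [model_params()] used for generation.
#' @param config base [sim_config()]; its `T0`/`H0` are overridden per
#'   session.
#' @param T0_range,H0_range ranges the per-session initial needs are drawn
#'   uniformly from.
#' @param schedule_args list of arguments passed to
#'   [generate_trial_schedule()] (besides `duration`).
#' @param rng_seed optional integer seed governing the whole dataset.
#' @return List with `sessions` (combined experiment-format trial table),
#'   `truth` (per-session `session_result` objects plus the generating
#'   parameters) and `spec` (the generation settings).
#' @export
generate_dataset <- function(n_sessions = 22,
                             geom = well_geometry(),
                             params = default_params("behavior"),
                             config = sim_config(record_stride = 100L),
                             T0_range = c(0.8, 1.2),
                             H0_range = c(0.8, 1.2),
                             schedule_args = list(),
                             rng_seed = NULL) {
  if (n_sessions < 1) stop("'n_sessions' must be at least 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  params <- as_params(params)
  truth <- vector("list", n_sessions)
  tabs <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    sched <- do.call(generate_trial_schedule,
                     c(list(duration = config$duration), schedule_args))
    cfg <- config
    cfg$rng_seed <- NULL # one stream for the whole dataset
    cfg$T0 <- stats::runif(1, T0_range[1], T0_range[2])
    cfg$H0 <- stats::runif(1, H0_range[1], H0_range[2])
    res <- simulate_session(cfg, sched, geom, params,
                            session_id = sprintf("s%03d", i))
    truth[[i]] <- res
    tabs[[i]] <- res$trials[, c("session_id", "trial_time_s", "label",
                                "outcome")]
  }
  list(sessions = do.call(rbind, c(tabs, list(make.row.names = FALSE))),
       truth = list(sessions = truth, params = params, geom = geom),
       spec = list(n_sessions = n_sessions, T0_range = T0_range,
                   H0_range = H0_range, rng_seed = rng_seed,
                   schedule_args = schedule_args))
}
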