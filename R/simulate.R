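#' Simulation configuration
#'
#' @param dt integration step, seconds.
#' @param duration simulated session length, seconds; `duration/dt` must be a
#'   whole number of steps.
#' @param x0 initial position (default: the saddle between the reward wells).
#' @param T0,H0 initial thirst and hunger magnitudes.
#' @param r_water,r_food need decrement per collected water / food reward.
#' @param feedback_delay delay, seconds, between a rewarded choice and its
#'   need decrement.
#' @param rng_seed optional integer seed applied before simulating.
#' @param miss_termination optional integer; end the session once this many
#'   consecutive Go-trial misses occur (`NULL` = never terminate early).
#' @param record_stride store the position every `record_stride` steps
#'   (1 = full resolution).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, duration = 7200, x0 = c(5, 0),
                       T0 = 1, H0 = 1,
                       r_water = 0.006, r_food = 0.004,
                       feedback_delay = 180, rng_seed = NULL,
                       miss_termination = NULL, record_stride = 1L) {
  if (dt <= 0) stop("'dt' must be positive")
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("'duration' must be an integer number of steps of size 'dt'")
  if (r_water <= 0 || r_food <= 0) stop("reward decrements must be positive")
  if (T0 < 0 || H0 < 0) stop("initial needs must be non-negative")
  if (!is.null(miss_termination) &&
      (miss_termination < 1 || miss_termination != round(miss_termination)))
    stop("'miss_termination' must be a positive integer or NULL")
  structure(list(dt = dt, duration = duration, x0 = as.numeric(x0),
                 T0 = T0, H0 = H0, r_water = r_water, r_food = r_food,
                 feedback_delay = feedback_delay, rng_seed = rng_seed,
                 miss_termination = miss_termination,
                 record_stride = as.integer(record_stride)),
            class = "sim_config")
}

#' Trial schedule
#'
#' @param trial_times strictly increasing trial onset times, seconds.
#' @param labels per-trial label, `"Go"` or `"NoGo"`.
#' @return An object of class `trial_schedule`.
#' @seealso [generate_trial_schedule()]
#' @export
trial_schedule <- function(trial_times, labels) {
  trial_times <- as.numeric(trial_times)
  labels <- as.character(labels)
  if (length(trial_times) != length(labels))
    stop("'trial_times' and 'labels' must have equal length")
  if (length(trial_times) && any(diff(trial_times) <= 0))
    stop("'trial_times' must be strictly increasing")
  if (!all(labels %in% c("Go", "NoGo")))
    stop("labels must be 'Go' or 'NoGo'")
  structure(list(trial_times = trial_times, labels = labels),
            class = "trial_schedule")
}

#' Stimulation protocol for need perturbations
#'
#' Models transient (optogenetic-style) thirst input as a square wave added
#' to the thirst magnitude seen by the dynamics during each epoch.
#'
#' @param onsets epoch onset times, seconds.
#' @param stim_duration epoch length, seconds.
#' @param stim_magnitude additive thirst input during an epoch.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(onsets, stim_duration = 10, stim_magnitude = 18) {
  onsets <- sort(as.numeric(onsets))
  if (stim_magnitude < 0) stop("'stim_magnitude' must be non-negative")
  if (stim_duration <= 0) stop("'stim_duration' must be positive")
  if (length(onsets) > 1 && any(diff(onsets) < stim_duration))
    stop("stimulation epochs must not overlap")
  structure(list(onsets = onsets, stim_duration = stim_duration,
                 stim_magnitude = stim_magnitude),
            class = "stim_protocol")
}

#' One Euler-Maruyama step of the needs-landscape diffusion
#'
#' Reference (R-level) single update: `x + dt*g*(-grad U) +
#' sqrt(dt)*n*noise_draw`. The session simulators run the same update in
#' compiled code.
#'
#' @param x current position, 2-vector.
#' @param thirst,hunger current need magnitudes.
#' @param geom a [well_geometry()].
#' @param params a [model_params()].
#' @param dt step size, seconds.
#' @param noise_draw 2-vector of standard normal draws.
#' @return Updated position 2-vector.
#' @export
langevin_step <- function(x, thirst, hunger, geom, params, dt, noise_draw) {
  params <- as_params(params)
  if (dt <= 0) stop("'dt' must be positive")
  drift <- -potential_gradient(x, thirst, hunger, geom, params$s)
  as.numeric(x) + dt * params$g * drift +
    sqrt(dt) * params$n * as.numeric(noise_draw)
}

# shared driver for all session simulators
run_core <- function(config, schedule, geom, params, feedback = TRUE,
                     stim_add = numeric(0), force_steps = integer(0),
                     force_margin = 1, session_id = "s1") {
  geom <- as_geometry(geom)
  params <- as_params(params)
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  if (!inherits(schedule, "trial_schedule"))
    stop("'schedule' must be a trial_schedule")
  if (length(schedule$trial_times) &&
      (min(schedule$trial_times) < 0 ||
       max(schedule$trial_times) > config$duration))
    stop("schedule times must lie within [0, duration]")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  n_steps <- as.integer(round(config$duration / config$dt))
  trial_steps <- as.integer(round(schedule$trial_times / config$dt))
  is_go <- as.integer(schedule$labels == "Go")
  delay_steps <- as.integer(round(config$feedback_delay / config$dt))
  miss_lim <- if (is.null(config$miss_termination)) 0L
              else as.integer(config$miss_termination)

  res <- cpp_simulate(config$x0, config$T0, config$H0,
                      geom$mu_other, geom$mu_water, geom$mu_food,
                      geom$sigma2, params$g, params$n, params$s,
                      config$dt, n_steps, trial_steps, is_go,
                      config$r_water, config$r_food, delay_steps, feedback,
                      stim_add, as.integer(force_steps), force_margin,
                      miss_lim, config$record_stride)

  k <- res$trials_done
  zl <- c("water", "food", "miss")
  trials <- data.frame(
    session_id = rep(session_id, k),
    trial_time_s = schedule$trial_times[seq_len(k)],
    label = schedule$labels[seq_len(k)],
    outcome = ifelse(schedule$labels[seq_len(k)] == "Go",
                     zl[res$zone[seq_len(k)] + 1L], "nogo"),
    zone_at_trial = zl[res$zone[seq_len(k)] + 1L],
    thirst_true = res$T[seq_len(k)],
    hunger_true = res$H[seq_len(k)],
    stringsAsFactors = FALSE)

  nr <- res$n_rec
  traj <- cbind(time_s = res$rec_step[seq_len(nr)] * config$dt,
                res$traj[seq_len(nr), , drop = FALSE])
  colnames(traj) <- c("time_s", "x", "y")

  structure(list(trials = trials, trajectory = traj,
                 T_final = res$T_final, H_final = res$H_final,
                 pending_water = res$pending_water,
                 pending_food = res$pending_food,
                 end_time_s = res$end_step * config$dt,
                 config = config, params = params, geom = geom,
                 rng_seed = config$rng_seed),
            class = "session_result")
}

#' Simulate a full behavioural session
#'
#' Integrates the Langevin dynamics over the session, emits the zone of the
#' current position as the outcome of every Go trial, and decrements the
#' matching need by the reward size a fixed delay after each rewarded choice
#' (clamped at zero). No-Go trials emit no reward and trigger no feedback but
#' their zone is still recorded.
#'
#' @param config a [sim_config()].
#' @param schedule a [trial_schedule()].
#' @param geom a [well_geometry()].
#' @param params a [model_params()].
#' @param session_id identifier stored in the trial table.
#' @return A `session_result`: trial table (`trials`), position trajectory
#'   (`trajectory`, with a time column), final/pending need bookkeeping and
#'   the configuration used.
#' @export
simulate_session <- function(config, schedule, geom = well_geometry(),
                             params = default_params("behavior"),
                             session_id = "s1") {
  run_core(config, schedule, geom, params, session_id = session_id)
}

# additive thirst square wave, indexed by integration step
stim_wave <- function(stim, dt, n_steps) {
  if (is.null(stim)) return(numeric(0))
  if (!inherits(stim, "stim_protocol")) stop("'stim' must be a stim_protocol")
  w <- numeric(n_steps)
  for (on in stim$onsets) {
    i0 <- floor(on / dt) + 1L
    i1 <- min(n_steps, ceiling((on + stim$stim_duration) / dt))
    if (i0 <= n_steps) w[i0:i1] <- w[i0:i1] + stim$stim_magnitude
  }
  w
}

#' Simulate a session with thirst stimulation epochs
#'
#' Identical to [simulate_session()] except that the thirst magnitude seen by
#' the dynamics is transiently increased by `stim$stim_magnitude` during each
#' stimulation epoch, the gradient scale is multiplied by `g_scale`, and
#' reward feedback is disabled by default. Defaults model brief thirst-neuron
#' stimulation in a hungry-only state (high `H0`, near-zero `T0`).
#'
#' @inheritParams simulate_session
#' @param stim a [stim_protocol()].
#' @param g_scale extra multiplier on the gradient scale `g`.
#' @param feedback logical; deliver reward feedback on needs.
#' @return A `session_result` with the protocol attached as `$stim`.
#' @export
simulate_opto_behavior <- function(config = sim_config(duration = 3600,
                                                       T0 = 0.05, H0 = 0.5),
                                   schedule, stim,
                                   geom = well_geometry(),
                                   params = default_params("behavior"),
                                   g_scale = 3.3, feedback = FALSE,
                                   session_id = "s1") {
  params <- as_params(params)
  params$g <- params$g * g_scale
  n_steps <- as.integer(round(config$duration / config$dt))
  out <- run_core(config, schedule, geom, params, feedback = feedback,
                  stim_add = stim_wave(stim, config$dt, n_steps),
                  session_id = session_id)
  out$stim <- stim
  out
}

#' Goal-dimension response to thirst stimulation without behaviour
#'
#' Runs stimulation epochs with no trial schedule (no cues, no rewards) and
#' returns the goal-dimension projection around each epoch onset in 1-s bins
#' from -10 s to +20 s, baseline-subtracted (mean of the 10 s before onset).
#'
#' @param config a [sim_config()]; defaults model a hungry *and* thirsty
#'   state.
#' @param stim a [stim_protocol()]; default 25 epochs at 1-min spacing.
#' @param geom a [well_geometry()].
#' @param params a [model_params()]; `g` is multiplied by `g_scale`.
#' @param g_scale extra multiplier on the gradient scale.
#' @param n_runs independent repetitions of the protocol.
#' @return List with `times` (bin centres, s), `epochs` (epoch x time matrix
#'   of baseline-subtracted projections) and `mean` (across epochs).
#' @export
simulate_opto_prebehavior <- function(config = sim_config(duration = 1560,
                                                          T0 = 0.8, H0 = 2.25),
                                      stim = stim_protocol(onsets =
                                        30 + 60 * (0:24)),
                                      geom = well_geometry(),
                                      params = default_params("neuropixels"),
                                      g_scale = 3.3, n_runs = 3) {
  params <- as_params(params)
  params$g <- params$g * g_scale
  rel <- -10:20
  dt <- config$dt
  stride <- as.integer(round(1 / dt)) # sample the projection once per second
  cfg <- config
  cfg$record_stride <- stride
  n_steps <- as.integer(round(config$duration / dt))
  wave <- stim_wave(stim, dt, n_steps)
  epochs <- NULL
  for (r in seq_len(n_runs)) {
    res <- run_core(cfg, trial_schedule(numeric(0), character(0)), geom,
                    params, feedback = FALSE, stim_add = wave)
    proj <- goal_projection(res$trajectory[, c("x", "y")], geom)
    tsec <- res$trajectory[, "time_s"]
    for (on in stim$onsets) {
      idx <- match(round(on + rel), round(tsec))
      if (anyNA(idx)) next
      ser <- proj[idx]
      epochs <- rbind(epochs, ser - mean(ser[rel < 0]))
    }
  }
  list(times = rel, epochs = epochs, mean = colMeans(epochs))
}

#' Simulate the forced-transition alternative model
#'
#' Contrast class for the diffusion model: the noise scale is reduced so far
#' that no switch occurs spontaneously, and transitions are instead driven by
#' noise-free external impulses at Poisson-random times. Each impulse carries
#' the state along the goal dimension to `force_margin` beyond the saddle
#' projection, so every impulse applied from within a well produces exactly
#' one switch.
#'
#' @inheritParams simulate_session
#' @param params low-noise parameter set (default the "persistent" preset,
#'   g = 8, n = 0.5).
#' @param force_rate Poisson rate of impulse events, per second.
#' @param force_margin distance past the saddle projection, subspace units.
#' @param force_times optional explicit event times (overrides `force_rate`).
#' @return A `session_result` with the event times attached as
#'   `$force_times`.
#' @export
simulate_forced_transition <- function(config, schedule,
                                       geom = well_geometry(),
                                       params = default_params("persistent"),
                                       force_rate = 0.006,
                                       force_margin = 1,
                                       force_times = NULL,
                                       session_id = "s1") {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  cfg <- config
  cfg$rng_seed <- NULL # already applied; event draw shares the stream
  if (is.null(force_times)) {
    force_times <- numeric(0)
    t <- 0
    repeat {
      t <- t + stats::rexp(1, force_rate)
      if (t >= config$duration) break
      force_times <- c(force_times, t)
    }
  }
  out <- run_core(cfg, schedule, geom, params,
                  force_steps = sort(as.integer(round(force_times /
                                                        config$dt))),
                  force_margin = force_margin, session_id = session_id)
  out$force_times <- sort(force_times)
  out
}

#' @export
print.session_result <- function(x, ...) {
  tr <- x$trials
  go <- tr$label == "Go"
  cat(sprintf("Simulated session '%s': %d trials (%d Go) over %.0f s\n",
              tr$session_id[1], nrow(tr), sum(go), x$end_time_s))
  if (any(go)) {
    tb <- table(factor(tr$outcome[go], c("water", "food", "miss")))
    cat(sprintf("  Go outcomes: %d water, %d food, %d miss\n",
                tb[["water"]], tb[["food"]], tb[["miss"]]))
  }
  cat(sprintf("  final needs: thirst %.3f, hunger %.3f\n",
              x$T_final, x$H_final))
  invisible(x)
}
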