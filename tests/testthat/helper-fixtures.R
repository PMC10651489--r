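# Shared fixtures, generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# the reference study-condition dataset: 22 two-hour sessions under the
# published fitted parameters, experiment-like initial needs
ref_dataset <- function() {
  memo("ref_dataset", generate_dataset(
    n_sessions = 22,
    config = sim_config(record_stride = 100L, miss_termination = 40L),
    rng_seed = 20240101))
}

ref_trials <- function() {
  memo("ref_trials", behavioral_needs(ref_dataset()$sessions))
}

# small dataset for fast structural tests
small_dataset <- function() {
  memo("small_dataset", generate_dataset(
    n_sessions = 3,
    config = sim_config(record_stride = 100L, miss_termination = 40L),
    rng_seed = 4242))
}

small_trials <- function() {
  memo("small_trials", behavioral_needs(small_dataset()$sessions))
}

# long fixed-need session (no reward feedback), zone sampled every 10 s
fixed_need_session <- function() {
  memo("fixed_need_session", {
    sched <- trial_schedule(seq(10, 29990, by = 10),
                            rep("Go", 2999))
    simulate_opto_behavior(
      sim_config(duration = 30000, T0 = 1, H0 = 1, rng_seed = 71,
                 record_stride = 100L),
      sched, stim_protocol(onsets = numeric(0)),
      g_scale = 1, feedback = FALSE)
  })
}

# goal-dimension value at each trial time, from the recorded trajectory
trial_goal_values <- function(res) {
  proj <- goal_projection(res$trajectory[, c("x", "y")], res$geom)
  idx <- findInterval(res$trials$trial_time_s, res$trajectory[, "time_s"])
  proj[pmax(1L, idx)]
}

# build a session table from an explicit outcome sequence (10 s spacing)
toy_session <- function(outcomes, session_id = "toy",
                        labels = NULL, times = NULL) {
  n <- length(outcomes)
  if (is.null(labels)) labels <- ifelse(outcomes == "nogo", "NoGo", "Go")
  if (is.null(times)) times <- seq(10, by = 10, length.out = n)
  data.frame(session_id = session_id, trial_time_s = times,
             label = labels, outcome = outcomes, stringsAsFactors = FALSE)
}
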