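geom <- well_geometry()
prm <- default_params("behavior")

test_that("a noiseless step at a stationary point stays put", {
  p0 <- model_params(prm$g, 1e-12, prm$s)
  x1 <- langevin_step(geom$mu_other, 0, 0, geom, p0, 0.01, c(0, 0))
  expect_equal(x1, geom$mu_other, tolerance = 1e-10)
})

test_that("pure diffusion has per-axis increment variance dt * n^2", {
  # g = 0 reduces the update to scaled white noise; check the compiled path
  cfg <- sim_config(duration = 1000, dt = 0.01, T0 = 1, H0 = 1,
                    rng_seed = 5, record_stride = 1L)
  res <- simulate_session(cfg, trial_schedule(numeric(0), character(0)),
                          geom, model_params(1e-12, 2, prm$s))
  inc <- diff(res$trajectory[, c("x", "y")])
  v <- apply(inc, 2, var)
  expect_lt(max(abs(v - 0.01 * 2^2) / (0.01 * 2^2)), 0.03)
  expect_lt(abs(mean(inc)), 0.005)
})

test_that("seeded simulations are bit-reproducible", {
  cfg <- sim_config(duration = 300, rng_seed = 99)
  sched <- generate_trial_schedule(300, rng_seed = 1)
  a <- simulate_session(cfg, sched, geom, prm)
  b <- simulate_session(cfg, sched, geom, prm)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$trials, b$trials)
})

test_that("the compiled integrator matches the R reference step", {
  # one deterministic step (noise ~ 0) from a generic point
  cfg <- sim_config(duration = 0.01, dt = 0.01, x0 = c(2, 3), T0 = 1.2,
                    H0 = 0.8, rng_seed = 1, record_stride = 1L)
  res <- simulate_session(cfg, trial_schedule(numeric(0), character(0)),
                          geom, model_params(prm$g, 1e-14, prm$s))
  ref <- langevin_step(c(2, 3), 1.2, 0.8, geom,
                       model_params(prm$g, 1e-14, prm$s), 0.01, c(0, 0))
  expect_equal(unname(res$trajectory[2, c("x", "y")]), ref,
               tolerance = 1e-10)
})

test_that("zero needs yield only misses once settled in the other well", {
  cfg <- sim_config(duration = 600, x0 = c(-8, 0), T0 = 0, H0 = 0,
                    rng_seed = 3)
  sched <- trial_schedule(seq(30, 590, by = 10), rep("Go", 57))
  res <- simulate_session(cfg, sched, geom, prm)
  expect_gt(mean(res$trials$outcome == "miss"), 0.8)
})

test_that("reward bookkeeping is conserved exactly", {
  cfg <- sim_config(duration = 1800, T0 = 3, H0 = 3, rng_seed = 8)
  sched <- generate_trial_schedule(1800, rng_seed = 9)
  res <- simulate_session(cfg, sched, geom, prm)
  n_w <- sum(res$trials$outcome == "water")
  n_f <- sum(res$trials$outcome == "food")
  # delivered decrements = choices made minus still-pending deliveries
  expect_equal((n_w - res$pending_water) * cfg$r_water, 3 - res$T_final,
               tolerance = 1e-12)
  expect_equal((n_f - res$pending_food) * cfg$r_food, 3 - res$H_final,
               tolerance = 1e-12)
})

test_that("No-Go trials carry no reward and still record the zone", {
  cfg <- sim_config(duration = 600, T0 = 1, H0 = 1, rng_seed = 12)
  sched <- trial_schedule(seq(20, 580, by = 20), rep("NoGo", 29))
  res <- simulate_session(cfg, sched, geom, prm)
  expect_true(all(res$trials$outcome == "nogo"))
  expect_true(all(res$trials$zone_at_trial %in% c("water", "food", "miss")))
  expect_equal(res$T_final, 1) # no feedback from No-Go trials
  expect_equal(res$H_final, 1)
})

test_that("feedback arrives exactly one delay after the choice", {
  cfg <- sim_config(duration = 400, T0 = 1, H0 = 1, feedback_delay = 100,
                    rng_seed = 21, x0 = geom$mu_water)
  # single Go trial at t = 50 from inside the water well with mild noise
  sched <- trial_schedule(50, "Go")
  res <- simulate_session(cfg, sched, geom,
                          model_params(prm$g, 0.3, prm$s))
  expect_identical(res$trials$outcome, "water")
  expect_equal(res$T_final, 1 - cfg$r_water)
  # a session ending before the delay leaves the decrement pending
  cfg2 <- sim_config(duration = 100, T0 = 1, H0 = 1, feedback_delay = 100,
                     rng_seed = 21, x0 = geom$mu_water)
  res2 <- simulate_session(cfg2, trial_schedule(50, "Go"), geom,
                           model_params(prm$g, 0.3, prm$s))
  expect_equal(res2$pending_water, 1)
  expect_equal(res2$T_final, 1)
})

test_that("zero-magnitude stimulation reproduces the plain simulation", {
  cfg <- sim_config(duration = 600, T0 = 0.05, H0 = 0.5, rng_seed = 31)
  sched <- generate_trial_schedule(600, rng_seed = 32)
  a <- simulate_opto_behavior(cfg, sched,
                              stim_protocol(onsets = c(60, 180, 300),
                                            stim_magnitude = 0),
                              geom, prm, g_scale = 1, feedback = TRUE)
  b <- simulate_session(cfg, sched, geom, prm)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$trials$outcome, b$trials$outcome)
})

test_that("thirst stimulation in a hungry state evokes probabilistic water
           choices, denser inside the epoch than before it", {
  onsets <- 60 * seq_len(25) - 30
  stim <- stim_protocol(onsets = onsets)
  n_water_epoch <- integer(0)
  dens_in <- dens_pre <- 0
  for (seed in 1:3) {
    cfg <- sim_config(duration = 1560, T0 = 0.05, H0 = 0.5,
                      rng_seed = 400 + seed)
    sched <- generate_trial_schedule(1560, rng_seed = 500 + seed)
    res <- simulate_opto_behavior(cfg, sched, stim, geom, prm)
    wt <- res$trials$trial_time_s[res$trials$outcome == "water"]
    for (on in onsets) {
      n_water_epoch <- c(n_water_epoch,
                         sum(wt >= on & wt < on + 20))
      dens_in <- dens_in + sum(wt >= on & wt < on + 10) / 10
      dens_pre <- dens_pre + sum(wt >= on - 10 & wt < on) / 10
    }
  }
  frac <- mean(n_water_epoch >= 1)
  expect_gt(frac, 0)    # the effect is probabilistic:
  expect_lt(frac, 1)    # some but not all epochs contain a water choice
  expect_gt(dens_in, dens_pre)
})

test_that("pre-behaviour stimulation pulls the goal projection towards water
           and decays gradually after offset", {
  set.seed(600)
  out <- simulate_opto_prebehavior(
    config = sim_config(duration = 1560, T0 = 0.8, H0 = 2.25,
                        rng_seed = 601),
    n_runs = 3)
  expect_equal(nrow(out$epochs), 75)
  during <- out$times > 0 & out$times <= 10
  post <- out$times > 10 & out$times <= 15
  expect_gt(mean(out$mean[during]), 0)
  # gradual relaxation: shortly after offset the mean response is still
  # positive, not an instantaneous drop to baseline
  expect_gt(mean(out$mean[post]), 0)
  expect_lt(mean(out$mean[post]), max(out$mean))
  # heterogeneous epoch responses: across-epoch spread of the peak exceeds
  # the within-epoch baseline variability
  peak <- apply(out$epochs[, during], 1, max)
  base_var <- mean(apply(out$epochs[, out$times < 0], 1, var))
  expect_gt(var(peak), base_var / 10)
})

test_that("forced-transition switches coincide with force events only", {
  # needs high enough that no reward well vanishes over the session
  cfg <- sim_config(duration = 3600, T0 = 3, H0 = 3, rng_seed = 51,
                    x0 = geom$mu_water)
  tt <- seq(15, 3585, by = 10)
  sched <- trial_schedule(tt, rep("Go", length(tt)))
  # no events -> no switches at the too-persistent noise level
  res0 <- simulate_forced_transition(cfg, sched, geom,
                                     force_times = numeric(0))
  z0 <- res0$trials$outcome[res0$trials$outcome %in% c("water", "food")]
  expect_equal(length(rle(z0)$lengths), 1L)
  # each event applied from within a well produces exactly one switch
  ev <- c(600, 1500, 2400, 3300)
  res1 <- simulate_forced_transition(cfg, sched, geom, force_times = ev)
  z1 <- res1$trials$outcome[res1$trials$outcome %in% c("water", "food")]
  runs <- rle(z1)
  expect_equal(length(runs$lengths), length(ev) + 1L)
  # switches happen at the event times (first trial after each event flips)
  tt <- res1$trials$trial_time_s[res1$trials$outcome %in%
                                   c("water", "food")]
  sw_times <- tt[cumsum(runs$lengths)[-length(runs$lengths)] + 1L]
  expect_true(all(abs(sw_times - ev - 5) < 10))
})

test_that("switch frequency rises with noise and falls with gradient scale", {
  tt <- seq(10, 5990, by = 10)
  sched <- trial_schedule(tt, rep("Go", length(tt)))
  n_switch <- function(params, seed) {
    cfg <- sim_config(duration = 6000, T0 = 1, H0 = 1, rng_seed = seed)
    res <- simulate_opto_behavior(cfg, sched,
                                  stim_protocol(onsets = numeric(0)),
                                  geom, params, g_scale = 1,
                                  feedback = FALSE)
    z <- res$trials$outcome[res$trials$outcome %in% c("water", "food")]
    sum(z[-1] != z[-length(z)])
  }
  s_deco <- n_switch(default_params("decoherent"), 61)
  s_pers <- n_switch(default_params("persistent"), 62)
  expect_gt(s_deco, s_pers)
})

test_that("bout lengths under fixed needs are geometric", {
  # the two-state (memoryless) reduction holds once the trial spacing
  # exceeds the within-well relaxation time (~8 s): use 20 s cues. High
  # fixed needs keep the miss zone rare so miss gaps do not mix the
  # per-trial switch probability.
  tt <- seq(20, 89980, by = 20)
  res <- simulate_opto_behavior(
    sim_config(duration = 90000, T0 = 2.5, H0 = 2.5, rng_seed = 72,
               record_stride = 1000L),
    trial_schedule(tt, rep("Go", length(tt))),
    stim_protocol(onsets = numeric(0)),
    g_scale = 1, feedback = FALSE)
  z <- res$trials$outcome[res$trials$outcome %in% c("water", "food")]
  runs <- rle(z)$lengths
  p_hat <- 1 / mean(runs)
  # chi-square goodness of fit against geometric(p_hat), binning the tail
  # so all expected counts are >= 5; df loses one for the estimated p
  k_max <- max(2, stats::qgeom(1 - 5 / length(runs), p_hat) + 1)
  obs <- tabulate(pmin(runs, k_max), nbins = k_max)
  expe <- stats::dgeom(seq_len(k_max) - 1, p_hat) * length(runs)
  expe[k_max] <- length(runs) - sum(expe[-k_max])
  x2 <- sum((obs - expe)^2 / expe)
  p_val <- stats::pchisq(x2, df = k_max - 2, lower.tail = FALSE)
  expect_gt(p_val, 0.01)
})

test_that("miss termination truncates the session", {
  # low noise pins the state in the "other" well: every trial is a miss
  cfg <- sim_config(duration = 3600, T0 = 0, H0 = 0, x0 = c(-8, 0),
                    rng_seed = 77, miss_termination = 30L)
  tt <- seq(10, 3590, by = 10)
  sched <- trial_schedule(tt, rep("Go", length(tt)))
  res <- simulate_session(cfg, sched, geom, default_params("persistent"))
  expect_equal(nrow(res$trials), 30L)
  expect_lt(res$end_time_s, 3600)
})
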