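test_that("behavioural needs follow the future-reward definition", {
  # two sessions with equal totals so the medians equal the session totals
  t1 <- toy_session(c("water", "food", "water", "miss", "food", "water"),
                    session_id = "a")
  t2 <- toy_session(c("food", "water", "water", "water", "miss", "food"),
                    session_id = "b")
  ann <- behavioral_needs(rbind(t1, t2))
  a <- ann[ann$session_id == "a", ]
  # first trial: all rewards still ahead, totals equal the medians
  expect_equal(a$thirst[1], 1)
  expect_equal(a$hunger[1], 1)
  expect_equal(a$relative_need[1], 0)
  expect_equal(a$thirst[6], 1 / 3) # one of three waters still ahead
  # all water collected, food still pending: thirst 0, relative need -1
  b <- ann[ann$session_id == "b", ]
  expect_equal(b$thirst[5], 0)
  expect_equal(b$relative_need[5], -1)
  # both needs exhausted: relative need undefined
  expect_true(is.na(b$relative_need[6]) || b$hunger[6] > 0)
  # hand recount of the full annotation for session a (3 water, 2 food)
  expect_equal(a$thirst, c(3, 2, 2, 1, 1, 1) / 3)
  expect_equal(a$hunger, c(2, 2, 1, 1, 1, 0) / 2)
})

test_that("selectivity index counts cumulative choices", {
  expect_equal(unname(selectivity_index(toy_session(rep("water", 4)))), 1)
  expect_equal(unname(selectivity_index(toy_session(rep("food", 4)))), -1)
  expect_equal(unname(selectivity_index(
    toy_session(c("water", "food", "water", "food")))), 0)
  expect_equal(unname(selectivity_index(
    toy_session(c("water", "water", "water", "food")))), 0.5)
})

test_that("geometric persistence fit equals the closed form 1/mean", {
  alt <- toy_session(rep(c("water", "food"), 30))
  pf <- persistence_fit(alt, n_boot = 50)
  expect_equal(pf$p_hat, 1)
  set.seed(20)
  runs <- stats::rgeom(1e4, 0.1) + 1
  outcomes <- unlist(lapply(seq_along(runs), function(i)
    rep(c("water", "food")[1 + i %% 2], runs[i])))
  pf2 <- persistence_fit(toy_session(outcomes), n_boot = 50)
  expect_equal(pf2$p_hat, 1 / mean(runs))
  expect_lt(abs(pf2$p_hat - 0.1), 0.01)
  # bootstrap CI brackets the point estimate
  expect_true(pf2$ci[1] <= pf2$p_hat && pf2$p_hat <= pf2$ci[2])
})

# annotated table with exogenously assigned needs (decoupled from the
# future-reward bookkeeping, so choice/need dependence is fully controlled)
exo_trials <- function(n, rule, n_sessions = 4, seed = 21) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sessions), function(k) {
    thirst <- runif(n, 0.05, 1)
    hunger <- runif(n, 0.05, 1)
    rn <- (thirst - hunger) / (thirst + hunger)
    d <- toy_session(rule(rn), session_id = paste0("s", k))
    d$thirst <- thirst; d$hunger <- hunger; d$relative_need <- rn
    d$remaining_water <- 100; d$remaining_food <- 100
    d
  }))
}

test_that("need-independent choices give a flat need regression", {
  tr <- exo_trials(500, function(rn)
    sample(c("water", "food"), length(rn), replace = TRUE))
  cp <- choice_probability_vs_need(tr, n_boot = 50)
  expect_lt(abs(cp$slope), 0.1)
})

test_that("a deterministic need-threshold rule yields a step in the bins", {
  tr <- exo_trials(500, function(rn) ifelse(rn > 0, "water", "food"),
                   seed = 22)
  cp <- choice_probability_vs_need(tr, n_boot = 20)
  lo <- cp$bins[cp$bins$need < -0.05, "p_water"]
  hi <- cp$bins[cp$bins$need > 0.05, "p_water"]
  expect_true(all(lo < 0.2))
  expect_true(all(hi > 0.8))
})

test_that("self-transition regression matches a closed-form OLS recount", {
  set.seed(23)
  out <- sample(c("water", "food"), 60, replace = TRUE,
                prob = c(0.6, 0.4))
  tr <- behavioral_needs(toy_session(out))
  st <- self_transition_regression(tr, min_remaining = 0, n_boot = 20)
  d <- st$pairs[st$pairs$prev == "water", ]
  x <- cbind(1, d$relative_need)
  y <- as.numeric(d$outcome == "water")
  beta <- solve(crossprod(x), crossprod(x, y))
  expect_equal(st$water$slope, beta[2], tolerance = 1e-10)
})

test_that("perfect persistence gives intercept one and slope zero", {
  # persistent outcomes with exogenously varying needs
  set.seed(27)
  mk <- function(type, id) {
    d <- toy_session(rep(type, 40), session_id = id)
    d$thirst <- runif(40, 0.1, 1)
    d$hunger <- runif(40, 0.1, 1)
    d$relative_need <- (d$thirst - d$hunger) / (d$thirst + d$hunger)
    d$remaining_water <- 50
    d$remaining_food <- 50
    d
  }
  tr <- rbind(mk("water", "a"), mk("food", "b"))
  st <- suppressWarnings(
    self_transition_regression(tr, min_remaining = 0, n_boot = 10))
  expect_equal(st$water$slope, 0, tolerance = 1e-10)
  expect_equal(unname(stats::coef(st$water$fit)[1]), 1, tolerance = 1e-10)
  expect_equal(st$food$slope, 0, tolerance = 1e-10)
})

test_that("mirrored data flips the self-transition slopes", {
  tr <- small_trials()
  st <- self_transition_regression(tr, n_boot = 10)
  mir <- small_dataset()$sessions
  mir$outcome <- c(water = "food", food = "water", miss = "miss",
                   nogo = "nogo")[mir$outcome]
  st2 <- self_transition_regression(behavioral_needs(mir), n_boot = 10)
  expect_equal(st$water$slope, -st2$food$slope, tolerance = 1e-10)
  expect_equal(st$food$slope, -st2$water$slope, tolerance = 1e-10)
})

test_that("transition matrix MLE counts are exact on a toy sequence", {
  tr <- behavioral_needs(
    toy_session(c("water", "water", "food", "food", "water")),
    median_totals = c(water = 3, food = 2))
  # hold relative need inside the window by widening it to [-1, 1]
  tm <- transition_matrix_mle(tr, window = c(-1, 1), n_boot = 10)
  expect_equal(unname(tm$matrix), matrix(0.5, 2, 2))
  expect_equal(unname(rowSums(tm$matrix)), c(1, 1))
})

test_that("switch probability grows with elapsed time between choices", {
  res <- fixed_need_session()
  tr <- res$trials
  tr$session_id <- "fixed"
  tv <- transition_vs_interval(tr, needs = c(1, 1), window = NULL,
                               breaks = seq(0, 60, by = 10))
  b <- tv$bins[is.finite(tv$bins$p_switch), ]
  expect_gt(b$p_switch[nrow(b)], b$p_switch[1])
  expect_true(all(b$p_theory >= 0 & b$p_theory <= 1))
  expect_true(all(diff(b$p_theory) >= 0))
})

test_that("predictor comparison separates sticky and memoryless regimes", {
  # sticky Markov choices, independent of (exogenous) needs
  sticky <- exo_trials(300, function(rn) {
    o <- character(length(rn)); o[1] <- "water"
    for (i in 2:length(rn)) {
      o[i] <- if (stats::runif(1) < 0.95) o[i - 1] else
        setdiff(c("water", "food"), o[i - 1])
    }
    o
  }, seed = 24)
  cmp1 <- choice_predictor_comparison(sticky, seed = 1)
  expect_gt(mean(cmp1$auc_prev_choice), mean(cmp1$auc_needs) + 0.1)
  # memoryless need-threshold choices
  thresh <- exo_trials(300, function(rn)
    ifelse(stats::runif(length(rn)) < stats::plogis(20 * rn),
           "water", "food"), seed = 25)
  cmp2 <- choice_predictor_comparison(thresh, seed = 2)
  expect_gt(mean(cmp2$auc_needs), mean(cmp2$auc_prev_choice) + 0.1)
  # permuted labels carry no information
  perm <- sticky
  set.seed(26)
  perm$outcome <- sample(perm$outcome)
  cmp3 <- choice_predictor_comparison(perm, seed = 3)
  expect_lt(abs(mean(cmp3$auc_needs) - 0.5), 0.12)
  expect_lt(abs(mean(cmp3$auc_prev_choice) - 0.5), 0.12)
})

test_that("stimulation choice densities are normalized on the window", {
  tr <- small_trials()
  onsets <- seq(200, 6000, by = 400)
  d <- stim_choice_density(tr, onsets, window = c(-30, 60))
  for (type in unique(d$outcome)) {
    y <- d$density[d$outcome == type]
    expect_equal(sum(y) * (90 / (length(y) - 1)), 1, tolerance = 0.02)
  }
  # no choices near stimulation -> no density rows
  far <- toy_session(c("water", "food"), times = c(10, 20))
  expect_null(stim_choice_density(far, onsets = 5000))
})

test_that("goal-dimension switch analysis behaves at its degenerate limits", {
  set.seed(25)
  # constant goal value per bout with instantaneous jumps at switches
  out <- unlist(lapply(1:20, function(i)
    rep(c("water", "food")[1 + i %% 2], 5 + (i %% 3))))
  goal <- ifelse(out == "water", 7.5, -7.5)
  ga <- goal_switch_analysis(goal, out)
  expect_equal(ga$auc_choice_all, 1)
  expect_equal(ga$auc_choice_preswitch, 1)
  # permuted switch labels carry no information
  goal_r <- rnorm(length(out))
  ga2 <- goal_switch_analysis(goal_r, sample(out))
  expect_lt(abs(ga2$auc_switch - 0.5), 0.15)
  expect_true(all(ga2$switch_prob$p_switch >= 0 &
                    ga2$switch_prob$p_switch <= 1))
})

test_that("phase portraits normalize densities and detect all-stay data", {
  out <- rep("water", 50)
  goal <- rnorm(50, 7.5, 0.5)
  pp <- phase_portrait(goal, out, n_resample = 50)
  expect_equal(sum(pp$density$switch), 0)
  set.seed(26)
  res <- fixed_need_session()
  rew <- res$trials$outcome %in% c("water", "food")
  g <- trial_goal_values(res)[rew]
  pp2 <- phase_portrait(g, res$trials$outcome[rew], n_resample = 100)
  expect_equal(sum(pp2$density$stay), 1, tolerance = 1e-10)
  expect_equal(sum(pp2$density$switch), 1, tolerance = 1e-10)
})

test_that("statistics are source-agnostic: file round-trip changes nothing", {
  tr <- small_trials()
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(small_dataset()$sessions, path)
  tr2 <- behavioral_needs(read_sessions(path))
  pf1 <- persistence_fit(tr, n_boot = 10)
  pf2 <- persistence_fit(tr2, n_boot = 10)
  expect_identical(pf1$p_hat, pf2$p_hat)
  expect_identical(selectivity_index(tr), selectivity_index(tr2))
})
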