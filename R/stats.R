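# Behavioural statistics, applied identically to simulated and
# experiment-format session tables.

reward_outcomes <- c("water", "food")

go_trials <- function(trials) {
  out <- trials[trials$label == "Go", , drop = FALSE]
  out[order(out$session_id, out$trial_time_s), , drop = FALSE]
}

#' Annotate trials with behavioural thirst, hunger and relative need
#'
#' Behavioural thirst at a trial is the number of water rewards still to be
#' collected in that session (future rewards), normalized by the median
#' session total across the dataset; hunger analogously for food. Relative
#' need is `(thirst - hunger) / (thirst + hunger)` in `[-1, 1]` (`NA` when
#' both needs are zero). Raw remaining-reward counts are kept as
#' `remaining_water` / `remaining_food` for exclusion rules.
#'
#' @param trials session table (all sessions of a dataset).
#' @param median_totals optional named pair `c(water=, food=)` of median
#'   session totals; computed from the supplied dataset when `NULL`.
#' @return `trials` with columns `thirst`, `hunger`, `relative_need`,
#'   `remaining_water`, `remaining_food` added, and the totals used attached
#'   as attribute `median_totals`.
#' @export
behavioral_needs <- function(trials, median_totals = NULL) {
  trials <- trials[order(trials$session_id, trials$trial_time_s), ,
                   drop = FALSE]
  sid <- trials$session_id
  w <- as.numeric(trials$outcome == "water")
  f <- as.numeric(trials$outcome == "food")
  tot_w <- tapply(w, sid, sum)
  tot_f <- tapply(f, sid, sum)
  if (is.null(median_totals)) {
    median_totals <- c(water = stats::median(tot_w),
                       food = stats::median(tot_f))
  }
  if (any(median_totals <= 0))
    stop("median totals must be positive; supply 'median_totals'")
  # rewards collected before the current trial (exclusive cumulative count)
  cw <- unlist(tapply(w, sid, function(v) cumsum(v) - v), use.names = FALSE)
  cf <- unlist(tapply(f, sid, function(v) cumsum(v) - v), use.names = FALSE)
  trials$remaining_water <- as.numeric(tot_w[sid]) - cw
  trials$remaining_food <- as.numeric(tot_f[sid]) - cf
  trials$thirst <- trials$remaining_water / median_totals[["water"]]
  trials$hunger <- trials$remaining_food / median_totals[["food"]]
  denom <- trials$thirst + trials$hunger
  trials$relative_need <- ifelse(denom > 0,
                                 (trials$thirst - trials$hunger) / denom,
                                 NA_real_)
  rownames(trials) <- NULL
  attr(trials, "median_totals") <- median_totals
  trials
}

#' Per-session choice selectivity index
#'
#' `(cumulative water - cumulative food) / (cumulative water + cumulative
#' food)`: +1 all water, -1 all food.
#'
#' @param trials session table (one or more sessions).
#' @return Named numeric vector, one index per session.
#' @export
selectivity_index <- function(trials) {
  sid <- unique(trials$session_id)
  vapply(sid, function(id) {
    o <- trials$outcome[trials$session_id == id]
    nw <- sum(o == "water"); nf <- sum(o == "food")
    if (nw + nf == 0) return(NA_real_)
    (nw - nf) / (nw + nf)
  }, numeric(1))
}

# run lengths of identical consecutive rewarded choices, one session
session_run_lengths <- function(outcomes) {
  r <- outcomes[outcomes %in% reward_outcomes]
  if (!length(r)) return(integer(0))
  rle(r)$lengths
}

#' Geometric fit to reward-choice persistence (bout) lengths
#'
#' Pools the run lengths of identical consecutive rewarded choices across
#' sessions and fits the geometric switch probability by maximum likelihood
#' (`p_hat = 1 / mean(run length)`), with a session-level bootstrap
#' confidence interval.
#'
#' @param trials session table.
#' @param n_boot bootstrap resamples (sessions resampled with replacement).
#' @param conf confidence level.
#' @return List of class `bout_summary`: pooled `run_lengths`, per-session
#'   list `by_session`, `p_hat`, `ci`, `n_boot`.
#' @export
persistence_fit <- function(trials, n_boot = 1000, conf = 0.95) {
  go <- go_trials(trials)
  by_session <- lapply(split(go$outcome, go$session_id),
                       session_run_lengths)
  pooled <- unlist(by_session, use.names = FALSE)
  if (!length(pooled)) stop("no rewarded choices in 'trials'")
  p_hat <- 1 / mean(pooled)
  bs <- vapply(seq_len(n_boot), function(i) {
    take <- sample(length(by_session), replace = TRUE)
    1 / mean(unlist(by_session[take], use.names = FALSE))
  }, numeric(1))
  a <- (1 - conf) / 2
  structure(list(run_lengths = pooled, by_session = by_session,
                 p_hat = p_hat,
                 ci = stats::quantile(bs, c(a, 1 - a), names = FALSE),
                 n_boot = n_boot),
            class = "bout_summary")
}

#' @export
print.bout_summary <- function(x, ...) {
  cat(sprintf(paste0("Geometric persistence fit: p = %.4f ",
                     "(95%% CI %.4f-%.4f), %d bouts, mean length %.2f\n"),
              x$p_hat, x$ci[1], x$ci[2], length(x$run_lengths),
              mean(x$run_lengths)))
  invisible(x)
}

# 5-percentile bins of pooled relative need; returns factor of bin index.
# Degenerate spreads (all values equal) collapse to a single bin.
need_bins <- function(rn, width = 0.05) {
  qs <- unique(stats::quantile(rn, probs = seq(0, 1, width), na.rm = TRUE,
                               type = 1))
  if (length(qs) < 2) return(factor(rep(1L, length(rn))))
  cut(rn, breaks = qs, include.lowest = TRUE)
}

boot_ci_by_session <- function(df, stat, n_boot, conf = 0.95) {
  ids <- unique(df$session_id)
  bs <- vapply(seq_len(n_boot), function(i) {
    take <- sample(ids, replace = TRUE)
    stat(do.call(rbind, lapply(take, function(id)
      df[df$session_id == id, , drop = FALSE])))
  }, numeric(1))
  a <- (1 - conf) / 2
  stats::quantile(bs, c(a, 1 - a), names = FALSE, na.rm = TRUE)
}

#' Water-choice probability as a function of relative need
#'
#' Linear regression of the binary water-choice indicator on relative need
#' over rewarded Go trials, plus per-5-percentile-bin maximum-likelihood
#' water fractions with session-level bootstrap confidence intervals.
#'
#' @param trials annotated session table ([behavioral_needs()]).
#' @param n_boot bootstrap resamples for the slope and bin CIs.
#' @param bin_width percentile bin width (0.05 = 5-percentile bins).
#' @return List: `fit` (the `lm`), `slope`, `r_squared`, `slope_ci`, and
#'   `bins` (one row per bin: centre, MLE fraction, CI, count).
#' @export
choice_probability_vs_need <- function(trials, n_boot = 1000,
                                       bin_width = 0.05) {
  go <- go_trials(trials)
  d <- go[go$outcome %in% reward_outcomes & is.finite(go$relative_need), ,
          drop = FALSE]
  d$water <- as.numeric(d$outcome == "water")
  fit <- stats::lm(water ~ relative_need, data = d)
  slope_ci <- boot_ci_by_session(d, function(b)
    stats::coef(stats::lm(water ~ relative_need, data = b))[2], n_boot)
  bin <- need_bins(d$relative_need, bin_width)
  cent <- tapply(d$relative_need, bin, mean)
  frac <- tapply(d$water, bin, mean)
  nb <- tapply(d$water, bin, length)
  lo <- hi <- rep(NA_real_, nlevels(bin))
  for (k in seq_len(nlevels(bin))) {
    yk <- d$water[as.integer(bin) == k]
    if (length(yk) >= 3) {
      bs <- vapply(seq_len(n_boot), function(i)
        mean(sample(yk, replace = TRUE)), numeric(1))
      lo[k] <- stats::quantile(bs, 0.025)
      hi[k] <- stats::quantile(bs, 0.975)
    }
  }
  list(fit = fit,
       slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       slope_ci = slope_ci,
       bins = data.frame(need = as.numeric(cent), p_water = as.numeric(frac),
                         lo = lo, hi = hi, n = as.numeric(nb)))
}

# consecutive rewarded-choice pairs with the current trial's annotation
choice_pairs <- function(trials, require_adjacent = FALSE) {
  out <- NULL
  for (sid in unique(trials$session_id)) {
    go <- trials[trials$session_id == sid & trials$label == "Go", ,
                 drop = FALSE]
    go <- go[order(go$trial_time_s), , drop = FALSE]
    ri <- which(go$outcome %in% reward_outcomes)
    if (length(ri) < 2) next
    a <- ri[-length(ri)]; b <- ri[-1]
    if (require_adjacent) {
      keep <- b == a + 1L
      a <- a[keep]; b <- b[keep]
    }
    if (!length(a)) next
    row <- go[b, , drop = FALSE]
    row$prev <- go$outcome[a]
    row$dt <- go$trial_time_s[b] - go$trial_time_s[a]
    out <- rbind(out, row)
  }
  out
}

#' Self-transition probability regressions
#'
#' For each reward type, a linear regression predicting a repeat of the
#' previous rewarded choice from the current relative need, after dropping
#' trials with fewer than `min_remaining` remaining rewards of either type
#' (sampling-floor exclusion), plus binned MLE repeat fractions.
#'
#' @param trials annotated session table.
#' @param min_remaining exclusion threshold on remaining rewards.
#' @param n_boot bootstrap resamples for slope CIs.
#' @param bin_width percentile bin width for the MLE curve.
#' @return List with one element per choice type (`water`, `food`): `fit`,
#'   `slope`, `r_squared`, `slope_ci`, `bins`; plus `pairs`, the data used.
#' @export
self_transition_regression <- function(trials, min_remaining = 10,
                                       n_boot = 1000, bin_width = 0.05) {
  pr <- choice_pairs(trials)
  pr <- pr[is.finite(pr$relative_need) &
           pr$remaining_water >= min_remaining &
           pr$remaining_food >= min_remaining, , drop = FALSE]
  res <- list(pairs = pr)
  for (type in reward_outcomes) {
    d <- pr[pr$prev == type, , drop = FALSE]
    d$repeat_choice <- as.numeric(d$outcome == type)
    fit <- stats::lm(repeat_choice ~ relative_need, data = d)
    ci <- boot_ci_by_session(d, function(b)
      stats::coef(stats::lm(repeat_choice ~ relative_need, data = b))[2],
      n_boot)
    bin <- need_bins(d$relative_need, bin_width)
    res[[type]] <- list(
      fit = fit, slope = unname(stats::coef(fit)[2]),
      r_squared = summary(fit)$r.squared, slope_ci = ci,
      bins = data.frame(
        need = as.numeric(tapply(d$relative_need, bin, mean)),
        p_repeat = as.numeric(tapply(d$repeat_choice, bin, mean)),
        n = as.numeric(tapply(d$repeat_choice, bin, length))))
  }
  res
}

#' Maximum-likelihood Markov transition matrix under balanced needs
#'
#' Transition counts over consecutive rewarded choices restricted to trials
#' whose relative need lies inside `window`, row-normalized, with
#' session-level bootstrap CIs on the diagonal.
#'
#' @param trials annotated session table.
#' @param window relative-need window (default balanced needs).
#' @param n_boot bootstrap resamples.
#' @return List: `matrix` (2 x 2, rows = previous choice `food`, `water`),
#'   `counts`, `diag_ci` (bootstrap CIs for `P_ff` and `P_ww`), `n`.
#' @export
transition_matrix_mle <- function(trials, window = c(-0.25, 0.25),
                                  n_boot = 1000) {
  pr <- choice_pairs(trials)
  pr <- pr[is.finite(pr$relative_need) &
           pr$relative_need >= window[1] & pr$relative_need <= window[2], ,
           drop = FALSE]
  lv <- c("food", "water")
  cnt <- table(factor(pr$prev, lv), factor(pr$outcome, lv))
  mat <- prop.table(cnt, 1)
  di <- function(b, type) {
    d <- b[b$prev == type, , drop = FALSE]
    if (!nrow(d)) return(NA_real_)
    mean(d$outcome == type)
  }
  ci <- rbind(food = boot_ci_by_session(pr, function(b) di(b, "food"),
                                        n_boot),
              water = boot_ci_by_session(pr, function(b) di(b, "water"),
                                         n_boot))
  colnames(ci) <- c("lo", "hi")
  list(matrix = unclass(as.matrix(mat)), counts = unclass(as.matrix(cnt)),
       diag_ci = ci, n = nrow(pr))
}

#' Switch probability versus time between choices, with theory overlay
#'
#' Bins the elapsed time between consecutive rewarded choices (under
#' balanced needs) and estimates the per-bin switch probability, overlaid
#' with the closed-form transition-matrix prediction evaluated at `needs`.
#'
#' @param trials annotated session table.
#' @param geom,params model used for the theoretical overlay.
#' @param needs `c(thirst, hunger)` at which the theory is evaluated.
#' @param window balanced-need restriction on relative need (`NULL` = no
#'   restriction).
#' @param breaks time-bin boundaries, seconds.
#' @return List: `bins` (per-bin time, empirical switch probability,
#'   binomial CI, count, theoretical probability) and `r_squared` between
#'   theory and data across bins.
#' @export
transition_vs_interval <- function(trials, geom = well_geometry(),
                                   params = default_params("behavior"),
                                   needs = c(1, 1),
                                   window = c(-0.25, 0.25),
                                   breaks = seq(0, 60, by = 7.5)) {
  pr <- choice_pairs(trials)
  if (!is.null(window) && "relative_need" %in% names(pr))
    pr <- pr[is.finite(pr$relative_need) &
             pr$relative_need >= window[1] & pr$relative_need <= window[2], ,
             drop = FALSE]
  pr <- pr[pr$dt <= max(breaks), , drop = FALSE]
  pr$switch <- as.numeric(pr$outcome != pr$prev)
  bin <- cut(pr$dt, breaks, include.lowest = TRUE)
  t_mid <- tapply(pr$dt, bin, mean)
  p_emp <- tapply(pr$switch, bin, mean)
  nb <- tapply(pr$switch, bin, length)
  ci <- t(vapply(seq_len(nlevels(bin)), function(k) {
    x <- sum(pr$switch[as.integer(bin) == k], na.rm = TRUE)
    nn <- sum(as.integer(bin) == k, na.rm = TRUE)
    if (nn == 0) return(c(NA_real_, NA_real_))
    as.numeric(stats::binom.test(x, nn)$conf.int)
  }, numeric(2)))
  rates <- kramers_rates(needs[1], needs[2], geom, params)
  # average off-diagonal switch probability at the bin's mean elapsed time
  p_th <- vapply(as.numeric(t_mid), function(tt) {
    if (is.na(tt)) return(NA_real_)
    tm <- transition_matrix(tt, rates = rates)
    mean(c(tm["water", "food"], tm["food", "water"]))
  }, numeric(1))
  keep <- is.finite(p_emp) & is.finite(p_th)
  ssr <- sum((p_emp[keep] - p_th[keep])^2)
  sst <- sum((p_emp[keep] - mean(p_emp[keep]))^2)
  list(bins = data.frame(t = as.numeric(t_mid),
                         p_switch = as.numeric(p_emp),
                         lo = ci[, 1], hi = ci[, 2],
                         n = as.numeric(nb), p_theory = p_th),
       r_squared = 1 - ssr / sst)
}

auc_of <- function(score, label) {
  if (length(unique(label)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Needs versus previous choice as predictors of the upcoming choice
#'
#' Per session, fits an RBF-kernel support vector machine on (i) the
#' behavioural thirst and hunger features and (ii) the previous-choice
#' indicator alone, each on a random 50% split, and reports held-out AUCs
#' for predicting the upcoming rewarded choice.
#'
#' @param trials annotated session table.
#' @param cost SVM regularization weight.
#' @param seed integer seed for the train/test splits.
#' @return Data frame with one row per session: `auc_needs`,
#'   `auc_prev_choice`, `n`; the paired mean difference as attribute
#'   `mean_diff`.
#' @export
choice_predictor_comparison <- function(trials, cost = 1, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  pr <- choice_pairs(trials)
  out <- NULL
  for (sid in unique(pr$session_id)) {
    d <- pr[pr$session_id == sid, , drop = FALSE]
    d <- d[is.finite(d$thirst) & is.finite(d$hunger), , drop = FALSE]
    y <- factor(d$outcome, reward_outcomes)
    if (nrow(d) < 20 || length(unique(y)) < 2) next
    tr <- sample(nrow(d), floor(nrow(d) / 2))
    te <- setdiff(seq_len(nrow(d)), tr)
    svm_auc <- function(xmat) {
      # kernel width scaled by total feature variance (the "scale" rule)
      v <- stats::var(as.numeric(xmat))
      gam <- 1 / (ncol(xmat) * max(v, 1e-12))
      if (length(unique(y[tr])) < 2) return(NA_real_)
      m <- e1071::svm(xmat[tr, , drop = FALSE], y[tr], cost = cost,
                      gamma = gam, kernel = "radial", scale = FALSE)
      dv <- attr(stats::predict(m, xmat[te, , drop = FALSE],
                                decision.values = TRUE),
                 "decision.values")
      sc <- dv[, 1]
      # orient the decision score towards "water"
      if (!startsWith(colnames(dv)[1], "water")) sc <- -sc
      auc_of(sc, as.numeric(y[te] == "water"))
    }
    a_need <- svm_auc(cbind(d$thirst, d$hunger))
    a_prev <- svm_auc(cbind(as.numeric(d$prev == "water")))
    out <- rbind(out, data.frame(session_id = sid, auc_needs = a_need,
                                 auc_prev_choice = a_prev, n = nrow(d)))
  }
  attr(out, "mean_diff") <- mean(out$auc_prev_choice - out$auc_needs,
                                 na.rm = TRUE)
  out
}

#' Choice-time densities around stimulation onsets
#'
#' Gaussian kernel density estimates (Scott's bandwidth rule) of Go-choice
#' times relative to the nearest stimulation onset, per outcome class,
#' normalized over the analysis window.
#'
#' @param trials session table.
#' @param onsets stimulation onset times, seconds.
#' @param window analysis window around onset, seconds.
#' @param n_grid evaluation points.
#' @return Data frame: `time`, `outcome`, `density` (integrating to 1 per
#'   outcome class over the window).
#' @export
stim_choice_density <- function(trials, onsets, window = c(-30, 60),
                                n_grid = 181) {
  go <- go_trials(trials)
  out <- NULL
  grid <- seq(window[1], window[2], length.out = n_grid)
  for (type in reward_outcomes) {
    tt <- go$trial_time_s[go$outcome == type]
    if (!length(tt)) next
    off <- vapply(tt, function(x) x - onsets[which.min(abs(x - onsets))],
                  numeric(1))
    off <- off[off >= window[1] & off <= window[2]]
    if (length(off) < 2) next
    dens <- stats::density(off, bw = stats::bw.nrd(off), from = window[1],
                           to = window[2], n = n_grid)
    y <- dens$y / (sum(dens$y) * diff(grid[1:2])) # renormalize on window
    out <- rbind(out, data.frame(time = grid, outcome = type, density = y))
  }
  out
}

#' Goal-dimension predictiveness of choices and switches
#'
#' From per-trial goal-dimension values and rewarded outcomes: (i) AUC for
#' predicting the upcoming choice from the goal value, overall and on trials
#' at or just before switches; (ii) switch probability as a 1-D linear
#' discriminant rescaling of the distance of the goal value from the
#' midpoint; (iii) AUC for predicting switches from that distance.
#'
#' @param goal per-trial goal-dimension values (rewarded trials, in order).
#' @param outcomes matching rewarded outcomes (`"water"`/`"food"`).
#' @param midpoint goal-dimension midpoint between the wells.
#' @param pre_switch_window how many trials before a switch count as
#'   "pre-switch".
#' @return List: `auc_choice_all`, `auc_choice_preswitch`, `auc_switch`,
#'   `switch_prob` (data frame with per-trial LDA-rescaled switch
#'   probability), `switch_rate`.
#' @export
goal_switch_analysis <- function(goal, outcomes, midpoint = 0,
                                 pre_switch_window = 1L) {
  stopifnot(length(goal) == length(outcomes))
  y <- as.numeric(outcomes == "water")
  sw <- c(NA, as.numeric(outcomes[-1] != outcomes[-length(outcomes)]))
  auc_all <- auc_of(goal, y)
  # trials at or just before a switch: switch occurs at t+1 .. t+window
  pre <- rep(FALSE, length(goal))
  si <- which(sw == 1)
  for (k in seq_len(pre_switch_window)) {
    idx <- si - k
    pre[idx[idx >= 1]] <- TRUE
  }
  auc_pre <- auc_of(goal[pre], y[pre])
  mag <- abs(goal - midpoint)
  ok <- !is.na(sw)
  auc_sw <- auc_of(-mag[ok], sw[ok]) # smaller distance -> likelier switch
  post <- tryCatch({
    ld <- MASS::lda(x = matrix(mag[ok], ncol = 1), grouping = sw[ok])
    stats::predict(ld, matrix(mag[ok], ncol = 1))$posterior[, "1"]
  }, error = function(e) {
    # degenerate magnitudes (constant within groups): fall back to the
    # marginal switch rate
    rep(mean(sw[ok]), sum(ok))
  })
  list(auc_choice_all = auc_all, auc_choice_preswitch = auc_pre,
       auc_switch = auc_sw,
       switch_prob = data.frame(goal = goal[ok], magnitude = mag[ok],
                                switch = sw[ok], p_switch = post),
       switch_rate = mean(sw, na.rm = TRUE))
}

#' Phase portrait of goal-dimension position and velocity
#'
#' Per rewarded trial, the goal-dimension position and its change to the
#' next rewarded trial (the trial-to-trial velocity), labelled stay/switch
#' by the next outcome. Densities of stay and switch trials inside the
#' transition zone (positions within `zone_halfwidth` of the midpoint) are
#' binned over velocity, normalized to sum to 1, and averaged over
#' resamples drawn to match `target_switch_fraction`.
#'
#' @param goal per-trial goal-dimension values (rewarded trials, in order).
#' @param outcomes matching rewarded outcomes.
#' @param midpoint goal-dimension midpoint.
#' @param zone_halfwidth transition-zone half-width (default: half the
#'   distance from midpoint to a well projection under the default
#'   geometry).
#' @param v_breaks velocity bin boundaries.
#' @param n_resample resamples matching the target switch fraction.
#' @param target_switch_fraction switch fraction to resample to (`NULL` =
#'   the observed fraction, no rebalancing).
#' @return List: `points` (position, velocity, label), `density` (per
#'   velocity bin, stay and switch densities), `switch_fraction`.
#' @export
phase_portrait <- function(goal, outcomes, midpoint = 0,
                           zone_halfwidth = 3.75,
                           v_breaks = seq(-15, 15, by = 2.5),
                           n_resample = 1000,
                           target_switch_fraction = NULL) {
  stopifnot(length(goal) == length(outcomes))
  n <- length(goal)
  if (n < 2) stop("need at least two rewarded trials")
  pos <- goal[-n]
  vel <- diff(goal)
  lab <- ifelse(outcomes[-1] == outcomes[-n], "stay", "switch")
  pts <- data.frame(position = pos, velocity = vel, label = lab)
  inz <- abs(pos - midpoint) <= zone_halfwidth
  zone <- pts[inz, , drop = FALSE]
  zone$velocity <- pmin(max(v_breaks), pmax(min(v_breaks), zone$velocity))
  bin_density <- function(v) {
    h <- tabulate(cut(v, v_breaks, include.lowest = TRUE),
                  nbins = length(v_breaks) - 1)
    if (sum(h) == 0) return(rep(0, length(h)))
    h / sum(h)
  }
  i_stay <- which(zone$label == "stay")
  i_switch <- which(zone$label == "switch")
  obs_frac <- length(i_switch) / max(1, nrow(zone))
  frac <- if (is.null(target_switch_fraction)) obs_frac else
    target_switch_fraction
  m <- nrow(zone)
  n_sw <- max(1L, round(frac * m))
  n_st <- max(1L, m - n_sw)
  d_stay <- matrix(0, n_resample, length(v_breaks) - 1)
  d_switch <- matrix(0, n_resample, length(v_breaks) - 1)
  for (r in seq_len(n_resample)) {
    st <- if (length(i_stay)) sample(i_stay, n_st, replace = TRUE) else
      integer(0)
    sv <- if (length(i_switch)) sample(i_switch, n_sw, replace = TRUE) else
      integer(0)
    d_stay[r, ] <- bin_density(zone$velocity[st])
    d_switch[r, ] <- bin_density(zone$velocity[sv])
  }
  mid <- (v_breaks[-1] + v_breaks[-length(v_breaks)]) / 2
  list(points = pts,
       density = data.frame(velocity = mid,
                            stay = colMeans(d_stay),
                            switch = colMeans(d_switch)),
       switch_fraction = obs_frac,
       zone_n = c(stay = length(i_stay), switch = length(i_switch)))
}
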