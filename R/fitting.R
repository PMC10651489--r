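# Joint likelihood fitting of the scale triple (g, n, s).
#
# Three datasets are built from annotated trial tables and scored with the
# closed-form theory: (i) sequential rewarded trial pairs under the
# time-dependent two-state transition matrix; (ii) individual rewarded
# choices under the two-zone Boltzmann probability; (iii) Go trials near
# satiation (including misses) under the three-zone Boltzmann probability.
# The loss is the sum of the three per-trial mean negative log-likelihoods.

#' Build the three fitting datasets from annotated trials
#'
#' @param trials a session table (see [read_sessions()]) annotated with
#'   `thirst` and `hunger` columns ([behavioral_needs()]).
#' @param satiation_threshold trials with both needs strictly below this
#'   value form the satiation set.
#' @return List with data frames `pairs` (previous choice, next choice,
#'   elapsed time, needs at the previous reward), `choices` (rewarded trials
#'   not adjacent to a miss) and `satiation` (near-satiation Go trials,
#'   including misses).
#' @export
build_datasets <- function(trials, satiation_threshold = 0.5) {
  need_cols <- c("session_id", "trial_time_s", "label", "outcome",
                 "thirst", "hunger")
  if (!all(need_cols %in% names(trials)))
    stop("'trials' must carry columns ", paste(need_cols, collapse = ", "),
         " (run behavioral_needs() first)")
  pairs <- NULL; choices <- NULL; satia <- NULL
  for (sid in unique(trials$session_id)) {
    go <- trials[trials$session_id == sid & trials$label == "Go", ,
                 drop = FALSE]
    go <- go[order(go$trial_time_s), , drop = FALSE]
    rewarded <- go$outcome %in% c("water", "food")
    ri <- which(rewarded)
    if (length(ri) < 2L) {
      if (length(ri) < 2L && nrow(go) > 0)
        warning("session ", sid, " has fewer than 2 rewarded trials; ",
                "no pairs contributed")
    } else {
      a <- ri[-length(ri)]
      b <- ri[-1L]
      ok <- b == a + 1L # no Go-trial miss in between
      if (any(ok)) {
        pairs <- rbind(pairs, data.frame(
          session_id = sid,
          prev = go$outcome[a[ok]], nxt = go$outcome[b[ok]],
          dt = go$trial_time_s[b[ok]] - go$trial_time_s[a[ok]],
          thirst = go$thirst[a[ok]], hunger = go$hunger[a[ok]],
          stringsAsFactors = FALSE))
      }
    }
    # rewarded trials whose flanking Go trials are not misses
    if (length(ri)) {
      miss <- go$outcome == "miss"
      prev_miss <- c(FALSE, miss[-length(miss)])
      next_miss <- c(miss[-1L], FALSE)
      keep <- ri[!prev_miss[ri] & !next_miss[ri]]
      if (length(keep))
        choices <- rbind(choices, go[keep, c("session_id", "outcome",
                                             "thirst", "hunger")])
    }
    near <- go$thirst < satiation_threshold & go$hunger < satiation_threshold
    if (any(near))
      satia <- rbind(satia, go[near, c("session_id", "outcome",
                                       "thirst", "hunger")])
  }
  rownames(choices) <- NULL
  rownames(satia) <- NULL
  list(pairs = pairs, choices = choices, satiation = satia)
}

# value (and optionally gradient wrt g, n, s) of the composite loss.
# idx2 / idx3 subset the choice and satiation sets (batching).
nll_eval <- function(params, datasets, geom, spacing = 0.25,
                     idx2 = NULL, idx3 = NULL, grad = FALSE) {
  g <- params$g; n <- params$n; s <- params$s
  val <- 0
  gr <- c(g = 0, n = 0, s = 0)
  parts <- c(pairs = NA_real_, choices = NA_real_, satiation = NA_real_)

  pr <- datasets$pairs
  if (!is.null(pr) && nrow(pr)) {
    rv <- rates_vec(pr$thirst, pr$hunger, geom, params)
    om <- rv$owf + rv$ofw
    e <- exp(-om * pr$dt)
    pi_w <- rv$ofw / om
    pi_f <- rv$owf / om
    from_w <- pr$prev == "water"
    to_same <- pr$prev == pr$nxt
    p_ww <- pi_w * (1 - e) + e
    p_ff <- pi_f * (1 - e) + e
    p <- ifelse(from_w, ifelse(to_same, p_ww, 1 - p_ww),
                        ifelse(to_same, p_ff, 1 - p_ff))
    if (any(p <= 0)) stop("non-positive pair probability: numerical failure")
    parts["pairs"] <- mean(-log(p))
    val <- val + parts[["pairs"]]
    if (grad) {
      de <- -pr$dt * e # d e / d omega_k, either rate
      dpi_w_owf <- -rv$ofw / om^2
      dpi_w_ofw <- rv$owf / om^2
      dP_ww_owf <- dpi_w_owf * (1 - e) + (1 - pi_w) * de
      dP_ww_ofw <- dpi_w_ofw * (1 - e) + (1 - pi_w) * de
      dpi_f_owf <- rv$ofw / om^2
      dpi_f_ofw <- -rv$owf / om^2
      dP_ff_owf <- dpi_f_owf * (1 - e) + (1 - pi_f) * de
      dP_ff_ofw <- dpi_f_ofw * (1 - e) + (1 - pi_f) * de
      sgn <- ifelse(to_same, 1, -1)
      dp_owf <- ifelse(from_w, sgn * dP_ww_owf, sgn * dP_ff_owf)
      dp_ofw <- ifelse(from_w, sgn * dP_ww_ofw, sgn * dP_ff_ofw)
      for (k in 1:3) {
        gr[k] <- gr[k] + mean(-(dp_owf * rv$d_owf[, k] +
                                dp_ofw * rv$d_ofw[, k]) / p)
      }
    }
  }

  # evaluated in row chunks to bound the trials x grid working memory
  bterm <- function(dat, three_zone, chunk = 256L) {
    q <- quad_grid(geom, spacing)
    kap <- g / n^2
    n_tot <- nrow(dat)
    tot_nll <- 0
    tot_grad <- numeric(3)
    for (lo in seq(1L, n_tot, by = chunk)) {
      hi <- min(n_tot, lo + chunk - 1L)
      da <- dat[lo:hi, , drop = FALSE]
      m <- tcrossprod(s * da$thirst, q$pw) + tcrossprod(s * da$hunger, q$pf) +
        matrix(q$po, nrow(da), length(q$po), byrow = TRUE)
      lg_m <- log(m)
      w <- exp(kap * lg_m)
      S <- w %*% q$mask * q$cell
      denom <- if (three_zone) rowSums(S) else S[, 1] + S[, 2]
      pick <- cbind(seq_len(nrow(da)),
                    match(ifelse(da$outcome == "miss", "other", da$outcome),
                          colnames(q$mask)))
      p <- S[pick] / denom
      if (any(p <= 0))
        stop("non-positive zone probability: numerical failure")
      tot_nll <- tot_nll + sum(-log(p))
      if (grad) {
        wl <- w * lg_m
        Sg <- (wl %*% q$mask) * q$cell / n^2            # d/dg
        Sn <- (wl %*% q$mask) * q$cell * (-2 * g / n^3) # d/dn
        dms <- (tcrossprod(da$thirst, q$pw) +
                  tcrossprod(da$hunger, q$pf)) / m
        Ss <- ((w * dms) %*% q$mask) * q$cell * kap     # d/ds
        for (k in 1:3) {
          dS <- switch(k, Sg, Sn, Ss)
          ddenom <- if (three_zone) rowSums(dS) else dS[, 1] + dS[, 2]
          dp <- (dS[pick] - p * ddenom) / denom
          tot_grad[k] <- tot_grad[k] + sum(-dp / p)
        }
      }
    }
    out <- list(value = tot_nll / n_tot)
    if (grad) out$grad <- tot_grad / n_tot
    out
  }

  ch <- datasets$choices
  if (!is.null(ch) && nrow(ch)) {
    if (!is.null(idx2)) ch <- ch[idx2, , drop = FALSE]
    t2 <- bterm(ch, three_zone = FALSE)
    parts["choices"] <- t2$value
    val <- val + t2$value
    if (grad) gr <- gr + t2$grad
  }
  sa <- datasets$satiation
  if (!is.null(sa) && nrow(sa)) {
    if (!is.null(idx3)) sa <- sa[idx3, , drop = FALSE]
    t3 <- bterm(sa, three_zone = TRUE)
    parts["satiation"] <- t3$value
    val <- val + t3$value
    if (grad) gr <- gr + t3$grad
  }
  if (!is.finite(val)) stop("non-finite loss")
  list(value = val, grad = if (grad) gr else NULL, parts = parts)
}

#' Composite negative log-likelihood of the scale parameters
#'
#' Mean per-trial negative log-likelihood of the pair, choice and satiation
#' datasets under the closed-form theory, added together.
#'
#' @param params a [model_params()] (or named `c(g=, n=, s=)`).
#' @param datasets output of [build_datasets()].
#' @param geom a [well_geometry()].
#' @param spacing quadrature spacing used for the Boltzmann terms.
#' @return Scalar loss with attribute `parts` (the three per-dataset means).
#' @export
joint_nll <- function(params, datasets, geom = well_geometry(),
                      spacing = 0.25) {
  params <- as_params(params)
  ev <- nll_eval(params, datasets, geom, spacing)
  structure(ev$value, parts = ev$parts)
}

#' Gradient of [joint_nll()] with respect to (g, n, s)
#'
#' Analytic gradient: the pair term differentiates the Kramers rates (with
#' the stationary-point locations held fixed, exact by the envelope theorem);
#' the Boltzmann terms differentiate the quadrature weights directly.
#'
#' @inheritParams joint_nll
#' @return Named numeric gradient `c(g, n, s)`.
#' @export
joint_nll_grad <- function(params, datasets, geom = well_geometry(),
                           spacing = 0.25) {
  params <- as_params(params)
  nll_eval(params, datasets, geom, spacing, grad = TRUE)$grad
}

#' Fit the landscape scale parameters to behavioural trial tables
#'
#' Jointly fits the gradient scale `g`, noise scale `n` and foraging weight
#' `s` by first-order adaptive gradient descent (Adam) on the composite
#' negative log-likelihood, parameterized in logs to enforce positivity. The
#' Boltzmann terms are re-batched every epoch; the pair term is evaluated in
#' full.
#'
#' @param trials session table; if the `thirst`/`hunger` annotation columns
#'   are absent they are added with [behavioral_needs()].
#' @param geom a [well_geometry()].
#' @param init initial [model_params()].
#' @param batch_fraction fraction of the choice and satiation sets scored per
#'   epoch (subject to `batch_min`).
#' @param batch_min minimum batch size.
#' @param lr Adam learning rate.
#' @param max_epochs epoch cap.
#' @param tol,patience convergence: stop once the smoothed loss improves by
#'   less than `tol` for `patience` consecutive epochs.
#' @param spacing quadrature spacing for the Boltzmann terms.
#' @param seed integer seed for batch draws (deterministic fits).
#' @param satiation_threshold passed to [build_datasets()].
#' @return An object of class `needfit`.
#' @export
fit_landscape <- function(trials, geom = well_geometry(),
                          init = model_params(2, 2, 5),
                          batch_fraction = 1 / 50, batch_min = 100L,
                          lr = 0.1, max_epochs = 400L,
                          tol = 1e-6, patience = 50L,
                          spacing = 0.25, seed = 1L,
                          satiation_threshold = 0.5) {
  if (!all(c("thirst", "hunger") %in% names(trials)))
    trials <- behavioral_needs(trials)
  datasets <- build_datasets(trials, satiation_threshold)
  init <- as_params(init)
  geom <- as_geometry(geom)
  if (!is.null(seed)) set.seed(seed)

  theta <- log(c(g = init$g, n = init$n, s = init$s))
  m1 <- v1 <- numeric(3)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n2 <- nrow(datasets$choices)
  n3 <- nrow(datasets$satiation)
  bs2 <- if (is.null(n2)) 0 else min(n2, max(batch_min,
                                             ceiling(batch_fraction * n2)))
  bs3 <- if (is.null(n3)) 0 else min(n3, max(batch_min,
                                             ceiling(batch_fraction * n3)))
  trace <- numeric(0)
  smooth <- NA_real_
  stall <- 0L
  converged <- FALSE
  for (epoch in seq_len(max_epochs)) {
    idx2 <- if (bs2 > 0 && bs2 < n2) sample.int(n2, bs2) else NULL
    idx3 <- if (bs3 > 0 && bs3 < n3) sample.int(n3, bs3) else NULL
    p <- model_params(exp(theta[1]), exp(theta[2]), exp(theta[3]))
    ev <- nll_eval(p, datasets, geom, spacing, idx2, idx3, grad = TRUE)
    gth <- ev$grad * exp(theta) # chain rule onto log-scale
    m1 <- b1 * m1 + (1 - b1) * gth
    v1 <- b2 * v1 + (1 - b2) * gth^2
    mh <- m1 / (1 - b1^epoch)
    vh <- v1 / (1 - b2^epoch)
    theta <- theta - lr * mh / (sqrt(vh) + eps)
    trace <- c(trace, ev$value)
    new_smooth <- if (is.na(smooth)) ev$value else {
      0.9 * smooth + 0.1 * ev$value
    }
    improved <- !is.na(smooth) && smooth - new_smooth >= tol
    smooth <- new_smooth
    stall <- if (improved) 0L else stall + 1L
    if (stall >= patience) { converged <- TRUE; break }
  }
  est <- model_params(exp(theta[1]), exp(theta[2]), exp(theta[3]))
  final <- nll_eval(est, datasets, geom, spacing)
  structure(list(params = est,
                 coefficients = c(g = est$g, n = est$n, s = est$s),
                 loss = final$value, parts = final$parts,
                 trace = trace, converged = converged,
                 epochs = length(trace),
                 datasets = datasets, geom = geom, init = init,
                 control = list(batch_fraction = batch_fraction,
                                batch_min = batch_min, lr = lr,
                                max_epochs = max_epochs, tol = tol,
                                patience = patience, spacing = spacing,
                                seed = seed)),
            class = "needfit")
}

#' @export
print.needfit <- function(x, ...) {
  cat("Needs-landscape diffusion model fit\n")
  cat(sprintf("  g = %.6g   n = %.6g   s = %.6g\n",
              x$coefficients["g"], x$coefficients["n"],
              x$coefficients["s"]))
  cat(sprintf("  composite NLL %.5f (%s) after %d epochs\n", x$loss,
              if (x$converged) "converged" else "epoch cap reached",
              x$epochs))
  invisible(x)
}

#' @export
coef.needfit <- function(object, ...) object$coefficients

#' @export
logLik.needfit <- function(object, ...) {
  # negative composite per-trial mean NLL; comparable between fits on the
  # same datasets only
  structure(-object$loss, df = 3L, class = "logLik")
}

#' @export
summary.needfit <- function(object, ...) {
  ns <- vapply(object$datasets, function(d) if (is.null(d)) 0L else nrow(d),
               integer(1))
  out <- list(coefficients = object$coefficients, loss = object$loss,
              parts = object$parts, n = ns, converged = object$converged,
              epochs = object$epochs, init = object$init)
  class(out) <- "summary.needfit"
  out
}

#' @export
print.summary.needfit <- function(x, ...) {
  cat("Needs-landscape diffusion model fit\n\nCoefficients:\n")
  print(signif(x$coefficients, 7))
  cat(sprintf("\nComposite NLL: %.5f\n", x$loss))
  cat("Per-dataset mean NLL:\n")
  print(signif(x$parts, 5))
  cat("Dataset sizes:\n")
  print(x$n)
  cat(sprintf("\n%s after %d epochs (from g = %.3g, n = %.3g, s = %.3g)\n",
              if (x$converged) "Converged" else "Stopped at epoch cap",
              x$epochs, x$init$g, x$init$n, x$init$s))
  invisible(x)
}

#' Predicted choice and transition probabilities from a fit
#'
#' @param object a `needfit`.
#' @param newdata data frame; for `type = "transition"` columns `prev`
#'   (`"water"`/`"food"`), `dt`, `thirst`, `hunger`; for the Boltzmann types
#'   columns `thirst`, `hunger`.
#' @param type `"transition"` (probability of the next rewarded choice given
#'   the previous one and the elapsed time), `"choice"` (two-zone equilibrium
#'   probability) or `"satiation"` (three-zone, including miss).
#' @param ... unused.
#' @return Matrix of probabilities, one row per row of `newdata`.
#' @export
predict.needfit <- function(object, newdata,
                            type = c("transition", "choice", "satiation"),
                            ...) {
  type <- match.arg(type)
  p <- object$params
  g <- object$geom
  if (type == "transition") {
    rv <- rates_vec(newdata$thirst, newdata$hunger, g, p)
    om <- rv$owf + rv$ofw
    e <- exp(-om * newdata$dt)
    p_ww <- (rv$ofw / om) * (1 - e) + e
    p_ff <- (rv$owf / om) * (1 - e) + e
    w <- newdata$prev == "water"
    cbind(water = ifelse(w, p_ww, 1 - p_ff),
          food = ifelse(w, 1 - p_ww, p_ff))
  } else {
    t(vapply(seq_len(nrow(newdata)), function(i) {
      boltzmann_choice_probs(newdata$thirst[i], newdata$hunger[i], g, p,
                             include_other = (type == "satiation"),
                             spacing = object$control$spacing)
    }, numeric(if (type == "satiation") 3L else 2L)))
  }
}

#' Forward-simulate sessions from a fitted model
#'
#' @param object a `needfit`.
#' @param nsim number of sessions.
#' @param seed optional integer seed.
#' @param config base [sim_config()]; per-session initial needs are drawn
#'   from `T0_range`/`H0_range`.
#' @param T0_range,H0_range uniform ranges of the initial needs.
#' @param ... passed to [generate_trial_schedule()].
#' @return As [generate_dataset()].
#' @export
simulate.needfit <- function(object, nsim = 1, seed = NULL,
                             config = sim_config(record_stride = 100L),
                             T0_range = c(0.8, 1.2), H0_range = c(0.8, 1.2),
                             ...) {
  generate_dataset(n_sessions = nsim, geom = object$geom,
                   params = object$params, config = config,
                   T0_range = T0_range, H0_range = H0_range,
                   schedule_args = list(...), rng_seed = seed)
}

#' @export
plot.needfit <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", xlab = "epoch",
       ylab = "composite NLL (batched)",
       main = "Optimization trace", ...)
  invisible(x)
}
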