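# Closed-form / semi-analytic predictions: barrier heights along the
# inter-well axis, Kramers escape rates, the time-dependent two-state
# transition matrix, and Boltzmann equilibrium choice probabilities.
#
# Thermal identifications: friction gamma = 1, K_bT = n^2, harmonic well
# frequency nu_A = 1/sigma^2 and transition-state frequency nu_ts = 2/sigma^2
# (the transition state is approximated as twice as stiff as a well). The
# gradient scale g acts as a multiplier on the landscape itself.

# potential along the food -> water segment, lambda in [0, 1]
line_potential <- function(lambda, thirst, hunger, geom, s) {
  d <- geom$mu_water - geom$mu_food
  x <- cbind(geom$mu_food[1] + lambda * d[1], geom$mu_food[2] + lambda * d[2])
  potential(x, thirst, hunger, geom, s)
}

#' Barrier geometry between the reward wells
#'
#' Locates the two reward-well minima and the saddle of the landscape,
#' restricted to the straight segment between the food and water well
#' centres, and returns the landscape values there scaled by the gradient
#' scale `g` (which acts as an energy scale in the rate theory).
#'
#' @param thirst,hunger positive need magnitudes.
#' @param geom a [well_geometry()].
#' @param params a [model_params()].
#' @param tol location tolerance of the 1-D searches.
#' @return Named vector `c(U_saddle, U_water_min, U_food_min)` (units of
#'   g-scaled landscape depth), with attribute `lambda` holding the three
#'   locations on the segment (0 = food centre, 1 = water centre).
#' @export
barrier_heights <- function(thirst, hunger, geom = well_geometry(),
                            params = default_params("behavior"),
                            tol = 1e-8) {
  check_needs(thirst, hunger)
  geom <- as_geometry(geom)
  params <- as_params(params)
  if (thirst == 0 || hunger == 0)
    warning("a reward well has zero need: landscape is degenerate ",
            "between the reward wells")
  f <- function(l) line_potential(l, thirst, hunger, geom, params$s)
  # locate the local minima of U along the segment: the food well is the
  # first, the water well the last; the saddle is the maximum in between.
  # (A shallow well is still a *local* minimum even when the opposite
  # well-side boundary lies lower.)
  lg <- seq(0, 1, length.out = 401)
  ug <- f(lg)
  ng <- length(lg)
  loc_min <- c(ug[1] <= ug[2],
               ug[2:(ng - 1)] <= ug[1:(ng - 2)] &
                 ug[2:(ng - 1)] <= ug[3:ng],
               ug[ng] <= ug[ng - 1])
  i_f <- which(loc_min)[1]
  i_w <- which(loc_min)[sum(loc_min)]
  o_f <- stats::optimize(f, lg[c(max(1, i_f - 1), min(ng, i_f + 1))],
                         tol = tol)
  o_w <- stats::optimize(f, lg[c(max(1, i_w - 1), min(ng, i_w + 1))],
                         tol = tol)
  o_s <- if (i_f == i_w) {
    list(maximum = o_f$minimum, objective = o_f$objective) # merged wells
  } else {
    stats::optimize(f, c(o_f$minimum, o_w$minimum), maximum = TRUE,
                    tol = tol)
  }
  out <- params$g * c(U_saddle = o_s$objective, U_water_min = o_w$objective,
                      U_food_min = o_f$objective)
  attr(out, "lambda") <- c(saddle = o_s$maximum, water = o_w$minimum,
                           food = o_f$minimum)
  out
}

kramers_prefactor <- function(sigma2) {
  sqrt((1 / sigma2) * (2 / sigma2)) / (2 * pi)
}

#' Kramers transition rates between the reward wells
#'
#' Escape rates over the saddle for a diffusing state in a harmonic well,
#' `omega = sqrt(nu_A * nu_ts) / (2 pi gamma) * exp(-(U_saddle - U_source) /
#' n^2)`, with `gamma = 1`, `K_bT = n^2`, `nu_A = 1/sigma^2` and `nu_ts =
#' 2/sigma^2`. `omega_wf` is the water-to-food rate, `omega_fw` food-to-water.
#'
#' @inheritParams barrier_heights
#' @return Named vector `c(omega_wf, omega_fw)`, per second.
#' @export
kramers_rates <- function(thirst, hunger, geom = well_geometry(),
                          params = default_params("behavior")) {
  params <- as_params(params)
  geom <- as_geometry(geom)
  b <- barrier_heights(thirst, hunger, geom, params)
  if (b[["U_saddle"]] < b[["U_water_min"]] ||
      b[["U_saddle"]] < b[["U_food_min"]])
    warning("negative barrier: Kramers approximation invalid")
  pre <- kramers_prefactor(geom$sigma2)
  n2 <- params$n^2
  c(omega_wf = pre * exp(-(b[["U_saddle"]] - b[["U_water_min"]]) / n2),
    omega_fw = pre * exp(-(b[["U_saddle"]] - b[["U_food_min"]]) / n2))
}

#' Time-dependent two-state transition matrix
#'
#' Solution of the two-state master equation between the food and water zones
#' with the Kramers rates: `P_ww(t) = (1 - pi_w) exp(-(omega_wf +
#' omega_fw) t) + pi_w` with equilibrium weight `pi_w = omega_fw / (omega_wf
#' + omega_fw)`, and analogously for food; off-diagonals by complement.
#'
#' @param t elapsed time(s) since the conditioning choice, seconds.
#' @inheritParams barrier_heights
#' @param rates optional precomputed [kramers_rates()] output.
#' @return For scalar `t`, a 2 x 2 matrix with rows/cols `food`, `water`
#'   (rows sum to 1); for vector `t`, a length(t) x 4 matrix with columns
#'   `P_ff`, `P_fw`, `P_wf`, `P_ww`.
#' @export
transition_matrix <- function(t, thirst = 1, hunger = 1,
                              geom = well_geometry(),
                              params = default_params("behavior"),
                              rates = NULL) {
  if (any(t < 0)) stop("'t' must be non-negative")
  if (is.null(rates)) rates <- kramers_rates(thirst, hunger, geom, params)
  om <- rates[["omega_wf"]] + rates[["omega_fw"]]
  pi_w <- rates[["omega_fw"]] / om
  pi_f <- rates[["omega_wf"]] / om
  e <- exp(-om * t)
  p_ww <- (1 - pi_w) * e + pi_w
  p_ff <- (1 - pi_f) * e + pi_f
  if (length(t) == 1L) {
    matrix(c(p_ff, 1 - p_ff, 1 - p_ww, p_ww), 2, 2, byrow = TRUE,
           dimnames = list(from = c("food", "water"),
                           to = c("food", "water")))
  } else {
    cbind(P_ff = p_ff, P_fw = 1 - p_ff, P_wf = 1 - p_ww, P_ww = p_ww)
  }
}

# ---- Boltzmann quadrature ---------------------------------------------------

# cached grid data (well densities and zone masks) per geometry x spacing
.quad_cache <- new.env(parent = emptyenv())

quad_grid <- function(geom, spacing) {
  key <- paste(c(format(unlist(geom[c("mu_other", "mu_water", "mu_food",
                                      "sigma2")]), digits = 17), spacing),
               collapse = "|")
  got <- .quad_cache[[key]]
  if (!is.null(got)) return(got)
  # midpoint rule: cell centres, so the water/food boundary y = 0 is never
  # a grid point and the default geometry's mirror symmetry is exact
  xs <- seq(-25 + spacing / 2, 20, by = spacing)
  ys <- seq(-20 + spacing / 2, 20, by = spacing)
  gr <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  pw <- well_density(gr, geom$mu_water, geom$sigma2)
  pf <- well_density(gr, geom$mu_food, geom$sigma2)
  po <- well_density(gr, geom$mu_other, geom$sigma2)
  z <- zone(gr, geom)
  out <- list(pw = pw, pf = pf, po = po,
              mask = cbind(water = z == "water", food = z == "food",
                           other = z == "miss"),
              cell = spacing^2)
  .quad_cache[[key]] <- out
  out
}

# zone-wise integrals of exp(-g U / n^2) = m^(g/n^2) for one (T, H)
boltzmann_integrals <- function(thirst, hunger, geom, params, spacing) {
  q <- quad_grid(geom, spacing)
  m <- params$s * thirst * q$pw + params$s * hunger * q$pf + q$po
  w <- m^(params$g / params$n^2)
  as.numeric(crossprod(w, q$mask)) * q$cell
}

#' Boltzmann equilibrium choice probabilities
#'
#' Zone-wise integrals of the equilibrium weight `exp(-g U(x) / n^2)` over a
#' midpoint-rule grid covering `[-25, 20] x [-20, 20]`, normalized either
#' over the two reward zones (the reward-trial choice probability) or over
#' all three zones (the near-satiation outcome probability, including
#' misses).
#'
#' @param thirst,hunger non-negative need magnitudes.
#' @param geom a [well_geometry()].
#' @param params a [model_params()].
#' @param include_other logical; include the "other needs" zone in the
#'   normalization.
#' @param spacing grid spacing of the quadrature.
#' @param check logical; re-evaluate at half the spacing and error if any
#'   probability moves by more than `1e-4` (quadrature convergence
#'   self-check).
#' @return Named probability vector (`water`, `food`, and with
#'   `include_other` also `other`), summing to 1.
#' @export
boltzmann_choice_probs <- function(thirst, hunger, geom = well_geometry(),
                                   params = default_params("behavior"),
                                   include_other = FALSE,
                                   spacing = 0.125, check = FALSE) {
  check_needs(thirst, hunger)
  geom <- as_geometry(geom)
  params <- as_params(params)
  ints <- boltzmann_integrals(thirst, hunger, geom, params, spacing)
  names(ints) <- c("water", "food", "other")
  p <- if (include_other) ints / sum(ints) else {
    ints[c("water", "food")] / sum(ints[c("water", "food")])
  }
  if (check) {
    ints2 <- boltzmann_integrals(thirst, hunger, geom, params, spacing / 2)
    names(ints2) <- c("water", "food", "other")
    p2 <- if (include_other) ints2 / sum(ints2) else {
      ints2[c("water", "food")] / sum(ints2[c("water", "food")])
    }
    if (max(abs(p - p2)) > 1e-4)
      stop("quadrature not converged at spacing ", spacing,
           "; refine the grid")
  }
  p
}

# ---- vectorized internals shared with the fitting engine -------------------

# Landscape values (unscaled by g) and d(U)/ds at the food minimum, saddle and
# water minimum on the inter-well segment, vectorized over (thirst, hunger).
# Coarse grid bracket followed by bisection on the sign change of dm/dlambda;
# degenerate cases (a vanished well) keep the bracketing grid location, where
# the envelope argument for parameter derivatives still applies because the
# location is pinned.
barriers_vec <- function(thirst, hunger, geom, s, n_bisect = 30L) {
  d <- geom$mu_water - geom$mu_food
  s2 <- geom$sigma2
  nT <- length(thirst)
  lg <- seq(0, 1, length.out = 81)
  phi_line <- function(lambda, mu) {
    # lambda may be scalar/vector (grid) or per-case vector
    px <- geom$mu_food[1] + lambda * d[1] - mu[1]
    py <- geom$mu_food[2] + lambda * d[2] - mu[2]
    exp(-(px^2 + py^2) / (2 * s2)) / (2 * pi * s2)
  }
  # dm/dlambda at per-case lambda vectors
  m_prime <- function(l) {
    pxw <- geom$mu_food[1] + l * d[1] - geom$mu_water[1]
    pyw <- geom$mu_food[2] + l * d[2] - geom$mu_water[2]
    pxf <- l * d[1]
    pyf <- l * d[2]
    pxo <- geom$mu_food[1] + l * d[1] - geom$mu_other[1]
    pyo <- geom$mu_food[2] + l * d[2] - geom$mu_other[2]
    c0 <- 1 / (2 * pi * s2)
    fw <- (s * thirst) * c0 * exp(-(pxw^2 + pyw^2) / (2 * s2))
    ff <- (s * hunger) * c0 * exp(-(pxf^2 + pyf^2) / (2 * s2))
    fo <- c0 * exp(-(pxo^2 + pyo^2) / (2 * s2))
    aw <- -(pxw * d[1] + pyw * d[2]) / s2
    af <- -(pxf * d[1] + pyf * d[2]) / s2
    ao <- -(pxo * d[1] + pyo * d[2]) / s2
    fw * aw + ff * af + fo * ao
  }
  # grid bracket (cases x grid): the wells are the first and last local
  # maxima of the mixture along the segment; the saddle is the minimum in
  # between (coincides with a well when the wells have merged)
  ng <- length(lg)
  mw <- matrix(phi_line(lg, geom$mu_water), nT, ng, byrow = TRUE)
  mf <- matrix(phi_line(lg, geom$mu_food), nT, ng, byrow = TRUE)
  mo <- matrix(phi_line(lg, geom$mu_other), nT, ng, byrow = TRUE)
  m <- (s * thirst) * mw + (s * hunger) * mf + mo
  loc_max <- cbind(m[, 1] >= m[, 2],
                   m[, 2:(ng - 1), drop = FALSE] >=
                     m[, 1:(ng - 2), drop = FALSE] &
                     m[, 2:(ng - 1), drop = FALSE] >=
                     m[, 3:ng, drop = FALSE],
                   m[, ng] >= m[, ng - 1])
  i_f <- max.col(loc_max, ties.method = "first")
  i_w <- ng + 1L - max.col(loc_max[, ng:1, drop = FALSE],
                           ties.method = "first")
  cols <- col(m)
  m_in <- ifelse(cols >= i_f & cols <= i_w, m, Inf)
  i_s <- max.col(-m_in, ties.method = "first")
  refine <- function(idx) {
    lo0 <- lg[pmax(idx - 1L, 1L)]
    hi0 <- lg[pmin(idx + 1L, ng)]
    f_lo <- m_prime(lo0)
    f_hi <- m_prime(hi0)
    ok <- sign(f_lo) * sign(f_hi) < 0 # interior stationary point bracketed
    lo <- lo0
    hi <- hi0
    for (k in seq_len(n_bisect)) {
      mid <- 0.5 * (lo + hi)
      f_mid <- m_prime(mid)
      take_lo <- sign(f_mid) == sign(f_lo)
      lo <- ifelse(take_lo, mid, lo)
      f_lo <- ifelse(take_lo, f_mid, f_lo)
      hi <- ifelse(take_lo, hi, mid)
    }
    ifelse(ok, 0.5 * (lo + hi), lg[idx])
  }
  l_f <- refine(i_f)
  l_w <- refine(i_w)
  l_s <- refine(i_s)
  val <- function(l) {
    mm <- (s * thirst) * phi_line(l, geom$mu_water) +
          (s * hunger) * phi_line(l, geom$mu_food) +
          phi_line(l, geom$mu_other)
    dms <- thirst * phi_line(l, geom$mu_water) +
           hunger * phi_line(l, geom$mu_food)
    list(U = -log(mm), dUds = -dms / mm)
  }
  vf <- val(l_f); vw <- val(l_w); vs <- val(l_s)
  list(U_f = vf$U, U_w = vw$U, U_s = vs$U,
       dUds_f = vf$dUds, dUds_w = vw$dUds, dUds_s = vs$dUds,
       lambda = cbind(food = l_f, saddle = l_s, water = l_w))
}

# Kramers rates and their partials wrt (g, n, s), vectorized over (T, H)
rates_vec <- function(thirst, hunger, geom, params) {
  b <- barriers_vec(thirst, hunger, geom, params$s)
  pre <- kramers_prefactor(geom$sigma2)
  n2 <- params$n^2
  bw <- params$g * (b$U_s - b$U_w) # water -> food barrier
  bf <- params$g * (b$U_s - b$U_f)
  owf <- pre * exp(-bw / n2)
  ofw <- pre * exp(-bf / n2)
  list(
    owf = owf, ofw = ofw,
    d_owf = cbind(g = -owf * (b$U_s - b$U_w) / n2,
                  n = owf * 2 * bw / params$n^3,
                  s = -owf * params$g * (b$dUds_s - b$dUds_w) / n2),
    d_ofw = cbind(g = -ofw * (b$U_s - b$U_f) / n2,
                  n = ofw * 2 * bf / params$n^3,
                  s = -ofw * params$g * (b$dUds_s - b$dUds_f) / n2))
}
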