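#' Isotropic bivariate Gaussian well density
#'
#' Density of an isotropic bivariate normal, the shape of each landscape well.
#'
#' @param x numeric 2-vector or n x 2 matrix of positions.
#' @param centre numeric 2-vector, well centre.
#' @param sigma2 positive scalar variance.
#' @return Positive scalar (or vector of length n).
#' @export
well_density <- function(x, centre, sigma2) {
  x <- as_xy(x)
  if (!is.numeric(centre) || length(centre) != 2L || !all(is.finite(centre)))
    stop("'centre' must be a finite 2-vector")
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0 ||
      !is.finite(sigma2))
    stop("'sigma2' must be a positive scalar")
  d2 <- (x[, 1] - centre[1])^2 + (x[, 2] - centre[2])^2
  exp(-d2 / (2 * sigma2)) / (2 * pi * sigma2)
}

# coerce positions to an n x 2 matrix, rejecting non-finite coordinates
as_xy <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 2L) stop("positions must be 2-vectors or an n x 2 matrix")
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("positions must have two columns")
  if (!all(is.finite(x))) stop("non-finite position coordinates")
  x
}

# the (positive) Gaussian mixture under the landscape, n-vector
mixture_density <- function(x, thirst, hunger, geom, s) {
  geom <- as_geometry(geom)
  s * thirst * well_density(x, geom$mu_water, geom$sigma2) +
    s * hunger * well_density(x, geom$mu_food, geom$sigma2) +
    well_density(x, geom$mu_other, geom$sigma2)
}

#' Energy landscape of needs
#'
#' The potential is the negative log of a Gaussian mixture whose water and
#' food components are weighted by the current thirst and hunger magnitudes
#' (times the foraging weight `s`); the "other needs" component has constant
#' weight 1. Wells are local minima; raising a need deepens its well.
#'
#' @param x position, 2-vector or n x 2 matrix.
#' @param thirst,hunger non-negative scalars, current need magnitudes.
#' @param geom a [well_geometry()].
#' @param s positive scalar foraging weight.
#' @return Scalar (or n-vector) potential value.
#' @export
potential <- function(x, thirst, hunger, geom, s) {
  check_needs(thirst, hunger)
  if (!is.numeric(s) || length(s) != 1L || s <= 0)
    stop("'s' must be a positive scalar")
  -log(mixture_density(x, thirst, hunger, geom, s))
}

#' Analytic spatial gradient of the potential
#'
#' Closed-form gradient of [potential()] with respect to position: with
#' mixture m(x), grad U = -grad m / m and each Gaussian component contributes
#' phi_i(x) (mu_i - x) / sigma^2 to grad m.
#'
#' @inheritParams potential
#' @return 2-vector (or n x 2 matrix) of partial derivatives.
#' @export
potential_gradient <- function(x, thirst, hunger, geom, s) {
  check_needs(thirst, hunger)
  geom <- as_geometry(geom)
  x <- as_xy(x)
  pw <- well_density(x, geom$mu_water, geom$sigma2)
  pf <- well_density(x, geom$mu_food, geom$sigma2)
  po <- well_density(x, geom$mu_other, geom$sigma2)
  m <- s * thirst * pw + s * hunger * pf + po
  gx <- (s * thirst * pw * (geom$mu_water[1] - x[, 1]) +
         s * hunger * pf * (geom$mu_food[1] - x[, 1]) +
         po * (geom$mu_other[1] - x[, 1])) / geom$sigma2
  gy <- (s * thirst * pw * (geom$mu_water[2] - x[, 2]) +
         s * hunger * pf * (geom$mu_food[2] - x[, 2]) +
         po * (geom$mu_other[2] - x[, 2])) / geom$sigma2
  out <- cbind(-gx / m, -gy / m)
  if (nrow(out) == 1L) drop(out) else out
}

#' Behavioural zone of a position
#'
#' Maximum-likelihood partition of the subspace by the *unscaled* well
#' densities: a cue arriving while the state sits in a zone emits that zone's
#' choice. Ties between the "other" well and either reward well resolve to
#' miss; ties between water and food resolve to water. Because all wells share
#' one variance, this equals a nearest-centre rule.
#'
#' @param x position, 2-vector or n x 2 matrix.
#' @param geom a [well_geometry()].
#' @return Character scalar/vector in `c("water", "food", "miss")`.
#' @export
zone <- function(x, geom) {
  geom <- as_geometry(geom)
  x <- as_xy(x)
  po <- well_density(x, geom$mu_other, geom$sigma2)
  pw <- well_density(x, geom$mu_water, geom$sigma2)
  pf <- well_density(x, geom$mu_food, geom$sigma2)
  out <- ifelse(po >= pw & po >= pf, "miss",
         ifelse(pw >= pf, "water", "food"))
  if (length(out) == 1L) out[[1]] else out
}

#' Projection onto the goal dimension
#'
#' Projects positions onto the unit vector from the food well centre to the
#' water well centre (the "goal dimension"); with the default geometry this is
#' simply the second coordinate.
#'
#' @param x position 2-vector, or an n x 2 trajectory matrix.
#' @param geom a [well_geometry()].
#' @return Scalar or numeric vector of projections.
#' @export
goal_projection <- function(x, geom) {
  geom <- as_geometry(geom)
  u <- geom$mu_water - geom$mu_food
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("water and food centres coincide")
  u <- u / nu
  x <- as_xy(x)
  drop(x %*% u)
}
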