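#' Well geometry of the needs landscape
#'
#' The landscape lives on a 2-D subspace with three isotropic Gaussian wells:
#' "other needs", water (thirst) and food (hunger). The default centres form an
#' equilateral triangle and all wells share the same variance, so the
#' maximum-density zone partition reduces to a nearest-centre rule.
#'
#' @param mu_other,mu_water,mu_food numeric 2-vectors, well centres.
#' @param sigma2 positive scalar, shared isotropic variance of every well.
#' @return An object of class `well_geometry`.
#' @examples
#' geom <- well_geometry()
#' dist(rbind(geom$mu_other, geom$mu_water, geom$mu_food)) # equilateral
#' @export
well_geometry <- function(mu_other = c(-8, 0),
                          mu_water = c(5, 7.5),
                          mu_food = c(5, -7.5),
                          sigma2 = 20) {
  for (m in list(mu_other, mu_water, mu_food)) {
    if (!is.numeric(m) || length(m) != 2L || !all(is.finite(m)))
      stop("well centres must be finite numeric 2-vectors")
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1L || !is.finite(sigma2) ||
      sigma2 <= 0)
    stop("'sigma2' must be a positive scalar")
  cen <- rbind(mu_other, mu_water, mu_food)
  if (any(dist(cen) < sqrt(.Machine$double.eps)))
    stop("well centres must be pairwise distinct")
  structure(list(mu_other = as.numeric(mu_other),
                 mu_water = as.numeric(mu_water),
                 mu_food = as.numeric(mu_food),
                 sigma2 = as.numeric(sigma2)),
            class = "well_geometry")
}

#' Scale parameters of the diffusion model
#'
#' @param g positive scalar; gradient (landscape) scale.
#' @param n positive scalar; noise scale. Larger `n` drives more frequent
#'   switches, larger `g` fewer.
#' @param s positive scalar; foraging weight scaling thirst and hunger
#'   relative to the fixed "other needs" well.
#' @return An object of class `model_params`.
#' @seealso [default_params()] for the named presets.
#' @export
model_params <- function(g, n, s) {
  v <- c(g = g, n = n, s = s)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("'g', 'n' and 's' must all be strictly positive and finite")
  structure(list(g = as.numeric(g), n = as.numeric(n), s = as.numeric(s)),
            class = "model_params")
}

#' Named parameter presets
#'
#' `"behavior"` is the published maximum-likelihood fit of the model to the
#' full behavioural dataset of the head-fixed two-reward assay;
#' `"neuropixels"` the fit restricted to the electrophysiology cohort.
#' `"decoherent"` and `"persistent"` are the deliberately unbalanced
#' noise-to-gradient regimes used to illustrate too frequent and too rare
#' switching, respectively.
#'
#' @param set preset name.
#' @return A [model_params()] object.
#' @export
default_params <- function(set = c("behavior", "neuropixels",
                                   "decoherent", "persistent")) {
  set <- match.arg(set)
  switch(set,
    behavior    = model_params(g = 2.4383774, n = 2.74393,  s = 6.4874935),
    neuropixels = model_params(g = 2.5563507, n = 2.807799, s = 6.4874935),
    decoherent  = model_params(g = 2.0,       n = 8.0,      s = 6.4874935),
    persistent  = model_params(g = 8.0,       n = 0.5,      s = 6.4874935))
}

#' @export
print.well_geometry <- function(x, ...) {
  cat("Needs-landscape well geometry (shared isotropic variance)\n")
  cat(sprintf("  other: (%g, %g)\n", x$mu_other[1], x$mu_other[2]))
  cat(sprintf("  water: (%g, %g)\n", x$mu_water[1], x$mu_water[2]))
  cat(sprintf("  food : (%g, %g)\n", x$mu_food[1], x$mu_food[2]))
  cat(sprintf("  sigma^2 = %g\n", x$sigma2))
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Model scales: g = %.7g, n = %.6g, s = %.7g\n", x$g, x$n, x$s))
  invisible(x)
}

as_geometry <- function(geom) {
  if (!inherits(geom, "well_geometry")) stop("'geom' must be a well_geometry")
  geom
}

as_params <- function(params) {
  if (inherits(params, "model_params")) return(params)
  if (is.numeric(params) && length(params) == 3L &&
      !is.null(names(params)) && all(c("g", "n", "s") %in% names(params)))
    return(model_params(params[["g"]], params[["n"]], params[["s"]]))
  stop("'params' must be a model_params object or named c(g=, n=, s=)")
}

check_needs <- function(thirst, hunger) {
  if (!is.numeric(thirst) || !is.numeric(hunger) ||
      any(!is.finite(thirst)) || any(!is.finite(hunger)))
    stop("'thirst' and 'hunger' must be finite numerics")
  if (any(thirst < 0) || any(hunger < 0))
    stop("needs must be non-negative")
  invisible(NULL)
}
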