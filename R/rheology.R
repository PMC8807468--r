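# Shear-thinning blood rheology: Quemada viscosity and shear-rate magnitude.

#' Quemada viscosity parameters
#'
#' Parameter set for the Quemada shear-thinning viscosity model
#' \deqn{\mu(\dot\gamma) = \mu_p \left(1 - \tfrac12 k(\dot\gamma) H\right)^{-2},
#'   \quad k(\dot\gamma) = \frac{k_0 + k_\infty\sqrt{\dot\gamma/\dot\gamma_c}}
#'                              {1 + \sqrt{\dot\gamma/\dot\gamma_c}}}
#' with plasma viscosity \eqn{\mu_p} (Pa s), hematocrit \eqn{H} and intrinsic
#' viscosity limits \eqn{k_0} (zero shear) and \eqn{k_\infty} (infinite shear).
#'
#' The default constants come from the Cokelet-fit parameterization of whole
#' blood evaluated at 45\% hematocrit:
#' \eqn{k_0 = \exp(3.874 - 10.41H + 13.8H^2 - 6.738H^3)},
#' \eqn{k_\infty = \exp(1.3435 - 2.803H + 2.711H^2 - 0.6479H^3)},
#' \eqn{\dot\gamma_c = \exp(-6.1508 + 27.923H - 25.6H^2 + 3.697H^3)} s^-1,
#' with plasma viscosity 1.32 mPa s. They give a high-shear asymptote of about
#' 3.6 mPa s and a zero-shear viscosity of about 0.10 Pa s at H = 0.45.
#'
#' @param plasma_viscosity plasma viscosity in Pa s.
#' @param hematocrit red-cell volume fraction in (0, 1).
#' @param k0 zero-shear intrinsic viscosity (dimensionless).
#' @param k_inf infinite-shear intrinsic viscosity (dimensionless).
#' @param gamma_c characteristic shear rate in 1/s.
#' @return An object of class `quemada_params`.
#' @export
#' @examples
#' qp <- quemada_params()
#' quemada_viscosity(c(0, 100, 1e5), qp)
quemada_params <- function(plasma_viscosity = 1.32e-3,
                           hematocrit = 0.45,
                           k0 = NULL, k_inf = NULL, gamma_c = NULL) {
  H <- hematocrit
  stopifnot(is.numeric(H), length(H) == 1L, H > 0, H < 1,
            plasma_viscosity > 0)
  if (is.null(k0))     k0     <- exp(3.874 - 10.41 * H + 13.8 * H^2 - 6.738 * H^3)
  if (is.null(k_inf))  k_inf  <- exp(1.3435 - 2.803 * H + 2.711 * H^2 - 0.6479 * H^3)
  if (is.null(gamma_c)) gamma_c <- exp(-6.1508 + 27.923 * H - 25.6 * H^2 + 3.697 * H^3)
  stopifnot(gamma_c > 0, k0 > 0, k_inf > 0)
  # finite, positive viscosity for all shear rates requires 1 - k H / 2 > 0;
  # k is monotone between k0 and k_inf so checking both ends suffices
  if (k0 * H >= 2 || k_inf * H >= 2)
    stop("invalid Quemada parameters: k*H must be < 2 for finite viscosity ",
         "(k0*H = ", signif(k0 * H, 4), ", k_inf*H = ", signif(k_inf * H, 4), ")")
  structure(list(plasma_viscosity = plasma_viscosity, hematocrit = H,
                 k0 = k0, k_inf = k_inf, gamma_c = gamma_c),
            class = "quemada_params")
}

#' @exportS3Method base::print
print.quemada_params <- function(x, ...) {
  cat("Quemada viscosity parameters\n")
  cat(sprintf("  plasma viscosity : %.4g Pa s\n", x$plasma_viscosity))
  cat(sprintf("  hematocrit       : %.3f\n", x$hematocrit))
  cat(sprintf("  k0 / k_inf       : %.4g / %.4g\n", x$k0, x$k_inf))
  cat(sprintf("  gamma_c          : %.4g 1/s\n", x$gamma_c))
  cat(sprintf("  zero / inf shear : %.4g / %.4g Pa s\n",
              quemada_viscosity(0, x), quemada_limits(x)["mu_inf"]))
  invisible(x)
}

#' Fluid properties
#'
#' Density plus rheology: either a [quemada_params()] object or a constant
#' dynamic viscosity override (Pa s).
#'
#' @param density fluid density in kg/m^3 (whole blood: 1060).
#' @param rheology a `quemada_params` object, or a single number interpreted
#'   as a constant dynamic viscosity in Pa s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, rheology = quemada_params()) {
  stopifnot(is.numeric(density), length(density) == 1L, density > 0)
  if (is.numeric(rheology)) {
    stopifnot(length(rheology) == 1L, rheology > 0)
  } else if (!inherits(rheology, "quemada_params")) {
    stop("rheology must be quemada_params() or a constant viscosity in Pa s")
  }
  structure(list(density = density, rheology = rheology),
            class = "fluid_properties")
}

#' Scalar shear-rate magnitude from a velocity-gradient tensor
#'
#' Computes \eqn{\dot\gamma = \sqrt{2\,D\!:\!D}} where
#' \eqn{D = \tfrac12(\nabla u + \nabla u^T)} is the strain-rate tensor. For
#' simple shear du/dy = s this equals |s|; rigid-body rotation gives 0.
#'
#' @param grad a 2x2 velocity-gradient matrix (entry `[i, j]` = du_i/dx_j,
#'   in 1/s), or a list of such matrices.
#' @return Shear-rate magnitude(s) in 1/s.
#' @export
shear_rate_magnitude <- function(grad) {
  if (is.list(grad)) return(vapply(grad, shear_rate_magnitude, numeric(1)))
  stopifnot(is.matrix(grad), all(dim(grad) == c(2L, 2L)))
  if (!all(is.finite(grad))) stop("non-finite velocity gradient")
  D <- (grad + t(grad)) / 2
  sqrt(2 * sum(D * D))
}

#' Quemada viscosity at a given shear rate
#'
#' @param gamma_dot shear rate(s) in 1/s, non-negative.
#' @param params a [quemada_params()] object.
#' @param gamma_min regularization floor (1/s) applied inside the
#'   \eqn{\sqrt{\dot\gamma/\dot\gamma_c}} evaluation; keeps derivatives
#'   bounded near zero shear without measurably changing the viscosity.
#' @return Dynamic viscosity in Pa s, same shape as `gamma_dot`.
#' @export
quemada_viscosity <- function(gamma_dot, params = quemada_params(),
                              gamma_min = 1e-6) {
  stopifnot(inherits(params, "quemada_params"))
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop("gamma_dot must be finite and non-negative")
  g <- pmax(gamma_dot, gamma_min)
  s <- sqrt(g / params$gamma_c)
  k <- (params$k0 + params$k_inf * s) / (1 + s)
  mu <- params$plasma_viscosity * (1 - 0.5 * k * params$hematocrit)^-2
  # exact zero-shear value for literally zero input (floor only guards sqrt)
  mu[gamma_dot == 0] <-
    params$plasma_viscosity * (1 - 0.5 * params$k0 * params$hematocrit)^-2
  mu
}

#' Analytic zero- and infinite-shear viscosity limits
#'
#' @param params a [quemada_params()] object.
#' @return Named vector `c(mu_0 = , mu_inf = )` in Pa s.
#' @export
quemada_limits <- function(params = quemada_params()) {
  c(mu_0   = params$plasma_viscosity * (1 - 0.5 * params$k0 * params$hematocrit)^-2,
    mu_inf = params$plasma_viscosity * (1 - 0.5 * params$k_inf * params$hematocrit)^-2)
}

#' Pointwise viscosity field from a shear-rate field
#'
#' Applies the configured rheology elementwise to a shear-rate field. With a
#' constant-viscosity override the output is identically that constant.
#'
#' @param gamma_dot_field numeric vector/matrix of shear rates (1/s).
#' @param fluid a [fluid_properties()] object.
#' @return Viscosity field (Pa s) of the same shape.
#' @export
viscosity_field <- function(gamma_dot_field, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (is.numeric(fluid$rheology)) {
    out <- gamma_dot_field
    out[] <- fluid$rheology
    return(out)
  }
  out <- gamma_dot_field
  out[] <- quemada_viscosity(as.numeric(gamma_dot_field), fluid$rheology)
  out
}
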