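# Four-species shear-driven thrombosis model: kinetics, switching functions,
# wall-flux gating and thrombus bookkeeping.
#
# Species:
#   RP  resting platelets    (relative concentration, advected + diffusing)
#   AP  activated platelets  (relative concentration, advected + diffusing)
#   C   coagulant            (nmol/L, diffusion only -- never advected)
#   BP  bound platelets      (nmol/L, immobile -- local ODE, the thrombus)

#' Thrombosis model parameters
#'
#' Kinetic constants, diffusivities and switching thresholds of the
#' four-species shear-driven thrombosis model. Source terms:
#' \deqn{S_{RP} = k_{RP}[AP][RP], \quad S_{AP} = k_{AP}[AP][RP]}
#' \deqn{S_C = k_{C1}\,\phi_C(BP)\,[AP] + k_{C2}\,\phi_C(C)\,[AP](1-\phi_{\dot\gamma})}
#' \deqn{S_{BP} = k_{BP}\,\phi_{BP}(AP, C)\,\phi_{\dot\gamma}\,[AP]}
#' where \eqn{\phi(x) = x^2/(x^2 + x_t^2)} gates each reaction by its species
#' threshold and \eqn{\phi_{\dot\gamma} = \dot\gamma_t^2/(\dot\gamma^2 +
#' \dot\gamma_t^2)} confines thrombus deposition to low-shear regions.
#'
#' RP and AP are relative (dimensionless) concentrations; C and BP are in
#' nmol/L. The kinetics are deliberately accelerated relative to physiological
#' coagulation so that clot growth completes within tens of cardiac cycles.
#'
#' @param D_RP,D_AP,D_C_base species diffusivities, m^2/s. The effective
#'   coagulant diffusivity is `D_C_base` times the local shear switch
#'   \eqn{\phi_{\dot\gamma}}.
#' @param k_RP resting-platelet consumption constant, 1/s (negative).
#' @param k_AP activated-platelet production constant, 1/s.
#' @param k_C1,k_C2 coagulant production/consumption constants, nmol/(L s)
#'   (`k_C2` negative).
#' @param k_BP bound-platelet deposition constant, nmol/(L s).
#' @param k_c_wall inward coagulant wall-flux magnitude, nmol/(L m s).
#' @param gamma_t shear-rate threshold, 1/s.
#' @param AP_t activated-platelet threshold (relative units).
#' @param C_t coagulant threshold, nmol/L.
#' @param BP_t bound-platelet threshold, nmol/L; also gates the momentum sink.
#' @param TAWSS_threshold wall-shear gate for the coagulant flux, Pa.
#' @param wall_relative_concentration Dirichlet wall value for RP and AP
#'   (relative units).
#' @param literal_shear_switch if `TRUE`, use the literal mixed-unit form
#'   \eqn{\dot\gamma_t^2/(\dot\gamma + \dot\gamma_t^2)} of the shear switch
#'   instead of the dimensionally consistent default (sensitivity option).
#' @return An object of class `thrombosis_params`.
#' @export
thrombosis_params <- function(D_RP = 1.6e-13,
                              D_AP = 1.6e-11,
                              D_C_base = 1.0e-8,
                              k_RP = -0.15,
                              k_AP = 3.0,
                              k_C1 = 16.0,
                              k_C2 = -6.0,
                              k_BP = 12.0,
                              k_c_wall = 16.0,
                              gamma_t = 50.0,
                              AP_t = 15.0,
                              C_t = 10.0,
                              BP_t = 20.0,
                              TAWSS_threshold = 0.15,
                              wall_relative_concentration = 2,
                              literal_shear_switch = FALSE) {
  stopifnot(D_RP >= 0, D_AP >= 0, D_C_base >= 0,
            gamma_t > 0, AP_t > 0, C_t > 0, BP_t > 0, TAWSS_threshold > 0)
  if (k_RP >= 0) stop("k_RP must be negative (resting platelets are consumed)")
  if (k_C2 >= 0) stop("k_C2 must be negative (coagulant consumption term)")
  if (k_AP <= 0 || k_C1 <= 0 || k_BP <= 0 || k_c_wall < 0)
    stop("k_AP, k_C1, k_BP must be positive and k_c_wall non-negative")
  structure(list(D_RP = D_RP, D_AP = D_AP, D_C_base = D_C_base,
                 k_RP = k_RP, k_AP = k_AP, k_C1 = k_C1, k_C2 = k_C2,
                 k_BP = k_BP, k_c_wall = k_c_wall,
                 gamma_t = gamma_t, AP_t = AP_t, C_t = C_t, BP_t = BP_t,
                 TAWSS_threshold = TAWSS_threshold,
                 wall_relative_concentration = wall_relative_concentration,
                 literal_shear_switch = isTRUE(literal_shear_switch)),
            class = "thrombosis_params")
}

#' @exportS3Method base::print
print.thrombosis_params <- function(x, ...) {
  cat("Thrombosis model parameters (four-species shear-driven model)\n")
  cat(sprintf("  kinetics : k_RP %.3g 1/s, k_AP %.3g 1/s, k_C1 %.3g, k_C2 %.3g, k_BP %.3g nmol/(L s)\n",
              x$k_RP, x$k_AP, x$k_C1, x$k_C2, x$k_BP))
  cat(sprintf("  thresholds: gamma_t %.3g 1/s, AP_t %.3g, C_t %.3g nmol/L, BP_t %.3g nmol/L\n",
              x$gamma_t, x$AP_t, x$C_t, x$BP_t))
  cat(sprintf("  wall flux : %.3g nmol/(L m s) where TAWSS < %.3g Pa and BP < BP_t\n",
              x$k_c_wall, x$TAWSS_threshold))
  invisible(x)
}

#' Sigmoidal switching function
#'
#' \eqn{\phi(x) = x^2/(x^2 + x_t^2)}: 0 at x = 0, one half at the threshold,
#' saturating to 1. Multi-species switching coefficients are products of
#' these factors (see [switching_bp()]).
#'
#' @param x species concentration(s), non-negative.
#' @param x_t threshold (same units as `x`), positive.
#' @return Values in \[0, 1\].
#' @export
switching <- function(x, x_t) {
  stopifnot(x_t > 0)
  if (any(x < 0, na.rm = TRUE)) stop("switching argument must be non-negative")
  x^2 / (x^2 + x_t^2)
}

#' Bound-platelet switching coefficient (product form)
#'
#' \eqn{\phi_{BP}(AP, C) = \phi(AP; AP_t)\,\phi(C; C_t)}.
#'
#' @param AP activated-platelet relative concentration(s).
#' @param C coagulant concentration(s), nmol/L.
#' @param params a [thrombosis_params()] object.
#' @return Values in \[0, 1\].
#' @export
switching_bp <- function(AP, C, params = thrombosis_params()) {
  switching(AP, params$AP_t) * switching(C, params$C_t)
}

#' Shear-rate switching coefficient
#'
#' Dimensionally consistent form \eqn{\phi_{\dot\gamma} =
#' \dot\gamma_t^2/(\dot\gamma^2 + \dot\gamma_t^2)}: equals 1 in stasis, one
#' half at the shear threshold and decays to 0 at high shear, confining
#' thrombus growth to low-shear regions. Setting `literal_shear_switch` in
#' the parameters restores the mixed-unit variant
#' \eqn{\dot\gamma_t^2/(\dot\gamma + \dot\gamma_t^2)} for sensitivity checks.
#'
#' @param gamma_dot shear rate(s), 1/s, non-negative.
#' @param params a [thrombosis_params()] object.
#' @return Values in (0, 1].
#' @export
shear_switch <- function(gamma_dot, params = thrombosis_params()) {
  if (any(gamma_dot < 0, na.rm = TRUE)) stop("gamma_dot must be non-negative")
  gt2 <- params$gamma_t^2
  if (params$literal_shear_switch) gt2 / (gamma_dot + gt2)
  else gt2 / (gamma_dot^2 + gt2)
}

#' Reaction source terms for the four species
#'
#' Evaluates the pointwise reaction terms (see [thrombosis_params()] for the
#' forms). All four terms are proportional to AP, so a quiescent region with
#' no activated platelets generates nothing; \eqn{S_{BP} \ge 0} always (the
#' model has no thrombus lysis).
#'
#' @param RP,AP relative concentrations (vectors allowed).
#' @param C,BP concentrations in nmol/L.
#' @param phi_gamma local shear switching coefficient(s) in \[0, 1\], from
#'   [shear_switch()].
#' @param params a [thrombosis_params()] object.
#' @return List with elements `S_RP`, `S_AP` (relative units/s) and `S_C`,
#'   `S_BP` (nmol/(L s)).
#' @export
source_terms <- function(RP, AP, C, BP, phi_gamma,
                         params = thrombosis_params()) {
  if (any(c(RP, AP, C, BP) < 0, na.rm = TRUE))
    stop("species concentrations must be non-negative")
  list(
    S_RP = params$k_RP * AP * RP,
    S_AP = params$k_AP * AP * RP,
    S_C  = params$k_C1 * switching(BP, params$BP_t) * AP +
           params$k_C2 * switching(C, params$C_t) * AP * (1 - phi_gamma),
    S_BP = params$k_BP * switching_bp(AP, C, params) * phi_gamma * AP
  )
}

#' Coagulant wall-flux gate
#'
#' The coagulant receives an inward wall flux of magnitude `k_c_wall` on
#' facets where the previous cycle's time-averaged wall shear stress is below
#' the TAWSS threshold AND the adjacent bound-platelet concentration is still
#' below `BP_t`; zero elsewhere. RP and AP take a fixed relative wall value
#' and BP a zero-flux condition (handled by the transport stepper).
#'
#' @param tawss previous-cycle TAWSS per facet, Pa (`Inf` disables the flux,
#'   which is the first-cycle policy).
#' @param BP adjacent-cell bound-platelet concentration per facet, nmol/L.
#' @param params a [thrombosis_params()] object.
#' @return Flux magnitude per facet, nmol/(L m s).
#' @export
coagulant_wall_flux <- function(tawss, BP, params = thrombosis_params()) {
  if (any(tawss < 0, na.rm = TRUE)) stop("TAWSS must be non-negative")
  ifelse(tawss < params$TAWSS_threshold & BP < params$BP_t,
         params$k_c_wall, 0)
}

#' Thrombus indicator and volume
#'
#' Cells with \eqn{BP \ge BP_t} count as thrombosed; the reported "volume" is
#' the thrombosed area times a unit (1 m) depth, in cm^3. BP_t is the single
#' BP threshold of the model (it also sets the half-strength point of the
#' momentum sink), so it doubles as the thrombus cut.
#'
#' @param BP bound-platelet field, nmol/L (vector or matrix over cells).
#' @param cell_area per-cell area in m^2 (scalar or same shape as `BP`).
#' @param BP_t threshold, nmol/L.
#' @param region optional logical mask restricting the tally (e.g. the FL).
#' @return List: `indicator` (0/1 field), `volume_cm3`.
#' @export
thrombus_mask <- function(BP, cell_area, BP_t = 20, region = NULL) {
  if (any(BP < 0, na.rm = TRUE)) stop("BP must be non-negative")
  ind <- (BP >= BP_t) * 1
  sel <- if (is.null(region)) ind else ind * (region * 1)
  volume_m3 <- sum(sel * cell_area) * 1.0   # unit depth of 1 m
  list(indicator = ind, volume_cm3 = volume_m3 * 1e6)
}

# --- cycle ledger -----------------------------------------------------------

#' Create a cycle ledger
#'
#' Accumulates running time integrals of wall shear stress magnitude (per
#' boundary facet) and of shear rate, activated platelets and viscosity (per
#' cell) during a cardiac cycle, and publishes their cycle averages at each
#' cycle boundary. The published TAWSS of cycle n is the only TAWSS consulted
#' by the coagulant wall flux during cycle n+1; before the first completed
#' cycle the published TAWSS is +Inf, which disables the wall flux (the
#' first-cycle policy standing in for the flow-only pre-cycles).
#'
#' @param n_facets number of wall facets tracked.
#' @param n_cells number of mesh cells tracked.
#' @param period cycle period, s.
#' @return An object of class `cycle_ledger`.
#' @export
cycle_ledger <- function(n_facets, n_cells, period) {
  stopifnot(n_facets >= 1, n_cells >= 1, period > 0)
  structure(list(
    period = period, cycle = 0L, t_accum = 0,
    acc_wss = numeric(n_facets),
    acc_gamma = numeric(n_cells), acc_AP = numeric(n_cells),
    acc_mu = numeric(n_cells),
    tawss = rep(Inf, n_facets),         # published (previous completed cycle)
    avg_gamma = rep(NA_real_, n_cells),
    avg_AP = rep(NA_real_, n_cells),
    avg_mu = rep(NA_real_, n_cells),
    volume_trace = data.frame(time = numeric(0), volume_cm3 = numeric(0),
                              fl_fraction = numeric(0))
  ), class = "cycle_ledger")
}

#' Accumulate instantaneous fields into the cycle ledger
#'
#' @param ledger a [cycle_ledger()] object.
#' @param wss instantaneous wall shear stress magnitude per facet, Pa.
#' @param gamma_dot instantaneous shear-rate field per cell, 1/s.
#' @param AP instantaneous activated-platelet field per cell.
#' @param dt time increment, s.
#' @param mu optional instantaneous viscosity field per cell, Pa s.
#' @param cycle_boundary if `TRUE`, close the cycle after accumulating:
#'   divide by the period, publish the cycle averages (swapping the TAWSS
#'   buffer used by the wall flux) and reset the accumulators.
#' @return The updated ledger.
#' @export
update_ledger <- function(ledger, wss, gamma_dot, AP, dt,
                          mu = NULL, cycle_boundary = FALSE) {
  stopifnot(inherits(ledger, "cycle_ledger"), dt > 0)
  ledger$acc_wss   <- ledger$acc_wss   + abs(wss) * dt
  ledger$acc_gamma <- ledger$acc_gamma + gamma_dot * dt
  ledger$acc_AP    <- ledger$acc_AP    + AP * dt
  if (!is.null(mu)) ledger$acc_mu <- ledger$acc_mu + mu * dt
  ledger$t_accum <- ledger$t_accum + dt
  if (cycle_boundary) {
    Tc <- ledger$t_accum   # actual accumulated span (== period up to roundoff)
    ledger$tawss     <- ledger$acc_wss / Tc
    ledger$avg_gamma <- ledger$acc_gamma / Tc
    ledger$avg_AP    <- ledger$acc_AP / Tc
    ledger$avg_mu    <- ledger$acc_mu / Tc
    ledger$acc_wss[] <- 0; ledger$acc_gamma[] <- 0
    ledger$acc_AP[] <- 0; ledger$acc_mu[] <- 0
    ledger$t_accum <- 0
    ledger$cycle <- ledger$cycle + 1L
  }
  ledger
}

#' Previous-cycle TAWSS published by the ledger
#'
#' Before any completed cycle this is +Inf on every facet, i.e. the coagulant
#' wall flux is off.
#'
#' @param ledger a [cycle_ledger()] object.
#' @return TAWSS per facet, Pa.
#' @export
ledger_tawss <- function(ledger) {
  stopifnot(inherits(ledger, "cycle_ledger"))
  ledger$tawss
}
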