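# Pulsatile incompressible flow: inlet waveform, three-element Windkessel
# outlet, thrombus momentum sink, and the R-side wrapper around the compiled
# projection solver.

#' Pulsatile inlet waveform
#'
#' A periodic aortic-like flow waveform represented by a truncated Fourier
#' series: one systolic forward peak followed by a short reverse-flow phase
#' in early diastole, then near-zero diastolic flow. The underlying shape is
#' a systolic half-sine-squared bump (duration `systole_fraction` of the
#' cycle) and a reverse bump (duration `reverse_fraction`), scaled so the
#' cycle mean equals `mean_velocity`; its Fourier coefficients (stored) are
#' what the solver evaluates, so the waveform is smooth and exactly periodic.
#'
#' @param frequency cardiac frequency, Hz.
#' @param mean_velocity cycle-mean inlet velocity, m/s.
#' @param systole_fraction fraction of the cycle occupied by forward systolic
#'   flow.
#' @param reverse_fraction fraction occupied by the reverse-flow phase.
#' @param reverse_strength reverse-phase flow volume as a fraction of the
#'   forward volume.
#' @param n_harmonics number of Fourier harmonics retained.
#' @return An object of class `inlet_waveform` with the complex Fourier
#'   coefficients in `$coef` (coef\[1\] is the mean).
#' @export
inlet_waveform <- function(frequency = 1.02, mean_velocity = 0.10,
                           systole_fraction = 0.33, reverse_fraction = 0.15,
                           reverse_strength = 0.15, n_harmonics = 12) {
  stopifnot(frequency > 0, systole_fraction > 0, reverse_fraction >= 0,
            systole_fraction + reverse_fraction < 1,
            reverse_strength >= 0, reverse_strength < 1, n_harmonics >= 2)
  ts <- systole_fraction; tr <- reverse_fraction
  # forward amplitude A and reverse amplitude B such that the shape has
  # unit mean: A*ts/2 - B*tr/2 = 1 with B*tr/2 = reverse_strength * A*ts/2
  A <- 2 / (ts * (1 - reverse_strength))
  B <- if (tr > 0) reverse_strength * A * ts / tr else 0
  shape <- function(tau) {
    out <- numeric(length(tau))
    s1 <- tau < ts
    out[s1] <- A * sin(pi * tau[s1] / ts)^2
    s2 <- tau >= ts & tau < ts + tr
    out[s2] <- -B * sin(pi * (tau[s2] - ts) / tr)^2
    out
  }
  n <- 4096L
  tau <- (seq_len(n) - 1) / n
  co <- stats::fft(shape(tau)) / n
  coef <- co[seq_len(n_harmonics + 1L)]   # mean + n_harmonics harmonics
  structure(list(frequency = frequency, period = 1 / frequency,
                 mean_velocity = mean_velocity, coef = coef,
                 n_harmonics = n_harmonics),
            class = "inlet_waveform")
}

#' Instantaneous flat-profile inlet velocity
#'
#' Evaluates the waveform's Fourier series at time `t`. The value is imposed
#' uniformly over the inlet (flat profile), so the instantaneous inlet flow
#' rate equals this velocity times the inlet width (per unit depth).
#'
#' @param t time(s), s.
#' @param waveform an [inlet_waveform()] object.
#' @return Inlet velocity value(s), m/s; exactly periodic in `1/frequency`.
#' @export
inlet_velocity <- function(t, waveform) {
  stopifnot(inherits(waveform, "inlet_waveform"))
  k <- seq_len(waveform$n_harmonics)
  ph <- outer(t, k, function(tt, kk) exp(2i * pi * kk * waveform$frequency * tt))
  val <- Re(waveform$coef[1]) + 2 * Re(ph %*% waveform$coef[-1])
  drop(val) * waveform$mean_velocity
}

#' Three-element Windkessel parameters
#'
#' Lumped outlet model with characteristic impedance `R_c`, peripheral
#' resistance `R_p` and compliance `C`. All flows are per unit depth of the
#' planar model, so resistances are in Pa s/m^2 and the compliance in
#' m^2/Pa. Defaults are chosen so the true-lumen outlet pressure of the
#' default dissection configuration oscillates in a physiological
#' 80--120 mmHg band (documented placeholders, freely overridable).
#'
#' @param C compliance.
#' @param R_p peripheral resistance.
#' @param R_c characteristic impedance.
#' @param P0 initial stored pressure, Pa.
#' @return An object of class `windkessel_params`.
#' @export
windkessel_params <- function(C = 2.15e-7, R_p = 6.5e6, R_c = 3.4e5,
                              P0 = 10600) {
  stopifnot(C > 0, R_p > 0, R_c > 0)
  structure(list(C = C, R_p = R_p, R_c = R_c, P_wk = P0),
            class = "windkessel_params")
}

#' Advance the Windkessel ODE one step
#'
#' Implicit (backward-Euler) update of the stored pressure
#' \eqn{C\,dP_{wk}/dt = Q - P_{wk}/R_p}; the returned outlet pressure is
#' \eqn{P = P_{wk} + Q R_c}. With constant Q the steady state is
#' \eqn{P = Q(R_c + R_p)}.
#'
#' @param Q instantaneous outflow (per unit depth), m^2/s.
#' @param wk a [windkessel_params()] object (carries the state `P_wk`).
#' @param dt time step, s.
#' @return List with `P` (outlet pressure, Pa) and `wk` (updated state).
#' @export
windkessel_step <- function(Q, wk, dt) {
  stopifnot(inherits(wk, "windkessel_params"), dt > 0)
  wk$P_wk <- (wk$P_wk + dt * Q / wk$C) / (1 + dt / (wk$R_p * wk$C))
  list(P = wk$P_wk + Q * wk$R_c, wk = wk)
}

#' Brinkman-type thrombus momentum sink
#'
#' The body force \eqn{F = k_M \frac{BP^2}{BP^2 + BP_t^2} u} applied with a
#' negative sign in the momentum balance: clot-free blood (BP = 0) is
#' unhindered, fully thrombosed regions approach a Darcy-like drag of
#' coefficient \eqn{k_M}; at BP = BP_t the drag is half-saturated.
#'
#' @param BP bound-platelet concentration(s), nmol/L.
#' @param u velocity component(s), m/s (any shape recyclable with `BP`).
#' @param k_M sink constant, kg/(m^3 s).
#' @param BP_t bound-platelet threshold, nmol/L.
#' @return Force density (same shape), N/m^3.
#' @export
fictitious_force <- function(BP, u, k_M = 1e7, BP_t = 20) {
  if (any(BP < 0, na.rm = TRUE)) stop("BP must be non-negative")
  k_M * BP^2 / (BP^2 + BP_t^2) * u
}

# --- solver state -----------------------------------------------------------

#' Initialize a coupled flow/species state on a mesh
#'
#' @param mesh an `flt_mesh`.
#' @param fluid a [fluid_properties()] object.
#' @param thromb a [thrombosis_params()] object.
#' @param bc boundary-condition description: a list with `west` (either
#'   `list(type = "velocity", waveform = )` or `list(type = "pressure",
#'   value = )` where value is a constant or function of time) and `east`
#'   (`list(type = "windkessel", wk = )` or `list(type = "pressure",
#'   value = )`).
#' @param flap optional list from [build_flap_system()]; `NULL` for rigid.
#' @param k_M momentum-sink constant, kg/(m^3 s).
#' @param k_pen solid-penalization coefficient, kg/(m^3 s); large compared
#'   to `k_M` so walls and flap are far less permeable than mature clot.
#' @param body_force optional function of time giving a uniform axial body
#'   force, N/m^3 (used by oscillatory-channel verification).
#' @return An object of class `flt_state`.
#' @export
flow_state <- function(mesh, fluid = fluid_properties(),
                       thromb = thrombosis_params(),
                       bc = list(west = list(type = "pressure", value = 0),
                                 east = list(type = "pressure", value = 0)),
                       flap = NULL, k_M = 1e7, k_pen = 1e8,
                       body_force = NULL) {
  stopifnot(inherits(mesh, "flt_mesh"))
  nx <- mesh$nx; ny <- mesh$ny
  nfac <- nrow(mesh$facets)
  nst <- if (is.null(flap)) 0L else length(flap$cols)
  st <- structure(list(
    mesh = mesh, fluid = fluid, thromb = thromb, bc = bc, flap = flap,
    k_M = k_M, k_pen = k_pen, body_force = body_force,
    u = matrix(0, nx + 1, ny), v = matrix(0, nx, ny + 1),
    p = matrix(0, nx, ny),
    RP = matrix(1, nx, ny), AP = matrix(1, nx, ny),
    C = matrix(0, nx, ny), BP = matrix(0, nx, ny),
    mu = matrix(NA_real_, nx, ny), gamma = matrix(0, nx, ny),
    solid_frac = matrix(0, nx, ny),
    wss = numeric(nfac), tawss_prev = rep(Inf, nfac),
    flap_w = numeric(nst), flap_wdot = numeric(nst),
    pwk = if (!is.null(bc$east$wk)) bc$east$wk$P_wk else 0,
    t = 0,
    acc_wss = numeric(nfac), acc_gamma = numeric(nx * ny),
    acc_AP = numeric(nx * ny), acc_mu = numeric(nx * ny), acc_t = 0,
    clip_log = list()
  ), class = "flt_state")
  # start from a uniform pressure equal to the stored outlet pressure so the
  # Dirichlet outlet does not launch a spurious startup transient
  p0 <- if (identical(bc$east$type, "windkessel")) bc$east$wk$P_wk else 0
  st$p[] <- p0
  st$p_west_applied <- p0
  st$p_east_applied <- p0
  st
}

# grid description consumed by the compiled kernel
build_grid_list <- function(state) {
  mesh <- state$mesh
  side_code <- c(W = 0L, E = 1L, S = 2L, N = 3L)
  fac <- mesh$facets
  if (mesh$kind == "channel") {
    inlet_rows <- seq_len(mesh$ny) - 1L
    outlet_rows <- inlet_rows
  } else {
    inlet_rows <- mesh$tl_rows - 1L
    outlet_rows <- mesh$tl_rows - 1L
  }
  flap <- state$flap
  wall_tags <- c("outer_wall", "flap_tl_side", "flap_fl_side",
                 "fl_endwall", "tear_edge", "wall")
  list(nx = mesh$nx, ny = mesh$ny, dx = mesh$dx[1], dy = mesh$dy,
       cell_type = mesh$cell_type,
       facet_i = fac$i - 1L, facet_j = fac$j - 1L,
       facet_side = unname(side_code[fac$side]), facet_len = fac$length,
       facet_is_wall = fac$tag %in% wall_tags,
       inlet_rows = inlet_rows, outlet_rows = outlet_rows,
       flap_cols = if (is.null(flap)) integer(0) else flap$cols - 1L,
       flap_y0 = if (is.null(flap)) numeric(0) else flap$y0,
       flap_y1 = if (is.null(flap)) numeric(0) else flap$y1,
       flap_row_lo = if (is.null(flap)) integer(0) else min(mesh$flap_rows) - 1L,
       flap_row_hi = if (is.null(flap)) integer(0) else max(mesh$flap_rows) - 1L,
       y_faces = mesh$y_faces)
}

build_par_list <- function(state, nsteps, dt, species_on, flap_on,
                           advance_flow = TRUE, wall_flux_on = TRUE,
                           species_advection = TRUE, reactions_on = TRUE,
                           cg_rtol = 1e-9, cg_maxit = 20000L,
                           c_wall_delta = 1e-3) {
  fluid <- state$fluid; th <- state$thromb
  mu_is_const <- is.numeric(fluid$rheology)
  qp <- if (mu_is_const) quemada_params() else fluid$rheology
  tt <- state$t + dt * (seq_len(nsteps) - 1)
  bcw <- state$bc$west; bce <- state$bc$east
  evalbc <- function(bcv, tt) {
    if (is.null(bcv)) return(rep(0, length(tt)))
    if (is.function(bcv)) return(vapply(tt, bcv, numeric(1)))
    rep(bcv, length(tt))
  }
  inlet_u <- if (identical(bcw$type, "velocity")) {
    if (inherits(bcw$waveform, "inlet_waveform"))
      inlet_velocity(tt, bcw$waveform)
    else evalbc(bcw$value, tt)
  } else rep(0, nsteps)
  west_p <- if (identical(bcw$type, "pressure")) evalbc(bcw$value, tt)
            else rep(0, nsteps)
  east_p <- if (identical(bce$type, "pressure")) evalbc(bce$value, tt)
            else rep(0, nsteps)
  fx <- if (is.null(state$body_force)) rep(0, nsteps)
        else vapply(tt, state$body_force, numeric(1))
  wk <- bce$wk
  flap <- state$flap
  list(rho = fluid$density, dt = dt, k_M = state$k_M,
       BP_t_sink = th$BP_t, k_pen = state$k_pen,
       advance_flow = advance_flow, species_on = species_on,
       flap_on = flap_on && !is.null(flap) && !isTRUE(flap$rigid),
       west_bc = if (identical(bcw$type, "velocity")) 0L else 1L,
       east_bc = if (identical(bce$type, "windkessel")) 2L else 1L,
       inlet_u = inlet_u, west_p = west_p, east_p = east_p, fx = fx,
       cg_rtol = cg_rtol, cg_maxit = as.integer(cg_maxit),
       mu_is_const = mu_is_const,
       mu_const = if (mu_is_const) fluid$rheology else 0,
       mu_p = qp$plasma_viscosity, hct = qp$hematocrit,
       qk0 = qp$k0, qkinf = qp$k_inf, qgc = qp$gamma_c, qgmin = 1e-6,
       D_RP = th$D_RP, D_AP = th$D_AP, D_C_base = th$D_C_base,
       k_RP = th$k_RP, k_AP = th$k_AP, k_C1 = th$k_C1, k_C2 = th$k_C2,
       k_BP = th$k_BP, gamma_t = th$gamma_t, AP_t = th$AP_t, C_t = th$C_t,
       BP_t = th$BP_t, TAWSS_threshold = th$TAWSS_threshold,
       c_wall_flux_density = th$k_c_wall * c_wall_delta,
       wall_relative_concentration = th$wall_relative_concentration,
       literal_shear_switch = th$literal_shear_switch,
       species_advection = species_advection,
       reactions_on = reactions_on,
       wall_flux_on = wall_flux_on,
       wk_C = if (is.null(wk)) 1 else wk$C,
       wk_Rp = if (is.null(wk)) 1 else wk$R_p,
       wk_Rc = if (is.null(wk)) 1 else wk$R_c,
       flap_Minv = if (is.null(flap) || isTRUE(flap$rigid))
         matrix(0, 0, 0) else flap$Minv,
       flap_relax = if (is.null(flap)) 0.5 else flap$params$relax,
       flap_cap = if (is.null(flap)) 0 else flap$cap,
       flap_tear = if (is.null(flap)) logical(0) else flap$tear)
}

#' Advance the coupled solver
#'
#' Runs `nsteps` time steps of the per-step sequence: inlet/Windkessel
#' update, flap load/solve/penalization update, momentum predictor +
#' pressure projection (with the thrombus momentum sink), species transport
#' and reaction, ledger accumulation. Components can be toggled for
#' verification runs.
#'
#' @param state an [flow_state()] object.
#' @param nsteps number of steps.
#' @param dt time step, s.
#' @param species_on advance the thrombosis species.
#' @param flap_on update the mobile flap (ignored for rigid/absent flap).
#' @param advance_flow advance the flow (FALSE freezes the velocity field,
#'   e.g. to exercise the species stepper on a stored flow).
#' @param wall_flux_on enable the TAWSS-gated coagulant wall flux.
#' @param species_advection include the advection operator for RP/AP
#'   (verification toggle).
#' @param reactions_on include the reaction source terms (verification
#'   toggle; with reactions off the stepper is pure transport).
#' @param ... tuning overrides passed to the kernel (`cg_rtol`, `cg_maxit`,
#'   `c_wall_delta`).
#' @return The updated `flt_state`; per-step diagnostics in `$diag`
#'   (inlet/outlet flux, outlet pressure, kinetic energy, max velocity,
#'   CG iterations, flap excursion, max divergence).
#' @export
advance <- function(state, nsteps, dt, species_on = FALSE, flap_on = FALSE,
                    advance_flow = TRUE, wall_flux_on = TRUE,
                    species_advection = TRUE, reactions_on = TRUE, ...) {
  stopifnot(inherits(state, "flt_state"), nsteps >= 1, dt > 0)
  gr <- build_grid_list(state)
  par <- build_par_list(state, nsteps, dt, species_on, flap_on,
                        advance_flow = advance_flow,
                        wall_flux_on = wall_flux_on,
                        species_advection = species_advection,
                        reactions_on = reactions_on, ...)
  stl <- list(u = state$u, v = state$v, p = state$p,
              RP = state$RP, AP = state$AP, C = state$C, BP = state$BP,
              flap_w = state$flap_w, tawss_prev = state$tawss_prev,
              pwk = state$pwk, t = state$t,
              p_west_applied = state$p_west_applied,
              p_east_applied = state$p_east_applied,
              acc_wss = state$acc_wss, acc_gamma = state$acc_gamma,
              acc_AP = state$acc_AP, acc_mu = state$acc_mu,
              acc_t = state$acc_t)
  out <- cpp_advance(stl, gr, par, as.integer(nsteps))
  if (isTRUE(out$blew_up))
    stop("flow solver diverged at t = ", signif(out$t, 6),
         " s (max |u| = ", signif(max(out$diag$umax, na.rm = TRUE), 4),
         " m/s, CFL = ",
         signif(max(out$diag$umax, na.rm = TRUE) * dt / state$mesh$dx[1], 3),
         "); reduce dt")
  dim(out$u) <- dim(state$u); dim(out$v) <- dim(state$v)
  dim(out$p) <- dim(state$p)
  for (f in c("RP", "AP", "C", "BP")) dim(out[[f]]) <- dim(state[[f]])
  state$u <- out$u; state$v <- out$v; state$p <- out$p
  state$RP <- out$RP; state$AP <- out$AP; state$C <- out$C; state$BP <- out$BP
  state$mu <- out$mu; state$gamma <- out$gamma
  state$solid_frac <- out$solid_frac
  state$wss <- out$wss
  state$flap_w <- out$flap_w; state$flap_wdot <- out$flap_wdot
  state$pwk <- out$pwk; state$t <- out$t
  state$p_west_applied <- out$p_west_applied
  state$p_east_applied <- out$p_east_applied
  state$acc_wss <- out$acc_wss; state$acc_gamma <- out$acc_gamma
  state$acc_AP <- out$acc_AP; state$acc_mu <- out$acc_mu
  state$acc_t <- out$acc_t
  state$diag <- out$diag
  state
}

#' Advance the flow one time step
#'
#' Single-step wrapper around [advance()] with the species frozen.
#'
#' @inheritParams advance
#' @return Updated `flt_state`.
#' @export
step_flow <- function(state, dt, ...) {
  advance(state, 1L, dt, species_on = FALSE, ...)
}

#' Advance the species one time step on the current (frozen) flow
#'
#' @inheritParams advance
#' @return Updated `flt_state`.
#' @export
step_species <- function(state, dt, wall_flux_on = TRUE, ...) {
  advance(state, 1L, dt, species_on = TRUE, advance_flow = FALSE,
          wall_flux_on = wall_flux_on, ...)
}

#' Wall shear stress on boundary facets
#'
#' Magnitude of \eqn{\mu\,\partial u_t/\partial n} on each tagged boundary
#' facet, from a one-sided quadratic fit of the tangential velocity through
#' the no-slip wall. This is the instantaneous integrand of the per-cycle
#' TAWSS.
#'
#' @param state an `flt_state` after at least one step (so the viscosity
#'   field is populated), or any state with `u`, `v`, `mu` set.
#' @return Data frame: the mesh facet table plus a `wss` column, Pa.
#' @export
wall_shear_stress <- function(state) {
  stopifnot(inherits(state, "flt_state"))
  mesh <- state$mesh
  fac <- mesh$facets
  u <- state$u; v <- state$v
  mu <- state$mu
  if (all(is.na(mu))) mu <- viscosity_field(state$gamma, state$fluid)
  nx <- mesh$nx; ny <- mesh$ny
  dyv <- mesh$dy; dxs <- mesh$dx[1]
  yc <- mesh$y_centers
  ubar <- (u[-(nx + 1), , drop = FALSE] + u[-1, , drop = FALSE]) / 2
  vbar <- (v[, -(ny + 1), drop = FALSE] + v[, -1, drop = FALSE]) / 2
  wss <- numeric(nrow(fac))
  for (k in seq_len(nrow(fac))) {
    i <- fac$i[k]; j <- fac$j[k]; s <- fac$side[k]
    if (s %in% c("S", "N")) {
      j2 <- if (s == "S") j + 1L else j - 1L
      d1 <- dyv[j] / 2
      u1 <- ubar[i, j]
      if (j2 >= 1 && j2 <= ny) {
        d2 <- d1 + abs(yc[j2] - yc[j])
        u2 <- ubar[i, j2]
        slope <- (u1 * d2^2 - u2 * d1^2) / (d1 * d2 * (d2 - d1))
      } else slope <- u1 / d1
    } else {
      i2 <- if (s == "W") i + 1L else i - 1L
      d1 <- dxs / 2
      v1 <- vbar[i, j]
      if (i2 >= 1 && i2 <= nx) {
        d2 <- 1.5 * dxs
        v2 <- vbar[i2, j]
        slope <- (v1 * d2^2 - v2 * d1^2) / (d1 * d2 * (d2 - d1))
      } else slope <- v1 / d1
    }
    wss[k] <- mu[i, j] * abs(slope)
  }
  fac$wss <- wss
  fac
}
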