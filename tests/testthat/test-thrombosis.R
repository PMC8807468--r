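# Four-species thrombosis model: switching functions, source terms, wall
# flux gating, ledger bookkeeping and the transport stepper.

test_that("switching functions hit their midpoints, limits and bounds", {
  p <- thrombosis_params()
  expect_equal(switching(0, 10), 0)
  expect_equal(switching(10, 10), 0.5)        # midpoint identity
  expect_equal(switching(1e9, 10), 1, tolerance = 1e-10)
  # product coefficient: both factors at midpoint -> 1/4
  expect_equal(switching_bp(p$AP_t, p$C_t, p), 0.25)
  # shear switch: 1 in stasis, 1/2 at the threshold, -> 0 at high shear
  expect_equal(shear_switch(0, p), 1)
  expect_equal(shear_switch(p$gamma_t, p), 0.5)
  expect_lt(shear_switch(1e8, p), 1e-10)
  # bounds and monotonicity over a sweep
  g <- 10^seq(-3, 6, length.out = 60)
  phi <- shear_switch(g, p)
  expect_true(all(phi > 0 & phi <= 1))
  expect_true(all(diff(phi) <= 0))
  x <- 10^seq(-3, 6, length.out = 60)
  s <- switching(x, p$C_t)
  expect_true(all(s >= 0 & s <= 1) && all(diff(s) >= 0))
  # literal (mixed-unit) variant midpoint moves to gamma_t^2
  pl <- thrombosis_params(literal_shear_switch = TRUE)
  expect_equal(shear_switch(pl$gamma_t^2, pl), 0.5)
})

test_that("source terms reproduce the kinetic constants at limit inputs", {
  p <- thrombosis_params()
  # unit relative concentrations: S_AP = k_AP
  s <- source_terms(RP = 1, AP = 1, C = 0, BP = 0, phi_gamma = 1, p)
  expect_equal(s$S_AP, 3.0)
  expect_equal(s$S_RP, -0.15)
  # AP multiplies every term: AP = 0 zeroes all four sources
  s0 <- source_terms(RP = 2, AP = 0, C = 50, BP = 50, phi_gamma = 0.3, p)
  expect_true(all(abs(unlist(s0)) == 0))
  # saturating low-shear limit: S_BP -> k_BP * AP
  s1 <- source_terms(RP = 0, AP = 1e6, C = 1e6, BP = 0, phi_gamma = 1, p)
  expect_equal(s1$S_BP / 1e6, 12.0, tolerance = 1e-8)
  # closed switches: no BP, no C, no shear -> S_C = 0
  s2 <- source_terms(RP = 1, AP = 5, C = 0, BP = 0, phi_gamma = 1, p)
  expect_equal(s2$S_C, 0)
  expect_gte(s1$S_BP, 0)
  expect_error(source_terms(-1, 1, 0, 0, 1, p), "non-negative")
})

test_that("coagulant wall flux is gated by previous-cycle TAWSS and local BP", {
  p <- thrombosis_params()
  # both conditions met -> the full flux constant
  expect_equal(coagulant_wall_flux(0.10, 5, p), 16.0)
  # high TAWSS -> no flux regardless of BP
  expect_equal(coagulant_wall_flux(0.30, 5, p), 0)
  # saturated BP -> no flux even at low TAWSS
  expect_equal(coagulant_wall_flux(0.10, 25, p), 0)
  # vectorized over facets; Inf TAWSS (first-cycle policy) disables
  expect_equal(coagulant_wall_flux(c(0.1, 0.2, Inf), c(5, 5, 5), p),
               c(16, 0, 0))
})

test_that("thrombus mask and volume follow the BP threshold", {
  expect_equal(thrombus_mask(matrix(0, 4, 4), 1e-6)$volume_cm3, 0)
  # half the cells at/above threshold
  BP <- matrix(c(25, 25, 0, 0), 2, 2)
  tm <- thrombus_mask(BP, cell_area = 1e-6, BP_t = 20)
  expect_equal(tm$volume_cm3, 2 * 1e-6 * 1e6)
  expect_equal(sum(tm$indicator), 2)
  # region restriction
  reg <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(thrombus_mask(BP, 1e-6, 20, region = reg)$volume_cm3, 1)
})

test_that("cycle ledger averages WSS over the cycle and publishes at boundaries", {
  led <- cycle_ledger(n_facets = 3, n_cells = 4, period = 1)
  # before any completed cycle the published TAWSS is +Inf (flux disabled)
  expect_true(all(is.infinite(ledger_tawss(led))))
  # constant WSS over a full cycle -> TAWSS equals the constant
  nt <- 200; dt <- 1 / nt
  for (k in seq_len(nt))
    led <- update_ledger(led, wss = c(0.3, 0.1, 0), gamma_dot = rep(2, 4),
                         AP = rep(1.5, 4), dt = dt,
                         cycle_boundary = (k == nt))
  expect_equal(ledger_tawss(led), c(0.3, 0.1, 0), tolerance = 1e-12)
  expect_equal(led$avg_gamma, rep(2, 4))
  expect_equal(led$avg_AP, rep(1.5, 4))
  expect_equal(led$cycle, 1L)
  # rectified sinusoid: TAWSS = 2A/pi
  A <- 0.4
  led2 <- cycle_ledger(1, 1, period = 1)
  tmid <- (seq_len(2000) - 0.5) / 2000
  for (k in seq_len(2000))
    led2 <- update_ledger(led2, A * abs(sin(2 * pi * tmid[k])), 0, 0,
                          dt = 1 / 2000, cycle_boundary = (k == 2000))
  expect_equal(ledger_tawss(led2), 2 * A / pi, tolerance = 1e-4)
  # accumulators reset after publishing
  expect_equal(led2$t_accum, 0)
})

test_that("uniform-field reactions match an independent ODE integration", {
  skip_if_not_installed("deSolve")
  mesh <- benchmark_channel(0.01, 0.01, 1e-3, unit = "m")
  st <- flow_state(mesh, fluid = fluid_properties(1060, 0.0035))
  dt <- 5e-4; tend <- 2
  st <- advance(st, round(tend / dt), dt, species_on = TRUE,
                advance_flow = FALSE, wall_flux_on = FALSE)
  ode_fn <- function(t, y, p) list(c(-0.15 * y[2] * y[1], 3 * y[2] * y[1]))
  ref <- deSolve::ode(c(RP = 1, AP = 1), c(0, tend), ode_fn, NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(st$AP[5, 5], ref[2, "AP"], tolerance = 5e-3,
               ignore_attr = TRUE)
  expect_lt(abs(st$AP[5, 5] - ref[2, "AP"]) / ref[2, "AP"], 0.005)
  expect_lt(abs(st$RP[5, 5] - ref[2, "RP"]), 0.005)
  # BP and C stay identically zero: the cascade cannot self-start
  expect_equal(max(st$C), 0)
  expect_equal(max(st$BP), 0)
})

test_that("advected platelet Gaussian translates with the flow", {
  mesh <- benchmark_channel(1, 0.1, 0.0025, unit = "m")
  st <- flow_state(mesh, fluid = fluid_properties(1060, 0.0035))
  u0 <- 0.5; sig <- 0.04; x0 <- 0.2
  st$u[] <- u0
  X <- matrix(mesh$x_centers, mesh$nx, mesh$ny)
  st$AP <- exp(-((X - x0)^2) / (2 * sig^2))
  st$RP[] <- 0
  tend <- 0.6; dt <- 0.4 * 0.0025 / u0
  st <- advance(st, round(tend / dt), dt, species_on = TRUE,
                advance_flow = FALSE, wall_flux_on = FALSE)
  g_ex <- exp(-((X - x0 - u0 * tend)^2) / (2 * sig^2))
  sel <- X > 0.35
  l2 <- sqrt(sum((st$AP[sel] - g_ex[sel])^2) / sum(g_ex[sel]^2))
  expect_lt(l2, 0.02)
})

test_that("coagulant Gaussian spreads with the heat-kernel variance", {
  mesh <- benchmark_channel(0.012, 0.012, 3e-4, unit = "m")
  st <- flow_state(mesh, fluid = fluid_properties(1060, 0.0035))
  st$RP[] <- 0; st$AP[] <- 0
  s0 <- 8e-4; D <- 1e-8
  X <- matrix(mesh$x_centers, mesh$nx, mesh$ny)
  Y <- matrix(mesh$y_centers, mesh$nx, mesh$ny, byrow = TRUE)
  r2 <- (X - 0.006)^2 + (Y - 0.006)^2
  st$C <- exp(-r2 / (2 * s0^2))
  tend <- 30
  st <- advance(st, round(tend / 0.25), 0.25, species_on = TRUE,
                advance_flow = FALSE, wall_flux_on = FALSE)
  s2t <- s0^2 + 2 * D * tend
  c_ex <- s0^2 / s2t * exp(-r2 / (2 * s2t))
  expect_lt(sqrt(sum((st$C - c_ex)^2) / sum(c_ex^2)), 0.02)
})

test_that("C is never advected and BP is never transported", {
  mesh <- benchmark_channel(1, 0.2, 0.005, unit = "m")
  X <- matrix(mesh$x_centers, mesh$nx, mesh$ny)
  g0 <- exp(-((X - 0.2)^2) / (2 * 0.04^2))
  st <- flow_state(mesh, fluid = fluid_properties(1060, 0.0035),
                   thromb = thrombosis_params(D_C_base = 0))
  st$u[] <- 0.5; st$RP[] <- 0; st$AP[] <- 0
  st$C <- g0; st$BP <- 20 * g0
  st <- advance(st, 100, 0.004, species_on = TRUE, advance_flow = FALSE,
                wall_flux_on = FALSE, reactions_on = FALSE)
  expect_equal(max(abs(st$C - g0)), 0)
  expect_equal(max(abs(st$BP - 20 * g0)), 0)
})

test_that("species diffusion converges at second order on a Gaussian", {
  err <- sapply(c(6e-4, 3e-4), function(h) {
    mesh <- benchmark_channel(0.012, 0.012, h, unit = "m")
    st <- flow_state(mesh, fluid = fluid_properties(1060, 0.0035))
    st$RP[] <- 0; st$AP[] <- 0
    s0 <- 8e-4; D <- 1e-8
    X <- matrix(mesh$x_centers, mesh$nx, mesh$ny)
    Y <- matrix(mesh$y_centers, mesh$nx, mesh$ny, byrow = TRUE)
    r2 <- (X - 0.006)^2 + (Y - 0.006)^2
    st$C <- exp(-r2 / (2 * s0^2))
    st <- advance(st, 300, 0.1, species_on = TRUE,
                  advance_flow = FALSE, wall_flux_on = FALSE)
    s2t <- s0^2 + 2 * D * 30
    c_ex <- s0^2 / s2t * exp(-r2 / (2 * s2t))
    sqrt(sum((st$C - c_ex)^2) / sum(c_ex^2))
  })
  order <- log2(err[1] / err[2])
  expect_gt(order, 1.5)
})
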