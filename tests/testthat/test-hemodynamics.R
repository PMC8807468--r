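# Flow solver: momentum sink, Windkessel, inlet waveform and the
# channel-flow verification oracles.

test_that("thrombus momentum sink saturates through the BP switch", {
  expect_equal(fictitious_force(0, 1), 0)
  # half saturation at BP = BP_t: |F|/|u| = k_M / 2
  expect_equal(fictitious_force(20, 1), 5e6)
  expect_equal(fictitious_force(1e9, 1) / 1, 1e7, tolerance = 1e-6)
  # antiparallel to velocity, linear in u
  expect_equal(fictitious_force(20, -2), -1e7)
  expect_error(fictitious_force(-1, 1), "non-negative")
})

test_that("Windkessel reaches Q*(Rc+Rp) and decays with its RC time", {
  wk <- windkessel_params(C = 1e-7, R_p = 5e6, R_c = 2e5, P0 = 0)
  Q <- 2e-3; dt <- 1e-3
  for (k in 1:200000) {
    s <- windkessel_step(Q, wk, dt); wk <- s$wk
  }
  expect_equal(s$P, Q * (5e6 + 2e5), tolerance = 1e-4)
  # zero-flow decay from P0: exponential with tau = Rp*C
  wk2 <- windkessel_params(C = 1e-7, R_p = 5e6, R_c = 2e5, P0 = 1e4)
  tau <- 5e6 * 1e-7
  t <- 0
  for (k in 1:500) { s2 <- windkessel_step(0, wk2, 1e-3); wk2 <- s2$wk }
  expect_equal(wk2$P_wk, 1e4 * exp(-0.5 / tau), tolerance = 2e-3)
  # zero flow from zero state stays zero
  wk3 <- windkessel_params(P0 = 0)
  expect_equal(windkessel_step(0, wk3, 0.01)$P, 0)
})

test_that("inlet waveform is periodic with one systolic peak and a reverse phase", {
  wf <- inlet_waveform()
  expect_equal(wf$frequency, 1.02)
  t <- seq(0, wf$period, length.out = 2001)[-2001]
  u <- inlet_velocity(t, wf)
  # exact periodicity
  expect_equal(inlet_velocity(0.123, wf),
               inlet_velocity(0.123 + 5 / 1.02, wf), tolerance = 1e-12)
  # cycle mean matches the configured mean to < 0.1%
  expect_lt(abs(mean(u) - wf$mean_velocity) / wf$mean_velocity, 1e-3)
  # a single dominant forward peak
  pk <- which(diff(sign(diff(u))) == -2) + 1
  expect_equal(sum(u[pk] > 0.5 * max(u)), 1L)
  # reverse flow occurs, after the systolic peak
  expect_lt(min(u), 0)
  expect_gt(which.min(u), which.max(u))
  # zero-amplitude waveform: identically zero
  wf0 <- inlet_waveform(mean_velocity = 0)
  expect_equal(max(abs(inlet_velocity(t, wf0))), 0)
})

test_that("pressure-driven channel flow converges to the Poiseuille profile", {
  mu <- 0.0035; rho <- 1060; W <- 0.01; L <- 0.05; dP <- 0.14
  mesh <- benchmark_channel(L, W, 5e-4, unit = "m")
  st <- flow_state(mesh, fluid = fluid_properties(rho, mu),
                   bc = list(west = list(type = "pressure", value = dP),
                             east = list(type = "pressure", value = 0)))
  st <- advance(st, 4000, 0.01)
  G <- dP / L
  yc <- mesh$y_centers
  u_exact <- G / (2 * mu) * yc * (W - yc)
  prof <- (st$u[-1, ] + st$u[-(mesh$nx + 1), ])[50, ] / 2
  expect_lt(max(abs(prof - u_exact)) / max(u_exact), 0.01)
  # discrete incompressibility to solver tolerance
  expect_lt(max(st$diag$div_max), 1e-6)
  # WSS = 6 mu U / W on both walls within 2%
  U <- sum(prof * mesh$dy) / W
  wss <- wall_shear_stress(st)
  mid <- wss[wss$i == 50, ]
  expect_equal(nrow(mid), 2L)
  expect_lt(max(abs(mid$wss - 6 * mu * U / W)) / (6 * mu * U / W), 0.02)
  # linearity: doubling the pressure drop doubles the WSS (Stokes regime)
  st2 <- flow_state(mesh, fluid = fluid_properties(rho, mu),
                    bc = list(west = list(type = "pressure", value = 2 * dP),
                              east = list(type = "pressure", value = 0)))
  st2 <- advance(st2, 4000, 0.01)
  wss2 <- wall_shear_stress(st2)
  expect_equal(median(wss2$wss[wss2$i == 50]) / median(mid$wss), 2,
               tolerance = 0.01)
})

test_that("oscillatory channel flow matches the Womersley series solution", {
  mu <- 0.0035; rho <- 1060; nu <- mu / rho
  W <- 0.01; L <- 0.01; om <- 2 * pi * 1.02; Tp <- 1 / 1.02; G0 <- 200
  mesh <- benchmark_channel(L, W, 2.5e-4, unit = "m", nx = 4, ny = 40)
  womersley <- function(y, t) {
    beta <- sqrt(1i * om / nu)
    uhat <- G0 / (1i * rho * om) *
      (1 - cosh(beta * (y - W / 2)) / cosh(beta * W / 2))
    Re(uhat * exp(1i * om * t))
  }
  st <- flow_state(mesh, fluid = fluid_properties(rho, mu),
                   bc = list(west = list(type = "pressure",
                                         value = function(t) G0 * L * cos(om * t)),
                             east = list(type = "pressure", value = 0)))
  yc <- mesh$y_centers
  for (j in seq_len(mesh$ny)) st$u[, j] <- womersley(yc[j], 0)
  st$p <- matrix(G0 * (L - mesh$x_centers), mesh$nx, mesh$ny)
  st$p_west_applied <- G0 * L
  st <- advance(st, 2000, Tp / 2000)
  prof <- (st$u[-1, ] + st$u[-(mesh$nx + 1), ])[2, ] / 2
  u_ex <- womersley(yc, Tp)
  expect_lt(sqrt(sum((prof - u_ex)^2) / sum(u_ex^2)), 0.03)
})

test_that("fully thrombosed channel flux matches the Brinkman solution", {
  mu <- 0.0035; rho <- 1060; W <- 0.01; L <- 0.02; dP <- 10
  mesh <- benchmark_channel(L, W, 5e-4, unit = "m")
  st <- flow_state(mesh, fluid = fluid_properties(rho, mu),
                   bc = list(west = list(type = "pressure", value = dP),
                             east = list(type = "pressure", value = 0)))
  st$BP <- matrix(2000, mesh$nx, mesh$ny)      # BP >> BP_t: sink ~ k_M
  st <- advance(st, 400, 1e-3)
  G <- dP / L
  K <- 1e7 * 2000^2 / (2000^2 + 20^2)
  kap <- sqrt(K / mu)
  Q_exact <- G / K * (W - 2 / kap * tanh(kap * W / 2))
  Q_num <- sum(st$u[2, ] * mesh$dy)
  expect_lt(abs(Q_num - Q_exact) / Q_exact, 0.02)
})

test_that("quiescent fluid stays quiescent with zero wall shear stress", {
  mesh <- benchmark_channel(0.1, 0.02, 2e-3, unit = "m")
  st <- flow_state(mesh, fluid = fluid_properties(1060, 0.0035))
  st1 <- advance(st, 5, 1e-3)
  expect_equal(max(abs(st1$u)), 0)
  expect_equal(max(abs(st1$v)), 0)
  expect_equal(max(wall_shear_stress(st1)$wss), 0)
})
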