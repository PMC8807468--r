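# Reduced-order flap: clamped-beam mechanics, transmural load sampling,
# penalized-interface mesh updates and displacement reporting.

test_that("uniform load recovers the classical clamped-beam deflection", {
  fp <- flap_params(E_flap = 6.75e6, thickness = 0.8e-3, span = 0.2,
                    foundation = 0)
  n <- 101
  w <- solve_flap(rep(100, n), fp)
  w_exact <- 100 * fp$span^4 / (384 * fp$E_flap * fp$I)
  expect_lt(abs(w[(n + 1) / 2] - w_exact) / w_exact, 0.01)
  # clamped ends: displacement tends to zero at the extremities
  expect_lt(abs(w[1]), abs(w[(n + 1) / 2]) * 0.01)
})

test_that("flap deflection is linear in load and in 1/E", {
  fp <- flap_params(E_flap = 6.75e6, span = 0.15, foundation = 0)
  q <- sin(seq(0, pi, length.out = 51)) * 80
  w <- solve_flap(q, fp)
  expect_equal(solve_flap(2 * q, fp), 2 * w)
  expect_equal(solve_flap(-q, fp), -w)            # odd symmetry
  fp2 <- flap_params(E_flap = 13.5e6, span = 0.15, foundation = 0)
  expect_equal(solve_flap(q, fp2), w / 2)
  # zero load -> zero displacement; rigid -> zero displacement
  expect_equal(solve_flap(rep(0, 51), fp), rep(0, 51))
  expect_equal(solve_flap(q, flap_params("rigid")), rep(0, 51))
  # flexible preset deflects at least as much as the stiffer preset
  wf <- solve_flap(q, flap_params("flexible", span = 0.15, foundation = 0))
  ws <- solve_flap(q, flap_params("stiffer", span = 0.15, foundation = 0))
  expect_true(all(abs(wf) >= abs(ws) - 1e-15))
})

test_that("foundation stiffness scales with E and stiffens the response", {
  kf <- foundation_from_plate(6.75e6)
  expect_equal(foundation_from_plate(13.5e6), 2 * kf)
  fp0 <- flap_params(E_flap = 6.75e6, span = 0.2, foundation = 0)
  fp1 <- flap_params(E_flap = 6.75e6, span = 0.2, foundation = kf)
  q <- rep(100, 101)
  expect_lt(max(abs(solve_flap(q, fp1))), max(abs(solve_flap(q, fp0))))
  # away from the clamped ends the foundation response approaches q/kf
  w1 <- solve_flap(q, fp1)
  expect_equal(w1[51], 100 / kf, tolerance = 0.05)
})

test_that("transmural load samples the two flap faces and zeroes tears", {
  mesh <- generate_fixtures("mini_dissection")
  flap <- build_flap_system(mesh, flap_params("flexible"))
  st <- flow_state(mesh, flap = flap)
  # uniform pressure -> zero load
  st$p[] <- 500
  ld <- transmural_load(st)
  expect_equal(max(abs(ld$dp)), 0)
  # constructed TL/FL pressures -> constant offset on material, 0 on tears
  jlo <- min(mesh$flap_rows) - 1L; jhi <- max(mesh$flap_rows) + 1L
  st$p[, seq_len(jlo)] <- 100
  st$p[, jhi:mesh$ny] <- 80
  ld <- transmural_load(st)
  expect_equal(unique(ld$dp[!ld$tear]), 20)
  expect_true(all(ld$dp[ld$tear] == 0))
  # antisymmetric pressure doubles the load (linearity)
  st$p[, seq_len(jlo)] <- 100; st$p[, jhi:mesh$ny] <- -100
  expect_equal(unique(transmural_load(st)$dp[!ld$tear]), 200)
})

test_that("penalized-interface mesh update respects rest state, cap and velocity", {
  mesh <- generate_fixtures("mini_dissection")
  flap <- build_flap_system(mesh, flap_params("flexible"))
  n <- length(flap$cols)
  # zero displacement: identical mesh, zero interface velocity
  mm <- move_mesh(mesh, numeric(n), flap, dt = 1e-3)
  expect_identical(mm$mesh, mesh)
  expect_equal(mm$w, numeric(n))
  # prescribed sinusoidal motion: peak interface speed = amplitude * omega
  a <- 2e-3; om <- 2 * pi * 1.02; dt <- 1e-4
  shape <- sin(pi * seq_len(n) / (n + 1))
  wmax <- 0
  for (t in seq(0, 1 / 1.02, by = dt)[-1]) {
    d1 <- a * sin(om * t) * shape
    d0 <- a * sin(om * (t - dt)) * shape
    mm <- move_mesh(mesh, d1, flap, dt, prev_displacement = d0)
    wmax <- max(wmax, max(abs(mm$w)))
  }
  expect_equal(wmax, a * om, tolerance = 0.01)
  # occupancy conserves the flap material: sum(frac * dy) = thickness, and
  # the bottom flap row is vacated when the flap shifts up by one row
  dy <- diff(mesh$y_faces)
  dy_flap <- dy[mesh$flap_rows[1]]
  mm2 <- move_mesh(mesh, rep(dy_flap, n), flap, 1e-3)
  i <- flap$cols[which(!flap$tear)[5]]
  t_flap <- flap$y1 - flap$y0
  expect_equal(sum(mm2$mesh$flap_frac[i, ] * dy), t_flap, tolerance = 1e-12)
  expect_equal(mm2$mesh$flap_frac[i, mesh$flap_rows[1]], 0)
  # displacement beyond the cap is halved back toward the previous value
  mm3 <- move_mesh(mesh, rep(2 * flap$cap, n), flap, 1e-3)
  expect_gt(mm3$halvings, 0)
  expect_equal(sum(mm3$mesh$flap_frac[i, ] * dy), t_flap, tolerance = 1e-12)
})

test_that("per-cycle displacement maxima are reported in mm", {
  times <- seq(0, 2, by = 0.01)
  W <- outer(sin(2 * pi * times), c(1e-3, 2e-3))
  out <- max_flap_displacement(times, W, period = 1,
                               cuts = list(proximal = 1, distal = 2))
  expect_setequal(unique(out$station), c("global", "proximal", "distal"))
  g <- out[out$station == "global", ]
  expect_equal(g$max_mm, rep(2, nrow(g)), tolerance = 1e-3)
  expect_equal(out$max_mm[out$station == "proximal"][1], 1, tolerance = 1e-3)
  # rigid history: all zeros
  out0 <- max_flap_displacement(times, 0 * W, period = 1)
  expect_true(all(out0$max_mm == 0))
})
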