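# Post-processing: vorticity, lambda2 vortex regions, cut-plane pressure
# differences, growth-phase segmentation and the displacement-volume
# regression.

# helper: state with a prescribed cell-centered velocity (set on faces)
make_state_with_velocity <- function(mesh, ufun, vfun) {
  st <- flow_state(mesh, fluid = fluid_properties(1060, 0.0035))
  xf <- mesh$x_faces; yc <- mesh$y_centers
  xc <- mesh$x_centers; yf <- mesh$y_faces
  for (j in seq_len(mesh$ny)) st$u[, j] <- ufun(xf, yc[j])
  for (j in seq_len(mesh$ny + 1)) st$v[, j] <- vfun(xc, yf[j])
  st$mu[] <- 0.0035
  st
}

test_that("vorticity matches analytic fields", {
  mesh <- benchmark_channel(0.1, 0.1, 2.5e-3, unit = "m")
  Om <- 3
  st <- make_state_with_velocity(mesh,
    function(x, y) -Om * (y - 0.05), function(x, y) Om * (x - 0.05))
  om <- vorticity_field(st)
  interior <- om[3:(mesh$nx - 2), 3:(mesh$ny - 2)]
  expect_equal(mean(interior), 2 * Om, tolerance = 1e-6)
  expect_lt(max(abs(interior - 2 * Om)), 1e-6)
  # uniform flow: zero vorticity
  stu <- make_state_with_velocity(mesh, function(x, y) 0.4,
                                  function(x, y) 0)
  expect_lt(max(abs(vorticity_field(stu)[3:(mesh$nx - 2), 3:(mesh$ny - 2)])),
            1e-12)
  # Poiseuille: vorticity changes sign across the centerline
  stp <- make_state_with_velocity(mesh,
    function(x, y) y * (0.1 - y), function(x, y) 0)
  omp <- vorticity_field(stp)
  mid <- omp[10, c(10, 31)]
  expect_lt(abs(sum(mid)), 1e-8)   # antisymmetric about the centerline
})

test_that("lambda2 flags rotation but not shear, Galilean invariantly", {
  mesh <- benchmark_channel(0.1, 0.1, 2.5e-3, unit = "m")
  Om <- 4   # Om^2 = 16 > 10: flagged at the default threshold
  st <- make_state_with_velocity(mesh,
    function(x, y) -Om * (y - 0.05), function(x, y) Om * (x - 0.05))
  vr <- vortex_regions(st)
  interior <- vr$lambda2[3:(mesh$nx - 2), 3:(mesh$ny - 2)]
  expect_equal(mean(interior), -Om^2, tolerance = 1e-6)
  expect_gt(sum(vr$labels > 0), 0.8 * length(interior))
  # Galilean invariance: adding uniform translation changes nothing away
  # from the no-slip walls (whose ghosts are frame-fixed)
  st2 <- make_state_with_velocity(mesh,
    function(x, y) 1.7 - Om * (y - 0.05), function(x, y) Om * (x - 0.05))
  vr2 <- vortex_regions(st2)
  ii <- 3:(mesh$nx - 2); jj <- 3:(mesh$ny - 2)
  expect_equal(vr2$lambda2[ii, jj], vr$lambda2[ii, jj], tolerance = 1e-10)
  # slow rotation Om^2 < 10: nothing flagged
  sts <- make_state_with_velocity(mesh,
    function(x, y) -2 * (y - 0.05), function(x, y) 2 * (x - 0.05))
  expect_equal(nrow(vortex_regions(sts)$regions), 0L)
  # pure shear: lambda2 = 0, no flagged cells
  stsh <- make_state_with_velocity(mesh, function(x, y) 50 * y,
                                   function(x, y) 0)
  vrs <- vortex_regions(stsh)
  expect_lt(max(abs(vrs$lambda2[3:(mesh$nx - 2), 3:(mesh$ny - 2)])), 1e-6)
  expect_equal(nrow(vrs$regions), 0L)
  # uniform flow: zero flagged cells
  expect_equal(nrow(vortex_regions(make_state_with_velocity(mesh,
    function(x, y) 0.4, function(x, y) 0))$regions), 0L)
})

test_that("cut-plane pressure differences average the lumen cross-sections", {
  mesh <- generate_fixtures("mini_dissection")
  st <- flow_state(mesh)
  st$p[] <- 90
  st$p[, mesh$tl_rows] <- 110
  cuts <- cut_planes(mesh$domain)
  dp <- cut_plane_dp(st, cuts)
  expect_equal(dp$dp, rep(20, 3))
  expect_setequal(dp$name, c("proximal", "middle", "distal"))
  # identical fields -> zero difference; linear scaling
  st$p[] <- 50
  expect_equal(cut_plane_dp(st, cuts)$dp, rep(0, 3))
  st$p[] <- 90; st$p[, mesh$tl_rows] <- 110
  st2 <- st; st2$p <- 3 * st$p
  expect_equal(cut_plane_dp(st2, cuts)$dp, 3 * dp$dp)
  # cut outside the domain errors
  expect_error(cut_plane_dp(st, data.frame(name = "bad", x = 10)), "outside")
})

test_that("growth-phase segmentation brackets a logistic trace", {
  t <- seq(0, 15, by = 0.05)
  Vmax <- 150; k <- 1.2; t0 <- 7
  V <- Vmax / (1 + exp(-k * (t - t0)))
  ph <- growth_phase_segmentation(t, V, window = 1)
  expect_false(ph$degenerate)
  expect_lt(ph$lag_end, t0)
  expect_gt(ph$accelerated_end, t0)
  expect_equal(ph$plateau_value, V[length(V)], tolerance = 1e-12)
  expect_lt(abs(ph$plateau_value - Vmax) / Vmax, 0.05)
  # rates ordered: accelerated fastest
  expect_gt(ph$phase_rates["accelerated"], ph$phase_rates["lag"])
  expect_gt(ph$phase_rates["accelerated"], ph$phase_rates["plateau"])
  # constant zero trace: degenerate
  expect_true(growth_phase_segmentation(t, rep(0, length(t)))$degenerate)
  # linear ramp: the whole run is accelerated
  ph2 <- growth_phase_segmentation(t, 2 * t, window = 1)
  expect_equal(ph2$lag_end, min(t))
  expect_equal(ph2$accelerated_end, max(t))
  # decreasing trace rejected
  expect_error(growth_phase_segmentation(t, rev(V)), "non-decreasing")
})

test_that("displacement-volume regression recovers exact and noisy lines", {
  r <- displacement_volume_regression(c(0, 1, 2), c(10, 20, 30))
  expect_equal(r$slope, 10)
  expect_equal(r$intercept, 10)
  expect_equal(r$r_squared, 1)
  expect_false(r$underdetermined)
  # two points: perfect fit but flagged under-determined
  r2 <- displacement_volume_regression(c(0, 2), c(5, 9))
  expect_true(r2$underdetermined)
  expect_equal(r2$r_squared, 1)
  # noisy line, n = 100: slope recovered within its standard-error band
  set.seed(7)
  x <- runif(100, 0, 4)
  y <- 147 + 13.5 * x + rnorm(100, sd = 2)
  r3 <- displacement_volume_regression(x, y)
  se <- summary(stats::lm(y ~ x))$coefficients[2, 2]
  expect_lt(abs(r3$slope - 13.5), 3 * se)
  expect_error(displacement_volume_regression(c(1, 1), c(2, 3)), "identical")
})

test_that("cycle summaries are exact area-weighted region means", {
  mesh <- generate_fixtures("mini_dissection")
  st <- flow_state(mesh)
  nx <- mesh$nx; ny <- mesh$ny
  st$cycle_avg <- list(avg_mu = matrix(0.004, nx, ny),
                       avg_gamma = matrix(30, nx, ny),
                       avg_AP = matrix(2, nx, ny), tawss = NULL)
  s <- field_cycle_summary(st)
  expect_equal(s$mean_mu[s$region == "TL"], 0.004)
  expect_equal(s$mean_gamma[s$region == "FL"], 30)
  # empty thrombus region reported as missing, not zero
  expect_true(is.na(s$mean_mu[s$region == "thrombus"]))
  # two-region constructed field: exact weighting
  fld <- matrix(1, nx, ny); fld[, mesh$fl_rows] <- 3
  st$cycle_avg$avg_mu <- fld
  s2 <- field_cycle_summary(st)
  expect_equal(s2$mean_mu[s2$region == "TL"], 1)
  expect_equal(s2$mean_mu[s2$region == "FL"], 3)
})
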