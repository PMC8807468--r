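# Quemada shear-thinning rheology and shear-rate magnitude

test_that("shear-rate magnitude matches closed forms for canonical gradients", {
  # simple shear du/dy = s
  expect_equal(shear_rate_magnitude(matrix(c(0, 0, 3.2, 0), 2, 2)), 3.2)
  expect_equal(shear_rate_magnitude(matrix(c(0, 0, -3.2, 0), 2, 2)), 3.2)
  # rigid-body rotation: antisymmetric gradient, D = 0
  expect_equal(shear_rate_magnitude(matrix(c(0, 2, -2, 0), 2, 2)), 0)
  # pure extension du/dx = a, dv/dy = -a: gamma = sqrt(2*(a^2+a^2)) = 2|a|
  a <- 0.7
  expect_equal(shear_rate_magnitude(diag(c(a, -a))), 2 * a)
  expect_error(shear_rate_magnitude(matrix(c(0, 0, NaN, 0), 2, 2)),
               "non-finite")
})

test_that("Quemada viscosity hits its analytic zero- and high-shear limits", {
  qp <- quemada_params()
  lims <- quemada_limits(qp)
  expect_equal(quemada_viscosity(0, qp), unname(lims["mu_0"]))
  expect_equal(quemada_viscosity(1e12, qp), unname(lims["mu_inf"]),
               tolerance = 1e-3)
  # default high-shear asymptote in the physiological whole-blood band
  expect_gt(lims["mu_inf"], 0.003)
  expect_lt(lims["mu_inf"], 0.006)
  # parameter sets with k*H >= 2 (nonphysical singularity) are rejected
  expect_error(quemada_params(k0 = 5, hematocrit = 0.45), "k\\*H")
})

test_that("Quemada viscosity is continuous, monotone and bounded by its limits", {
  set.seed(42)
  for (rep in 1:20) {
    H <- runif(1, 0.2, 0.6)
    k0 <- runif(1, 1.5, 1.9) * 2 / H * 0.5   # keep k0*H < 1.9
    ki <- runif(1, 0.3, 0.9) * k0
    qp <- quemada_params(hematocrit = H, k0 = k0, k_inf = ki,
                         gamma_c = runif(1, 1, 20))
    g <- sort(c(0, 10^runif(40, -4, 5)))
    mu <- quemada_viscosity(g, qp)
    expect_true(all(diff(mu) <= 1e-12), label = "monotone non-increasing")
    lims <- quemada_limits(qp)
    expect_true(all(mu <= lims["mu_0"] + 1e-12 & mu >= lims["mu_inf"] - 1e-12))
  }
  # continuity: vanishing increments for gamma > 0; at gamma = 0 the
  # regularization floor leaves only a far-sub-percent offset
  qp <- quemada_params()
  for (g in c(1e-6, 1, 100)) {
    eps <- 1e-9
    expect_lt(abs(quemada_viscosity(g + eps, qp) - quemada_viscosity(g, qp)),
              1e-5 * quemada_viscosity(g, qp))
  }
  expect_lt(abs(quemada_viscosity(1e-9, qp) - quemada_viscosity(0, qp)),
            5e-3 * quemada_viscosity(0, qp))
})

test_that("viscosity_field applies rheology pointwise and honors overrides", {
  qp <- quemada_params()
  fl <- fluid_properties(1060, qp)
  g <- matrix(c(0, 1, 10, 100, 1000, 1e4), 2, 3)
  mu <- viscosity_field(g, fl)
  expect_equal(dim(mu), dim(g))
  expect_equal(mu[1, 1], quemada_viscosity(0, qp))
  # uniform shear field -> uniform viscosity
  expect_equal(length(unique(as.numeric(viscosity_field(matrix(50, 3, 3), fl)))), 1L)
  # constant-viscosity override ignores the shear field
  flc <- fluid_properties(1060, 0.004)
  expect_true(all(viscosity_field(g, flc) == 0.004))
  # Poiseuille ordering: highest shear at walls -> lowest viscosity
  yc <- seq(0.025, 0.975, length.out = 20)
  gam <- abs(1 - 2 * yc) * 100             # |du/dy| of a parabola
  mup <- viscosity_field(gam, fl)
  expect_equal(which.max(mup), which.min(gam))
  expect_equal(which.min(mup), which.max(gam))
})
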