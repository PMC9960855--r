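test_that("the water viscosity model matches its correlation values", {
  expect_equal(water_viscosity(10), 1.30e-3, tolerance = 1e-3)
  expect_equal(water_viscosity(20), 1.00e-3, tolerance = 5e-3)
  expect_error(water_viscosity(-5), "0-100")
  expect_error(water_viscosity(120), "0-100")
})

test_that("Stokes-Einstein conversion and its scalings are exact", {
  # D consistent with a 474 Angstroem sphere in 10 degC water
  expect_equal(stokes_einstein(3.3669e-12, 10), 474, tolerance = 1e-3)
  # doubling the viscosity halves the radius at fixed D and T
  r1 <- stokes_einstein(3e-12, 25, viscosity = 1e-3)
  r2 <- stokes_einstein(3e-12, 25, viscosity = 2e-3)
  expect_equal(r1 / r2, 2)
  expect_error(stokes_einstein(-1e-12, 10), "D")
})

test_that("a noise-free single exponential inverts to its rate", {
  m <- dls_model(474, angles = 90, temperature = 10)
  cs <- simulate_dls(m)
  inv <- invert_correlogram(cs$traces[[1]], n_grid = 100)
  qm <- angle_to_q(scattering_geometry(6328, 1.332, 90)) * 1e10
  g_true <- stokes_D(474, 10) * qm^2
  expect_equal(inv$mean_rate, g_true, tolerance = 0.01)
  expect_lt(inv$pdi, 0.02)                      # monodisperse, noise-free
  expect_equal(inv$beta, 0.8, tolerance = 0.01)
  expect_equal(nrow(inv$modes), 1L)             # unimodal distribution
})

test_that("the Gamma grid density does not move the mean rate", {
  m <- dls_model(474, angles = 90, temperature = 10)
  tr <- simulate_dls(m)$traces[[1]]
  m100 <- invert_correlogram(tr, n_grid = 100)$mean_rate
  m200 <- invert_correlogram(tr, n_grid = 200)$mean_rate
  m50 <- invert_correlogram(tr, n_grid = 50)$mean_rate
  expect_lt(abs(m200 - m100) / m100, 0.005)
  expect_lt(abs(m50 - m100) / m100, 0.005)
})

test_that("a bimodal rate distribution is resolved at moderate noise", {
  tau <- 10^seq(-6, 0, length.out = 200)
  g1 <- 0.5 * exp(-500 * tau) + 0.5 * exp(-5000 * tau)
  set.seed(31)
  g2 <- 1 + 0.8 * g1^2 + rnorm(length(tau), sd = 0.02)
  inv <- invert_correlogram(list(tau = tau, g2 = g2), n_grid = 200)
  expect_gte(nrow(inv$modes), 2L)
  big <- inv$modes[order(-inv$modes$weight), ][1:2, ]
  rates <- sort(big$mean_rate)
  # mode positions are recovered on the decade scale (the floor
  # truncation shifts rates upward at this noise level) with comparable
  # weights and a rate ratio near the true factor of ten
  expect_equal(log10(rates[1]), log10(500), tolerance = 0.08)
  expect_equal(log10(rates[2]), log10(5000), tolerance = 0.08)
  expect_gt(min(big$weight), 0.25)
})

test_that("non-decaying and baseline-shifted traces are rejected", {
  tau <- 10^seq(-6, 0, length.out = 100)
  expect_error(invert_correlogram(list(tau = tau, g2 = rep(1, 100))),
               "decay")
  expect_error(invert_correlogram(list(tau = tau,
                                       g2 = 1.2 + 0.8 * exp(-1000 * tau))),
               "baseline")
})

test_that("exact linear Gamma(q^2) data recover the diffusion coefficient", {
  D <- 3.37e-12
  angles <- seq(40, 110, by = 5)
  geom <- list(wavelength = 6328, refractive_index = 1.332, temperature = 10)
  q2 <- vapply(angles, function(a) {
    (angle_to_q(scattering_geometry(6328, 1.332, a)) * 1e10)^2
  }, numeric(1))
  fit <- suppressWarnings(fit_diffusion(D * q2, geom, angles = angles))
  expect_equal(fit$D, D, tolerance = 1e-9)
  expect_equal(fit$D_origin, D, tolerance = 1e-9)
  expect_lt(abs(fit$intercept), 1e-6 * max(D * q2))
  expect_error(fit_diffusion(D * q2[1:2], geom, angles = angles[1:2]),
               "3 angles")
  expect_error(suppressWarnings(fit_diffusion(-D * q2, geom,
                                              angles = angles)),
               "nonphysical")
})

test_that("the diffusion slope is unbiased under 2 percent rate noise", {
  D <- 3.37e-12
  angles <- seq(40, 110, by = 5)
  geom <- list(wavelength = 6328, refractive_index = 1.332, temperature = 10)
  q2 <- vapply(angles, function(a) {
    (angle_to_q(scattering_geometry(6328, 1.332, a)) * 1e10)^2
  }, numeric(1))
  set.seed(99)
  slopes <- vapply(1:100, function(s) {
    rates <- D * q2 * (1 + 0.02 * rnorm(length(q2)))
    fit_diffusion(rates, geom, angles = angles)$D
  }, numeric(1))
  expect_lt(abs(mean(slopes) / D - 1), 0.005)
})

test_that("the full pipeline recovers the radius it simulated, noise-free", {
  for (R in c(200, 474, 1000)) {
    cs <- simulate_dls(dls_model(R, temperature = 10),
                       tau_grid = 10^seq(-6, 0, length.out = 150))
    out <- pcs_pipeline(cs, n_grid = 100)
    expect_equal(out$rh, R, tolerance = 0.01)
  }
})

test_that("the seeded noisy reference preset lands on its nominal radius", {
  cs <- preset_dls_curves(preset("dmpc_pure"), noise_sd = 0.02, seed = 12)
  out <- pcs_pipeline(cs, n_grid = 100)
  expect_equal(out$rh, 474, tolerance = 24 / 474)
  expect_gt(out$diffusion$r_squared, 0.98)
})
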