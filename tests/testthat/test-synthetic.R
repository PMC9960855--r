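test_that("a thin shell scatters like sinc^2(qR) at low q", {
  R <- 460
  m <- vesicle_model(R, polydispersity = 0,
                     profile = data.frame(center = 0, width = 1,
                                          amplitude = 1))
  q <- seq(0.002, 0.02, length.out = 800)
  cv <- simulate_saxs(m, q_grid = q, noise = 0)
  # first minimum of the shell form factor at q = pi / R
  i <- which.min(cv$intensity[q < 0.01])
  expect_equal(q[i], pi / R, tolerance = 2e-3)
  # intensity tracks (sin(qR)/q)^2 for a thin shell away from the zeros
  ref <- (sin(q * R) / q)^2
  sel <- ref > 0.05 * max(ref)
  ratio <- cv$intensity[sel] / ref[sel]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.02)
})

test_that("a degenerate uniform-sphere profile has the Guinier RG of a sphere", {
  R <- 100
  m <- vesicle_model(R, polydispersity = 0,
                     radial_profile = function(r) as.numeric(r <= R))
  q <- seq(0.0005, 0.01, length.out = 60)   # q RG < 0.8
  cv <- simulate_saxs(m, q_grid = q, noise = 0)
  fit <- stats::lm(log(cv$intensity) ~ I(q^2))
  rg <- sqrt(-3 * coef(fit)[2])
  expect_equal(unname(rg), sqrt(3 / 5) * R, tolerance = 0.01)
})

test_that("Schulz averaging converges to the monodisperse curve as width -> 0", {
  prof <- bilayer_profile(head_sep = 35)
  q <- exp(seq(log(0.004), log(0.3), length.out = 200))
  mono <- simulate_saxs(vesicle_model(460, 0, prof), q_grid = q)
  near <- simulate_saxs(vesicle_model(460, 0.001, prof), q_grid = q)
  # a pointwise relative error diverges at the form-factor zeros (any
  # finite width fills them in); measure against the local envelope
  n <- length(q)
  env <- vapply(seq_len(n), function(i) {
    max(mono$intensity[max(1, i - 5):min(n, i + 5)])
  }, numeric(1))
  expect_lt(max(abs(near$intensity - mono$intensity) / env), 0.01)
})

test_that("all generators are reproducible under a fixed seed", {
  pre <- preset("dmpc_pure")
  q <- exp(seq(log(0.004), log(0.6), length.out = 150))
  a <- simulate_saxs(preset_vesicle_model(pre), q_grid = q, seed = 3,
                     noise = 0.02)
  b <- simulate_saxs(preset_vesicle_model(pre), q_grid = q, seed = 3,
                     noise = 0.02)
  expect_identical(a$intensity, b$intensity)
  wa <- preset_waxs_curve(pre, 10, noise = 0.02, seed = 4)
  wb <- preset_waxs_curve(pre, 10, noise = 0.02, seed = 4)
  expect_identical(wa$intensity, wb$intensity)
  da <- preset_dsc_curve(pre, noise_sd = 0.01, seed = 5)
  db <- preset_dsc_curve(pre, noise_sd = 0.01, seed = 5)
  expect_identical(da$heat_flow, db$heat_flow)
  ca <- preset_dls_curves(pre, noise_sd = 0.02, seed = 6)
  cb <- preset_dls_curves(pre, noise_sd = 0.02, seed = 6)
  expect_identical(ca$traces[[5]]$g2, cb$traces[[5]]$g2)
  # and noisy simulation without a seed is refused
  expect_error(simulate_waxs(1.5, 0.02, q_grid = default_waxs_qgrid(),
                             noise = 0.01), "seed")
})

test_that("wide-angle generator peaks where told and scales its width", {
  q <- default_waxs_qgrid()
  cv <- simulate_waxs(1.5, 0.025, amplitude = 1, background = 0.1,
                      q_grid = q)
  expect_equal(q[which.max(cv$intensity)], 1.5, tolerance = 2e-3)
  # doubling the hwhm doubles the measured full width at half maximum
  fwhm <- function(c) {
    y <- c$intensity - 0.1
    above <- range(which(y > max(y) / 2))
    q[above[2]] - q[above[1]]
  }
  w1 <- fwhm(simulate_waxs(1.5, 0.05, 1, 0.1, q_grid = q))
  w2 <- fwhm(simulate_waxs(1.5, 0.10, 1, 0.1, q_grid = q))
  expect_equal(w2 / w1, 2, tolerance = 0.05)
  flat <- simulate_waxs(1.5, 0.05, amplitude = 0, background = 0.1,
                        q_grid = q)
  expect_equal(flat$intensity, rep(0.1, length(q)))
  expect_warning(simulate_waxs(2.5, 0.05, q_grid = q), "outside")
})

test_that("DSC generator produces the configured peak structure", {
  grid <- seq(7, 40, by = 0.05)
  one <- simulate_dsc(dsc_model(data.frame(center = 24.64, hwhm = 0.45,
                                           amplitude = 1)), grid)
  expect_equal(one$temperature[which.max(one$heat_flow)], 24.64,
               tolerance = 0.051)
  two <- simulate_dsc(dsc_model(data.frame(center = c(20, 26),
                                           hwhm = c(0.5, 0.5),
                                           amplitude = c(1, 1))), grid)
  y <- two$heat_flow
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  expect_length(locmax, 2)
  base <- simulate_dsc(dsc_model(data.frame(center = numeric(0),
                                            hwhm = numeric(0),
                                            amplitude = numeric(0)),
                                 baseline = c(0.5, 0.01)), grid)
  expect_equal(base$heat_flow, 0.5 + 0.01 * grid)
})

test_that("DLS generator obeys the Siegert relation and Gamma = D q^2", {
  tau <- 10^seq(-7, 0, length.out = 300)
  m <- dls_model(474, angles = c(40, 60, 80, 100), beta = 1,
                 temperature = 10)
  cs <- simulate_dls(m, tau_grid = tau)
  # beta = 1: g2 -> 2 as tau -> 0
  expect_equal(cs$traces[[1]]$g2[1], 2, tolerance = 1e-3)
  D <- stokes_D(474, 10)
  for (tr in cs$traces) {
    qm <- angle_to_q(scattering_geometry(6328, 1.332, tr$angle)) * 1e10
    # ln(g2 - 1) linear in tau with slope -2 D q^2
    sel <- tr$g2 - 1 > 1e-4
    fit <- stats::lm(log(tr$g2[sel] - 1) ~ tr$tau[sel])
    expect_equal(unname(coef(fit)[2]), -2 * D * qm^2, tolerance = 1e-6)
  }
  # doubling q quadruples the decay rate: check via 40 vs 90.02 degrees
  q40 <- angle_to_q(scattering_geometry(6328, 1.332, 40))
  th2 <- 2 * asin(2 * sin(40 / 2 * pi / 180)) * 180 / pi
  cs2 <- simulate_dls(dls_model(474, angles = c(40, th2), beta = 1,
                                temperature = 10), tau_grid = tau)
  rate <- function(tr) {
    sel <- tr$g2 - 1 > 1e-4
    -coef(stats::lm(log(tr$g2[sel] - 1) ~ tr$tau[sel]))[2] / 2
  }
  expect_equal(unname(rate(cs2$traces[[2]]) / rate(cs2$traces[[1]])), 4,
               tolerance = 1e-6)
  expect_error(dls_model(numeric(0)), "empty")
})

test_that("model constructors reject inconsistent profiles", {
  expect_error(vesicle_model(460, 0.6), "polydispersity")
  expect_error(vesicle_model(20, profile = bilayer_profile(35)), "extent")
  bad <- data.frame(center = c(-17, 0, 17), width = c(3, 4, 3),
                    amplitude = c(1, 0.5, 1))   # tail must be negative
  expect_error(vesicle_model(460, 0.1, bad), "head")
  expect_error(lamellar_component(-0.1), "q1")
  expect_error(dsc_model(data.frame(center = 24, hwhm = -1, amplitude = 1)),
               "hwhm")
})
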