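test_that("molar fractions follow the defining ratio and sum to one", {
  comp <- sample_composition(90, 10, 0)
  expect_equal(molar_fraction(comp, "naproxen"), 0.10)
  expect_equal(molar_fraction(sample_composition(100, 0, 0), "aescin"), 0)
  expect_equal(molar_fraction(sample_composition(89, 10, 1), "aescin"), 0.01)
  # fractions over all three species sum to 1
  comp2 <- sample_composition(89.4, 10, 0.6)
  total <- sum(vapply(c("dmpc", "naproxen", "aescin"),
                      function(s) molar_fraction(comp2, s), numeric(1)))
  expect_equal(total, 1)
  expect_error(sample_composition(0, 0, 0), "at least one")
  expect_error(sample_composition(-1, 2, 0), ">= 0")
})

test_that("angle_to_q reproduces hand-evaluated geometries and limits", {
  # HeNe in water at 90 degrees, evaluated by hand: 4 pi 1.33/6328 sin(45)
  expect_equal(angle_to_q(scattering_geometry(6328, 1.33, 90)),
               1.8676e-3, tolerance = 1e-4)
  # lambda = 2 pi, 180 degrees: q = 2 exactly
  expect_equal(angle_to_q(scattering_geometry(2 * pi, 1, 179.99999)), 2,
               tolerance = 1e-6)
  # strictly increasing in angle, decreasing in wavelength
  angles <- seq(10, 170, by = 10)
  qs <- vapply(angles, function(a)
    angle_to_q(scattering_geometry(6328, 1.33, a)), numeric(1))
  expect_true(all(diff(qs) > 0))
  lams <- seq(4000, 8000, by = 500)
  ql <- vapply(lams, function(l)
    angle_to_q(scattering_geometry(l, 1.33, 90)), numeric(1))
  expect_true(all(diff(ql) < 0))
  expect_error(scattering_geometry(6328, 0.9, 90), "refractive")
  expect_error(scattering_geometry(6328, 1.33, 190), "angle")
})

test_that("curve and thermogram constructors enforce their invariants", {
  expect_error(scattering_curve(c(1, 2, 2), c(1, 1, 1)), "increasing")
  expect_error(scattering_curve(c(-1, 1), c(1, 1)), "> 0")
  expect_error(scattering_curve(c(1, 2), c(1, NA)), "finite")
  expect_error(scattering_curve(c(1, 2), c(1, 1), sigma = c(1, -1)), "sigma")
  expect_error(thermogram(1:5, rnorm(5)), "10 points")
  expect_error(thermogram(c(1:9, 9), rnorm(10)), "increasing")
  expect_error(correlogram_set(list()), "non-empty")
  expect_error(
    correlogram_set(list(list(angle = 90, tau = c(2, 1), g2 = c(1, 1)))),
    "increasing")
})

test_that("adaptive rebin merges as configured and conserves weighted means", {
  q <- seq(0.01, 1, length.out = 100)
  I <- 1 / q^2
  cv <- scattering_curve(q, I)
  # identity configuration
  id <- adaptive_rebin(cv, min_step = 1, min_delta = 0)
  expect_equal(id$q, q)
  expect_equal(id$intensity, I)
  # fixed bins of 4 (brute-force oracle: plain block means)
  rb <- adaptive_rebin(cv, min_step = 4, min_delta = 0)
  expect_length(rb$q, 25)
  expect_equal(rb$intensity, colMeans(matrix(I, nrow = 4)))
  expect_equal(rb$q, colMeans(matrix(q, nrow = 4)))
  expect_true(all(diff(rb$q) > 0))
  # sigma-weighted path: global weighted mean conserved over the full range
  set.seed(1)
  sig <- runif(100, 0.5, 2)
  cvs <- scattering_curve(q, I, sigma = sig)
  rbs <- adaptive_rebin(cvs, min_step = 5, min_delta = 0)
  w_orig <- sum(I / sig^2) / sum(1 / sig^2)
  w_reb <- sum(rbs$intensity / rbs$sigma^2) / sum(1 / rbs$sigma^2)
  expect_equal(w_reb, w_orig, tolerance = 1e-12)
  # merged uncertainty follows inverse-variance pooling
  expect_equal(rbs$sigma[1], 1 / sqrt(sum(1 / sig[1:5]^2)))
  # fractional-width rule produces wider bins at low q on a log-like grid
  rd <- adaptive_rebin(cv, min_step = 1, min_delta = 0.05)
  expect_lt(length(rd$q), length(q))
  expect_true(all(diff(rd$q) > 0))
  expect_error(adaptive_rebin(cv, min_step = 0), "min_step")
  expect_error(adaptive_rebin(cv, min_delta = -1), "min_delta")
})

test_that("curves, thermograms and correlograms round-trip through disk", {
  withr::with_tempdir({
    cv <- scattering_curve(c(0.1, 0.2, 0.3), c(3, 2, 1),
                           sigma = c(0.1, 0.1, 0.2), temperature = 10,
                           kind = "waxs")
    for (ext in c("dat", "csv")) {
      path <- paste0("curve.", ext)
      write_curve(cv, path)
      back <- read_curve(path)
      expect_equal(back$q, cv$q)
      expect_equal(back$intensity, cv$intensity)
      expect_equal(back$sigma, cv$sigma)
      expect_equal(back$temperature, 10)
      expect_equal(back$kind, "waxs")
    }
    tg <- thermogram(seq(7, 40, by = 1), rnorm(34), heating_rate = 0.5)
    write_thermogram(tg, "t.csv")
    tg2 <- read_thermogram("t.csv")
    expect_equal(tg2$temperature, tg$temperature)
    expect_equal(tg2$heat_flow, tg$heat_flow)
    expect_equal(tg2$heating_rate, 0.5)
    cs <- simulate_dls(dls_model(474, angles = c(50, 90), temperature = 10),
                       tau_grid = 10^seq(-6, 0, length.out = 50))
    write_correlogram(cs, "c.csv")
    cs2 <- read_correlogram("c.csv")
    expect_equal(length(cs2$traces), 2)
    expect_equal(cs2$traces[[2]]$g2, cs$traces[[2]]$g2)
    expect_equal(cs2$temperature, 10)
  })
})

test_that("readers report malformed input and honour metadata", {
  withr::with_tempdir({
    writeLines(c("# temperature_C=15", "0.1 1.0", "0.2 abc", "0.3 3.0"),
               "bad.dat")
    expect_error(read_curve("bad.dat"), "line 3")
    writeLines(c("0.3 1.0", "0.1 2.0"), "mono.dat")
    expect_error(read_curve("mono.dat"), "increasing")
    writeLines(c("# temperature_C=15", "# q_unit=nm^-1", "1.0 5.0", "2.0 4.0"),
               "nm.dat")
    cv <- read_curve("nm.dat")
    expect_equal(cv$temperature, 15)
    expect_equal(cv$q, c(0.1, 0.2))  # converted to 1/Angstroem
  })
})
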