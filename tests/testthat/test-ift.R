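test_that("a noise-free solid sphere inverts to the analytic distribution", {
  R <- 100
  res <- ift(sphere_curve(R), ift_config(rmax = 220))
  # p(r) against the closed-form sphere pair-distance distribution
  pan <- sphere_pddf(res$r, R)
  pan <- pan * max(res$p) / max(pan)
  expect_lt(max(abs(res$p - pan)) / max(res$p), 0.02)
  expect_equal(res$rg, sqrt(3 / 5) * R, tolerance = 0.01)
  expect_equal(rg_from_pddf(res), res$rg)
})

test_that("radius of gyration matches closed forms for shells and spikes", {
  # uniform hollow shell: RG^2 = (3/5)(R2^5 - R1^5)/(R2^3 - R1^3)
  res <- ift(shell_curve(440, 475), ift_config(rmax = 1000))
  expect_equal(res$rg, shell_rg(440, 475), tolerance = 0.02)
  # delta-like spike at r = d: RG = d / sqrt(2)
  r <- seq(0, 100, length.out = 2001)
  p <- exp(-(r - 60)^2 / (2 * 0.1^2))
  expect_equal(rg_from_pddf(list(r = r, p = p)), 60 / sqrt(2),
               tolerance = 1e-4)
  # analytic sphere p(r) integrates to sqrt(3/5) R
  expect_equal(rg_from_pddf(list(r = r, p = sphere_pddf(r, 50))),
               sqrt(3 / 5) * 50, tolerance = 1e-4)
  expect_error(rg_from_pddf(list(r = r, p = -p)), "undefined")
})

test_that("a vesicle with head-tail contrast shows the membrane oscillation", {
  cv <- preset_saxs_curve(preset("dmpc_pure"), 10)
  res <- suppressWarnings(ift(cv, ift_config(rmax = 1200)))
  # negative lobe at small r from the +/- contrast of the bilayer
  small_r <- res$r < 50
  expect_lt(min(res$p[small_r]), 0)
  # support extends to about twice the shell radius: nearly all of the
  # distance mass lies below 2.2 R
  beyond <- res$r > 2.2 * 460
  expect_lt(sum(abs(res$p[beyond])), 0.05 * sum(abs(res$p)))
  # the main mass sits around the vesicle diameter, not the membrane
  expect_gt(res$r[which.max(res$p)], 400)
})

test_that("boundary conditions and degenerate inputs behave as documented", {
  cfg <- ift_config(rmax = 220)
  res <- ift(sphere_curve(100), cfg)
  expect_equal(res$p[1], 0)
  expect_equal(res$p[length(res$p)], 0)
  # all-zero intensities: p identically zero, rg undefined and flagged
  q <- sphere_curve(100)$q
  res0 <- suppressWarnings(ift(scattering_curve(q, rep(0, length(q))), cfg))
  expect_equal(max(abs(res0$p)), 0)
  expect_true(is.na(res0$rg))
  expect_true("rg_undefined" %in% res0$flags)
  expect_error(ift(scattering_curve(q[1:30], rep(1, 30)), cfg), "50 points")
  expect_warning(ift(sphere_curve(100, qmin = 0.02), cfg), "extrapolation")
})

test_that("the forward model is self-consistent under re-inversion", {
  cfg <- ift_config(rmax = 220)
  res <- ift(sphere_curve(100), cfg)
  q2 <- exp(seq(log(0.004), log(0.35), length.out = 280))
  fwd <- ift_forward(res, q2)
  res2 <- ift(scattering_curve(q2, fwd), cfg)
  rel_l2 <- sqrt(sum((res2$p - res$p)^2) / sum(res$p^2))
  expect_lt(rel_l2, 0.01)
})

test_that("intensity scaling propagates linearly and leaves RG unchanged", {
  cv <- sphere_curve(100)
  cfg <- ift_config(rmax = 220)
  a <- ift(cv, cfg)
  b <- ift(scattering_curve(cv$q, cv$intensity * 37.5), cfg)
  expect_equal(b$p, a$p * 37.5, tolerance = 1e-8)
  expect_equal(b$rg, a$rg, tolerance = 1e-10)
  expect_equal(b$alpha, a$alpha)
})

test_that("IFT RG agrees with a Guinier fit on the same noise-free curve", {
  # small vesicle measured to low enough q that q RG < 1 is populated
  prof <- bilayer_profile(head_sep = 35)
  m <- vesicle_model(300, 0.08, prof, scale = 1e-14)
  q <- exp(seq(log(5e-4), log(0.3), length.out = 500))
  cv <- simulate_saxs(m, q_grid = q)
  res <- ift(cv, ift_config(rmax = 750))
  guinier <- q < 1 / res$rg
  gfit <- stats::lm(log(cv$intensity[guinier]) ~ I(q[guinier]^2))
  rg_guinier <- sqrt(-3 * coef(gfit)[2])
  expect_equal(res$rg, unname(rg_guinier), tolerance = 0.03)
})

test_that("RG is stable across seeded noisy replicates of the reference vesicle", {
  pre <- preset("dmpc_pure")
  rgs <- vapply(1:20, function(s) {
    cv <- preset_saxs_curve(pre, 10, noise = 0.02, seed = s)
    suppressWarnings(ift(cv, ift_config(rmax = 1050)))$rg
  }, numeric(1))
  expect_lt(sd(rgs) / mean(rgs), 0.02)
})

test_that("the automatic multiplier picks the L-curve corner sensibly", {
  cv <- sphere_curve(100)
  cfg <- ift_config(rmax = 220)
  ladder <- alpha_ladder(1e-4, 1e4, 25)
  # noise-free data: low alpha region (within two ladder steps of the
  # smallest alpha whose solution the sweep already reaches)
  a <- auto_multiplier(cv, cfg, alphas = ladder)
  expect_lte(a, ladder[8])
  # a one-step ladder returns its only value
  expect_equal(auto_multiplier(cv, cfg, alphas = 0.5), 0.5)
})
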