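# Photon correlation spectroscopy: regularized inverse-Laplace relaxation
# analysis of g2(tau), diffusion fit of mean relaxation rate vs q^2, and
# Stokes-Einstein conversion to a hydrodynamic radius.

#' Temperature-dependent viscosity of water
#'
#' eta(T) = 2.414e-5 * 10^(247.8 / (T - 140)) Pa s with T in kelvin
#' (Vogel-type correlation, valid for liquid water between 0 and 100 deg C).
#'
#' @param temperature Temperature \[deg C\].
#' @return Dynamic viscosity \[Pa s\].
#' @examples
#' water_viscosity(10)  # ~1.30e-3 Pa s
#' @export
water_viscosity <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature < 0) ||
      any(temperature > 100)) {
    stop("water viscosity model is valid for 0-100 degC only", call. = FALSE)
  }
  TK <- temperature + 273.15
  2.414e-5 * 10^(247.8 / (TK - 140))
}

#' Inverse-Laplace inversion of a correlogram
#'
#' Solves the Siegert-reduced field correlation
#' sqrt(g2(tau) - 1) = sqrt(beta) * Int G(Gamma) exp(-Gamma tau) dGamma
#' for a non-negative relaxation-rate distribution G on a log-spaced Gamma
#' grid, by Tikhonov-regularized non-negative least squares (CONTIN-style;
#' second-difference penalty). The regularizer is selected on the L-curve
#' unless given. The coherence factor beta is recovered from the tau -> 0
#' amplitude; the mean rate and polydispersity index come from the
#' distribution moments.
#'
#' @param trace A list with `tau` \[s\] and `g2`, e.g. one element of a
#'   [correlogram_set()]'s `traces`.
#' @param regularizer `"auto"` or a positive value.
#' @param n_grid Number of Gamma grid points.
#' @param decades Width of the Gamma grid \[log10 units\], centered on the
#'   apparent decay rate of the trace.
#' @return An object of class `relaxation_result` with fields `Gamma`
#'   (grid \[1/s\]), `G` (normalized distribution), `mean_rate` \[1/s\],
#'   `pdi` (mu2 / mean^2), `beta`, `alpha` (regularizer used) and `angle`
#'   when the trace carries one.
#' @export
invert_correlogram <- function(trace, regularizer = "auto", n_grid = 200,
                               decades = 4) {
  tau <- as.numeric(trace$tau); g2 <- as.numeric(trace$g2)
  stopifnot(length(tau) == length(g2), all(tau > 0),
            !is.unsorted(tau, strictly = TRUE))
  tail_idx <- tau >= stats::quantile(tau, 0.9)
  baseline <- mean(g2[tail_idx])
  if (abs(baseline - 1) > 0.05) {
    stop(sprintf("g2 baseline %.3f deviates from 1 by more than 0.05",
                 baseline), call. = FALSE)
  }
  y2 <- g2 - 1
  if (max(y2) < 0.01) stop("trace does not decay: nothing to invert",
                           call. = FALSE)
  y <- sqrt(pmax(y2, 0))
  # propagated weights for the square-root (Siegert) transform:
  # var(sqrt(y2)) ~ var(g2) / (4 y2). The trace is truncated where the
  # *smoothed* signal falls below twice the noise floor: past that point
  # sqrt(max(y2, 0)) is dominated by clipping bias, and isolated noise
  # excursions above the floor would otherwise masquerade as slow modes.
  noise_sd <- stats::sd(y2[tail_idx])
  have_noise <- is.finite(noise_sd) && noise_sd > 1e-8
  if (have_noise) {
    y2s <- stats::runmed(y2, 7)
    below <- which(y2s < 2 * noise_sd)
    cut <- if (length(below)) below[1] else length(y2) + 1L
    keep <- seq_along(y2) < cut
    # second-order bias correction of the square-root transform, only for
    # points individually above the floor (it diverges as y -> 0)
    fix <- keep & y2 >= 2 * noise_sd
    y[fix] <- y[fix] + noise_sd^2 / (8 * y[fix]^3)
    vr <- noise_sd^2 / (4 * pmax(y2, 4 * noise_sd))
    # beyond the cut the (smoothed) signal is below twice the noise floor:
    # anchor those points at zero with an uncertainty of half the largest
    # field amplitude the floor allows (sd = sqrt(2 noise)/2). This keeps
    # slow components from hiding past the cut without handing individual
    # noise excursions the leverage to masquerade as slow modes, and any
    # genuine sub-floor tail sits within ~2 sd of the anchor.
    y[!keep] <- 0
    vr[!keep] <- noise_sd / 2
    wts <- 1 / sqrt(vr)
    if (sum(keep) < 10) stop("fewer than 10 points above the noise floor",
                             call. = FALSE)
    sd_min <- 1 / max(wts)
    wts <- wts / max(wts)
  } else {
    wts <- rep(1, length(y))
    sd_min <- NA_real_
  }

  # center the Gamma grid on the apparent 1/e decay time
  y0 <- max(y)
  i_e <- which(y <= y0 / exp(1))
  tau_e <- if (length(i_e)) tau[i_e[1]] else tau[length(tau)]
  G0 <- 1 / tau_e
  Gamma <- 10^seq(log10(G0) - decades / 2, log10(G0) + decades / 2,
                  length.out = n_grid)
  A <- exp(-outer(tau, Gamma))
  D <- diff_operator(n_grid, 2)

  solve_alpha <- function(a) {
    Aaug <- rbind(A * wts, sqrt(a) * D)
    baug <- c(y * wts, numeric(nrow(D)))
    s <- nnls_solve(Aaug, baug)
    x <- s$x
    list(x = x,
         rho = sqrt(sum((wts * (y - A %*% x))^2)),
         eta = sqrt(sum((D %*% x)^2)))
  }

  if (identical(regularizer, "auto")) {
    if (have_noise) {
      # For noisy traces the weighted residual is almost flat in alpha (a
      # smooth decay is fit equally well by a spike and by a hump), so
      # neither the L-curve nor the discrepancy principle can resolve the
      # regularizer. Use a noise-scaled default: proportional to the
      # expected weighted residual sum, vanishing in the noise-free limit.
      n_eff <- sum(wts > 0)
      alpha <- 8 * n_eff * sd_min^2
      sol <- solve_alpha(alpha)
    } else {
      ladder <- alpha_ladder(1e-8, 1e2, 21)
      sols <- lapply(ladder, solve_alpha)
      rho <- vapply(sols, `[[`, numeric(1), "rho")
      eta <- vapply(sols, `[[`, numeric(1), "eta")
      pick <- lcurve_corner(rho, eta)
      if (is.na(pick)) {
        # fallback: smallest alpha within 10% of the best attainable residual
        pick <- min(which(rho <= 1.1 * min(rho)))
      }
      alpha <- ladder[pick]
      sol <- sols[[pick]]
    }
  } else {
    stopifnot(is.numeric(regularizer), regularizer > 0)
    alpha <- regularizer
    sol <- solve_alpha(alpha)
  }

  x <- sol$x
  total <- sum(x)
  if (total <= 0) stop("inversion returned an empty distribution",
                       call. = FALSE)
  beta <- total^2
  G <- x / total

  # decompose into contiguous modes (NNLS yields exact zeros between them);
  # headline moments come from the dominant mode, as in peak analysis:
  # low-amplitude satellites at the grid edges are barely constrained by
  # the data yet carry enormous leverage on the raw first moment
  pos <- G > 0
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  midx <- which(runs$values)
  modes <- do.call(rbind, lapply(midx, function(i) {
    id <- starts[i]:ends[i]
    w <- sum(G[id])
    mr <- sum(G[id] * Gamma[id]) / w
    data.frame(weight = w, mean_rate = mr,
               pdi = sum(G[id] * (Gamma[id] - mr)^2) / (w * mr^2))
  }))
  dom <- which.max(modes$weight)
  mean_all <- sum(G * Gamma)
  out <- list(Gamma = Gamma, G = G,
              mean_rate = modes$mean_rate[dom],
              pdi = modes$pdi[dom],
              mode_weight = modes$weight[dom],
              modes = modes,
              mean_rate_all = mean_all,
              pdi_all = sum(G * (Gamma - mean_all)^2) / mean_all^2,
              beta = beta, alpha = alpha,
              angle = trace$angle %||% NA_real_)
  class(out) <- "relaxation_result"
  out
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat(sprintf("<relaxation_result> mean Gamma = %.4g 1/s, PDI = %.3g, beta = %.2f\n",
              x$mean_rate, x$pdi, x$beta))
  invisible(x)
}

#' Invert every trace of a correlogram set
#'
#' @param cs A [correlogram_set()].
#' @param ... Passed to [invert_correlogram()].
#' @return List of `relaxation_result`s.
#' @export
invert_correlogram_set <- function(cs, ...) {
  stopifnot(inherits(cs, "correlogram_set"))
  lapply(cs$traces, invert_correlogram, ...)
}

#' Diffusion coefficient from the angle dependence of the relaxation rate
#'
#' Weighted linear regression of the mean relaxation rate against q^2
#' (Gamma = D_T q^2). The default fit carries a free intercept as a
#' diagnostic for non-diffusive contributions; the through-origin slope is
#' reported alongside.
#'
#' @param rates Either a list of `relaxation_result`s (with angles) or a
#'   numeric vector of mean rates \[1/s\].
#' @param geometry A [correlogram_set()] (geometry fields used) or a list
#'   with `wavelength` \[Angstroem\], `refractive_index`, `temperature`.
#' @param angles Angles \[degrees\] when `rates` is a bare numeric vector.
#' @param weights Optional regression weights (default equal).
#' @return An object of class `diffusion_fit` with fields `D` \[m^2/s\],
#'   `D_se`, `intercept`, `D_origin` (through-origin slope), `r_squared`,
#'   `q2` \[1/m^2\] and `rates`.
#' @export
fit_diffusion <- function(rates, geometry, angles = NULL, weights = NULL) {
  if (is.list(rates) && !is.null(rates[[1]]$mean_rate)) {
    angles <- vapply(rates, `[[`, numeric(1), "angle")
    rates <- vapply(rates, `[[`, numeric(1), "mean_rate")
  }
  if (length(rates) < 3) stop("need at least 3 angles for a diffusion fit",
                              call. = FALSE)
  if (any(angles < 40 | angles > 110)) {
    warning("angles outside the 40-110 degree range", call. = FALSE)
  }
  q <- vapply(angles, function(a) {
    angle_to_q(scattering_geometry(geometry$wavelength,
                                   geometry$refractive_index, a))
  }, numeric(1)) * 1e10                      # 1/Ang -> 1/m
  q2 <- q^2
  w <- weights %||% rep(1, length(rates))
  fit <- stats::lm(rates ~ q2, weights = w)
  cf <- summary(fit)$coefficients
  D <- cf["q2", "Estimate"]
  fit0 <- stats::lm(rates ~ q2 - 1, weights = w)
  if (stats::coef(fit0)["q2"] <= 0 || D <= 0) {
    stop("negative diffusion slope: nonphysical fit", call. = FALSE)
  }
  out <- list(
    D = D, D_se = cf["q2", "Std. Error"],
    intercept = cf["(Intercept)", "Estimate"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    D_origin = unname(stats::coef(fit0)["q2"]),
    r_squared = summary(fit)$r.squared,
    q2 = q2, rates = rates, temperature = geometry$temperature
  )
  class(out) <- "diffusion_fit"
  out
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g +/- %.2g m^2/s (R^2 = %.4f)\n",
              x$D, x$D_se, x$r_squared))
  invisible(x)
}

#' Hydrodynamic radius via the Stokes-Einstein relation
#'
#' RH = kB T / (6 pi eta D_T), reported in Angstroem.
#'
#' @param D Translational diffusion coefficient \[m^2/s\].
#' @param temperature Temperature \[deg C\].
#' @param viscosity `"water-auto"` (temperature-dependent water model) or a
#'   value \[Pa s\].
#' @return Hydrodynamic radius \[Angstroem\].
#' @examples
#' stokes_einstein(3.37e-12, 10)  # ~473 Angstroem
#' @export
stokes_einstein <- function(D, temperature, viscosity = "water-auto") {
  stopifnot(is.finite(D), D > 0)
  eta <- if (identical(viscosity, "water-auto")) {
    water_viscosity(temperature)
  } else {
    stopifnot(is.numeric(viscosity), viscosity > 0)
    viscosity
  }
  TK <- temperature + 273.15
  .kB * TK / (6 * pi * eta * D) * 1e10
}

#' Full PCS pipeline: correlograms to hydrodynamic radius
#'
#' Inverts every trace, fits the diffusion coefficient from Gamma vs q^2
#' and converts it to RH with the Stokes-Einstein relation.
#'
#' The hydrodynamic radius uses the through-origin slope (the relation
#' Gamma = D_T q^2 has no intercept); the free-intercept fit is carried in
#' the result as a diagnostic for non-diffusive contributions.
#'
#' @param cs A [correlogram_set()].
#' @param viscosity `"water-auto"` or a value \[Pa s\].
#' @param ... Passed to [invert_correlogram()].
#' @return A list with `rh` \[Angstroem\], `diffusion` (the
#'   [fit_diffusion()] result), `inversions`, `viscosity` \[Pa s\] and
#'   `mean_pdi`.
#' @export
pcs_pipeline <- function(cs, viscosity = "water-auto", ...) {
  inv <- invert_correlogram_set(cs, ...)
  dif <- fit_diffusion(inv, cs)
  eta <- if (identical(viscosity, "water-auto")) {
    water_viscosity(cs$temperature)
  } else viscosity
  rh <- stokes_einstein(dif$D_origin, cs$temperature, viscosity)
  list(rh = rh, diffusion = dif, inversions = inv, viscosity = eta,
       mean_pdi = mean(vapply(inv, `[[`, numeric(1), "pdi")))
}
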