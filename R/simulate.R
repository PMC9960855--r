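# Synthetic-data generators for the four measurement types. All generators
# are deterministic given a seed; noise = 0 (or noise_sd = 0) gives the
# exact model curve.

#' Vesicle scattering model
#'
#' A spherical shell with a radial excess-scattering-length-density profile
#' built from Gaussian strips placed relative to the bilayer mid-plane
#' (positive head-group strips flanking a negative hydrocarbon-tail strip,
#' the head/tail contrast of a phospholipid bilayer in X-rays). The shell
#' radius is Schulz-distributed with a relative width `polydispersity`.
#'
#' @param mean_radius Mean mid-plane radius \[Angstroem\].
#' @param polydispersity Relative standard deviation of the radius, in
#'   `[0, 0.5)` (Schulz distribution).
#' @param profile Data frame with columns `center` (offset from the bilayer
#'   mid-plane \[Angstroem\]), `width` (Gaussian sigma \[Angstroem\]) and
#'   `amplitude` (signed contrast). Three-strip profiles must be symmetric
#'   with the head(+)/tail(-)/head(+) sign pattern. See [bilayer_profile()].
#' @param background Constant background intensity.
#' @param scale Overall intensity scale.
#' @param radial_profile Optional function `rho(r)` of the absolute radial
#'   coordinate overriding the strip profile (degenerate shapes such as a
#'   uniform sphere); requires `polydispersity = 0`.
#' @return An object of class `vesicle_model`.
#' @export
vesicle_model <- function(mean_radius, polydispersity = 0.1,
                          profile = bilayer_profile(), background = 0,
                          scale = 1, radial_profile = NULL) {
  stopifnot(is.finite(mean_radius), mean_radius > 0)
  if (polydispersity < 0 || polydispersity >= 0.5) {
    stop("polydispersity must be in [0, 0.5)", call. = FALSE)
  }
  if (is.null(radial_profile)) {
    stopifnot(is.data.frame(profile),
              all(c("center", "width", "amplitude") %in% names(profile)))
    if (any(profile$width <= 0)) stop("strip widths must be > 0", call. = FALSE)
    extent <- max(abs(profile$center) + 3 * profile$width)
    if (mean_radius <= extent) {
      stop("mean_radius must exceed the bilayer extent (",
           round(extent, 1), " Ang)", call. = FALSE)
    }
    if (nrow(profile) == 3) {
      ord <- order(profile$center)
      p <- profile[ord, ]
      sym <- isTRUE(all.equal(p$center[1], -p$center[3])) &&
        isTRUE(all.equal(p$width[1], p$width[3])) &&
        isTRUE(all.equal(p$amplitude[1], p$amplitude[3]))
      if (!sym || p$amplitude[1] <= 0 || p$amplitude[2] >= 0) {
        stop("three-strip profiles must be symmetric head(+)/tail(-)/head(+)",
             call. = FALSE)
      }
    }
  } else {
    stopifnot(is.function(radial_profile))
    if (polydispersity > 0) {
      stop("radial_profile overrides require polydispersity = 0", call. = FALSE)
    }
  }
  structure(
    list(mean_radius = mean_radius, polydispersity = polydispersity,
         profile = profile, background = background, scale = scale,
         radial_profile = radial_profile),
    class = "vesicle_model"
  )
}

#' Canonical three-strip bilayer contrast profile
#'
#' @param head_sep Head-to-head separation: distance between the two
#'   head-group strip centers \[Angstroem\].
#' @param head_width,tail_width Gaussian sigmas \[Angstroem\].
#' @param head_amp Positive head-group contrast amplitude.
#' @param tail_amp Negative tail contrast amplitude.
#' @return A data frame usable as `profile` in [vesicle_model()].
#' @export
bilayer_profile <- function(head_sep = 35, head_width = 3, head_amp = 1,
                            tail_width = 4.5, tail_amp = -0.8) {
  data.frame(
    center = c(-head_sep / 2, 0, head_sep / 2),
    width = c(head_width, tail_width, head_width),
    amplitude = c(head_amp, tail_amp, head_amp)
  )
}

#' Lamellar correlation-peak component
#'
#' Additive first- and second-order Bragg-like Lorentzian peaks of a stack
#' of correlated bilayers; the second order is fixed at twice the
#' first-order position.
#'
#' @param q1 First-order peak position \[1/Angstroem\].
#' @param intensity1,intensity2 Peak amplitudes (second order typically
#'   weaker).
#' @param hwhm Lorentzian half width at half maximum \[1/Angstroem\].
#' @return An object of class `lamellar_component`.
#' @export
lamellar_component <- function(q1, intensity1 = 1, intensity2 = 0.3,
                               hwhm = 0.004) {
  stopifnot(q1 > 0, hwhm > 0, intensity1 >= 0, intensity2 >= 0)
  structure(list(q1 = q1, intensity1 = intensity1, intensity2 = intensity2,
                 hwhm = hwhm),
            class = "lamellar_component")
}

.lorentz <- function(x, x0, gamma, A) A * gamma^2 / ((x - x0)^2 + gamma^2)

# Schulz distribution nodes/weights for the shell radius.
# z + 1 = 1/p^2; log-density used to stay finite for tiny polydispersity.
.schulz_nodes <- function(mean_radius, p, n = 51) {
  if (p <= 0) return(list(r = mean_radius, w = 1))
  z <- 1 / p^2 - 1
  sd <- mean_radius * p
  lo <- max(mean_radius - 5 * sd, mean_radius * 1e-3)
  hi <- mean_radius + 5 * sd
  gl <- pracma::gaussLegendre(n, lo, hi)
  logpdf <- (z + 1) * log((z + 1) / mean_radius) + z * log(gl$x) -
    (z + 1) * gl$x / mean_radius - lgamma(z + 1)
  w <- gl$w * exp(logpdf)
  list(r = gl$x, w = w / sum(w))
}

#' Simulate a small-angle scattering curve of polydisperse vesicles
#'
#' The scattering amplitude is the spherically symmetric transform
#' F(q) = 4 pi Int rho(r) r^2 sinc(q r) dr of the radial contrast profile,
#' evaluated by trapezoidal quadrature on a fine r-grid;
#' I(q) = scale * <F^2> over the Schulz radius distribution (51-node
#' Gauss-Legendre), plus optional lamellar peaks and a constant background.
#' Noise is multiplicative Gaussian with the given fractional level and is
#' reflected in the attached `sigma`.
#'
#' @param model A [vesicle_model()].
#' @param lam Optional [lamellar_component()].
#' @param q_grid Strictly increasing q values \[1/Angstroem\].
#' @param seed Integer seed (required when `noise > 0`).
#' @param noise Fractional noise level (0 = deterministic).
#' @param temperature,composition Metadata forwarded to the curve.
#' @param n_r Number of radial quadrature points.
#' @return A [scattering_curve()] of kind `"saxs"`.
#' @export
simulate_saxs <- function(model, lam = NULL, q_grid, seed = NULL, noise = 0,
                          temperature = NA_real_, composition = NULL,
                          n_r = 4096) {
  stopifnot(inherits(model, "vesicle_model"))
  q <- as.numeric(q_grid)
  stopifnot(all(q > 0), !is.unsorted(q, strictly = TRUE))

  nodes <- .schulz_nodes(model$mean_radius, model$polydispersity)
  if (is.null(model$radial_profile)) {
    extent <- max(abs(model$profile$center) + 6 * model$profile$width)
    r_max <- max(nodes$r) + extent
  } else {
    r_max <- 2.5 * model$mean_radius
  }
  r <- seq(0, r_max, length.out = n_r)
  dr <- r[2] - r[1]
  qr <- outer(q, r)
  S <- ifelse(qr == 0, 1, sin(qr) / qr)        # sinc kernel, nq x nr

  P <- vapply(seq_along(nodes$r), function(k) {
    R <- nodes$r[k]
    rho <- if (is.null(model$radial_profile)) {
      rowSums(vapply(seq_len(nrow(model$profile)), function(i) {
        with(model$profile[i, ],
             amplitude * exp(-(r - (R + center))^2 / (2 * width^2)))
      }, numeric(length(r))))
    } else {
      model$radial_profile(r)
    }
    rho * r^2
  }, numeric(length(r)))                        # nr x n_nodes
  Fq <- 4 * pi * dr * (S %*% P)                 # trapezoid (endpoints ~ 0)
  I <- model$scale * drop(Fq^2 %*% nodes$w) + model$background

  if (!is.null(lam)) {
    stopifnot(inherits(lam, "lamellar_component"))
    I <- I + .lorentz(q, lam$q1, lam$hwhm, lam$intensity1) +
      .lorentz(q, 2 * lam$q1, lam$hwhm, lam$intensity2)
  }

  sigma <- NULL
  if (noise > 0) {
    if (is.null(seed)) stop("noisy simulation requires a seed", call. = FALSE)
    set.seed(seed)
    sigma <- noise * abs(I)
    I <- I * (1 + noise * stats::rnorm(length(I)))
  }
  scattering_curve(q, I, sigma = sigma, temperature = temperature,
                   composition = composition, kind = "saxs")
}

#' Simulate a wide-angle chain-packing peak
#'
#' A single Lorentzian on a flat background; the peak position encodes the
#' lateral chain-chain correlation distance 2 pi / qpeak.
#'
#' @param qpeak Peak center \[1/Angstroem\].
#' @param hwhm Lorentzian half width at half maximum \[1/Angstroem\].
#' @param amplitude Peak amplitude.
#' @param background Flat background level.
#' @param q_grid Strictly increasing q values.
#' @param seed Integer seed (required when `noise > 0`).
#' @param noise Fractional multiplicative noise level.
#' @param temperature,composition Metadata forwarded to the curve.
#' @return A [scattering_curve()] of kind `"waxs"`.
#' @export
simulate_waxs <- function(qpeak, hwhm, amplitude = 1, background = 0.1,
                          q_grid, seed = NULL, noise = 0,
                          temperature = NA_real_, composition = NULL) {
  q <- as.numeric(q_grid)
  stopifnot(qpeak > 0, hwhm > 0, amplitude >= 0)
  if (qpeak < min(q) || qpeak > max(q)) {
    warning("qpeak lies outside the q grid", call. = FALSE)
  }
  I <- .lorentz(q, qpeak, hwhm, amplitude) + background
  sigma <- NULL
  if (noise > 0) {
    if (is.null(seed)) stop("noisy simulation requires a seed", call. = FALSE)
    set.seed(seed)
    sigma <- noise * abs(I)
    I <- I * (1 + noise * stats::rnorm(length(I)))
  }
  scattering_curve(q, I, sigma = sigma, temperature = temperature,
                   composition = composition, kind = "waxs")
}

#' DSC thermogram model
#'
#' @param peaks Data frame with columns `center` \[deg C\], `hwhm` \[deg C\]
#'   and `amplitude` (> 0); one row per transition peak.
#' @param baseline Length-2 numeric `c(intercept, slope)` of the linear
#'   instrumental baseline \[mW, mW / deg C\].
#' @param noise_sd Additive Gaussian noise standard deviation \[mW\].
#' @return An object of class `dsc_model`.
#' @export
dsc_model <- function(peaks, baseline = c(0, 0), noise_sd = 0) {
  stopifnot(is.data.frame(peaks),
            all(c("center", "hwhm", "amplitude") %in% names(peaks)))
  if (nrow(peaks) > 0 && (any(peaks$hwhm <= 0) || any(peaks$amplitude <= 0))) {
    stop("peak hwhm and amplitude must be > 0", call. = FALSE)
  }
  stopifnot(length(baseline) == 2, noise_sd >= 0)
  structure(list(peaks = peaks, baseline = baseline, noise_sd = noise_sd),
            class = "dsc_model")
}

#' Simulate a DSC thermogram
#'
#' Sum of Lorentzian transition peaks on a linear baseline with additive
#' Gaussian noise.
#'
#' @param model A [dsc_model()].
#' @param T_grid Strictly increasing temperatures \[deg C\].
#' @param seed Integer seed (required when `model$noise_sd > 0`).
#' @param heating_rate Metadata \[deg C / min\].
#' @return A [thermogram()].
#' @export
simulate_dsc <- function(model, T_grid = seq(7, 40, by = 0.05), seed = NULL,
                         heating_rate = 0.5) {
  stopifnot(inherits(model, "dsc_model"))
  temp <- as.numeric(T_grid)
  hf <- model$baseline[1] + model$baseline[2] * temp
  if (nrow(model$peaks) > 0) {
    for (i in seq_len(nrow(model$peaks))) {
      hf <- hf + with(model$peaks[i, ], .lorentz(temp, center, hwhm, amplitude))
    }
  }
  if (model$noise_sd > 0) {
    if (is.null(seed)) stop("noisy simulation requires a seed", call. = FALSE)
    set.seed(seed)
    hf <- hf + stats::rnorm(length(hf), sd = model$noise_sd)
  }
  thermogram(temp, hf, heating_rate = heating_rate)
}

#' DLS sample/instrument model
#'
#' @param radii Hydrodynamic radii of the diffusing species \[Angstroem\].
#' @param weights Positive intensity weights (normalized internally).
#' @param angles Scattering angles \[degrees\].
#' @param beta Coherence (intercept) factor in `(0, 1]`.
#' @param noise_sd Additive Gaussian noise on g2.
#' @param temperature Sample temperature \[deg C\].
#' @param wavelength Laser wavelength \[Angstroem\].
#' @param refractive_index Solvent refractive index.
#' @return An object of class `dls_model`.
#' @export
dls_model <- function(radii, weights = rep(1, length(radii)),
                      angles = seq(40, 110, by = 5), beta = 0.8,
                      noise_sd = 0, temperature = 10, wavelength = 6328,
                      refractive_index = 1.332) {
  if (length(radii) == 0) stop("species list must not be empty", call. = FALSE)
  stopifnot(all(radii > 0), all(weights > 0),
            length(weights) == length(radii),
            beta > 0, beta <= 1, noise_sd >= 0)
  structure(
    list(radii = radii, weights = weights / sum(weights), angles = angles,
         beta = beta, noise_sd = noise_sd, temperature = temperature,
         wavelength = wavelength, refractive_index = refractive_index),
    class = "dls_model"
  )
}

#' Simulate multi-angle DLS correlograms
#'
#' Per angle, the Siegert relation
#' g2(tau) = 1 + beta * (sum_i w_i exp(-D_i q^2 tau))^2 + noise, with the
#' diffusion coefficient of each species from the Stokes-Einstein relation
#' at the model temperature (water viscosity model) and q from the optical
#' geometry.
#'
#' @param model A [dls_model()].
#' @param tau_grid Strictly increasing positive lag times \[s\].
#' @param seed Integer seed (required when `model$noise_sd > 0`).
#' @return A [correlogram_set()].
#' @export
simulate_dls <- function(model, tau_grid = 10^seq(-6, 0, length.out = 200),
                         seed = NULL) {
  stopifnot(inherits(model, "dls_model"))
  tau <- as.numeric(tau_grid)
  eta <- water_viscosity(model$temperature)
  TK <- model$temperature + 273.15
  D <- .kB * TK / (6 * pi * eta * model$radii * 1e-10)   # m^2/s
  if (model$noise_sd > 0) {
    if (is.null(seed)) stop("noisy simulation requires a seed", call. = FALSE)
    set.seed(seed)
  }
  traces <- lapply(model$angles, function(a) {
    qA <- angle_to_q(scattering_geometry(model$wavelength,
                                         model$refractive_index, a))
    qm <- qA * 1e10                                       # 1/m
    g1 <- colSums(model$weights * exp(-outer(D * qm^2, tau)))
    g2 <- 1 + model$beta * g1^2
    if (model$noise_sd > 0) g2 <- g2 + stats::rnorm(length(tau),
                                                    sd = model$noise_sd)
    list(angle = a, tau = tau, g2 = g2)
  })
  correlogram_set(traces, wavelength = model$wavelength,
                  refractive_index = model$refractive_index,
                  temperature = model$temperature)
}

.kB <- 1.380649e-23  # Boltzmann constant [J/K]
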