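# Built-in presets: a DMPC reference plus a naproxen (10 mol%) series with
# 0.0-1.0 mol% aescin. Each preset carries the composition, the transition
# temperatures of its DSC model, the vesicle geometry for SAXS, a
# wide-angle peak table over 10-45 degC, the lamellar component that
# appears above the melting transition in additive-containing samples, and
# the hydrodynamic radius of its DLS model.
#
# The head-group separation of the bilayer contrast profile is not set
# directly: it is calibrated (one-dimensional root search, cached per
# preset) so that the modified Kratky-Porod pipeline applied to the
# noise-free curve at 10 degC returns the preset's nominal membrane
# thickness. The headline numbers of the study conditions are thereby
# executable end to end rather than stored results.

.preset_table <- data.frame(
  name = c("dmpc_pure", "nap10_aescin00", "nap10_aescin02", "nap10_aescin04",
           "nap10_aescin06", "nap10_aescin08", "nap10_aescin10"),
  n_dmpc = c(100, 90, 89.8, 89.6, 89.4, 89.2, 89),
  n_naproxen = c(0, 10, 10, 10, 10, 10, 10),
  n_aescin = c(0, 0, 0.2, 0.4, 0.6, 0.8, 1.0),
  tm_main = c(24.64, 24.40, 24.32, 24.24, 24.16, 24.08, 24.00),
  tm_domain = c(NA, NA, NA, NA, 22.8, 22.5, 22.2),
  domain_amp = c(0, 0, 0, 0, 0.20, 0.28, 0.35),
  dm_nominal = c(34.72, 34.55, 34.80, 34.60, 34.75, 34.52, 34.75),
  rh = c(474, 450, 562, 674, 786, 898, 1010),
  radius = c(460, 440, 550, 660, 770, 880, 990),
  stringsAsFactors = FALSE
)

#' List the built-in composition presets
#'
#' @param as_json Return a JSON string instead of a data frame.
#' @return Data frame of preset parameters (one row per composition), or a
#'   JSON string.
#' @export
list_presets <- function(as_json = FALSE) {
  if (as_json) {
    return(jsonlite::toJSON(.preset_table, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE))
  }
  .preset_table
}

#' Retrieve a composition preset
#'
#' @param name One of the names in `list_presets()$name`.
#' @return An object of class `vesana_preset`.
#' @export
preset <- function(name) {
  i <- match(name, .preset_table$name)
  if (is.na(i)) {
    stop("unknown preset '", name, "'; see list_presets()", call. = FALSE)
  }
  row <- .preset_table[i, ]
  comp <- sample_composition(row$n_dmpc, row$n_naproxen, row$n_aescin,
                             label = row$name)
  out <- c(as.list(row), list(composition = comp,
                              temperatures = seq(10, 45, by = 5),
                              polydispersity = 0.10))
  class(out) <- "vesana_preset"
  out
}

#' @export
print.vesana_preset <- function(x, ...) {
  cat(sprintf("<vesana_preset> %s: w(naproxen) = %.3f, w(aescin) = %.3f\n",
              x$name, molar_fraction(x$composition, "naproxen"),
              molar_fraction(x$composition, "aescin")))
  cat(sprintf("  Tm = %.2f degC, dm (nominal) = %.2f Ang, RH = %g Ang\n",
              x$tm_main, x$dm_nominal, x$rh))
  invisible(x)
}

#' Default SAXS q-grid of the presets
#'
#' Geometric grid over the instrument range 0.004-0.6 1/Angstroem.
#'
#' @param n Number of points.
#' @return Numeric vector.
#' @export
default_saxs_qgrid <- function(n = 1200) {
  exp(seq(log(0.004), log(0.6), length.out = n))
}

#' Default WAXS q-grid of the presets
#' @param n Number of points.
#' @return Numeric vector covering 1.0-1.8 1/Angstroem.
#' @export
default_waxs_qgrid <- function(n = 400) {
  seq(1.0, 1.8, length.out = n)
}

# calibration cache: head-group separation per (preset, geometry) signature
.preset_cache <- new.env(parent = emptyenv())

.bilayer_widths <- list(head_width = 3, head_amp = 1,
                        tail_width = 4.5, tail_amp = -0.8)

# root-search the head separation so that the Kratky-Porod pipeline on the
# noise-free 10 degC curve returns dm_nominal
.calibrated_head_sep <- function(pre) {
  key <- sprintf("%s_R%g_p%g_dm%g", pre$name, pre$radius,
                 pre$polydispersity, pre$dm_nominal)
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  qfull <- default_saxs_qgrid()
  qcal <- qfull[qfull >= 0.07 & qfull <= 0.32]
  dm_of <- function(hs) {
    prof <- bilayer_profile(head_sep = hs,
                            head_width = .bilayer_widths$head_width,
                            head_amp = .bilayer_widths$head_amp,
                            tail_width = .bilayer_widths$tail_width,
                            tail_amp = .bilayer_widths$tail_amp)
    m <- vesicle_model(pre$radius, pre$polydispersity, prof, scale = 1e-14)
    cv <- simulate_saxs(m, q_grid = qcal, noise = 0)
    mkp_thickness(cv, check_lamellar = FALSE)$dm
  }
  root <- stats::uniroot(function(hs) dm_of(hs) - pre$dm_nominal,
                         interval = c(26, 44), tol = 1e-4)
  .preset_cache[[key]] <- root$root
  root$root
}

#' Vesicle model of a preset at a given temperature
#'
#' Below the melting transition the full-contrast vesicle; the radius grows
#' slightly with temperature (pre-transition swelling). Above the
#' transition the shell contrast collapses (chain melting reduces the
#' electron-density difference) and the overall scale drops.
#'
#' @param pre A [preset()].
#' @param temperature Temperature \[deg C\].
#' @return A [vesicle_model()].
#' @export
preset_vesicle_model <- function(pre, temperature = 10) {
  stopifnot(inherits(pre, "vesana_preset"))
  hs <- .calibrated_head_sep(pre)
  prof <- bilayer_profile(head_sep = hs,
                          head_width = .bilayer_widths$head_width,
                          head_amp = .bilayer_widths$head_amp,
                          tail_width = .bilayer_widths$tail_width,
                          tail_amp = .bilayer_widths$tail_amp)
  below <- temperature < pre$tm_main
  radius <- pre$radius + 2 * (temperature - 10) / 5
  vesicle_model(radius, pre$polydispersity, prof,
                scale = if (below) 1e-14 else 5e-16,
                background = 1e-7)
}

#' Lamellar component of a preset at a given temperature
#'
#' `NULL` below the melting transition and for the additive-free
#' reference. Above it, aescin-containing samples develop a first/second
#' order doublet at q1 = 0.100 (repeat distance 62.8 Angstroem) whose
#' intensity grows with the aescin fraction; the naproxen-only sample shows
#' a weak, broad single first-order signal at lower q.
#'
#' @param pre A [preset()].
#' @param temperature Temperature \[deg C\].
#' @return A [lamellar_component()] or `NULL`.
#' @export
preset_lamellar <- function(pre, temperature = 40) {
  stopifnot(inherits(pre, "vesana_preset"))
  if (temperature < pre$tm_main) return(NULL)
  w <- molar_fraction(pre$composition, "aescin") * 100   # mol%
  if (pre$n_naproxen == 0) return(NULL)                  # stable reference
  if (w == 0) {
    return(lamellar_component(q1 = 0.088, intensity1 = 1.5e-4,
                              intensity2 = 0, hwhm = 0.012))
  }
  amp <- (0.5 + 1.5 * w) * 1e-3
  lamellar_component(q1 = 0.100, intensity1 = amp, intensity2 = 0.4 * amp,
                     hwhm = 0.004)
}

#' Synthetic SAXS curve of a preset
#'
#' @param pre A [preset()].
#' @param temperature Temperature \[deg C\].
#' @param q_grid q values (default [default_saxs_qgrid()]).
#' @param noise Fractional noise level.
#' @param seed Seed when `noise > 0`.
#' @return A [scattering_curve()].
#' @export
preset_saxs_curve <- function(pre, temperature = 10,
                              q_grid = default_saxs_qgrid(), noise = 0,
                              seed = NULL) {
  simulate_saxs(preset_vesicle_model(pre, temperature),
                lam = preset_lamellar(pre, temperature),
                q_grid = q_grid, seed = seed, noise = noise,
                temperature = temperature, composition = pre$composition)
}

#' Wide-angle peak parameters of a preset
#'
#' Chain-packing peak positions over the 10-45 degC ladder: a sharp peak
#' near 1.50 1/Angstroem in the ordered (gel) phase that moves to lower q
#' and broadens in the fluid phase; above the transition the additives
#' compress the chains (peak at slightly higher q). These values are
#' plausible chain-packing positions, not measured fixtures. The sample
#' with 1.0 mol% aescin aggregates on heating and its table stops at
#' 25 degC.
#'
#' @param pre A [preset()].
#' @return Data frame with `temperature`, `qpeak`, `hwhm`, `amplitude`.
#' @export
preset_waxs_table <- function(pre) {
  stopifnot(inherits(pre, "vesana_preset"))
  temps <- pre$temperatures
  if (pre$n_aescin >= 1.0 && pre$n_naproxen > 0) {
    temps <- temps[temps <= 25]
  }
  w <- molar_fraction(pre$composition, "aescin") * 100
  has_nap <- pre$n_naproxen > 0
  below <- temps < pre$tm_main
  qpeak <- ifelse(below,
                  1.504 - 4e-4 * (temps - 10),
                  1.455 - 5e-4 * (temps - 30) +
                    0.004 * has_nap + 0.008 * w)
  hwhm <- ifelse(below, 0.025, 0.12)
  data.frame(temperature = temps, qpeak = qpeak, hwhm = hwhm,
             amplitude = ifelse(below, 1.0, 0.45))
}

#' Synthetic WAXS curve of a preset
#'
#' @param pre A [preset()].
#' @param temperature One of the preset's tabulated temperatures.
#' @param q_grid q values.
#' @param noise Fractional noise level.
#' @param seed Seed when `noise > 0`.
#' @return A [scattering_curve()] of kind `"waxs"`.
#' @export
preset_waxs_curve <- function(pre, temperature = 10,
                              q_grid = default_waxs_qgrid(), noise = 0,
                              seed = NULL) {
  tab <- preset_waxs_table(pre)
  i <- match(temperature, tab$temperature)
  if (is.na(i)) {
    stop("temperature not tabulated for this preset (aggregation above the ",
         "transition?)", call. = FALSE)
  }
  simulate_waxs(tab$qpeak[i], tab$hwhm[i], tab$amplitude[i],
                background = 0.1, q_grid = q_grid, seed = seed,
                noise = noise, temperature = temperature,
                composition = pre$composition)
}

#' DSC model of a preset
#'
#' A sharp main transition peak; from 0.6 mol% aescin a broad second peak
#' below the main transition encodes the aescin-rich domains.
#'
#' @param pre A [preset()].
#' @param noise_sd Additive noise standard deviation \[mW\].
#' @return A [dsc_model()].
#' @export
preset_dsc_model <- function(pre, noise_sd = 0) {
  stopifnot(inherits(pre, "vesana_preset"))
  peaks <- data.frame(center = pre$tm_main, hwhm = 0.45, amplitude = 1.0)
  if (!is.na(pre$tm_domain)) {
    peaks <- rbind(peaks, data.frame(center = pre$tm_domain, hwhm = 1.2,
                                     amplitude = pre$domain_amp))
  }
  dsc_model(peaks, baseline = c(0.02, 0.001), noise_sd = noise_sd)
}

#' Synthetic DSC thermogram of a preset
#'
#' @param pre A [preset()].
#' @param T_grid Temperature grid \[deg C\].
#' @param noise_sd Additive noise standard deviation.
#' @param seed Seed when `noise_sd > 0`.
#' @return A [thermogram()].
#' @export
preset_dsc_curve <- function(pre, T_grid = seq(7, 40, by = 0.05),
                             noise_sd = 0, seed = NULL) {
  simulate_dsc(preset_dsc_model(pre, noise_sd), T_grid = T_grid, seed = seed)
}

#' DLS model of a preset
#'
#' A single diffusing species at the preset's hydrodynamic radius, measured
#' at 10 degC over the 40-110 degree angle ladder.
#'
#' @param pre A [preset()].
#' @param noise_sd Additive noise on g2.
#' @return A [dls_model()].
#' @export
preset_dls_model <- function(pre, noise_sd = 0) {
  stopifnot(inherits(pre, "vesana_preset"))
  dls_model(radii = pre$rh, weights = 1, angles = seq(40, 110, by = 5),
            beta = 0.8, noise_sd = noise_sd, temperature = 10,
            wavelength = 6328, refractive_index = 1.332)
}

#' Synthetic multi-angle correlograms of a preset
#'
#' @param pre A [preset()].
#' @param tau_grid Lag times \[s\].
#' @param noise_sd Additive noise on g2.
#' @param seed Seed when `noise_sd > 0`.
#' @return A [correlogram_set()].
#' @export
preset_dls_curves <- function(pre, tau_grid = 10^seq(-6, 0, length.out = 200),
                              noise_sd = 0, seed = NULL) {
  simulate_dls(preset_dls_model(pre, noise_sd), tau_grid = tau_grid,
               seed = seed)
}
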