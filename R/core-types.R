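#' Sample composition bookkeeping
#'
#' Holds the mole counts of the three components of a vesicle sample:
#' the matrix lipid (DMPC), the drug (naproxen) and the saponin (aescin).
#' Units are arbitrary but must be consistent across the three counts.
#'
#' @param n_dmpc,n_naproxen,n_aescin Non-negative mole counts; at least one
#'   must be positive.
#' @param label Free-text sample label.
#' @return An object of class `sample_composition`.
#' @examples
#' comp <- sample_composition(90, 10, 0, label = "nap10")
#' molar_fraction(comp, "naproxen")
#' @export
sample_composition <- function(n_dmpc, n_naproxen = 0, n_aescin = 0,
                               label = "") {
  n <- c(n_dmpc, n_naproxen, n_aescin)
  if (length(n) != 3L || !all(is.finite(n))) {
    stop("mole counts must be three finite numbers", call. = FALSE)
  }
  if (any(n < 0)) stop("mole counts must be >= 0", call. = FALSE)
  if (sum(n) <= 0) stop("at least one mole count must be > 0", call. = FALSE)
  structure(
    list(n_dmpc = n_dmpc, n_naproxen = n_naproxen, n_aescin = n_aescin,
         label = as.character(label)),
    class = "sample_composition"
  )
}

#' @export
print.sample_composition <- function(x, ...) {
  cat(sprintf("<sample_composition> %s\n", x$label))
  cat(sprintf("  n(DMPC) = %g, n(naproxen) = %g, n(aescin) = %g\n",
              x$n_dmpc, x$n_naproxen, x$n_aescin))
  cat(sprintf("  w(naproxen) = %.4f, w(aescin) = %.4f\n",
              molar_fraction(x, "naproxen"), molar_fraction(x, "aescin")))
  invisible(x)
}

#' Molar fraction of an additive
#'
#' w(species) = n_species / (n_DMPC + n_naproxen + n_aescin).
#'
#' @param composition A [sample_composition()].
#' @param species One of `"naproxen"`, `"aescin"` or `"dmpc"`.
#' @return A fraction in `[0, 1]`.
#' @export
molar_fraction <- function(composition, species = c("naproxen", "aescin", "dmpc")) {
  stopifnot(inherits(composition, "sample_composition"))
  species <- match.arg(species)
  total <- composition$n_dmpc + composition$n_naproxen + composition$n_aescin
  if (total <= 0) stop("total moles must be > 0", call. = FALSE)
  n <- switch(species,
    naproxen = composition$n_naproxen,
    aescin = composition$n_aescin,
    dmpc = composition$n_dmpc
  )
  n / total
}

#' Scattering curve container
#'
#' A one-dimensional scattering curve I(q), shared by SAXS and WAXS. The
#' q-grid is stored in reciprocal Angstroem and must be strictly increasing
#' and positive. Points can be masked (kept in storage, excluded from fits),
#' e.g. for known detector artifacts.
#'
#' @param q Strictly increasing positive scattering-vector magnitudes
#'   \[1/Angstroem\].
#' @param intensity Finite intensities, same length as `q` (arbitrary units).
#' @param sigma Optional positive point-wise uncertainties.
#' @param temperature Sample temperature \[deg C\] (metadata).
#' @param composition Optional [sample_composition()].
#' @param kind `"saxs"` or `"waxs"`.
#' @param mask Logical vector; `TRUE` marks points excluded from analysis.
#' @return An object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, temperature = NA_real_,
                             composition = NULL, kind = c("saxs", "waxs"),
                             mask = NULL) {
  kind <- match.arg(kind)
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) {
    stop("q and intensity must have equal length", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("q must be finite and > 0", call. = FALSE)
  }
  if (is.unsorted(q, strictly = TRUE)) {
    stop("q must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensity))) stop("intensity must be finite", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length mismatch", call. = FALSE)
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("sigma must be finite and > 0", call. = FALSE)
    }
  }
  if (is.null(mask)) mask <- rep(FALSE, length(q))
  mask <- as.logical(mask)
  if (length(mask) != length(q) || any(is.na(mask))) {
    stop("mask must be a logical vector matching q", call. = FALSE)
  }
  if (!is.null(composition)) stopifnot(inherits(composition, "sample_composition"))
  structure(
    list(q = q, intensity = intensity, sigma = sigma,
         temperature = as.numeric(temperature), composition = composition,
         kind = kind, mask = mask),
    class = "scattering_curve"
  )
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve:%s> %d points, q in [%.4g, %.4g] 1/Ang",
              x$kind, length(x$q), min(x$q), max(x$q)))
  if (is.finite(x$temperature)) cat(sprintf(", T = %g degC", x$temperature))
  if (any(x$mask)) cat(sprintf(", %d masked", sum(x$mask)))
  cat(if (is.null(x$sigma)) ", no sigma\n" else ", with sigma\n")
  invisible(x)
}

#' DSC thermogram container
#'
#' Heat-flow difference trace (sample minus reference) versus temperature.
#'
#' @param temperature Strictly increasing temperatures \[deg C\], length >= 10.
#' @param heat_flow Heat-flow values \[mW\], same length.
#' @param heating_rate Heating rate \[deg C / min\] (metadata).
#' @return An object of class `thermogram`.
#' @export
thermogram <- function(temperature, heat_flow, heating_rate = NA_real_) {
  temperature <- as.numeric(temperature); heat_flow <- as.numeric(heat_flow)
  if (length(temperature) != length(heat_flow)) {
    stop("temperature and heat_flow must have equal length", call. = FALSE)
  }
  if (length(temperature) < 10L) {
    stop("a thermogram needs at least 10 points", call. = FALSE)
  }
  if (any(!is.finite(temperature)) || is.unsorted(temperature, strictly = TRUE)) {
    stop("temperature must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(heat_flow))) stop("heat_flow must be finite", call. = FALSE)
  structure(
    list(temperature = temperature, heat_flow = heat_flow,
         heating_rate = as.numeric(heating_rate)),
    class = "thermogram"
  )
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("<thermogram> %d points, T in [%.2f, %.2f] degC\n",
              length(x$temperature), min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Light-scattering geometry
#'
#' Wavelength, solvent refractive index and scattering angle, as needed to
#' convert an angle to a scattering-vector magnitude.
#'
#' @param wavelength Laser/X-ray wavelength \[Angstroem\] (HeNe: 6328).
#' @param refractive_index Solvent refractive index (>= 1; 1 for X-rays).
#' @param angle Scattering angle \[degrees\], in (0, 180).
#' @return An object of class `scattering_geometry`.
#' @export
scattering_geometry <- function(wavelength, refractive_index = 1, angle = 90) {
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop("wavelength must be > 0", call. = FALSE)
  }
  if (!is.finite(refractive_index) || refractive_index < 1) {
    stop("refractive_index must be >= 1", call. = FALSE)
  }
  if (!is.finite(angle) || angle <= 0 || angle >= 180) {
    stop("angle must be in (0, 180) degrees", call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, refractive_index = refractive_index,
         angle = angle),
    class = "scattering_geometry"
  )
}

#' Scattering-vector magnitude from geometry
#'
#' q = 4 pi n / lambda * sin(theta / 2). The result carries the inverse of
#' the wavelength unit (Angstroem in, 1/Angstroem out).
#'
#' @param geom A [scattering_geometry()].
#' @return Scattering-vector magnitude.
#' @examples
#' # HeNe laser in water, 90 degrees
#' angle_to_q(scattering_geometry(6328, 1.33, 90))
#' @export
angle_to_q <- function(geom) {
  stopifnot(inherits(geom, "scattering_geometry"))
  4 * pi * geom$refractive_index / geom$wavelength *
    sin(geom$angle * pi / 180 / 2)
}

#' Multi-angle correlogram container
#'
#' A set of intensity autocorrelation traces g2(tau), one per scattering
#' angle, with the shared optical geometry and sample temperature needed for
#' the diffusion analysis.
#'
#' @param traces A list; each element a list with fields `angle` \[degrees\],
#'   `tau` (strictly increasing positive lag times \[s\]) and `g2`.
#' @param wavelength Laser wavelength \[Angstroem\].
#' @param refractive_index Solvent refractive index.
#' @param temperature Sample temperature \[deg C\].
#' @return An object of class `correlogram_set`.
#' @export
correlogram_set <- function(traces, wavelength = 6328, refractive_index = 1.332,
                            temperature = 25) {
  if (!is.list(traces) || length(traces) == 0) {
    stop("traces must be a non-empty list", call. = FALSE)
  }
  for (tr in traces) {
    if (!all(c("angle", "tau", "g2") %in% names(tr))) {
      stop("each trace needs fields angle, tau, g2", call. = FALSE)
    }
    if (length(tr$tau) != length(tr$g2)) {
      stop("tau and g2 must have equal length", call. = FALSE)
    }
    if (any(tr$tau <= 0) || is.unsorted(tr$tau, strictly = TRUE)) {
      stop("tau must be positive and strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(traces = traces, wavelength = wavelength,
         refractive_index = refractive_index,
         temperature = as.numeric(temperature)),
    class = "correlogram_set"
  )
}

#' @export
print.correlogram_set <- function(x, ...) {
  angs <- vapply(x$traces, function(t) t$angle, numeric(1))
  cat(sprintf("<correlogram_set> %d angles (%g-%g deg), T = %g degC\n",
              length(angs), min(angs), max(angs), x$temperature))
  invisible(x)
}

#' Adaptive (dynamic) rebinning of a scattering curve
#'
#' Greedy forward merging of adjacent points: a bin is closed once it holds
#' at least `min_step` points and its fractional q-width
#' (q_last - q_first) / q_center is at least `min_delta`. Within a bin the
#' intensity is the 1/sigma^2-weighted mean, q the same-weighted centroid,
#' and the merged uncertainty 1 / sqrt(sum(1 / sigma_i^2)). Without sigma,
#' plain means are used and no uncertainty is attached.
#'
#' `min_step = 1, min_delta = 0` is the identity. Masked points are dropped
#' before binning (they are excluded from every analysis anyway).
#'
#' @param curve A [scattering_curve()].
#' @param min_step Minimum number of points per bin (>= 1).
#' @param min_delta Minimum fractional q-width of a bin (>= 0).
#' @return A rebinned [scattering_curve()].
#' @export
adaptive_rebin <- function(curve, min_step = 1, min_delta = 0.005) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (!is.finite(min_step) || min_step < 1) {
    stop("min_step must be >= 1", call. = FALSE)
  }
  if (!is.finite(min_delta) || min_delta < 0) {
    stop("min_delta must be >= 0", call. = FALSE)
  }
  keep <- !curve$mask
  q <- curve$q[keep]; I <- curve$intensity[keep]
  s <- if (is.null(curve$sigma)) NULL else curve$sigma[keep]
  n <- length(q)
  if (n == 0) stop("all points are masked", call. = FALSE)
  w <- if (is.null(s)) rep(1, n) else 1 / s^2

  qb <- Ib <- sb <- numeric(0)
  i <- 1L
  while (i <= n) {
    j <- i
    repeat {
      count_ok <- (j - i + 1L) >= min_step
      qc <- (q[i] + q[j]) / 2
      width_ok <- (q[j] - q[i]) / qc >= min_delta
      if ((count_ok && width_ok) || j == n) break
      j <- j + 1L
    }
    idx <- i:j
    W <- sum(w[idx])
    qb <- c(qb, sum(w[idx] * q[idx]) / W)
    Ib <- c(Ib, sum(w[idx] * I[idx]) / W)
    if (!is.null(s)) sb <- c(sb, 1 / sqrt(W))
    i <- j + 1L
  }
  scattering_curve(qb, Ib, sigma = if (is.null(s)) NULL else sb,
                   temperature = curve$temperature,
                   composition = curve$composition, kind = curve$kind)
}
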