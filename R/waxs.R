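# Wide-angle analysis: chain-chain correlation distance d = 2 pi / qpeak
# from a Lorentzian fit of the chain-packing peak.

#' Fit the wide-angle chain-packing peak
#'
#' Fits a Lorentzian plus linear background to the unmasked points inside
#' `window` by Levenberg-Marquardt least squares and converts the fitted
#' center to the chain-chain correlation distance d = 2 pi / qpeak, with
#' the uncertainty propagated as sigma_d = 2 pi sigma_q / qpeak^2. Points
#' inside `mask_regions` (e.g. a known detector artifact) are excluded on
#' top of the curve's own mask.
#'
#' @param curve A [scattering_curve()] (kind `"waxs"`).
#' @param window `c(qlo, qhi)` fit window \[1/Angstroem\].
#' @param mask_regions List of `c(qlo, qhi)` intervals to exclude; the
#'   default covers the detector artifact near 1.3 (1/Angstroem).
#' @param shape `"lorentzian"` (default) or `"pseudo-voigt"` (an extra
#'   Gaussian-mixing parameter, useful for the broadened fluid-phase peak).
#' @return An object of class `waxs_fit` with fields `qpeak`, `qpeak_se`,
#'   `d_waxs`, `d_waxs_se`, `hwhm`, `temperature`.
#' @export
fit_waxs_peak <- function(curve, window = c(1.1, 1.75),
                          mask_regions = list(c(1.28, 1.34)),
                          shape = c("lorentzian", "pseudo-voigt")) {
  stopifnot(inherits(curve, "scattering_curve"))
  shape <- match.arg(shape)
  keep <- !curve$mask & curve$q >= window[1] & curve$q <= window[2]
  for (mr in mask_regions) {
    keep <- keep & !(curve$q >= mr[1] & curve$q <= mr[2])
  }
  if (sum(keep) < 8) stop("window contains fewer than 8 unmasked points",
                          call. = FALSE)
  q <- curve$q[keep]; I <- curve$intensity[keep]
  w <- if (is.null(curve$sigma)) rep(1, sum(keep)) else 1 / curve$sigma[keep]^2

  i0 <- which.max(I)
  start <- list(c0 = q[i0], g = diff(window) / 10,
                A = max(I) - stats::median(I),
                b0 = stats::median(I), b1 = 0)
  dat <- data.frame(x = q, y = I)
  form <- if (shape == "lorentzian") {
    y ~ b0 + b1 * x + A * g^2 / ((x - c0)^2 + g^2)
  } else {
    start$eta <- 0.5
    y ~ b0 + b1 * x + A * (eta * g^2 / ((x - c0)^2 + g^2) +
      (1 - eta) * exp(-log(2) * (x - c0)^2 / g^2))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("peak fit did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  qpeak <- unname(cf["c0"])
  if (qpeak < window[1] || qpeak > window[2]) {
    stop(sprintf("fitted peak center %.4g outside window [%g, %g]",
                 qpeak, window[1], window[2]), call. = FALSE)
  }
  se <- tryCatch(summary(fit)$coefficients["c0", "Std. Error"],
                 error = function(e) NA_real_)
  out <- list(
    qpeak = qpeak, qpeak_se = se,
    d_waxs = 2 * pi / qpeak,
    d_waxs_se = 2 * pi * se / qpeak^2,
    hwhm = unname(abs(cf["g"])),
    temperature = curve$temperature
  )
  class(out) <- "waxs_fit"
  out
}

#' @export
print.waxs_fit <- function(x, ...) {
  cat(sprintf("<waxs_fit> qpeak = %.4f +/- %.4f 1/Ang, d = %.3f +/- %.3f Ang",
              x$qpeak, x$qpeak_se, x$d_waxs, x$d_waxs_se))
  if (is.finite(x$temperature)) cat(sprintf(" (T = %g degC)", x$temperature))
  cat("\n")
  invisible(x)
}

#' Chain-chain correlation distance across a temperature series
#'
#' @param curves List of WAXS [scattering_curve()]s with distinct
#'   `temperature` metadata.
#' @param ... Passed on to [fit_waxs_peak()].
#' @return A data frame with columns `temperature`, `qpeak`, `qpeak_se`,
#'   `d_waxs`, `d_waxs_se`, ordered by temperature.
#' @export
d_waxs_series <- function(curves, ...) {
  if (length(curves) == 0) {
    return(data.frame(temperature = numeric(0), qpeak = numeric(0),
                      qpeak_se = numeric(0), d_waxs = numeric(0),
                      d_waxs_se = numeric(0)))
  }
  temps <- vapply(curves, function(cv) cv$temperature, numeric(1))
  if (anyNA(temps)) stop("every curve needs temperature metadata",
                         call. = FALSE)
  if (anyDuplicated(temps)) stop("duplicate temperatures in series",
                                 call. = FALSE)
  fits <- lapply(curves, fit_waxs_peak, ...)
  out <- data.frame(
    temperature = temps,
    qpeak = vapply(fits, `[[`, numeric(1), "qpeak"),
    qpeak_se = vapply(fits, `[[`, numeric(1), "qpeak_se"),
    d_waxs = vapply(fits, `[[`, numeric(1), "d_waxs"),
    d_waxs_se = vapply(fits, `[[`, numeric(1), "d_waxs_se")
  )
  out[order(out$temperature), , drop = FALSE]
}
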