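# DSC analysis: baseline handling, candidate-peak detection and
# multi-Lorentzian fitting of the main phase-transition temperature(s).

#' Detect candidate transition peaks in a thermogram
#'
#' The linear instrumental baseline is estimated robustly from the trace
#' (least squares on the lower half of the residual distribution, two
#' passes), then local maxima of the baseline-subtracted signal exceeding
#' `min_prominence` times its maximum excursion are returned, ordered by
#' temperature. Candidates closer than one half width are merged, keeping
#' the more prominent one.
#'
#' @param tg A [thermogram()].
#' @param min_prominence Fraction of the maximum baseline-subtracted signal
#'   a local maximum must exceed.
#' @return Numeric vector of candidate peak temperatures \[deg C\]
#'   (empty for a flat trace).
#' @export
detect_peaks <- function(tg, min_prominence = 0.1) {
  stopifnot(inherits(tg, "thermogram"))
  temp <- tg$temperature; hf <- tg$heat_flow
  base <- .robust_baseline(temp, hf)
  # light median smoothing so single-point noise excursions do not
  # register as local maxima
  y <- stats::runmed(hf - base, 5)
  top <- max(y)
  if (!is.finite(top) || top <= 0) return(numeric(0))
  # guard against pure baseline + numerical fuzz
  if (top < 1e-12 * max(abs(hf), 1)) return(numeric(0))
  thr <- min_prominence * top
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  cand <- which(is_max & y > thr)
  if (length(cand) == 0) return(numeric(0))
  # merge candidates within the local half width, keep higher prominence
  ord <- cand[order(-y[cand])]
  kept <- integer(0)
  for (i in ord) {
    hw <- .half_width_at(temp, y, i)
    if (all(abs(temp[i] - temp[kept]) > hw)) kept <- c(kept, i)
  }
  sort(temp[kept])
}

.robust_baseline <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  for (k in 1:2) {
    res <- y - cbind(1, x) %*% fit$coefficients
    keep <- res <= stats::median(res)
    fit <- stats::lm.fit(cbind(1, x[keep]), y[keep])
  }
  drop(cbind(1, x) %*% fit$coefficients)
}

# half width at half maximum around a local maximum, by grid scan
.half_width_at <- function(x, y, i) {
  half <- y[i] / 2
  right <- which(y[i:length(y)] < half)
  left <- which(rev(y[1:i]) < half)
  xr <- if (length(right)) x[i + right[1] - 1] else x[length(x)]
  xl <- if (length(left)) x[i - left[1] + 1] else x[1]
  max((xr - xl) / 2, x[2] - x[1])
}

#' Fit transition temperature(s) by multi-Lorentzian least squares
#'
#' Fits a linear baseline plus `n_peaks` Lorentzians
#' A * gamma^2 / ((T - T0)^2 + gamma^2) jointly by Levenberg-Marquardt
#' nonlinear least squares. Start values come from [detect_peaks()]. With
#' `n_peaks = "auto"`, a second peak is accepted when it improves the
#' reduced chi-square by at least 10 percent and its amplitude exceeds
#' three times its standard error (the shoulder criterion for additive-rich
#' domains).
#'
#' @param tg A [thermogram()].
#' @param n_peaks 1, 2 or `"auto"`.
#' @param window Optional `c(Tlo, Thi)` restricting the fit range \[deg C\].
#' @return An object of class `tm_fit` with fields `centers`, `hwhms`,
#'   `amplitudes`, `baseline`, standard errors (`centers_se`, `hwhms_se`,
#'   `amplitudes_se`), `chi2red`, `converged` and `n_peaks`. Peaks are
#'   ordered by decreasing temperature, so `centers[1]` is the main
#'   (highest-temperature) transition.
#' @export
fit_tm <- function(tg, n_peaks = 1, window = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  temp <- tg$temperature; hf <- tg$heat_flow
  if (!is.null(window)) {
    keep <- temp >= window[1] & temp <= window[2]
    if (sum(keep) < 10) stop("window contains too few points", call. = FALSE)
    temp <- temp[keep]; hf <- hf[keep]
  }
  auto <- identical(n_peaks, "auto")
  if (!auto && !(n_peaks %in% c(1, 2))) {
    stop("n_peaks must be 1, 2 or 'auto'", call. = FALSE)
  }
  cand <- detect_peaks(thermogram(temp, hf), min_prominence = 0.05)
  if (length(cand) == 0) stop("no candidate peaks to initialize from",
                              call. = FALSE)
  if (auto) {
    f1 <- .fit_tm_n(temp, hf, 1, cand)
    f2 <- tryCatch(.fit_tm_n(temp, hf, 2, cand), error = function(e) NULL)
    if (!is.null(f2) && is.finite(f2$chi2red) &&
        f2$chi2red <= 0.9 * f1$chi2red &&
        min(f2$amplitudes / f2$amplitudes_se, na.rm = TRUE) > 3) {
      return(f2)
    }
    return(f1)
  }
  .fit_tm_n(temp, hf, n_peaks, cand)
}

.fit_tm_n <- function(temp, hf, n_peaks, cand) {
  if (length(cand) < n_peaks) {
    # split the dominant candidate to seed a shoulder component
    if (n_peaks == 2 && length(cand) == 1) {
      hw <- .half_width_at(temp, hf - .robust_baseline(temp, hf),
                           which.min(abs(temp - cand)))
      cand <- c(cand - hw, cand)
    } else {
      stop("fewer candidate peaks than n_peaks; cannot initialize",
           call. = FALSE)
    }
  }
  base <- .robust_baseline(temp, hf)
  y0 <- hf - base
  # initialize from the n most prominent candidates (noise excursions can
  # contribute low-amplitude candidates that must not seed the fit)
  height <- vapply(cand, function(cc) y0[which.min(abs(temp - cc))],
                   numeric(1))
  centers0 <- sort(cand[order(-height)][seq_len(n_peaks)])
  start <- list(b0 = mean(base), b1 = 0)
  for (k in seq_len(n_peaks)) {
    i <- which.min(abs(temp - centers0[k]))
    start[[paste0("c", k)]] <- centers0[k]
    start[[paste0("g", k)]] <- .half_width_at(temp, y0, i)
    start[[paste0("a", k)]] <- max(y0[i], 1e-6)
  }
  terms <- paste0("a", seq_len(n_peaks), " * g", seq_len(n_peaks),
                  "^2 / ((x - c", seq_len(n_peaks), ")^2 + g",
                  seq_len(n_peaks), "^2)", collapse = " + ")
  form <- stats::as.formula(paste("y ~ b0 + b1 * x +", terms))
  dat <- data.frame(x = temp, y = hf)
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Lorentzian fit did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  centers <- cf[paste0("c", seq_len(n_peaks))]
  hwhms <- abs(cf[paste0("g", seq_len(n_peaks))])
  amps <- cf[paste0("a", seq_len(n_peaks))]
  ord <- order(-centers)
  rss <- sum(stats::resid(fit)^2)
  dof <- length(temp) - length(cf)
  out <- list(
    centers = unname(centers[ord]), hwhms = unname(hwhms[ord]),
    amplitudes = unname(amps[ord]),
    baseline = unname(cf[c("b0", "b1")]),
    centers_se = unname(se[paste0("c", seq_len(n_peaks))][ord]),
    hwhms_se = unname(se[paste0("g", seq_len(n_peaks))][ord]),
    amplitudes_se = unname(se[paste0("a", seq_len(n_peaks))][ord]),
    chi2red = rss / dof, converged = fit$convInfo$isConv %||% TRUE,
    n_peaks = n_peaks
  )
  if (any(out$centers < min(temp)) || any(out$centers > max(temp))) {
    stop("fitted peak center outside the data range", call. = FALSE)
  }
  class(out) <- "tm_fit"
  out
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("<tm_fit> %d peak(s), reduced chi2 = %.3g\n", x$n_peaks,
              x$chi2red))
  for (k in seq_len(x$n_peaks)) {
    cat(sprintf("  Tm%d = %.3f +/- %.3f degC (HWHM %.3f, amplitude %.3g)\n",
                k, x$centers[k], x$centers_se[k], x$hwhms[k],
                x$amplitudes[k]))
  }
  invisible(x)
}
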