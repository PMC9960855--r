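# Study orchestration: run the per-sample, per-temperature analysis chain
# and collect the headline quantities into one long-format summary table.

#' Estimate the maximum particle dimension from the low-q oscillations
#'
#' For a narrowly distributed vesicle population the low-q form-factor
#' oscillation minima are spaced by pi / R, so the shell radius follows
#' from the median minimum spacing (or from the first minimum position
#' when only one is visible); the maximum intra-particle distance is about
#' 2 R. Returns `margin * 2 R`, or `fallback` when no minimum is found
#' below `q_search`.
#'
#' @param curve A [scattering_curve()].
#' @param q_search Upper end of the search range \[1/Angstroem\].
#' @param margin Safety factor on the 2R estimate.
#' @param fallback Value returned when no oscillation minimum is detected.
#' @return Estimated rmax \[Angstroem\].
#' @export
estimate_rmax <- function(curve, q_search = 0.03, margin = 1.2,
                          fallback = 1200) {
  q <- curve$q[!curve$mask]; I <- curve$intensity[!curve$mask]
  sel <- q <= q_search & I > 0
  if (sum(sel) < 9) return(fallback)
  q <- q[sel]; y <- log(I[sel])
  y <- stats::runmed(y, 5)
  n <- length(y)
  # neighborhood minima (runmed ties defeat a strict two-sided test)
  h <- 3L
  mins <- which(vapply((h + 1):(n - h), function(i) {
    y[i] <= min(y[(i - h):(i + h)]) && y[i] < y[i - h] && y[i] < y[i + h]
  }, logical(1))) + h
  if (length(mins) == 0) return(fallback)
  # prominence filter: a genuine oscillation minimum is separated from its
  # neighbour by a maximum at least ~15 percent (0.15 log units) higher;
  # numerical ripples in the damped high-q region are not
  if (length(mins) > 1) {
    kept <- mins[1]
    for (m in mins[-1]) {
      prev <- kept[length(kept)]
      peak <- max(y[prev:m])
      if (peak - y[m] >= 0.15 && peak - y[prev] >= 0.15) kept <- c(kept, m)
    }
    mins <- kept
  }
  # successive minima are spaced by pi / R; the spacing still works when
  # the first-order minimum lies below the measured q range (large
  # vesicles), where the absolute position would misidentify the order
  R_est <- if (length(mins) >= 2) {
    pi / stats::median(diff(q[mins]))
  } else {
    pi / q[mins[1]]
  }
  margin * 2 * R_est
}

#' Run a full study from a manifest
#'
#' The manifest describes one sample per entry, either as a built-in
#' preset (synthetic data are generated on the fly) or as file paths
#' produced by the instrument pipeline. Analyses are gated the way a
#' temperature series on vesicles must be: the pair-distance distribution
#' is only computed below the fitted melting transition (above it the
#' vesicle contrast is lost), the Kratky-Porod thickness only at 10 degC
#' (higher temperatures risk aggregation artifacts), and the lamellar
#' analysis only above the transition. Failures are isolated per sample
#' and recorded, not fatal.
#'
#' @param manifest A list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{samples}{List; each element has either `preset = "<name>"` or
#'       the file fields `dsc`, `waxs` (named by temperature), `saxs`
#'       (named by temperature), `dls`.}
#'     \item{noise}{Optional list `saxs`, `waxs` (fractional), `dsc`,
#'       `dls` (additive sd) for synthetic samples; defaults 0.}
#'     \item{seed}{Base seed for synthetic noise (default 1).}
#'     \item{options}{Optional list: `n_peaks` (`"auto"`, 1 or 2),
#'       `mkp_window`, `waxs_window`, `ift_rmax` (`"auto"` or a number),
#'       `ift_alpha`.}
#'   }
#' @return An object of class `study_result`: list with `table` (long
#'   format: sample, w_naproxen, w_aescin, temperature, quantity, value,
#'   error), `details` (per-sample result objects) and `log` (character,
#'   one line per action or skip).
#' @export
run_study <- function(manifest) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  stopifnot(is.list(manifest), length(manifest$samples) > 0)
  noise <- manifest$noise %||% list()
  noise$saxs <- noise$saxs %||% 0; noise$waxs <- noise$waxs %||% 0
  noise$dsc <- noise$dsc %||% 0; noise$dls <- noise$dls %||% 0
  base_seed <- manifest$seed %||% 1
  opt <- manifest$options %||% list()
  n_peaks <- opt$n_peaks %||% "auto"
  mkp_window <- opt$mkp_window %||% c(0.08, 0.30)
  waxs_window <- opt$waxs_window %||% c(1.1, 1.75)

  rows <- list(); details <- list(); log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  add <- function(sample, comp, temperature, quantity, value, error = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample = sample,
      w_naproxen = molar_fraction(comp, "naproxen"),
      w_aescin = molar_fraction(comp, "aescin"),
      temperature = temperature, quantity = quantity,
      value = value, error = error, stringsAsFactors = FALSE)
  }

  for (si in seq_along(manifest$samples)) {
    sm <- manifest$samples[[si]]
    sname <- sm$name %||% sm$preset %||% paste0("sample", si)
    res <- tryCatch(
      .run_sample(sm, si, sname, noise, base_seed, n_peaks, mkp_window,
                  waxs_window, opt, note, add),
      error = function(e) {
        note("[%s] FAILED: %s", sname, conditionMessage(e))
        NULL
      }
    )
    details[[sname]] <- res
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(0), w_naproxen = numeric(0),
               w_aescin = numeric(0), temperature = numeric(0),
               quantity = character(0), value = numeric(0),
               error = numeric(0))
  structure(list(table = table, details = details, log = log),
            class = "study_result")
}

.run_sample <- function(sm, si, sname, noise, base_seed, n_peaks, mkp_window,
                        waxs_window, opt, note, add) {
  synthetic <- !is.null(sm$preset)
  pre <- if (synthetic) preset(sm$preset) else NULL
  comp <- if (synthetic) pre$composition else
    sample_composition(sm$n_dmpc %||% 1, sm$n_naproxen %||% 0,
                       sm$n_aescin %||% 0, label = sname)
  out <- list(name = sname)
  sseed <- base_seed + 1000 * si

  # ---- DSC -> Tm (gates everything else) ----
  tg <- if (synthetic) {
    preset_dsc_curve(pre, noise_sd = noise$dsc,
                     seed = if (noise$dsc > 0) sseed + 1 else NULL)
  } else if (!is.null(sm$dsc)) {
    if (!file.exists(sm$dsc)) stop("missing DSC file: ", sm$dsc)
    read_thermogram(sm$dsc)
  } else NULL
  tm <- NA_real_
  if (!is.null(tg)) {
    fit <- fit_tm(tg, n_peaks = n_peaks)
    tm <- fit$centers[1]
    add(sname, comp, NA, "tm", fit$centers[1], fit$centers_se[1])
    if (fit$n_peaks > 1) {
      add(sname, comp, NA, "tm_domain", fit$centers[2], fit$centers_se[2])
    }
    out$tm_fit <- fit
    note("[%s] Tm = %.2f degC (%d peak fit)", sname, tm, fit$n_peaks)
  } else {
    note("[%s] no DSC data; temperature gating uses Tm = 24 degC", sname)
    tm <- 24
  }

  # ---- WAXS series ----
  wx_curves <- list()
  if (synthetic) {
    tab <- preset_waxs_table(pre)
    wx_curves <- lapply(seq_len(nrow(tab)), function(k) {
      preset_waxs_curve(pre, tab$temperature[k], noise = noise$waxs,
                        seed = if (noise$waxs > 0) sseed + 10 + k else NULL)
    })
  } else if (!is.null(sm$waxs)) {
    for (tn in names(sm$waxs)) {
      path <- sm$waxs[[tn]]
      if (!file.exists(path)) { note("[%s] missing WAXS file %s", sname, path); next }
      cv <- read_curve(path)
      cv$temperature <- as.numeric(tn)
      wx_curves[[length(wx_curves) + 1]] <- cv
    }
  }
  if (length(wx_curves)) {
    ser <- d_waxs_series(wx_curves, window = waxs_window)
    for (k in seq_len(nrow(ser))) {
      add(sname, comp, ser$temperature[k], "d_waxs", ser$d_waxs[k],
          ser$d_waxs_se[k])
    }
    out$waxs <- ser
  }

  # ---- SAXS: IFT below Tm, MKP at 10 degC, lamellar above Tm ----
  sx <- list()
  if (synthetic) {
    for (tt in pre$temperatures) {
      sx[[as.character(tt)]] <- preset_saxs_curve(
        pre, tt, noise = noise$saxs,
        seed = if (noise$saxs > 0) sseed + 100 + tt else NULL)
    }
  } else if (!is.null(sm$saxs)) {
    for (tn in names(sm$saxs)) {
      path <- sm$saxs[[tn]]
      if (!file.exists(path)) { note("[%s] missing SAXS file %s", sname, path); next }
      cv <- read_curve(path)
      cv$temperature <- as.numeric(tn)
      sx[[tn]] <- cv
    }
  }
  out$ift <- list(); out$lamellar <- list()
  for (tn in names(sx)) {
    cv <- sx[[tn]]; tt <- cv$temperature
    if (tt < tm) {
      rmax <- opt$ift_rmax %||% "auto"
      if (identical(rmax, "auto")) rmax <- estimate_rmax(cv)
      cfg <- ift_config(rmax = rmax,
                        lagrange_multiplier = opt$ift_alpha %||% "auto")
      pr <- withCallingHandlers(
        ift(cv, cfg),
        warning = function(w) {
          note("[%s] IFT warning at %g degC: %s", sname, tt,
               conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      add(sname, comp, tt, "rg", pr$rg, NA)
      out$ift[[tn]] <- pr
      note("[%s] IFT at %g degC: RG = %.0f Ang (rmax %.0f)", sname, tt,
           pr$rg, rmax)
    } else {
      note("[%s] skip IFT at %g degC: above Tm (contrast lost)", sname, tt)
      lam <- lamellar_analysis(cv)
      if (lam$detected) {
        add(sname, comp, tt, "dlam", lam$dlam, 2 * pi * lam$q1_se / lam$q1^2)
        out$lamellar[[tn]] <- lam
        note("[%s] lamellar at %g degC: dlam = %.1f Ang (%s)", sname, tt,
             lam$dlam, if (lam$lamellar) "confirmed" else "unconfirmed")
      }
    }
    if (tt == 10) {
      mk <- tryCatch(mkp_thickness(cv, window = mkp_window),
                     error = function(e) {
                       note("[%s] MKP refused: %s", sname,
                            conditionMessage(e)); NULL })
      if (!is.null(mk)) {
        add(sname, comp, tt, "dm", mk$dm, NA)
        out$mkp <- mk
        note("[%s] MKP at 10 degC: dm = %.2f Ang", sname, mk$dm)
      }
    }
  }

  # ---- PCS at 10 degC ----
  cs <- if (synthetic) {
    preset_dls_curves(pre, noise_sd = noise$dls,
                      seed = if (noise$dls > 0) sseed + 500 else NULL)
  } else if (!is.null(sm$dls)) {
    if (!file.exists(sm$dls)) { note("[%s] missing DLS file %s", sname, sm$dls); NULL }
    else read_correlogram(sm$dls)
  } else NULL
  if (!is.null(cs)) {
    pcs <- pcs_pipeline(cs, n_grid = opt$pcs_grid %||% 100)
    add(sname, comp, cs$temperature, "rh", pcs$rh,
        pcs$rh * pcs$diffusion$D_se / pcs$diffusion$D)
    add(sname, comp, cs$temperature, "pdi", pcs$mean_pdi, NA)
    out$pcs <- pcs
    note("[%s] PCS: RH = %.0f Ang", sname, pcs$rh)
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d samples, %d records\n",
              length(x$details), nrow(x$table)))
  invisible(x)
}

#' Write summary CSVs and figures for a study
#'
#' One CSV per quantity (deterministic content, so re-running a study
#' reproduces the files byte for byte) and one PDF figure per quantity
#' mirroring the standard presentation: Tm, dm, dlam, RG and RH against
#' the aescin fraction; the chain-chain distance against temperature.
#'
#' @param study A `study_result` (or its `table`).
#' @param out_dir Output directory (created if needed).
#' @param plots Write PDF figures as well (default `TRUE`).
#' @return Character vector of files written, invisibly.
#' @export
make_report <- function(study, out_dir, plots = TRUE) {
  table <- if (inherits(study, "study_result")) study$table else study
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (qt in sort(unique(table$quantity))) {
    sub <- table[table$quantity == qt, , drop = FALSE]
    sub <- sub[order(sub$sample, sub$temperature), , drop = FALSE]
    path <- file.path(out_dir, paste0(qt, ".csv"))
    utils::write.csv(sub, path, row.names = FALSE)
    written <- c(written, path)
    if (plots && nrow(sub) > 0) {
      ppath <- file.path(out_dir, paste0(qt, ".pdf"))
      xvar <- if (qt == "d_waxs") "temperature" else "w_aescin"
      xlab <- if (qt == "d_waxs") "temperature [degC]" else "w(aescin)"
      sub$xaxis <- sub[[xvar]]
      gg <- ggplot2::ggplot(sub, ggplot2::aes(
        x = xaxis, y = value, colour = sample)) +
        ggplot2::geom_point() +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = value - error,
                                            ymax = value + error),
                               width = 0, na.rm = TRUE) +
        ggplot2::labs(x = xlab, y = qt) +
        ggplot2::theme_bw()
      grDevices::pdf(ppath, width = 6, height = 4)
      print(gg)
      grDevices::dev.off()
      written <- c(written, ppath)
    }
  }
  invisible(written)
}
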