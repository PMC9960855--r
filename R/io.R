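# On-disk dialects
# .dat: whitespace-separated numeric columns (q I [sigma]), '#' comment lines;
#       metadata as '# key=value'. Canonical format.
# .csv: named columns; same metadata convention in leading comment lines.
# q is stored in 1/Angstroem; readers can convert from 1/nm on request.

.parse_metadata <- function(lines) {
  meta <- list()
  com <- grep("^\\s*#", lines, value = TRUE)
  for (ln in com) {
    body <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  meta
}

.read_numeric_table <- function(path, sep) {
  lines <- readLines(path, warn = FALSE)
  meta <- .parse_metadata(lines)
  data_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(data_idx) == 0) stop("no data rows in ", path, call. = FALSE)
  body <- lines[data_idx]
  header <- NULL
  first <- strsplit(trimws(body[1]), sep)[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) {
    header <- trimws(first)
    body <- body[-1]
    data_idx <- data_idx[-1]
  }
  rows <- strsplit(trimws(body), sep)
  ncol <- length(rows[[1]])
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncol)
  for (k in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[k]]))
    if (length(vals) != ncol || any(is.na(vals))) {
      stop(sprintf("non-numeric or ragged row at line %d of %s",
                   data_idx[k], path), call. = FALSE)
    }
    mat[k, ] <- vals
  }
  if (!is.null(header)) colnames(mat) <- header
  list(data = mat, meta = meta)
}

.guess_format <- function(path, format) {
  if (!identical(format, "auto")) return(format)
  if (tolower(tools::file_ext(path)) == "csv") "csv" else "ascii"
}

#' Read a scattering curve from disk
#'
#' ASCII files hold whitespace-separated columns q, I and optionally sigma;
#' CSV files the named columns `q`, `intensity` and optionally `sigma`.
#' Comment lines starting with `#` may carry `key=value` metadata; the keys
#' `temperature_C`, `kind` and `q_unit` are honoured (`q_unit=nm^-1`
#' converts the grid to 1/Angstroem on input).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"ascii"` or `"csv"`.
#' @param qunit Override the q unit: `"A^-1"` (default) or `"nm^-1"`.
#' @return A [scattering_curve()].
#' @export
read_curve <- function(path, format = c("auto", "ascii", "csv"), qunit = NULL) {
  format <- .guess_format(path, match.arg(format))
  tab <- .read_numeric_table(path, if (format == "csv") "," else "\\s+")
  mat <- tab$data; meta <- tab$meta
  if (!is.null(colnames(mat))) {
    q <- mat[, "q"]; I <- mat[, "intensity"]
    s <- if ("sigma" %in% colnames(mat)) mat[, "sigma"] else NULL
  } else {
    if (ncol(mat) < 2) stop("need at least 2 numeric columns", call. = FALSE)
    q <- mat[, 1]; I <- mat[, 2]
    s <- if (ncol(mat) >= 3) mat[, 3] else NULL
  }
  unit <- qunit %||% meta$q_unit %||% "A^-1"
  if (identical(unit, "nm^-1")) q <- q / 10
  kind <- meta$kind %||% "saxs"
  if (is.unsorted(q, strictly = TRUE)) {
    stop("q column is not strictly increasing in ", path, call. = FALSE)
  }
  scattering_curve(q, I, sigma = s,
                   temperature = meta$temperature_C %||% NA_real_,
                   kind = kind)
}

#' Write a scattering curve to disk
#'
#' Full double precision is retained, so `read_curve(write_curve(x))`
#' round-trips numerically.
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @param format `"auto"`, `"ascii"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, format = c("auto", "ascii", "csv")) {
  stopifnot(inherits(curve, "scattering_curve"))
  format <- .guess_format(path, match.arg(format))
  meta <- c(sprintf("# kind=%s", curve$kind),
            if (is.finite(curve$temperature))
              sprintf("# temperature_C=%.17g", curve$temperature),
            "# q_unit=A^-1")
  cols <- list(q = curve$q, intensity = curve$intensity)
  if (!is.null(curve$sigma)) cols$sigma <- curve$sigma
  .write_table(cols, meta, path, format)
  invisible(path)
}

.write_table <- function(cols, meta, path, format) {
  mat <- do.call(cbind, lapply(cols, function(x) sprintf("%.17g", x)))
  if (format == "csv") {
    lines <- c(meta, paste(names(cols), collapse = ","),
               apply(mat, 1, paste, collapse = ","))
  } else {
    lines <- c(meta, apply(mat, 1, paste, collapse = " "))
  }
  writeLines(lines, path)
}

#' Read / write a DSC thermogram
#'
#' Two columns: temperature (deg C) and heat flow (mW). The metadata key
#' `heating_rate_C_min` is honoured.
#'
#' @param path File path.
#' @param format `"auto"`, `"ascii"` or `"csv"`.
#' @return A [thermogram()].
#' @export
read_thermogram <- function(path, format = c("auto", "ascii", "csv")) {
  format <- .guess_format(path, match.arg(format))
  tab <- .read_numeric_table(path, if (format == "csv") "," else "\\s+")
  mat <- tab$data
  if (!is.null(colnames(mat))) {
    temp <- mat[, "temperature"]; hf <- mat[, "heat_flow"]
  } else {
    temp <- mat[, 1]; hf <- mat[, 2]
  }
  thermogram(temp, hf, heating_rate = tab$meta$heating_rate_C_min %||% NA_real_)
}

#' @rdname read_thermogram
#' @param tg A [thermogram()].
#' @export
write_thermogram <- function(tg, path, format = c("auto", "ascii", "csv")) {
  stopifnot(inherits(tg, "thermogram"))
  format <- .guess_format(path, match.arg(format))
  meta <- c(if (is.finite(tg$heating_rate))
              sprintf("# heating_rate_C_min=%.17g", tg$heating_rate))
  .write_table(list(temperature = tg$temperature, heat_flow = tg$heat_flow),
               meta, path, format)
  invisible(path)
}

#' Read / write multi-angle correlograms
#'
#' Long-format CSV with columns `angle`, `tau`, `g2`; geometry metadata in
#' comment lines (`wavelength_A`, `refractive_index`, `temperature_C`).
#'
#' @param path File path.
#' @return A [correlogram_set()].
#' @export
read_correlogram <- function(path) {
  tab <- .read_numeric_table(path, ",")
  mat <- tab$data; meta <- tab$meta
  if (is.null(colnames(mat))) {
    if (ncol(mat) < 3) stop("need columns angle, tau, g2", call. = FALSE)
    colnames(mat) <- c("angle", "tau", "g2")
  }
  traces <- lapply(sort(unique(mat[, "angle"])), function(a) {
    sub <- mat[mat[, "angle"] == a, , drop = FALSE]
    ord <- order(sub[, "tau"])
    list(angle = a, tau = sub[ord, "tau"], g2 = sub[ord, "g2"])
  })
  correlogram_set(traces,
                  wavelength = meta$wavelength_A %||% 6328,
                  refractive_index = meta$refractive_index %||% 1.332,
                  temperature = meta$temperature_C %||% 25)
}

#' @rdname read_correlogram
#' @param cs A [correlogram_set()].
#' @export
write_correlogram <- function(cs, path) {
  stopifnot(inherits(cs, "correlogram_set"))
  meta <- c(sprintf("# wavelength_A=%.17g", cs$wavelength),
            sprintf("# refractive_index=%.17g", cs$refractive_index),
            sprintf("# temperature_C=%.17g", cs$temperature))
  angle <- unlist(lapply(cs$traces, function(t) rep(t$angle, length(t$tau))))
  tau <- unlist(lapply(cs$traces, function(t) t$tau))
  g2 <- unlist(lapply(cs$traces, function(t) t$g2))
  .write_table(list(angle = angle, tau = tau, g2 = g2), meta, path, "csv")
  invisible(path)
}

#' Serialize an analysis result to JSON
#'
#' @param x Any list-like result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
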