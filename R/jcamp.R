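#' Read a JCAMP-DX infrared spectrum
#'
#' Parses a JCAMP-DX file into a raw spectrum: wavenumber/intensity arrays
#' plus the intensity-unit declaration. Supports AFFN payloads in
#' `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)` form; the compressed
#' SQZ/DIF/DUP dialects are rejected with an explicit error. Wavenumbers
#' are returned ascending regardless of file order (JCAMP files are often
#' stored high-to-low), and an XUNITS of micrometers is converted to
#' wavenumbers via nu = 10^4 / lambda.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @return An object of class `raw_spectrum`: a list with `wavenumbers`
#'   (ascending, 1/cm), `intensities`, `y_units` (one of `"absorbance"`,
#'   `"transmittance"`, `"unknown"`) and `meta` (title, source file, and
#'   any resolution header).
#' @export
read_jcampdx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  hdr <- list()
  data_mode <- NULL
  data_lines <- character()
  in_data <- FALSE
  for (ln in lines) {
    ln <- sub("\\$\\$.*$", "", ln)  # strip comments
    if (grepl("^\\s*##", ln)) {
      if (in_data) in_data <- FALSE
      key <- toupper(gsub("[ _-]", "", sub("^\\s*##([^=]*)=.*$", "\\1", ln)))
      val <- trimws(sub("^\\s*##[^=]*=", "", ln))
      hdr[[key]] <- val
      if (key %in% c("XYDATA", "XYPOINTS")) {
        data_mode <- key
        in_data <- TRUE
      }
    } else if (in_data && nzchar(trimws(ln))) {
      data_lines <- c(data_lines, trimws(ln))
    }
  }

  if (is.null(data_mode) || length(data_lines) == 0L) {
    stop("JCAMP parse error: no XYDATA/XYPOINTS block in ", path,
         call. = FALSE)
  }

  # SQZ/DIF/DUP compressed payloads contain pseudo-digit letters; AFFN does
  # not use letters outside exponent markers.
  stripped <- gsub("[eE][+-]?[0-9]+", "", data_lines)
  if (any(grepl("[A-DF-Za-df-z@%]", stripped))) {
    stop("unsupported JCAMP dialect: SQZ/DIF/DUP-compressed data in ",
         path, call. = FALSE)
  }

  xf <- as.numeric(hdr[["XFACTOR"]] %||% "1")
  yf <- as.numeric(hdr[["YFACTOR"]] %||% "1")

  if (data_mode == "XYDATA") {
    if (!grepl("X\\+\\+", hdr[["XYDATA"]])) {
      stop("unsupported JCAMP dialect: XYDATA form '", hdr[["XYDATA"]],
           "'", call. = FALSE)
    }
    toks <- lapply(strsplit(data_lines, "[,;[:space:]]+"), function(t) {
      v <- suppressWarnings(as.numeric(t[nzchar(t)]))
      if (anyNA(v)) stop("JCAMP parse error: non-numeric payload in ",
                         path, call. = FALSE)
      v
    })
    y <- unlist(lapply(toks, function(v) v[-1])) * yf
    n_hdr <- suppressWarnings(as.numeric(hdr[["NPOINTS"]] %||% NA))
    firstx <- suppressWarnings(as.numeric(hdr[["FIRSTX"]] %||% NA))
    lastx <- suppressWarnings(as.numeric(hdr[["LASTX"]] %||% NA))
    if (is.na(firstx) || is.na(lastx)) {
      stop("JCAMP parse error: FIRSTX/LASTX missing in ", path,
           call. = FALSE)
    }
    n <- length(y)
    if (!is.na(n_hdr) && n_hdr != n) {
      stop("JCAMP parse error: NPOINTS=", n_hdr, " but ", n,
           " ordinates found in ", path, call. = FALSE)
    }
    if (n < 2L) stop("JCAMP parse error: fewer than 2 points in ", path,
                     call. = FALSE)
    x <- seq(firstx * xf, lastx * xf, length.out = n)
  } else {
    raw_toks <- unlist(
      strsplit(paste(data_lines, collapse = " "), "[,;[:space:]]+"))
    raw_toks <- raw_toks[nzchar(raw_toks)]
    toks <- suppressWarnings(as.numeric(raw_toks))
    if (anyNA(toks)) stop("JCAMP parse error: non-numeric payload in ",
                          path, call. = FALSE)
    if (length(toks) < 4L || length(toks) %% 2L != 0L) {
      stop("JCAMP parse error: XYPOINTS payload malformed in ", path,
           call. = FALSE)
    }
    x <- toks[seq(1L, length(toks), by = 2L)] * xf
    y <- toks[seq(2L, length(toks), by = 2L)] * yf
  }

  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("JCAMP parse error: non-finite values in ", path, call. = FALSE)
  }

  xunits <- toupper(hdr[["XUNITS"]] %||% "1/CM")
  if (grepl("MICROMETER|MICRON", xunits)) x <- 1e4 / x

  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (any(diff(x) <= 0)) {
    keep <- !duplicated(x)
    x <- x[keep]; y <- y[keep]
  }

  yunits <- toupper(hdr[["YUNITS"]] %||% "")
  y_units <- if (grepl("ABSORBANCE", yunits)) "absorbance"
  else if (grepl("TRANSMITTANCE", yunits)) "transmittance"
  else "unknown"

  structure(
    list(
      wavenumbers = x,
      intensities = y,
      y_units = y_units,
      meta = list(
        title = hdr[["TITLE"]] %||% "",
        resolution = hdr[["RESOLUTION"]] %||% NA_character_,
        source_file = path
      )
    ),
    class = "raw_spectrum"
  )
}

#' Write a spectrum as JCAMP-DX
#'
#' Serializes wavenumber/intensity arrays as an AFFN `(X++(Y..Y))` JCAMP-DX
#' file. The abscissa must be (numerically) equally spaced, as it is for
#' every grid this package produces.
#'
#' @param x Wavenumbers (1/cm), equally spaced.
#' @param y Intensities, same length as `x`.
#' @param path Output file path.
#' @param title `##TITLE` header value.
#' @param y_units `"absorbance"` or `"transmittance"`.
#' @return `path`, invisibly.
#' @export
write_jcampdx <- function(x, y, path, title = "irfgnet spectrum",
                          y_units = c("absorbance", "transmittance")) {
  y_units <- match.arg(y_units)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  dx <- diff(x)
  if (max(dx) - min(dx) > 1e-6 * max(abs(dx))) {
    stop("write_jcampdx requires an equally spaced abscissa", call. = FALSE)
  }
  hdr <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    paste0("##YUNITS=", toupper(y_units)),
    "##XFACTOR=1",
    "##YFACTOR=1",
    paste0("##FIRSTX=", format(x[1], digits = 12)),
    paste0("##LASTX=", format(x[length(x)], digits = 12)),
    paste0("##NPOINTS=", length(x)),
    paste0("##FIRSTY=", format(y[1], digits = 10)),
    "##XYDATA=(X++(Y..Y))"
  )
  per_line <- 6L
  starts <- seq(1L, length(y), by = per_line)
  body <- vapply(starts, function(i) {
    j <- min(i + per_line - 1L, length(y))
    paste(format(x[i], digits = 12),
          paste(formatC(y[i:j], digits = 9, format = "g"), collapse = " "))
  }, character(1))
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}

#' Convert a raw spectrum to absorbance
#'
#' Transmittance is converted via A = -log10(max(T, 1e-6)); values that look
#' like percent transmittance (maximum above 1.5) are first divided by 100.
#' Absorbance input is returned unchanged, so the conversion is idempotent.
#' When the file declares no intensity unit, a heuristic is applied:
#' a maximum above 1.5 indicates percent transmittance; otherwise values in
#' [0, 1.1] with a mean above 0.7 are taken as fractional transmittance
#' (IR transmittance hovers near 1 off-peak) and a mean below 0.3 as
#' absorbance; anything else is refused.
#'
#' @param raw A `raw_spectrum`.
#' @return A `raw_spectrum` with `y_units = "absorbance"`.
#' @export
to_absorbance <- function(raw) {
  stopifnot(inherits(raw, "raw_spectrum"))
  y <- raw$intensities
  units <- raw$y_units
  if (units == "unknown") {
    if (max(y) > 1.5) {
      units <- "transmittance"
    } else if (min(y) >= 0 && max(y) <= 1.1 && mean(y) > 0.7) {
      units <- "transmittance"
    } else if (mean(y) < 0.3) {
      units <- "absorbance"
    } else {
      stop("cannot resolve intensity units: YUNITS missing and value ",
           "distribution is inconclusive", call. = FALSE)
    }
  }
  if (units == "transmittance") {
    if (max(y) > 1.5) y <- y / 100
    y <- -log10(pmax(y, 1e-6))
  }
  raw$intensities <- y
  raw$y_units <- "absorbance"
  raw
}

`%||%` <- function(a, b) if (is.null(a)) b else a
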