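#' Construct a Raman spectrum
#'
#' A `raman_spectrum` is the basic measured object: a strictly increasing
#' wavenumber axis (Raman shift, cm^-1), an intensity trace in arbitrary
#' detector units, and free-form metadata describing the acquisition
#' (typically `cell_id`, `cell_line`, `organelle`, `timestamp_min`,
#' `accumulation_s`, `replicate_index`).
#'
#' Rows are sorted by wavenumber on construction; duplicated wavenumbers are
#' rejected.  At least 16 channels are required and all values must be
#' finite.
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1.
#' @param intensities Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumbers`.
#' @param meta Named list of metadata.  Scalar entries are serialized to
#'   file headers by [write_spectrum()].
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumbers`, `intensities` and `meta`.
#' @seealso [read_spectrum()], [resample_spectrum()]
#' @export
#' @examples
#' s <- raman_spectrum(600:620, rnorm(21, 100, 1), meta = list(organelle = "nucleolus"))
#' s
raman_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have the same length", call. = FALSE)
  }
  if (length(wavenumbers) < 16L) {
    stop("spectrum too short: at least 16 points are required, got ",
         length(wavenumbers), call. = FALSE)
  }
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers))) {
    stop("wavenumbers must be finite", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (anyDuplicated(wavenumbers)) {
    dup <- wavenumbers[duplicated(wavenumbers)][1L]
    stop("duplicate wavenumber: ", format(dup), call. = FALSE)
  }
  if (is.unsorted(wavenumbers)) {
    o <- order(wavenumbers)
    wavenumbers <- wavenumbers[o]
    intensities <- intensities[o]
  }
  if (!is.list(meta)) stop("meta must be a list", call. = FALSE)
  structure(list(wavenumbers = wavenumbers,
                 intensities = intensities,
                 meta = meta),
            class = "raman_spectrum")
}

#' @method print raman_spectrum
#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d channels, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  keep <- vapply(x$meta, function(v) is.atomic(v) && length(v) == 1L, logical(1))
  if (any(keep)) {
    m <- x$meta[keep]
    cat("  meta:", paste(names(m), unlist(m), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method length raman_spectrum
#' @export
length.raman_spectrum <- function(x) length(x$wavenumbers)

is_raman_spectrum <- function(x) inherits(x, "raman_spectrum")

#' Check that two spectra share the same wavenumber grid
#' @noRd
same_grid <- function(a, b, tol = 1e-9) {
  ga <- if (is_raman_spectrum(a)) a$wavenumbers else a
  gb <- if (is_raman_spectrum(b)) b$wavenumbers else b
  length(ga) == length(gb) && all(abs(ga - gb) <= tol * pmax(1, abs(ga)))
}

stop_grid_mismatch <- function(what = "spectra") {
  stop(what, " are not on the same wavenumber grid; resample first ",
       "(see resample_spectrum())", call. = FALSE)
}

#' Read a spectrum from a two-column text file
#'
#' Parses whitespace- or comma-delimited two-column files (wavenumber,
#' intensity).  Lines starting with `#` are treated as comments; comments of
#' the form `# key: value` are collected into the spectrum metadata.
#'
#' @param path Path to the file.
#' @param format `"auto"` (default, decided from the delimiter of the first
#'   data line), `"two_column_ascii"` (whitespace) or `"csv"` (comma).
#' @return A [raman_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "two_column_ascii", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  wn <- numeric(0)
  it <- numeric(0)
  nrec <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+\\s*", "", ln))
      if (grepl(":", body, fixed = TRUE)) {
        key <- trimws(sub(":.*$", "", body))
        val <- trimws(sub("^[^:]*:", "", body))
        if (nzchar(key)) {
          num <- suppressWarnings(as.numeric(val))
          meta[[key]] <- if (!is.na(num)) num else val
        }
      }
      next
    }
    if (format == "auto") {
      format <- if (grepl(",", ln, fixed = TRUE)) "csv" else "two_column_ascii"
    }
    fields <- if (format == "csv") {
      trimws(strsplit(ln, ",", fixed = TRUE)[[1]])
    } else {
      strsplit(ln, "\\s+")[[1]]
    }
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L) {
      stop(sprintf("parse failure at line %d of '%s': expected 2 numeric columns",
                   i, path), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals)) {
      stop(sprintf("parse failure at line %d of '%s': non-numeric value", i, path),
           call. = FALSE)
    }
    nrec <- nrec + 1L
    wn[nrec] <- vals[1L]
    it[nrec] <- vals[2L]
  }
  if (nrec < 16L) {
    stop(sprintf("too few data points in '%s': %d (need >= 16)", path, nrec),
         call. = FALSE)
  }
  raman_spectrum(wn, it, meta)
}

#' Write a spectrum to a two-column text file
#'
#' Scalar metadata entries are written as `# key: value` header lines, then
#' the wavenumber/intensity pairs with 12 significant digits, so a
#' write/read round trip preserves values to better than 1e-9 relative.
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output file path.
#' @param format `"two_column_ascii"` (whitespace delimited, default) or
#'   `"csv"`.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path,
                           format = c("two_column_ascii", "csv")) {
  format <- match.arg(format)
  stopifnot(is_raman_spectrum(spectrum))
  sep <- if (format == "csv") "," else " "
  out <- character(0)
  keep <- vapply(spectrum$meta, function(v) is.atomic(v) && length(v) == 1L,
                 logical(1))
  for (key in names(spectrum$meta)[keep]) {
    out <- c(out, sprintf("# %s: %s", key, format(spectrum$meta[[key]])))
  }
  out <- c(out, sprintf("%.12g%s%.12g", spectrum$wavenumbers, sep,
                        spectrum$intensities))
  ok <- tryCatch({
    writeLines(out, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a target wavenumber grid
#'
#' Linear interpolation onto `grid`.  Values at grid points shared with the
#' input axis are unchanged and affine intensity functions are reproduced
#' exactly; linear interpolation never overshoots, so non-negative input
#' stays non-negative.  Extrapolation outside the input range is refused.
#'
#' @param spectrum A [raman_spectrum()].
#' @param grid Target wavenumber axis (strictly increasing, within the
#'   spectrum's range).
#' @return A [raman_spectrum()] on `grid` with the input metadata.
#' @export
resample_spectrum <- function(spectrum, grid) {
  stopifnot(is_raman_spectrum(spectrum))
  grid <- as.numeric(grid)
  rng <- range(spectrum$wavenumbers)
  if (min(grid) < rng[1] - 1e-9 || max(grid) > rng[2] + 1e-9) {
    stop(sprintf(paste0("resampling would extrapolate: target grid ",
                        "[%.6g, %.6g] exceeds spectrum range [%.6g, %.6g]"),
                 min(grid), max(grid), rng[1], rng[2]), call. = FALSE)
  }
  yi <- stats::approx(spectrum$wavenumbers, spectrum$intensities,
                      xout = grid, method = "linear", rule = 1)$y
  raman_spectrum(grid, yi, spectrum$meta)
}

#' Default wavenumber grid
#'
#' The fingerprint-region grid used throughout the package when no
#' instrument grid is given: 600 to 1800 cm^-1 in 1 cm^-1 steps.
#'
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(600, 1800, by = 1)
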