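#' Subtract a reference background from a spectrum
#'
#' Channel-wise subtraction of a measured background (substrate, medium,
#' immersion-oil contribution) scaled by `scale`.  Both spectra must share
#' the wavenumber grid.
#'
#' @param spectrum A [raman_spectrum()].
#' @param background A [raman_spectrum()] on the same grid.
#' @param scale Multiplier applied to the background before subtraction
#'   (default 1).
#' @return A [raman_spectrum()] with the input metadata.
#' @export
subtract_background <- function(spectrum, background, scale = 1.0) {
  stopifnot(is_raman_spectrum(spectrum), is_raman_spectrum(background))
  if (!same_grid(spectrum, background)) stop_grid_mismatch("spectrum and background")
  raman_spectrum(spectrum$wavenumbers,
                 spectrum$intensities - scale * background$intensities,
                 spectrum$meta)
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial smoothing via `signal::sgolayfilt`.  A polynomial of
#' degree at most `polyorder` passes through unchanged.  Smoothing is
#' optional in the standard chain (off by default) because the
#' linear-combination fit itself averages channel noise.
#'
#' @param spectrum A [raman_spectrum()].
#' @param window_points Odd window length, at least 5 and at most the
#'   spectrum length (default 9).
#' @param polyorder Polynomial order, at most `window_points - 2` (default
#'   3); a window-minus-one order would make the filter an identity.
#' @return Smoothed [raman_spectrum()]; the wavenumber axis is untouched.
#' @export
smooth_spectrum <- function(spectrum, window_points = 9L, polyorder = 3L) {
  stopifnot(is_raman_spectrum(spectrum))
  window_points <- as.integer(window_points)
  polyorder <- as.integer(polyorder)
  if (window_points %% 2L == 0L) {
    stop("window_points must be odd, got ", window_points, call. = FALSE)
  }
  if (window_points < 5L) stop("window_points must be >= 5", call. = FALSE)
  if (polyorder > window_points - 2L) {
    # polyorder = window - 1 makes the filter an identity, not a smoother
    stop("polyorder (", polyorder, ") must be smaller than window_points - 1 (",
         window_points - 1L, ")", call. = FALSE)
  }
  if (window_points > length(spectrum)) {
    stop("window_points exceeds spectrum length", call. = FALSE)
  }
  y <- signal::sgolayfilt(spectrum$intensities, p = polyorder, n = window_points)
  raman_spectrum(spectrum$wavenumbers, y, spectrum$meta)
}

# Asymmetric least squares baseline (Eilers-Boelens).  Iteratively solves
# (W + lambda D'D) z = W y with a second-difference penalty; points above the
# current baseline get the small weight p, points below get 1 - p, so the
# baseline hugs the lower envelope under the Raman peaks while staying smooth.
als_baseline <- function(y, lambda = 1e7, p = 0.01, max_iter = 50L,
                         tol = 1e-6) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m, k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(max_iter)) {
    A <- DtD
    Matrix::diag(A) <- Matrix::diag(A) + w
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (sqrt(mean((w_new - w)^2)) < tol) {
      return(list(baseline = z, iterations = it))
    }
    w <- w_new
  }
  stop("ALS baseline did not converge after ", max_iter, " iterations",
       call. = FALSE)
}

# Iterative polynomial baseline (modified polyfit): fit a degree-d polynomial,
# clip the working trace to the fit, repeat until the fit stops moving.  An
# input that is itself a polynomial of degree <= d converges immediately to a
# zero corrected trace.
modpoly_baseline <- function(x, y, degree = 3L, max_iter = 500L, tol = 1e-4) {
  xs <- (x - mean(x)) / (diff(range(x)) / 2)
  X <- outer(xs, 0:degree, `^`)
  yw <- y
  scale <- max(abs(y), 1e-12)
  z <- rep(0, length(y))
  for (it in seq_len(max_iter)) {
    z_new <- as.numeric(X %*% qr.coef(qr(X), yw))
    if (max(abs(z_new - z)) < tol * scale) {
      return(list(baseline = z_new, iterations = it))
    }
    z <- z_new
    yw <- pmin(yw, z)
  }
  stop("polynomial baseline did not converge after ", max_iter, " iterations",
       call. = FALSE)
}

#' Baseline correction
#'
#' Estimates and removes the slowly varying background (dominated by
#' autofluorescence) under the Raman peaks.  Two estimators are available:
#'
#' * `"als"` — asymmetric least squares with second-difference smoothness
#'   penalty `lambda` and asymmetry `p`; the community standard for broad
#'   fluorescence under narrow Raman bands.
#' * `"polynomial"` — iterative polynomial fitting with clipping.
#'
#' The returned pair always satisfies `corrected = spectrum - baseline`
#' exactly, channel by channel.
#'
#' @param spectrum A [raman_spectrum()].
#' @param method `"als"` (default) or `"polynomial"`.
#' @param lambda ALS smoothness penalty (default 1e7).
#' @param p ALS asymmetry parameter (default 0.01).
#' @param degree Polynomial degree for `method = "polynomial"` (default 3).
#' @param max_iter Iteration cap (default 50 for ALS, 500 for polynomial);
#'   non-convergence is an error reporting the iteration count.
#' @param tol Convergence tolerance on the iterate update (default 1e-6 on
#'   the ALS weight vector, 1e-4 relative on the polynomial iterate).
#' @return List with elements `corrected` and `baseline`, both
#'   [raman_spectrum()]s on the input grid, plus `iterations`.
#' @export
correct_baseline <- function(spectrum, method = c("als", "polynomial"),
                             lambda = 1e7, p = 0.01, degree = 3L,
                             max_iter = NULL, tol = NULL) {
  stopifnot(is_raman_spectrum(spectrum))
  method <- match.arg(method)
  if (method == "als") {
    res <- als_baseline(spectrum$intensities, lambda = lambda, p = p,
                        max_iter = if (is.null(max_iter)) 50L else max_iter,
                        tol = if (is.null(tol)) 1e-6 else tol)
  } else {
    res <- modpoly_baseline(spectrum$wavenumbers, spectrum$intensities,
                            degree = degree,
                            max_iter = if (is.null(max_iter)) 500L else max_iter,
                            tol = if (is.null(tol)) 1e-4 else tol)
  }
  list(corrected = raman_spectrum(spectrum$wavenumbers,
                                  spectrum$intensities - res$baseline,
                                  spectrum$meta),
       baseline = raman_spectrum(spectrum$wavenumbers, res$baseline,
                                 spectrum$meta),
       iterations = res$iterations)
}

#' Run the standard preprocessing chain
#'
#' Background subtraction, optional Savitzky-Golay smoothing, then baseline
#' correction — in that fixed order — producing the spectrum that enters
#' the linear-combination fit.  Every applied step is recorded with its
#' parameters in the `log` element.
#'
#' The conservation identity `raw = processed + baseline + scale *
#' background` holds exactly when smoothing is disabled; with smoothing on,
#' the identity holds for the smoothed trace (the log records which).
#'
#' @param spectrum Raw [raman_spectrum()].
#' @param background Optional background [raman_spectrum()] on the same grid.
#' @param background_scale Background multiplier (default 1).
#' @param smooth Logical, apply Savitzky-Golay smoothing (default `FALSE`).
#' @param smooth_window,smooth_polyorder Smoothing parameters (defaults 9, 3).
#' @param baseline_method,lambda,p,degree Passed to [correct_baseline()].
#' @return An object of class `preprocess_result`: list with `processed`,
#'   `baseline`, `background` (scaled, or `NULL`), `per_channel_sd`
#'   (`NULL` here; filled by [average_replicates()]) and `log`.
#' @export
preprocess_spectrum <- function(spectrum, background = NULL,
                                background_scale = 1.0,
                                smooth = FALSE, smooth_window = 9L,
                                smooth_polyorder = 3L,
                                baseline_method = c("als", "polynomial"),
                                lambda = 1e7, p = 0.01, degree = 3L) {
  stopifnot(is_raman_spectrum(spectrum))
  baseline_method <- match.arg(baseline_method)
  log <- list()
  work <- spectrum
  bg_scaled <- NULL
  if (!is.null(background)) {
    work <- subtract_background(work, background, scale = background_scale)
    bg_scaled <- raman_spectrum(background$wavenumbers,
                                background_scale * background$intensities,
                                background$meta)
    log <- c(log, list(list(step = "subtract_background",
                            scale = background_scale)))
  }
  if (isTRUE(smooth)) {
    work <- smooth_spectrum(work, smooth_window, smooth_polyorder)
    log <- c(log, list(list(step = "smooth", window = smooth_window,
                            polyorder = smooth_polyorder)))
  }
  bl <- correct_baseline(work, method = baseline_method, lambda = lambda,
                         p = p, degree = degree)
  log <- c(log, list(list(step = "correct_baseline", method = baseline_method,
                          lambda = lambda, p = p, degree = degree,
                          iterations = bl$iterations)))
  structure(list(processed = bl$corrected, baseline = bl$baseline,
                 background = bg_scaled, per_channel_sd = NULL, log = log),
            class = "preprocess_result")
}

#' Average replicate spectra of one organelle
#'
#' Acquisition protocol: several (typically three) spectra are taken
#' sequentially from the same organelle and averaged.  Returns the
#' channel-wise mean together with the channel-wise sample standard
#' deviation, which can drive weighted fitting downstream.  Metadata are
#' merged from the first replicate with `replicate_index` dropped.
#'
#' @param spectra List of at least two [raman_spectrum()]s on the same grid
#'   with consistent `organelle` metadata.
#' @return A `preprocess_result` with `processed` (mean spectrum),
#'   `per_channel_sd`, and a one-entry `log`.
#' @export
average_replicates <- function(spectra) {
  if (!is.list(spectra) || length(spectra) < 2L) {
    stop("need at least 2 replicate spectra", call. = FALSE)
  }
  stopifnot(all(vapply(spectra, is_raman_spectrum, logical(1))))
  grid <- spectra[[1L]]$wavenumbers
  for (s in spectra[-1L]) {
    if (!same_grid(s$wavenumbers, grid)) stop_grid_mismatch("replicates")
  }
  orgs <- unique(unlist(lapply(spectra, function(s) s$meta$organelle)))
  if (length(orgs) > 1L) {
    stop("replicates carry mixed organelle labels: ",
         paste(orgs, collapse = ", "), call. = FALSE)
  }
  Y <- vapply(spectra, function(s) s$intensities, numeric(length(grid)))
  m <- rowMeans(Y)
  sdv <- apply(Y, 1L, stats::sd)
  meta <- spectra[[1L]]$meta
  meta$replicate_index <- NULL
  structure(list(processed = raman_spectrum(grid, m, meta),
                 baseline = NULL, background = NULL,
                 per_channel_sd = sdv,
                 log = list(list(step = "average_replicates",
                                 n = length(spectra)))),
            class = "preprocess_result")
}

#' @method print preprocess_result
#' @export
print.preprocess_result <- function(x, ...) {
  cat("<preprocess_result>\n")
  for (st in x$log) {
    pars <- st[setdiff(names(st), "step")]
    cat("  -", st$step,
        if (length(pars)) paste0("(", paste(names(pars), unlist(pars),
                                            sep = "=", collapse = ", "), ")"),
        "\n")
  }
  invisible(x)
}
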