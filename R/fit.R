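#' Options for the linear-combination fit
#'
#' @param nonneg Constrain component weights to be non-negative (default
#'   `TRUE`; concentrations are physical quantities).
#' @param residual_poly_degree Degree of the low-order polynomial fitted
#'   alongside the components to absorb what baseline correction leaves
#'   behind; `-1` disables it (default 4, smooth enough to track the
#'   residue of a broad fluorescence background yet far too stiff to
#'   absorb 8-40 cm^-1 Raman bands).
#' @param allow_shift Fit a single global wavenumber shift of the component
#'   references against the measured axis (default `TRUE`); this is the
#'   nonlinear parameter of the fit.
#' @param shift_bounds Half-width of the shift search interval in cm^-1
#'   (default 3).
#' @param detection_threshold Spectral-weight threshold below which a
#'   component is flagged as not reliably detected (default 0.1).
#' @param max_iter,tol Solver iteration cap and shift-search tolerance.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(nonneg = TRUE, residual_poly_degree = 4L,
                        allow_shift = TRUE, shift_bounds = 3,
                        detection_threshold = 0.1,
                        max_iter = 200L, tol = 1e-6) {
  if (shift_bounds < 0) stop("shift_bounds must be >= 0", call. = FALSE)
  if (detection_threshold < 0) {
    stop("detection_threshold must be >= 0", call. = FALSE)
  }
  residual_poly_degree <- as.integer(residual_poly_degree)
  if (residual_poly_degree < -1L) {
    stop("residual_poly_degree must be >= -1", call. = FALSE)
  }
  structure(list(nonneg = isTRUE(nonneg),
                 residual_poly_degree = residual_poly_degree,
                 allow_shift = isTRUE(allow_shift),
                 shift_bounds = as.numeric(shift_bounds),
                 detection_threshold = as.numeric(detection_threshold),
                 max_iter = as.integer(max_iter), tol = as.numeric(tol)),
            class = "fit_options")
}

# Evaluate the reference trace at wavenumbers nu - delta (a component shifted
# by +delta along the axis); constant continuation at the grid edges.
shift_trace <- function(ref, nu, delta) {
  if (delta == 0) return(ref)
  stats::approx(nu, ref, xout = nu - delta, method = "linear", rule = 2)$y
}

poly_basis <- function(nu, degree) {
  if (degree < 0L) return(NULL)
  xs <- (nu - mean(nu)) / (diff(range(nu)) / 2)
  outer(xs, 0:degree, `^`)
}

#' Decompose a spectrum into biomolecular component weights
#'
#' The core of biomolecular component analysis: a preprocessed organelle
#' spectrum `S` is modelled as a non-negative linear combination of the
#' calibrated component references plus a low-order residual polynomial,
#' with an optional global wavenumber shift `delta` as the nonlinear
#' nuisance parameter:
#'
#'   `S(nu) ~ sum_i c_i R_i(nu - delta) + P(nu)`
#'
#' The inner problem at fixed shift is solved exactly by active-set
#' non-negative least squares after projecting out the (unconstrained)
#' polynomial columns; the shift is then optimized by bounded 1-D golden
#' search over the inner solution.  When per-channel standard deviations
#' from replicate averaging are supplied, channels are weighted by
#' `1/sd^2`.
#'
#' Fitted spectral weights are converted to absolute concentrations via the
#' library's unit concentrations (weight 1.0 = 100 mg/ml for protein,
#' 20 mg/ml for RNA/DNA/lipid in the default calibration).  Components with
#' weight below the detection threshold (default 0.1) are reported but
#' flagged as unreliable.
#'
#' @param spectrum A preprocessed [raman_spectrum()] on the library grid.
#' @param library A [component_library()].
#' @param options A [fit_options()] object.
#' @param channel_sd Optional per-channel standard deviations (from
#'   [average_replicates()]); drives weighted fitting when present.
#' @return An object of class `bca_fit`: list with `weights`,
#'   `concentrations` (mg/ml), `weight_sd`, `shift` (cm^-1), `fitted` and
#'   `residual` spectra, `residual_poly` coefficients, `detected` flags,
#'   `r_squared` and `rms_residual`.
#' @export
fit_lcm <- function(spectrum, library, options = fit_options(),
                    channel_sd = NULL) {
  stopifnot(is_raman_spectrum(spectrum),
            inherits(library, "component_library"),
            inherits(options, "fit_options"))
  if (!same_grid(spectrum$wavenumbers, library$grid)) {
    stop_grid_mismatch("spectrum and component library")
  }
  nu <- spectrum$wavenumbers
  y <- spectrum$intensities
  n <- length(y)
  R0 <- component_matrix(library)
  k <- ncol(R0)
  nms <- component_names(library)

  ws <- rep(1, n)
  if (!is.null(channel_sd)) {
    if (length(channel_sd) != n) {
      stop("channel_sd length does not match the spectrum", call. = FALSE)
    }
    pos <- channel_sd[channel_sd > 0]
    if (length(pos) > 0) {
      floor_sd <- 1e-3 * stats::median(pos)
      ws <- 1 / pmax(channel_sd, floor_sd)
    }
  }
  P <- poly_basis(nu, options$residual_poly_degree)

  inner <- function(delta) {
    Rm <- vapply(seq_len(k), function(i) shift_trace(R0[, i], nu, delta),
                 numeric(n))
    Aw <- Rm * ws
    yw <- y * ws
    if (!is.null(P)) {
      Pw <- P * ws
      qrP <- qr(Pw)
      yp <- qr.resid(qrP, yw)
      Ap <- qr.resid(qrP, Aw)
    } else {
      Pw <- NULL; qrP <- NULL; yp <- yw; Ap <- Aw
    }
    if (options$nonneg) {
      sol <- nnls_solve(Ap, yp, max_iter = options$max_iter)
      cw <- sol$x
    } else {
      cw <- qr.coef(qr(Ap), yp)
      cw[is.na(cw)] <- 0
    }
    b <- if (!is.null(P)) {
      bb <- qr.coef(qrP, yw - Aw %*% cw)
      bb[is.na(bb)] <- 0
      bb
    } else numeric(0)
    model_w <- as.numeric(Aw %*% cw) +
      (if (!is.null(P)) as.numeric(Pw %*% b) else 0)
    rss_w <- sum((yw - model_w)^2)
    list(c = cw, b = b, Rm = Rm, rss_w = rss_w)
  }

  # Singularity guard on the unshifted design
  X0 <- cbind(R0 * ws, if (!is.null(P)) P * ws)
  if (qr(X0)$rank < ncol(X0)) {
    stop("singular design matrix: component references (plus polynomial) ",
         "are collinear on this grid", call. = FALSE)
  }

  delta <- 0
  if (options$allow_shift && options$shift_bounds > 0) {
    obj <- function(d) inner(d)$rss_w
    opt <- stats::optimize(obj, interval = c(-options$shift_bounds,
                                             options$shift_bounds),
                           tol = options$tol)
    # optimize() never evaluates the interval midpoint first; compare with
    # the unshifted solution so a zero-shift optimum is found exactly.
    delta <- if (opt$objective < obj(0)) opt$minimum else 0
  }
  fin <- inner(delta)

  weights <- stats::setNames(as.numeric(fin$c), nms)
  fitted_int <- as.numeric(fin$Rm %*% fin$c) +
    (if (!is.null(P)) as.numeric(P %*% fin$b) else 0)
  residual_int <- y - fitted_int

  # Covariance of the active components from the unconstrained normal
  # equations on the active set (plus polynomial columns).
  active <- if (options$nonneg) weights > 0 else rep(TRUE, k)
  weight_sd <- stats::setNames(rep(NA_real_, k), nms)
  if (any(active)) {
    X <- cbind(fin$Rm[, active, drop = FALSE] * ws,
               if (!is.null(P)) P * ws)
    dof <- n - ncol(X)
    if (dof >= 1) {
      sigma2 <- fin$rss_w / dof
      XtX <- crossprod(X)
      covm <- tryCatch(sigma2 * solve(XtX), error = function(e) NULL)
      if (!is.null(covm)) {
        weight_sd[active] <- sqrt(pmax(diag(covm)[seq_len(sum(active))], 0))
      }
    }
  }

  units <- vapply(library$components, function(cp) cp$unit_concentration,
                  numeric(1))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(residual_int^2) / tss else 0

  res <- structure(list(
    weights = weights,
    concentrations = weights * units,
    weight_sd = weight_sd,
    shift = delta,
    fitted = raman_spectrum(nu, fitted_int, spectrum$meta),
    residual = raman_spectrum(nu, residual_int, spectrum$meta),
    residual_poly = fin$b,
    detected = weights >= options$detection_threshold,
    detection_threshold = options$detection_threshold,
    r_squared = r2,
    rms_residual = sqrt(mean(residual_int^2)),
    options = options), class = "bca_fit")
  res
}

#' @method print bca_fit
#' @export
print.bca_fit <- function(x, ...) {
  cat("<bca_fit>\n")
  tab <- data.frame(weight = round(x$weights, 4),
                    concentration_mgml = round(x$concentrations, 2),
                    weight_sd = round(x$weight_sd, 4),
                    detected = x$detected)
  print(tab)
  cat(sprintf("  shift = %.3f cm^-1, R^2 = %.4f, RMS residual = %.4g\n",
              x$shift, x$r_squared, x$rms_residual))
  invisible(x)
}

#' Re-apply a detection threshold to a fit
#'
#' Recomputes the `detected` flags at a new weight threshold.  Weights and
#' concentrations are never altered or zeroed: sub-threshold components are
#' reported but marked unreliable (trace contributions).
#'
#' @param result A `bca_fit` from [fit_lcm()].
#' @param threshold Non-negative weight threshold.
#' @return The modified `bca_fit`.
#' @export
apply_detection_threshold <- function(result, threshold) {
  stopifnot(inherits(result, "bca_fit"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  result$detected <- result$weights >= threshold
  result$detection_threshold <- threshold
  result
}

#' Fit a collection of spectra into a profiles table
#'
#' Runs [fit_lcm()] on each spectrum and assembles the long-format
#' organelle-profile table used by the heterogeneity statistics: one row
#' per spectrum and analyte.  Spectra lacking `cell_id`, `cell_line` or
#' `organelle` metadata are skipped with a warning and counted in the
#' `n_skipped` attribute.
#'
#' @param spectra List of preprocessed [raman_spectrum()]s carrying
#'   `cell_id`, `cell_line` and `organelle` metadata.
#' @param library A [component_library()].
#' @param options A [fit_options()].
#' @return `data.frame` with columns `cell_line`, `cell_id`, `organelle`,
#'   `organelle_index`, `analyte`, `weight`, `weight_sd`,
#'   `concentration_mgml`, `detected`, `r_squared`, ordered by
#'   (cell_line, cell_id, organelle); attribute `n_skipped`.
#' @export
batch_fit <- function(spectra, library, options = fit_options()) {
  stopifnot(is.list(spectra))
  rows <- list()
  n_skipped <- 0L
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    m <- s$meta
    missing_keys <- c("cell_id", "cell_line", "organelle")[
      vapply(c("cell_id", "cell_line", "organelle"),
             function(kk) is.null(m[[kk]]) || !nzchar(as.character(m[[kk]])),
             logical(1))]
    if (length(missing_keys) > 0) {
      warning(sprintf("skipping spectrum %d: missing metadata (%s)", i,
                      paste(missing_keys, collapse = ", ")), call. = FALSE)
      n_skipped <- n_skipped + 1L
      next
    }
    fit <- fit_lcm(s, library, options)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_line = as.character(m$cell_line),
      cell_id = as.character(m$cell_id),
      organelle = as.character(m$organelle),
      organelle_index = if (is.null(m$organelle_index)) 1L else
        as.integer(m$organelle_index),
      analyte = names(fit$weights),
      weight = unname(fit$weights),
      weight_sd = unname(fit$weight_sd),
      concentration_mgml = unname(fit$concentrations),
      detected = unname(fit$detected),
      r_squared = fit$r_squared,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_line = character(0), cell_id = character(0),
               organelle = character(0), organelle_index = integer(0),
               analyte = character(0), weight = numeric(0),
               weight_sd = numeric(0), concentration_mgml = numeric(0),
               detected = logical(0), r_squared = numeric(0))
  out <- out[order(out$cell_line, out$cell_id, out$organelle,
                   out$organelle_index, out$analyte), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
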