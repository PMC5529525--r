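#' Calibrate a component profile from pure-compound measurements
#'
#' Builds a concentration-calibrated reference from spectra of pure
#' solutions at known concentrations.  The mean spectral shape is
#' extracted (mean of the L2-normalized measurement spectra, renormalized),
#' each measurement's amplitude is obtained by least-squares projection
#' onto that shape, and a regression through the origin of amplitude
#' against concentration gives the intensity per mg/ml.  The returned
#' profile is the shape scaled so that fitting a pure spectrum acquired at
#' `unit_concentration` yields spectral weight 1.0 — equalizing all
#' component profiles to the Raman intensity of their unit weight.
#'
#' Regression is forced through the origin because zero concentration
#' produces zero Raman signal.
#'
#' @param analyte Analyte name (`"protein"`, `"RNA"`, `"DNA"`, `"lipid"`
#'   or custom).
#' @param measurements List of `list(concentration = <mg/ml>, spectrum =
#'   <raman_spectrum>)` pairs; all spectra preprocessed and on one grid,
#'   all concentrations positive.  A single concentration point is
#'   accepted with a warning (scale taken from that point alone).
#' @param unit_concentration mg/ml corresponding to weight 1.0 (default
#'   100 for protein, 20 otherwise).
#' @return A [component_profile()] with a `calibration` attribute holding
#'   the per-measurement amplitudes, the fitted intensity-per-mg/ml scale
#'   and the regression r-squared.
#' @export
calibrate_component <- function(analyte, measurements,
                                unit_concentration =
                                  default_unit_concentration(analyte)) {
  if (!is.list(measurements) || length(measurements) < 1L) {
    stop("measurements must be a non-empty list", call. = FALSE)
  }
  conc <- vapply(measurements, function(m) as.numeric(m$concentration),
                 numeric(1))
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("all calibration concentrations must be positive", call. = FALSE)
  }
  specs <- lapply(measurements, `[[`, "spectrum")
  stopifnot(all(vapply(specs, is_raman_spectrum, logical(1))))
  grid <- specs[[1L]]$wavenumbers
  for (s in specs[-1L]) {
    if (!same_grid(s$wavenumbers, grid)) stop_grid_mismatch("calibration spectra")
  }
  if (length(unique(conc)) < 2L) {
    warning("single calibration concentration: scale taken from one point",
            call. = FALSE)
  }
  Y <- vapply(specs, function(s) s$intensities, numeric(length(grid)))
  norms <- sqrt(colSums(Y^2))
  if (any(norms == 0)) stop("a calibration spectrum is all zero", call. = FALSE)
  shape <- rowMeans(sweep(Y, 2L, norms, "/"))
  shape <- shape / sqrt(sum(shape^2))
  amplitudes <- as.numeric(crossprod(Y, shape))      # LS projection, |shape|=1
  scale <- sum(amplitudes * conc) / sum(conc^2)      # through-origin slope
  if (scale <= 0) {
    stop("calibration regression slope is not positive", call. = FALSE)
  }
  ss_res <- sum((amplitudes - scale * conc)^2)
  ss_tot <- sum((amplitudes - mean(amplitudes))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  ref <- pmax(shape * scale * unit_concentration, 0)
  profile <- component_profile(analyte, raman_spectrum(grid, ref),
                               unit_concentration)
  attr(profile, "calibration") <- list(analyte = analyte,
                                       concentrations = conc,
                                       amplitudes = amplitudes,
                                       fitted_scale = scale,
                                       r_squared = r2)
  profile
}

#' Convert spectral weights to absolute concentrations
#'
#' `concentration = weight * unit_concentration` for each analyte: a
#' protein weight of 1.0 is 100 mg/ml, an RNA weight of 0.5 is 10 mg/ml
#' under the default calibration.
#'
#' @param weights Named numeric vector of spectral weights.
#' @param library A [component_library()] providing the unit
#'   concentrations.
#' @return Named numeric vector of concentrations in mg/ml.
#' @export
weights_to_concentrations <- function(weights, library) {
  stopifnot(inherits(library, "component_library"))
  if (is.null(names(weights))) {
    stop("weights must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(names(weights), component_names(library))
  if (length(unknown)) {
    stop("unknown analyte(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  units <- vapply(library$components[names(weights)],
                  function(cp) cp$unit_concentration, numeric(1))
  weights * units
}
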