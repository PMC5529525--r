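# Evaluate code with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Describe a single Raman band
#'
#' @param center Band position in cm^-1.
#' @param fwhm Full width at half maximum in cm^-1 (positive).
#' @param amplitude Peak height, relative units (non-negative).
#' @param shape `"gaussian"`, `"lorentzian"` or `"pseudo_voigt"`.
#' @param eta Lorentzian fraction for the pseudo-Voigt shape, in \[0, 1\].
#' @return A `peak_spec` list.
#' @export
peak_spec <- function(center, fwhm, amplitude = 1,
                      shape = c("gaussian", "lorentzian", "pseudo_voigt"),
                      eta = 0.5) {
  shape <- match.arg(shape)
  if (fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape, eta = eta), class = "peak_spec")
}

eval_peak <- function(grid, pk) {
  gauss <- pk$amplitude * exp(-4 * log(2) * ((grid - pk$center) / pk$fwhm)^2)
  if (pk$shape == "gaussian") return(gauss)
  hw2 <- (pk$fwhm / 2)^2
  lor <- pk$amplitude * hw2 / ((grid - pk$center)^2 + hw2)
  if (pk$shape == "lorentzian") return(lor)
  pk$eta * lor + (1 - pk$eta) * gauss
}

#' Build a synthetic component profile from a peak list
#'
#' Sums the band shapes on the grid, max-normalizes, and wraps the result
#' as a calibrated [component_profile()].  Deterministic.
#'
#' @param name Analyte label.
#' @param peaks List of [peak_spec()]s; every center must lie within the
#'   grid range.
#' @param grid Wavenumber axis (default [default_grid()]).
#' @param unit_concentration mg/ml per unit weight (default from
#'   [default_unit_concentration()]).
#' @return A [component_profile()].
#' @export
make_component_profile <- function(name, peaks, grid = default_grid(),
                                   unit_concentration =
                                     default_unit_concentration(name)) {
  stopifnot(is.list(peaks), length(peaks) >= 1L)
  rng <- range(grid)
  for (pk in peaks) {
    if (!inherits(pk, "peak_spec")) {
      stop("peaks must be a list of peak_spec objects", call. = FALSE)
    }
    if (pk$center < rng[1] || pk$center > rng[2]) {
      stop(sprintf("peak at %g cm^-1 lies outside the grid [%g, %g]",
                   pk$center, rng[1], rng[2]), call. = FALSE)
    }
  }
  y <- rowSums(vapply(peaks, function(pk) eval_peak(grid, pk),
                      numeric(length(grid))))
  if (max(y) > 0) y <- y / max(y)
  component_profile(name, raman_spectrum(grid, y), unit_concentration)
}

#' Default four-component synthetic library
#'
#' Protein, RNA, lipid and DNA profiles built from canonical Raman band
#' positions (protein: 1003 phenylalanine, 1250 amide III, 1450 CH
#' deformation, 1660 amide I; RNA: 785, 1100, 1480, 1575; lipid: 1063,
#' 1301, 1440, 1745; DNA: 785, 1094), max-normalized, with the standard
#' unit concentrations (100 mg/ml protein, 20 mg/ml otherwise).  Band
#' positions and widths are modelling defaults chosen so the four profiles
#' are mutually well separated (pairwise cosine similarity below 0.8).
#'
#' @param grid Wavenumber axis (default [default_grid()]).
#' @return A [component_library()].
#' @export
default_component_library <- function(grid = default_grid()) {
  prot <- list(peak_spec(1003, 8, 1.0), peak_spec(1250, 30, 0.45),
               peak_spec(1450, 22, 0.6), peak_spec(1660, 40, 0.9))
  rna <- list(peak_spec(785, 18, 0.9), peak_spec(1100, 25, 0.5),
              peak_spec(1480, 25, 0.7), peak_spec(1575, 22, 0.8))
  lip <- list(peak_spec(1063, 15, 0.7), peak_spec(1301, 20, 0.8),
              peak_spec(1440, 25, 1.0), peak_spec(1745, 20, 0.5))
  dna <- list(peak_spec(785, 16, 1.0), peak_spec(1094, 22, 0.7))
  component_library(
    list(make_component_profile("protein", prot, grid),
         make_component_profile("RNA", rna, grid),
         make_component_profile("lipid", lip, grid),
         make_component_profile("DNA", dna, grid)),
    provenance = paste("Synthetic profiles; band positions approximate the",
                       "calibration substances (serum albumin, yeast RNA,",
                       "heart lipid extract, genomic DNA)."))
}

#' Simulate one organelle spectrum with known ground truth
#'
#' Forward model of the decomposition: weighted sum of (optionally shifted)
#' library components, plus a broad Gaussian fluorescence baseline, plus
#' additive Gaussian channel noise (a CCD read + shot-noise approximation;
#' Poisson noise available via `noise_model = "poisson"`).
#'
#' @param library A [component_library()].
#' @param weights Named non-negative weights (analytes present in the
#'   library; missing analytes default to 0).
#' @param baseline `NULL` for none, or a list with `amplitude`, `center`
#'   (cm^-1), `width` (Gaussian sigma, cm^-1) and optional `offset`.
#' @param noise_sd Standard deviation of additive channel noise (>= 0).
#' @param shift Global wavenumber shift applied to the components, cm^-1.
#' @param seed Integer seed; the same seed reproduces the spectrum exactly.
#' @param noise_model `"gaussian"` (default) or `"poisson"`.
#' @param meta Metadata for the returned spectrum.
#' @return List with `spectrum` (a [raman_spectrum()]) and `truth` (the
#'   full weight vector, baseline trace, shift, noise level and seed).
#' @export
simulate_spectrum <- function(library, weights, baseline = NULL,
                              noise_sd = 0, shift = 0, seed = NULL,
                              noise_model = c("gaussian", "poisson"),
                              meta = list()) {
  stopifnot(inherits(library, "component_library"))
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  nms <- component_names(library)
  unknown <- setdiff(names(weights), nms)
  if (length(unknown)) {
    stop("unknown analyte(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  w <- stats::setNames(numeric(length(nms)), nms)
  w[names(weights)] <- as.numeric(weights)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  nu <- library$grid
  R0 <- component_matrix(library)
  Rm <- vapply(seq_len(ncol(R0)),
               function(i) shift_trace(R0[, i], nu, shift),
               numeric(length(nu)))
  signal <- as.numeric(Rm %*% w)
  bl <- rep(0, length(nu))
  if (!is.null(baseline)) {
    off <- if (is.null(baseline$offset)) 0 else baseline$offset
    bl <- off + baseline$amplitude *
      exp(-(nu - baseline$center)^2 / (2 * baseline$width^2))
  }
  clean <- signal + bl
  noisy <- with_seed(seed, {
    if (noise_model == "poisson") {
      # Poisson counts around the clean trace, scaled so the sd at the mean
      # intensity level matches noise_sd.
      if (noise_sd > 0) {
        lam <- pmax(clean, 0) * mean(pmax(clean, 1e-9)) / noise_sd^2
        sc <- noise_sd^2 / mean(pmax(clean, 1e-9))
        stats::rpois(length(nu), lam) * sc
      } else clean
    } else {
      clean + stats::rnorm(length(nu), sd = noise_sd)
    }
  })
  list(spectrum = raman_spectrum(nu, noisy, meta),
       truth = list(weights = w, baseline = bl, shift = shift,
                    noise_sd = noise_sd, seed = seed))
}

#' Specify a synthetic cell population
#'
#' Per-cell concentration vectors over (organelle, analyte) pairs are drawn
#' from a multivariate distribution with the given means, standard
#' deviations and correlation matrix.  Variable names use the
#' `"organelle.analyte"` convention (e.g. `"nucleolus.protein"`).
#'
#' @param n_cells Number of cells (>= 3).
#' @param cell_line Cell-line label.
#' @param means Named vector of mean concentrations, mg/ml (all positive).
#' @param sds Named vector of standard deviations (same names).
#' @param correlation Correlation matrix over the variables (default
#'   identity).  Must be symmetric positive semidefinite.
#' @param distribution `"truncated_normal"` (multivariate normal truncated
#'   at 1 mg/ml) or `"lognormal"` (moment-matched on the natural scale,
#'   correlations applied on the log scale).
#' @param seed Integer seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_cells, cell_line, means, sds,
                            correlation = NULL,
                            distribution = c("truncated_normal", "lognormal"),
                            seed = NULL) {
  distribution <- match.arg(distribution)
  if (n_cells < 3L) stop("n_cells must be >= 3", call. = FALSE)
  if (is.null(names(means)) || anyNA(names(means))) {
    stop("means must be a named vector ('organelle.analyte')", call. = FALSE)
  }
  if (any(means <= 0)) stop("all mean concentrations must be > 0", call. = FALSE)
  if (!identical(sort(names(means)), sort(names(sds)))) {
    stop("means and sds must share names", call. = FALSE)
  }
  v <- names(means)
  if (is.null(correlation)) {
    correlation <- diag(length(v))
    dimnames(correlation) <- list(v, v)
  }
  correlation <- correlation[v, v, drop = FALSE]
  if (max(abs(correlation - t(correlation))) > 1e-10) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("correlation matrix is not positive semidefinite (eigenvalue %.4g)",
                 min(ev)), call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), cell_line = cell_line,
                 means = means, sds = sds[v], correlation = correlation,
                 distribution = distribution, seed = seed),
            class = "population_spec")
}

# Frozen default concentration parameters: organelle concentration ranges
# chosen so mean +/- 2 SD spans the typical single-cell spread (nucleolar
# protein 50-120 mg/ml, RNA 10-45, lipid 10-35; ER protein 20-120, RNA 5-20,
# lipid 5-60; mitochondrial protein 35-110, RNA 5-20, lipid 3-40).
default_population_params <- function(cell_line = c("WI38", "HeLa")) {
  cell_line <- match.arg(cell_line)
  means <- c(nucleolus.protein = 85, nucleolus.RNA = 27.5,
             nucleolus.lipid = 22.5,
             ER.protein = 70, ER.RNA = 12.5, ER.lipid = 32.5,
             mitochondrion.protein = 72.5, mitochondrion.RNA = 12.5,
             mitochondrion.lipid = 21.5)
  sds <- c(nucleolus.protein = 17.5, nucleolus.RNA = 8.75,
           nucleolus.lipid = 6.25,
           ER.protein = 25, ER.RNA = 3.75, ER.lipid = 13.75,
           mitochondrion.protein = 18.75, mitochondrion.RNA = 3.75,
           mitochondrion.lipid = 9.25)
  if (cell_line == "HeLa") {
    # HeLa organelles run 10-20% higher in protein and RNA
    means[c("nucleolus.protein", "nucleolus.RNA", "nucleolus.lipid")] <-
      means[c("nucleolus.protein", "nucleolus.RNA", "nucleolus.lipid")] * 1.12
    means["ER.protein"] <- means["ER.protein"] * 1.10
    means["mitochondrion.protein"] <- means["mitochondrion.protein"] * 1.10
    means["mitochondrion.RNA"] <- means["mitochondrion.RNA"] * 1.20
  }
  v <- names(means)
  R <- diag(length(v)); dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) { R[a, b] <<- r; R[b, a] <<- r }
  if (cell_line == "WI38") {
    set_r("nucleolus.protein", "nucleolus.RNA", 0.80)
    set_r("ER.protein", "ER.RNA", 0.80)
    set_r("mitochondrion.protein", "mitochondrion.RNA", 0.30)
    set_r("nucleolus.protein", "ER.protein", 0.75)
    set_r("nucleolus.protein", "ER.RNA", 0.70)
    set_r("nucleolus.RNA", "ER.protein", 0.70)
    set_r("nucleolus.RNA", "ER.RNA", 0.50)
    set_r("nucleolus.protein", "mitochondrion.protein", 0.60)
    set_r("nucleolus.RNA", "mitochondrion.RNA", 0.40)
    # consistency fills keeping the matrix positive definite
    set_r("nucleolus.RNA", "mitochondrion.protein", 0.45)
    set_r("nucleolus.protein", "mitochondrion.RNA", 0.35)
    set_r("ER.protein", "mitochondrion.protein", 0.45)
    set_r("ER.RNA", "mitochondrion.RNA", 0.30)
    set_r("ER.protein", "mitochondrion.RNA", 0.30)
    set_r("ER.RNA", "mitochondrion.protein", 0.35)
  } else {
    set_r("nucleolus.protein", "nucleolus.RNA", 0.80)
    set_r("ER.protein", "ER.RNA", 0.80)
    set_r("mitochondrion.protein", "mitochondrion.RNA", 0.35)
    set_r("nucleolus.protein", "ER.protein", 0.15)
    set_r("nucleolus.protein", "ER.RNA", 0.10)
    set_r("nucleolus.RNA", "ER.protein", 0.10)
    set_r("nucleolus.RNA", "ER.RNA", 0.15)
    set_r("nucleolus.protein", "mitochondrion.protein", 0.30)
    set_r("nucleolus.RNA", "mitochondrion.RNA", 0.10)
  }
  list(means = means, sds = sds, correlation = R)
}

#' Default population specification for a cell line
#'
#' WI-38-like populations couple nucleolar and ER profiles strongly
#' (protein-protein ~0.75, protein-RNA ~0.70, RNA-RNA ~0.50) while
#' HeLa-like populations leave the cross-organelle correlations weak
#' (<= 0.3) but keep the within-organelle protein-RNA coupling (~0.80 in
#' nucleolus and ER, ~0.3 in mitochondria) and run 10-20% higher in
#' protein and RNA means.
#'
#' @param cell_line `"WI38"` or `"HeLa"`.
#' @param n_cells Number of cells (default 50).
#' @param seed Integer seed.
#' @return A [population_spec()].
#' @export
default_population_spec <- function(cell_line = c("WI38", "HeLa"),
                                    n_cells = 50L, seed = NULL) {
  cell_line <- match.arg(cell_line)
  par <- default_population_params(cell_line)
  population_spec(n_cells, cell_line, par$means, par$sds, par$correlation,
                  seed = seed)
}

#' Draw a synthetic cell population
#'
#' Draws per-cell concentration vectors from the spec's distribution; the
#' sample correlation matrix converges to the spec correlation as the
#' number of cells grows.  All returned concentrations are positive
#' (truncation at 1 mg/ml for the truncated-normal model).
#'
#' @param spec A [population_spec()].
#' @return Long-format `data.frame` with columns `cell_line`, `cell_id`,
#'   `organelle`, `organelle_index`, `analyte`, `concentration_mgml`;
#'   attribute `truth` holds the generating spec.
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  v <- names(spec$means)
  d <- length(v)
  X <- with_seed(spec$seed, {
    if (spec$distribution == "lognormal") {
      cv2 <- (spec$sds / spec$means)^2
      sl <- sqrt(log1p(cv2))
      ml <- log(spec$means) - sl^2 / 2
      Sig <- spec$correlation * outer(sl, sl)
      Z <- MASS::mvrnorm(spec$n_cells, mu = ml, Sigma = Sig)
      exp(Z)
    } else {
      Sig <- spec$correlation * outer(spec$sds, spec$sds)
      Z <- MASS::mvrnorm(spec$n_cells, mu = spec$means, Sigma = Sig)
      pmax(Z, 1)
    }
  })
  X <- matrix(X, nrow = spec$n_cells, dimnames = list(NULL, v))
  parts <- strsplit(v, ".", fixed = TRUE)
  org <- vapply(parts, `[`, character(1), 1L)
  ana <- vapply(parts, function(p) paste(p[-1L], collapse = "."), character(1))
  ids <- sprintf("cell_%03d", seq_len(spec$n_cells))
  out <- data.frame(
    cell_line = spec$cell_line,
    cell_id = rep(ids, each = d),
    organelle = rep(org, times = spec$n_cells),
    organelle_index = 1L,
    analyte = rep(ana, times = spec$n_cells),
    concentration_mgml = as.numeric(t(X)),
    stringsAsFactors = FALSE)
  attr(out, "truth") <- spec
  out
}

#' Specify a synthetic time-lapse series
#'
#' Models the time-lapse protocol: one concentration measurement per
#' ~10-minute interval over ~1 hour in the same organelle, as a sinusoid
#' around a constant level plus Gaussian noise:
#' `c(t) = baseline_level + amplitude * sin(2*pi*frequency*t + phase) + noise`.
#'
#' @param duration_min Session length in minutes (default 60).
#' @param interval_min Sampling interval in minutes (default 10; must not
#'   exceed the duration).
#' @param baseline_level Mean concentration, mg/ml.
#' @param amplitude Oscillation amplitude, mg/ml (>= 0).
#' @param frequency Oscillation frequency in cycles per hour.
#' @param noise_sd Measurement noise SD, mg/ml (>= 0).
#' @param phase Phase in radians, or `NULL` to draw uniformly under `seed`.
#' @param seed Integer seed.
#' @param meta Metadata (cell_id, cell_line, organelle, analyte).
#' @return A `timeseries_spec` list.
#' @export
timeseries_spec <- function(duration_min = 60, interval_min = 10,
                            baseline_level = 25, amplitude = 5,
                            frequency = 2, noise_sd = 0, phase = NULL,
                            seed = NULL, meta = list()) {
  if (interval_min > duration_min) {
    stop("interval_min must not exceed duration_min", call. = FALSE)
  }
  if (amplitude < 0 || noise_sd < 0) {
    stop("amplitude and noise_sd must be >= 0", call. = FALSE)
  }
  structure(list(duration_min = duration_min, interval_min = interval_min,
                 baseline_level = baseline_level, amplitude = amplitude,
                 frequency = frequency, noise_sd = noise_sd, phase = phase,
                 seed = seed, meta = meta),
            class = "timeseries_spec")
}

#' Simulate a concentration time series
#'
#' @param spec A [timeseries_spec()].
#' @return List with `series` (a [raman_timeseries()]) and `truth` (the
#'   spec with the realized phase).
#' @export
simulate_timeseries <- function(spec) {
  stopifnot(inherits(spec, "timeseries_spec"))
  times <- seq(0, spec$duration_min, by = spec$interval_min)
  out <- with_seed(spec$seed, {
    phase <- if (is.null(spec$phase)) stats::runif(1, 0, 2 * pi) else spec$phase
    vals <- spec$baseline_level +
      spec$amplitude * sin(2 * pi * spec$frequency * times / 60 + phase) +
      stats::rnorm(length(times), sd = spec$noise_sd)
    list(vals = vals, phase = phase)
  })
  truth <- spec
  truth$phase <- out$phase
  list(series = raman_timeseries(times, out$vals, meta = spec$meta),
       truth = truth)
}
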