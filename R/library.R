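#' Calibrated component profile
#'
#' A component profile is a reference Raman spectrum of one biomolecular
#' class (protein, RNA, DNA, lipid, or a custom analyte), scaled so that a
#' spectral weight of 1.0 in the linear-combination fit corresponds to
#' `unit_concentration` mg/ml of the analyte.  Following the calibration
#' convention used here, unit weight is 100 mg/ml for proteins and 20 mg/ml
#' for RNA, DNA and lipids.
#'
#' @param name Analyte label.
#' @param reference A [raman_spectrum()] with non-negative intensities on
#'   the library grid.
#' @param unit_concentration Concentration in mg/ml corresponding to
#'   spectral weight 1.0; must be positive.
#' @return An object of class `component_profile`.
#' @export
component_profile <- function(name, reference, unit_concentration) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("component name must be a non-empty string", call. = FALSE)
  }
  stopifnot(is_raman_spectrum(reference))
  if (any(reference$intensities < 0)) {
    stop("component reference intensities must be non-negative", call. = FALSE)
  }
  if (!is.numeric(unit_concentration) || length(unit_concentration) != 1L ||
      !is.finite(unit_concentration) || unit_concentration <= 0) {
    stop("unit_concentration must be a positive number (mg/ml)", call. = FALSE)
  }
  structure(list(name = name, reference = reference,
                 unit_concentration = as.numeric(unit_concentration)),
            class = "component_profile")
}

#' @method print component_profile
#' @export
print.component_profile <- function(x, ...) {
  cat(sprintf("<component_profile> %s: unit weight = %g mg/ml, %d channels\n",
              x$name, x$unit_concentration, length(x$reference)))
  invisible(x)
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Component library
#'
#' An ordered collection of calibrated [component_profile()]s sharing one
#' wavenumber grid.  Construction checks that names are unique, that all
#' references are on the same grid, and that no two profiles are
#' near-collinear (pairwise cosine similarity must stay below 0.999), since
#' collinear columns make the linear-combination fit ill-posed.
#'
#' @param components List of [component_profile()] objects.
#' @param provenance Free-text note on the calibration substances (for the
#'   default library: serum albumin for protein, purified yeast RNA,
#'   genomic DNA, heart-lipid extract).
#' @return An object of class `component_library` with elements
#'   `components` (named list), `grid`, `provenance`.
#' @export
component_library <- function(components, provenance = "") {
  if (!is.list(components) || length(components) < 1L) {
    stop("components must be a non-empty list of component_profile objects",
         call. = FALSE)
  }
  ok <- vapply(components, inherits, logical(1), what = "component_profile")
  if (!all(ok)) stop("all components must be component_profile objects",
                     call. = FALSE)
  nms <- vapply(components, function(x) x$name, character(1))
  if (anyDuplicated(nms)) {
    stop("component names must be unique; duplicated: ",
         nms[duplicated(nms)][1L], call. = FALSE)
  }
  grid <- components[[1L]]$reference$wavenumbers
  for (cp in components[-1L]) {
    if (!same_grid(cp$reference$wavenumbers, grid)) {
      stop("component '", cp$name, "' is not on the library grid", call. = FALSE)
    }
  }
  n <- length(components)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      cs <- cosine_similarity(components[[i]]$reference$intensities,
                              components[[j]]$reference$intensities)
      if (cs >= 0.999) {
        stop(sprintf(paste0("components '%s' and '%s' are collinear ",
                            "(cosine similarity %.4f >= 0.999)"),
                     nms[i], nms[j], cs), call. = FALSE)
      }
    }
  }
  names(components) <- nms
  structure(list(components = components, grid = grid,
                 provenance = provenance),
            class = "component_library")
}

#' @method print component_library
#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %d components on %d channels (%g-%g cm^-1)\n",
              length(x$components), length(x$grid), min(x$grid), max(x$grid)))
  for (cp in x$components) {
    cat(sprintf("  %-10s unit weight = %g mg/ml\n", cp$name,
                cp$unit_concentration))
  }
  invisible(x)
}

component_names <- function(library) names(library$components)

#' Matrix of component reference intensities
#'
#' @param library A [component_library()].
#' @return Numeric matrix, one column per component, named.
#' @noRd
component_matrix <- function(library) {
  vapply(library$components, function(cp) cp$reference$intensities,
         numeric(length(library$grid)))
}

#' Write a component library to a directory bundle
#'
#' The bundle is a directory holding one two-column ASCII spectrum file per
#' component plus a `manifest.json` listing names, unit concentrations,
#' file names and the provenance note — so reference spectra remain
#' individually inspectable with any text tool.
#'
#' @param library A [component_library()].
#' @param path Directory to create/fill.
#' @return Invisibly, `path`.
#' @export
write_component_library <- function(library, path) {
  stopifnot(inherits(library, "component_library"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(library$components, function(cp) {
    fname <- paste0(cp$name, ".txt")
    write_spectrum(cp$reference, file.path(path, fname))
    list(name = cp$name, unit_concentration = cp$unit_concentration,
         file = fname)
  })
  manifest <- list(format = "ramanbca component library",
                   provenance = library$provenance,
                   components = unname(entries))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a component library bundle
#'
#' @param path Directory written by [write_component_library()] (or
#'   hand-assembled with the same layout).
#' @return A [component_library()].
#' @export
read_component_library <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under '", path, "'", call. = FALSE)
  manifest <- jsonlite::read_json(mf)
  comps <- lapply(manifest$components, function(e) {
    if (is.null(e$name) || !nzchar(e$name)) {
      stop("manifest entry without a component name", call. = FALSE)
    }
    if (is.null(e$unit_concentration)) {
      stop("manifest entry for '", e$name, "' is missing unit_concentration",
           call. = FALSE)
    }
    ref <- read_spectrum(file.path(path, e$file))
    component_profile(e$name, ref, e$unit_concentration)
  })
  component_library(comps,
                    provenance = if (is.null(manifest$provenance)) "" else
                      manifest$provenance)
}

#' Default unit concentration for an analyte
#'
#' The calibration convention: spectral weight 1.0 corresponds to 100 mg/ml
#' for proteins and 20 mg/ml for RNA, DNA and lipids.
#'
#' @param analyte Analyte name(s).
#' @return Numeric vector of unit concentrations in mg/ml.
#' @export
default_unit_concentration <- function(analyte) {
  ifelse(tolower(analyte) == "protein", 100, 20)
}
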