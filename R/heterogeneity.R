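# The heterogeneity statistics operate on the long-format profiles table
# written by batch_fit()/simulate_population(): columns cell_line, cell_id,
# organelle, organelle_index, analyte, concentration_mgml.

check_profiles <- function(profiles,
                           value_col = "concentration_mgml") {
  need <- c("cell_id", "organelle", "analyte", value_col)
  missing <- setdiff(need, names(profiles))
  if (length(missing)) {
    stop("profiles table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(profiles) == 0L) stop("profiles table is empty", call. = FALSE)
  invisible(profiles)
}

profile_values <- function(profiles, organelle, analyte,
                           value_col = "concentration_mgml",
                           organelle_index = NULL) {
  sel <- profiles$organelle == organelle & profiles$analyte == analyte
  if (!is.null(organelle_index) && "organelle_index" %in% names(profiles)) {
    sel <- sel & profiles$organelle_index == organelle_index
  }
  sub <- profiles[sel, , drop = FALSE]
  stats::setNames(sub[[value_col]], sub$cell_id)
}

strength_label <- function(r) {
  a <- abs(r)
  if (a < 0.3) "weak"
  else if (a < 0.5) "moderate"
  else if (a <= 0.7) "moderate-to-high"
  else "strong"
}

fisher_ci <- function(r, n, conf_level = 0.95) {
  if (n <= 3 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  hw <- stats::qnorm((1 + conf_level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

make_correlation_result <- function(org_a, ana_a, org_b, ana_b, xa, xb,
                                    conf_level = 0.95) {
  ids <- intersect(names(xa), names(xb))
  n <- length(ids)
  if (n < 3L) {
    miss_a <- length(setdiff(names(xb), names(xa)))
    miss_b <- length(setdiff(names(xa), names(xb)))
    stop(sprintf(paste0("fewer than 3 complete cell pairs (%d); %d cells ",
                        "lacked %s/%s and %d lacked %s/%s"),
                 n, miss_a, org_a, ana_a, miss_b, org_b, ana_b),
         call. = FALSE)
  }
  a <- xa[ids]; b <- xb[ids]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("Pearson r undefined: zero variance in ",
         if (stats::sd(a) == 0) paste(org_a, ana_a) else paste(org_b, ana_b),
         call. = FALSE)
  }
  r <- stats::cor(a, b)
  ci <- fisher_ci(r, n, conf_level)
  p <- tryCatch(stats::cor.test(a, b)$p.value, error = function(e) NA_real_)
  data.frame(organelle_a = org_a, analyte_a = ana_a,
             organelle_b = org_b, analyte_b = ana_b,
             r = r, n = n, ci_lo = ci[1], ci_hi = ci[2], p = p,
             strength = strength_label(r), stringsAsFactors = FALSE)
}

#' Summarize concentration profiles by group
#'
#' Per (cell_line, organelle, analyte) group: number of cells, mean, SD,
#' minimum and maximum concentration.  Single-observation groups report
#' SD 0 with `n = 1`.
#'
#' @param profiles Long-format profiles table (see [batch_fit()]).
#' @param value_col Column to summarize (default `"concentration_mgml"`).
#' @return `data.frame` sorted by (cell_line, organelle, analyte).
#' @export
summarize_profiles <- function(profiles, value_col = "concentration_mgml") {
  check_profiles(profiles, value_col)
  cl <- if ("cell_line" %in% names(profiles)) profiles$cell_line else ""
  key <- interaction(cl, profiles$organelle, profiles$analyte, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(profiles)), key), function(idx) {
    sub <- profiles[idx, , drop = FALSE]
    v <- sub[[value_col]]
    data.frame(cell_line = if ("cell_line" %in% names(sub))
                 sub$cell_line[1L] else NA_character_,
               organelle = sub$organelle[1L],
               analyte = sub$analyte[1L],
               n = length(v),
               mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               min = min(v),
               max = max(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_line, out$organelle, out$analyte), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation between two analytes within one organelle
#'
#' Pearson correlation over cells between the concentrations of two
#' analytes measured in the same organelle, paired strictly by `cell_id`;
#' confidence interval by the Fisher z transform.
#'
#' @param profiles Long-format profiles table.
#' @param organelle Organelle name.
#' @param analytes Character vector of the two analytes.
#' @param value_col Value column (default `"concentration_mgml"`; Pearson r
#'   is identical on weights or mg/ml since the two differ by a positive
#'   per-analyte scale).
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return One-row `data.frame` with `r`, `n`, `ci_lo`, `ci_hi`, `p` and a
#'   `strength` label (|r| < 0.3 weak, 0.3-0.5 moderate, 0.5-0.7
#'   moderate-to-high, > 0.7 strong).
#' @export
correlate_within <- function(profiles, organelle, analytes,
                             value_col = "concentration_mgml",
                             conf_level = 0.95) {
  check_profiles(profiles, value_col)
  stopifnot(length(analytes) == 2L)
  xa <- profile_values(profiles, organelle, analytes[1L], value_col)
  xb <- profile_values(profiles, organelle, analytes[2L], value_col)
  make_correlation_result(organelle, analytes[1L], organelle, analytes[2L],
                          xa, xb, conf_level)
}

#' Correlation between analytes in two organelles of the same cell
#'
#' Pearson correlation over cells between an analyte concentration in one
#' organelle and an analyte concentration in another organelle, paired by
#' `cell_id` with pairwise-complete deletion.  When the same organelle
#' appears on both sides (e.g. two mitochondria per cell) the two
#' per-cell profiles are paired by acquisition order via the
#' `organelle_index` column (1 vs 2).
#'
#' @param profiles Long-format profiles table.
#' @param organelle_a,analyte_a First member of the pair.
#' @param organelle_b,analyte_b Second member.
#' @param value_col,conf_level As in [correlate_within()].
#' @return One-row `data.frame` as in [correlate_within()].
#' @export
correlate_between <- function(profiles, organelle_a, analyte_a,
                              organelle_b, analyte_b,
                              value_col = "concentration_mgml",
                              conf_level = 0.95) {
  check_profiles(profiles, value_col)
  same_org <- identical(organelle_a, organelle_b)
  idx_a <- if (same_org) 1L else NULL
  idx_b <- if (same_org) 2L else NULL
  xa <- profile_values(profiles, organelle_a, analyte_a, value_col, idx_a)
  xb <- profile_values(profiles, organelle_b, analyte_b, value_col, idx_b)
  make_correlation_result(organelle_a, analyte_a, organelle_b, analyte_b,
                          xa, xb, conf_level)
}

#' One-way ANOVA between cell lines
#'
#' Classical fixed-effects one-way ANOVA of one analyte's concentration in
#' one organelle across cell lines.
#'
#' @param profiles Long-format profiles table with a `cell_line` column.
#' @param organelle Organelle name.
#' @param analyte Analyte name.
#' @param alpha Significance level (default 0.05).
#' @param value_col Value column.
#' @return One-row `data.frame` with group sizes, `F`, `p` and
#'   `significant` (p < alpha).
#' @export
anova_between_lines <- function(profiles, organelle, analyte, alpha = 0.05,
                                value_col = "concentration_mgml") {
  check_profiles(profiles, value_col)
  if (!"cell_line" %in% names(profiles)) {
    stop("profiles table lacks a cell_line column", call. = FALSE)
  }
  sub <- profiles[profiles$organelle == organelle &
                    profiles$analyte == analyte, , drop = FALSE]
  groups <- split(sub[[value_col]], sub$cell_line)
  if (length(groups) < 2L) {
    stop("ANOVA needs at least 2 cell-line groups, got ", length(groups),
         call. = FALSE)
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(sub[[value_col]]) == 0) {
    # no variation at all: between- and within-group SS are both zero
    Fv <- 0; pv <- 1
  } else {
    fit <- stats::aov(v ~ g, data = data.frame(v = sub[[value_col]],
                                               g = factor(sub$cell_line)))
    an <- summary(fit)[[1L]]
    Fv <- an[["F value"]][1L]
    pv <- an[["Pr(>F)"]][1L]
    if (is.nan(Fv) || is.na(Fv)) { Fv <- 0; pv <- 1 }
  }
  data.frame(organelle = organelle, analyte = analyte,
             groups = paste(sprintf("%s(n=%d)", names(sizes), sizes),
                            collapse = ", "),
             F = Fv, p = pv, significant = pv < alpha,
             stringsAsFactors = FALSE)
}

#' All pairwise correlations over an (organelle, analyte) scope
#'
#' Computes the Pearson correlation for every unordered pair of
#' (organelle, analyte) variables in the scope (within-organelle pairs via
#' [correlate_within()] semantics, cross-organelle pairs via
#' [correlate_between()]), plus the unit diagonal.  Off-diagonal p-values
#' receive a Benjamini-Hochberg adjustment (`p_adj`, `significant_adj`) as
#' supplementary columns; raw coefficients are never filtered.  Failing
#' entries (too few pairs, zero variance) are collected as rows with an
#' `error` message, not propagated as errors.
#'
#' @param profiles Long-format profiles table.
#' @param organelles Organelles in scope (default: those present).
#' @param analytes Analytes in scope (default: those present).
#' @param value_col,conf_level As in [correlate_within()].
#' @param alpha Significance level for the adjusted flags.
#' @return `data.frame` with one row per variable pair.
#' @export
correlation_matrix <- function(profiles, organelles = NULL, analytes = NULL,
                               value_col = "concentration_mgml",
                               conf_level = 0.95, alpha = 0.05) {
  check_profiles(profiles, value_col)
  if (is.null(organelles)) organelles <- unique(profiles$organelle)
  if (is.null(analytes)) analytes <- unique(profiles$analyte)
  vars <- expand.grid(organelle = organelles, analyte = analytes,
                      stringsAsFactors = FALSE)
  vars <- vars[order(match(vars$organelle, organelles),
                     match(vars$analyte, analytes)), , drop = FALSE]
  nv <- nrow(vars)
  rows <- list()
  for (i in seq_len(nv)) for (j in i:nv) {
    oa <- vars$organelle[i]; aa <- vars$analyte[i]
    ob <- vars$organelle[j]; ab <- vars$analyte[j]
    if (i == j) {
      xa <- profile_values(profiles, oa, aa, value_col)
      rows[[length(rows) + 1L]] <- data.frame(
        organelle_a = oa, analyte_a = aa, organelle_b = ob, analyte_b = ab,
        r = 1, n = length(xa), ci_lo = 1, ci_hi = 1, p = NA_real_,
        strength = "strong", error = NA_character_, stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch({
      cr <- if (oa == ob) {
        correlate_within(profiles, oa, c(aa, ab), value_col, conf_level)
      } else {
        correlate_between(profiles, oa, aa, ob, ab, value_col, conf_level)
      }
      cr$error <- NA_character_
      cr
    }, error = function(e) {
      data.frame(organelle_a = oa, analyte_a = aa,
                 organelle_b = ob, analyte_b = ab,
                 r = NA_real_, n = NA_integer_, ci_lo = NA_real_,
                 ci_hi = NA_real_, p = NA_real_, strength = NA_character_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  off <- out$organelle_a != out$organelle_b | out$analyte_a != out$analyte_b
  out$p_adj <- NA_real_
  out$p_adj[off] <- stats::p.adjust(out$p[off], method = "BH")
  out$significant_adj <- out$p_adj < alpha
  out
}
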