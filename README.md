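# ramanbca

Biomolecular component analysis (BCA) of single-organelle micro-Raman
spectra: decompose the Raman spectrum of one nucleolus, ER region or
mitochondrion of a live cell into **absolute concentrations (mg/ml) of
proteins, RNA, DNA and lipids**, then quantify cell-to-cell heterogeneity
and time-lapse dynamics of those concentrations.

The package is aimed at Raman microspectroscopists and quantitative cell
biologists who have (or want to simulate) single-point confocal Raman
spectra of subcellular structures and need the full chemometric chain in
one place:

* spectral I/O (two-column ASCII/CSV, inspectable component-library
  bundles with a JSON manifest), grid resampling;
* preprocessing: background subtraction, optional Savitzky–Golay
  smoothing, asymmetric-least-squares (ALS) or iterative-polynomial
  baseline correction, replicate averaging with per-channel SDs;
* concentration calibration of reference profiles (through-origin
  regression of projection amplitudes; weight 1.0 ≡ 100 mg/ml protein,
  20 mg/ml RNA/DNA/lipid);
* the decomposition engine: non-negative linear-combination fit with a
  residual polynomial and a bounded global wavenumber-shift nuisance
  parameter, detection flagging at weight 0.1;
* population statistics (summaries, within- and cross-organelle Pearson
  correlations with Fisher-z intervals, one-way ANOVA between cell
  lines) and time-lapse oscillation-rate analysis;
* a fully seeded synthetic-data generator (spectra, cell populations
  with prescribed correlation structure, time series) so every result
  can be validated against known ground truth.

## The model

A preprocessed spectrum `S(ν)` is fitted as

    S(ν) ≈ Σ_i c_i R_i(ν − δ) + P(ν),   c_i ≥ 0

where `R_i` are calibrated component references, `c_i` the spectral
weights (concentration = `c_i` × unit concentration), `δ` a global
wavenumber shift (±3 cm⁻¹) and `P` a low-order residual polynomial.  The
inner problem is solved exactly by active-set non-negative least squares
after projecting out the polynomial; the shift by bounded 1-D search.
The methods vignette (`vignettes/ramanbca-methods.Rmd`) explains the
science and every numerical choice.

## Worked example

```r
library(ramanbca)

lib <- default_component_library()          # protein, RNA, lipid, DNA

# a nucleolus-like spectrum: 85 mg/ml protein, 27.5 RNA, 22.5 lipid,
# broad fluorescence baseline, SNR ~ 20
sim <- simulate_spectrum(
  lib, c(protein = 0.85, RNA = 1.375, lipid = 1.125),
  baseline = list(amplitude = 0.7, center = 1200, width = 400),
  noise_sd = 0.073, seed = 42,
  meta = list(cell_id = "cell_001", cell_line = "HeLa",
              organelle = "nucleolus"))

pre <- preprocess_spectrum(sim$spectrum)    # ALS baseline correction
fit <- fit_lcm(pre$processed, lib)          # the BCA decomposition
fit
```

```
<bca_fit>
        weight concentration_mgml weight_sd detected
protein 0.8355              83.55    0.0130     TRUE
RNA     1.3905              27.81    0.0124     TRUE
lipid   1.1088              22.18    0.0130     TRUE
DNA     0.0000               0.00        NA    FALSE
  shift = 0.011 cm^-1, R^2 = 0.9517, RMS residual = 0.07283
```

The true concentrations (85, 27.5, 22.5 mg/ml) are recovered within ~2%
despite the baseline and noise; DNA, absent from the simulation, comes
back at weight 0 and is flagged undetected (threshold 0.1).

From many such fits, `batch_fit()` builds a long-format profiles table,
and then:

```r
pop <- simulate_population(default_population_spec("WI38", n_cells = 200,
                                                   seed = 1))
correlate_within(pop, "nucleolus", c("protein", "RNA"))
#   organelle_a analyte_a organelle_b analyte_b         r   n     ci_lo     ci_hi            p strength
# 1   nucleolus   protein   nucleolus       RNA 0.7999806 200 0.7437933 0.8449415 8.441389e-46   strong
```

Time-lapse series are summarized by significant direction changes per
hour (`oscillation_rate()`) and compared between groups with a rank test
(`compare_dynamics()`).

A thin command-line wrapper is installed at
`system.file("cli", "ramanbca", package = "ramanbca")` with subcommands
`simulate`, `fit`, `analyze`, `dynamics` and `pipeline`; `pipeline --demo
--seed 7 --out dir` runs the whole synthetic chain reproducibly and
writes a manifest with config, seed and output hashes.

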