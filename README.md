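# epistrat

Quantitative analysis of how the single-layered embryonic surface
epithelium becomes the stratified mouse epidermis (E12.5–E18.5), for
developmental and stem-cell biologists who want the tissue-growth
bookkeeping, the lineage kinetics, and the division-orientation
statistics of this system as tested, reusable code.

## The model

Absolute cell counts are not measurable in sections, so layer cell
numbers are tracked through a relative index combining linear densities
and body-axis lengths in the sagittal (s) and orthogonal (o) planes:

    n(t) = ρ_s l_s × ρ_o l_o        (arbitrary units; only ratios matter)

Growth happens in two phases:

* **Amplification (E12.5–E15.5).** Equipotent progenitors duplicate,
  p → p + p at rate λ₁. The ~7.4-fold rise of the total index over these
  three days gives λ₁ = ln(7.4)/3 ≈ 0.667/day (printed 0.66/day).
* **Maintenance (E15.5–E18.5).** Basal progenitors b divide at rate λ₂
  and either duplicate (probability 1−r) or commit and stratify into the
  non-proliferative suprabasal pool s (probability r):

      ḃ = λ₂(1−2r) b,   ṡ = λ₂ r b

  Proportionate growth of both layers (ḃ = ṡ) forces r = 1/3 exactly,
  and the observed twofold rise over three days gives λ₂ = ln 2 ≈
  0.693/day (printed 0.7/day).

As a consistency check, a short EdU pulse should mark a fraction λ·t_s of
cycling cells — 0.8 × (1/3 day) = 0.27 — doubling to ~0.53 after the
labeled cohort divides once.

The package provides the closed forms, exact Gillespie simulators, an
agent-based EdU pulse-chase model, angle binning
(parallel 0–29°, oblique 30–59°, perpendicular 60–90°) with chi-squared,
Kolmogorov–Smirnov, ANOVA and t-test comparisons, log-linear two-phase
fitting with an animal-level bootstrap, and a calibrated synthetic-data
generator standing in for the microscopy measurement tables.

## Worked example

```r
library(epistrat)

cfg <- generator_config(seed = 20)          # synthetic study conditions
tabs <- generate_tables(cfg)                # growth, density, EdU, angles
series <- build_cell_number_series(tabs$density, tabs$growth)

summarize_phase(series, "total", 12.5, 15.5)
#> Phase E12.5-E15.5 (total layer): fold change 6.98, exponential trend (score 17.6)
summarize_phase(series, "total", 15.5, 18.5)
#> Phase E15.5-E18.5 (total layer): fold change 1.96, linear trend (score -3.09)

fit_two_phase(series, n_bootstrap = 199, seed = 1,
              densities = tabs$density, growth = tabs$growth)
#>        parameter estimate ci_low ci_high
#>    lambda_phase1    0.655  0.628   0.687
#>  phase2_exponent    0.231  0.204   0.258
#>    lambda_phase2    0.692  0.613   0.773
```

The total index expands ~7-fold and is classified exponential during
amplification, then ~2-fold with a linear-like trend during maintenance;
the fitted rates bracket the model values 0.66/day and 0.7/day, with the
phase-2 rate obtained from the net exponent λ₂(1−2r) under r = 1/3.

```r
e165 <- subset(tabs$angles, stage == 16.5)
chi_squared_bins(
  bin_angles(subset(e165, genotype == "control")$angle_deg)$counts,
  bin_angles(subset(e165, genotype == "mutant")$angle_deg)$counts)
#> chi-squared (2x3 bins): statistic = 11.15, df = 2, p = 0.003796

short_pulse_fraction(0.8, 1/3)                                  # 0.267
pulse_chase_fraction(pulse_params(0.8, n_divisions_chase = 1))  # 0.533
```

The mutant's shift from ~40% to ~60% perpendicular divisions at E16.5 is
detected by the chi-squared comparison, and the EdU predictions reproduce
the 0.27 / ~0.5 labeled fractions.

`run_pipeline(pipeline_config(generator_config(seed = 1)))` chains all of
the above and (optionally) writes every table as CSV plus a JSON report.

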