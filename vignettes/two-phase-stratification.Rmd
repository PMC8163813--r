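---
title: "The two-phase model of embryonic epidermal stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-phase model of embryonic epidermal stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistrat)
```

## The biological problem and the model

Between embryonic day (E) 12.5 and E18.5 the mouse back-skin epidermis
turns from an essentially single-layered epithelium into a stratified
barrier. Because absolute cell counts are not measurable in sections, the
package works with a *relative* cell-number index: if $\rho_{\mathrm{s}}$
and $\rho_{\mathrm{o}}$ are a layer's linear cell densities in sagittal and
orthogonal (dorso-ventral) sections and $l_{\mathrm{s}}, l_{\mathrm{o}}$
the body-axis lengths, the total cell number of that layer grows in
proportion to

$$n(t) = \rho_{\mathrm{s}} l_{\mathrm{s}} \times \rho_{\mathrm{o}} l_{\mathrm{o}}.$$

This is `cell_number_index()`; only ratios of the index across stages are
meaningful, and the arbitrary proportionality constant is fixed to 1 (it
cancels from every fold change).

The dynamics are modelled in two phases.

**Amplification (E12.5–E15.5).** A single equipotent progenitor pool
duplicates at a constant rate, $p \to p + p$ at rate $\lambda_1$, so the
expected count grows as $n_0 e^{\lambda_1 t}$ (`phase1_closed_form()`).
A ~7.4-fold rise over these three days corresponds to
$\lambda_1 = \ln(7.4)/3 \approx 0.667$/day, conventionally printed as
0.66/day (`rate_from_fold()`).

**Maintenance (E15.5–E18.5).** The basal layer is a progenitor population
$b$ and the suprabasal layers a non-proliferative population $s$. At rate
$\lambda_2$ a basal cell either duplicates (probability $1-r$) or commits
to terminal differentiation and stratifies (probability $r$), giving

$$\dot b = \lambda_2 (1 - 2r)\, b, \qquad \dot s = \lambda_2 r\, b.$$

The stratification event is implemented as a direct conversion (one basal
cell removed, one suprabasal cell added): this is the unique reading
consistent with the $\dot b$ equation above under the stated event rate;
whether the underlying biology is delamination or oriented division is
left open by the model. Proportionate growth of both layers
($\dot b = \dot s$) forces $r = 1/3$ exactly (`r_from_flux_ratio()`), and
with equal layer sizes at the phase boundary the closed form
(`phase2_closed_form()`) keeps $b = s$ at all later times. A twofold rise
over three days then gives $\lambda_2 = \ln 2 \approx 0.693$/day, printed
as 0.7/day.

The two rates, and the $\lambda = 0.8$/day used in the EdU consistency
check below, are deliberately *not* harmonized: each is quoted at the
precision of the observable it is derived from, and the package keeps
them as independent parameters (`lineage_params()`).

```{r closed-forms}
phase1_closed_form(1, 0.66, 3)                 # amplification fold
phase2_closed_form(1, 1, 0.7, 1 / 3, 3)$total / 2  # maintenance fold
r_from_flux_ratio(1)
```

## Stochastic simulation

`simulate_phase1()` and `simulate_phase2()` are exact event-driven
(Gillespie) simulators using the population-level total rate
$\lambda n$: waiting times are exponential, and in phase 2 each event is a
duplication with probability $1-r$, otherwise a conversion. Per-agent
clocks would give the same law at higher cost; populations here are
thousands of cells, well inside the regime where the aggregate-rate
formulation is fast and unbiased. $b = 0$ is absorbing and freezes the
trajectory rather than erroring. Trajectories are sampled onto a fixed
output grid (default 0.1 day) regardless of event times, so replicates
align for averaging.

```{r gillespie}
sim <- simulate_phase1(2000, 0.66, 3, n_replicates = 50, seed = 1)
mean(sim$total[sim$time == 3]) / 2000   # vs exp(1.98) = 7.24
```

## EdU pulse-labeling predictions

With S-phase duration $t_s$ (default 1/3 day = 8 h) and cycle time
$1/\lambda$, a short pulse marks the fraction of cells in S-phase,
$\lambda t_s$ — at $\lambda = 0.8$/day this is $0.8 \times 1/3 = 0.27$
(`short_pulse_fraction()`). After the labeled cohort completes one round
of division its number doubles, to $\approx 0.53$
(`pulse_chase_fraction()`); how many rounds have completed is an explicit
parameter (`n_divisions_chase`) rather than being inferred from chase
timing, because the cohort-timing argument is heuristic.

`simulate_edu_cohort()` is the mechanistic check: an agent model in which
every cell carries a cycle of length $1/\lambda$ (optionally
gamma-distributed via `cycle_cv`), a uniformly random initial phase, and
an S-phase window placed immediately before division (G2+M collapsed to
zero; the placement can be shifted with `s_phase_offset`). Cells whose
S-phase overlaps the pulse window are labeled and both daughters inherit
the label. As the pulse shrinks the labeled fraction converges to
$\lambda t_s$. One behaviour deserves emphasis: over a chase the labeled
*fraction* is not monotone. The labeled cohort is pseudo-synchronized
(it sits just before mitosis), so the fraction first rises toward
$2\lambda t_s/(1+\lambda t_s)$ while the cohort divides, then relaxes
back as unlabeled cells complete their own divisions. The labeled *count*
is non-decreasing, and that is the invariant the tests assert.

## Division-orientation statistics

Angles between the division axis and the basement membrane are analysed
in the field's three categories. The published integer ranges (0–29°,
30–59°, 60–90°) are realized for continuous measurements as the bins
$[0, 30)$, $[30, 60)$, $[60, 90]$: 30° is oblique, 60° and 90°
perpendicular. Angles are assumed already folded into $[0, 90]$ by the
measurement convention (the acute angle is recorded); out-of-range values
are rejected with their row identified, never folded silently.

Group comparisons use the standard machinery: Pearson chi-squared on the
2×3 count table (`chi_squared_bins()`; note the statistic scales with
sample size, so it is *not* invariant under multiplying both groups'
counts — documented, not hidden), the asymptotic two-sample
Kolmogorov–Smirnov test on raw angles (`ks_two_sample()`), a pooled
variance two-tailed t-test (`compare_group_means()`), and a two-way
ANOVA on per-animal bin proportions (`proportions_anova()`). The exact
ANOVA design on angles is not standardized in this literature; the
implemented reading — `proportion ~ genotype * bin` with the
genotype-by-bin interaction as the reported result — tests whether the
*shape* of the orientation distribution differs between genotypes, which
is the scientific question (the genotype main effect is structurally null
because each animal's proportions sum to 1). That sum constraint also
makes the classical F reference anticonservative for small animal
numbers, so `n_permutations > 0` substitutes a permutation p-value
(shuffling genotype labels across animals), which is calibrated under the
exchangeable null; the classical F remains the default because it is the
named test in common practice. P-values are reported raw, with no
multiple-testing adjustment.

## The synthetic-data generator

No per-animal measurement tables are publicly deposited for this system,
so `generator_config()` + `generate_tables()` emulate them; they are the
package's study conditions, not a tuning knob.

* **Axis lengths** follow `intercept + slope * (stage − 12.5)` with
  Gaussian noise (SD 0.5 mm): sagittal 9.0 mm at E12.5 growing
  2.2 mm/day, orthogonal 4.5 mm at E12.5 growing 1.1 mm/day —
  crown–rump-scale values with a ~1.42-fold per-axis rise over the
  maintenance phase, i.e. a tissue-area doubling. The intercept is
  parameterized at the first observed stage rather than at day 0 because
  the extrapolated day-0 intercept of any realistic embryonic growth line
  is negative and physically meaningless.
* **Densities** are explicit per-stage knots (not fitted functions, so
  the calibration stays transparent and editable) with Gaussian noise
  (SD 1 cell/100 µm), truncated at zero: the basal density rises slightly
  (13.5 → 15.0 cells/100 µm over the amplification phase, then flat) and
  the suprabasal density rises from 0 at E12.5 to parity (15.0) at E15.5,
  then stays flat. A zero knot is generated as exactly zero — a layer
  that does not exist yet has no cells to miscount. Together with the
  area trajectory these knots put the noise-free total-index folds at
  7.42 (E12.5–E15.5) and 2.03 (E15.5–E18.5), matching the measured ~7.4
  and ~2.
* **EdU counts** are binomial draws, 100 counted cells per animal (the
  per-animal denominators behind the published fractions are not stated;
  100 is a typical section count and is flagged as an assumption). Basal
  fractions run at ~0.5 during amplification and drop ~40% afterwards;
  suprabasal fractions are high (0.35–0.45) during E13.5–E15.5 and
  collapse to ≤0.05 from E16.5.
* **Angles** come from three-component truncated-normal mixtures
  (components centred at 15°, 45°, 75°, SD 9°). At E15.5 both genotypes
  are random (equal bin masses); at E16.5/E17.5 the control preset holds
  ≈39% perpendicular mass and the mutant ≈58%, the ~40% vs ~60% contrast.
* **Replicates** mirror typical experimental group sizes: 10 embryos per
  stage for lengths, 5 animals per stage for densities/EdU/angles, 30
  angles per animal.

A master seed spawns named substreams, so each table is reproducible in
isolation and independent of generation order. What the generator does
*not* emulate: section-to-section heterogeneity within an animal, stage
misassignment, litter effects, or any imaging noise. Passing tests
therefore demonstrate that the pipeline recovers the truth under clean,
correctly-specified noise — they do not certify robustness to those real
data pathologies.

```{r generator}
cfg <- generator_config(seed = 1)
series <- build_cell_number_series(generate_density_table(cfg),
                                   generate_growth_table(cfg))
summarize_phase(series, "total", 12.5, 15.5)
summarize_phase(series, "total", 15.5, 18.5)
```

## Inference and its design choices

`fit_two_phase()` performs log-linear least squares on the total index
within each phase. The phase boundary is *fixed* at E15.5, not estimated:
seven time points cannot support a free changepoint plus two exponents
with any robustness, and the boundary is asserted by the density-parity
observation independently of the fit. The maintenance phase is fitted as
a small-exponent exponential rather than a literal straight line — at a
factor of 2 over three days the two are indistinguishable
(`summarize_phase()` classifies the trend by AIC, log-normal versus
normal likelihood on the same raw scale, with zero-residual fits detected
explicitly and a constant series reported as linear), and the exponential
is what the model actually predicts. The fitted phase-2 slope estimates
the net exponent $\lambda_2(1-2r)$; the reported `lambda_phase2`
multiplies it by 3, i.e. imposes the flux-balance value $r = 1/3$.

Uncertainty comes from a bootstrap that resamples *animals* (and embryos
for lengths) within each stage — the animal is the replicate unit, not
the cell. `recovery_experiment()` wraps the generate → rebuild → refit
loop and reports bias and RMSE; `config_from_params()` calibrates density
knots to an arbitrary parameter set by inverting the index relation
($\rho \propto \sqrt{n/A}$, with a suprabasal share ramping linearly to
1/2 at the switch), so ground truth is exact and noise-free recovery is
machine-precision.

Numerical conventions worth recording: $r = 1/2$ (zero net basal growth)
is handled by the analytic continuity limit, not a division;
`rate_from_fold()` refuses $r = 1/2$ because the rate is unidentifiable
from a fold there; degenerate zero-variance inputs to the statistical
tests return the limiting p-values (0 or 1) explicitly rather than NaN.

## Problem sizes

The shipped tests run the simulators at the scales at which the model's
claims are quantitative but cheap: 200 replicates of 2000 founder cells
for the amplification fold, 200 replicates of 1000+1000 cells for the
maintenance phase, 50,000 agents for the EdU short-pulse limit, 1000/500
simulated datasets for the chi-squared type-I/power checks, 25–50
datasets for bootstrap coverage and recovery. These sizes put the
Monte-Carlo standard errors well inside the tolerances being asserted.

## Known limitations

* The index is relative; nothing here estimates absolute cell counts or
  3-D tissue geometry.
* Phase 1 models a single undifferentiated pool; the split into basal
  and suprabasal compartments at the switch (default 1/2, matching the
  observed parity) is a modelling convenience exposed as a parameter,
  and the suprabasal proliferation seen during amplification is not
  mechanistically resolved.
* The EdU model ignores label dilution across divisions and
  pharmacokinetics of the pulse.
* The chi-squared and KS comparisons treat angles as independent across
  cells, ignoring within-animal correlation; the per-animal ANOVA and
  t-test are the analyses that respect the replicate structure.
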