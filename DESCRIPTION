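Package: epistrat
Title: Two-Phase Kinetics of Embryonic Epidermal Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for studying how a single-layered embryonic
    epithelium becomes a stratified epidermis. Reconstructs relative basal and
    suprabasal cell numbers from body-axis lengths and layer densities,
    implements the two-phase lineage model (an exponential amplification phase
    of progenitor duplication followed by a slow maintenance phase in which
    basal progenitors either duplicate or commit and stratify), provides exact
    event-driven (Gillespie) simulators alongside the closed-form solutions,
    predicts EdU pulse-labeling fractions from the division kinetics, analyses
    mitotic division-orientation angles (parallel/oblique/perpendicular
    binning, radial histograms, chi-squared, Kolmogorov-Smirnov, ANOVA and
    t-test comparisons), and estimates the kinetic parameters from cell-number
    series with bootstrap confidence intervals. A calibrated synthetic-data
    generator emulates the measurement tables so the full pipeline can be
    exercised and validated without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
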