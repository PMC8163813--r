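#' Truncated-normal mixture over division-orientation angles
#'
#' Defines a mixture of normal components truncated to `[0, 90]` degrees,
#' used to generate division-orientation angle samples for one
#' (genotype, stage) group.
#'
#' @param weights Non-negative component weights; normalized to sum to 1.
#' @param means Component means in degrees.
#' @param sds Component standard deviations in degrees (positive).
#' @return An object of class `"angle_mixture"`.
#' @seealso [mixture_bin_mass()], [generate_angle_dataset()]
#' @examples
#' angle_mixture(c(1, 1, 1) / 3, c(15, 45, 75), c(9, 9, 9))
#' @export
angle_mixture <- function(weights, means, sds) {
  if (length(weights) != length(means) || length(means) != length(sds)) {
    stop("`weights`, `means` and `sds` must have equal length", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("mixture weights must be non-negative with positive sum",
         call. = FALSE)
  }
  if (any(sds <= 0)) stop("component SDs must be positive", call. = FALSE)
  structure(list(weights = weights / sum(weights), means = means, sds = sds),
            class = "angle_mixture")
}

#' Analytic probability mass of an angle mixture on an interval
#'
#' Integrates the truncated-normal mixture density over `[lo, hi]` within
#' the support `[0, 90]`. Used to calibrate presets (e.g. the mass on
#' `[60, 90]` is the expected perpendicular proportion).
#'
#' @param mixture An [angle_mixture()].
#' @param lo,hi Interval bounds in degrees within `[0, 90]`.
#' @return The mixture probability mass on `[lo, hi]`.
#' @examples
#' m <- angle_mixture(c(0.4, 0.2, 0.4), c(15, 45, 75), c(9, 9, 9))
#' mixture_bin_mass(m, 60, 90)
#' @export
mixture_bin_mass <- function(mixture, lo, hi) {
  stopifnot(inherits(mixture, "angle_mixture"), lo <= hi, lo >= 0, hi <= 90)
  z <- function(x, m, s) stats::pnorm((x - m) / s)
  mass <- 0
  for (i in seq_along(mixture$weights)) {
    m <- mixture$means[i]; s <- mixture$sds[i]
    denom <- z(90, m, s) - z(0, m, s)
    mass <- mass + mixture$weights[i] * (z(hi, m, s) - z(lo, m, s)) / denom
  }
  mass
}

# inverse-CDF sampler for one truncated-normal component on [0, 90]
.rtnorm90 <- function(n, mean, sd) {
  plo <- stats::pnorm((0 - mean) / sd)
  phi <- stats::pnorm((90 - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, plo, phi))
}

.rmixture <- function(n, mixture) {
  comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                     prob = mixture$weights)
  x <- numeric(n)
  for (i in seq_along(mixture$weights)) {
    idx <- comp == i
    if (any(idx)) x[idx] <- .rtnorm90(sum(idx), mixture$means[i],
                                      mixture$sds[i])
  }
  # guard against floating-point spill at the support edges
  pmin(pmax(x, 0), 90)
}

#' Default division-orientation mixture presets
#'
#' Mixtures for a control and a spindle-orientation mutant genotype at
#' E15.5-E17.5, with components centred in the parallel, oblique and
#' perpendicular bins. At E15.5 both genotypes are random (equal bin
#' masses); at E16.5 and E17.5 the control carries ~40% perpendicular mass
#' and the mutant ~60%, with the complementary shift taken mostly from the
#' parallel bin.
#'
#' @return A named list of [angle_mixture()] objects keyed `"genotype@stage"`
#'   (e.g. `"control@16.5"`).
#' @export
default_angle_mixtures <- function() {
  comp <- function(w) angle_mixture(w, means = c(15, 45, 75),
                                    sds = c(9, 9, 9))
  random <- comp(c(1, 1, 1) / 3)
  control <- comp(c(0.40, 0.20, 0.40))
  mutant <- comp(c(0.17, 0.23, 0.60))
  list(
    "control@15.5" = random, "mutant@15.5" = random,
    "control@16.5" = control, "mutant@16.5" = mutant,
    "control@17.5" = control, "mutant@17.5" = mutant
  )
}

#' Synthetic-data generator configuration
#'
#' Defines the study conditions the generator emulates: a linear body-axis
#' growth law per axis, per-stage density knots per layer and axis, per-stage
#' EdU-positive fractions per layer, and truncated-normal angle mixtures per
#' (genotype, stage). The defaults are calibrated so that the reconstructed
#' total cell-number index rises ~7.4-fold over E12.5-E15.5 and ~2-fold over
#' E15.5-E18.5, with suprabasal/basal density parity from E15.5 onward and a
#' collapse of suprabasal EdU incorporation after E15.5.
#'
#' Axis lengths follow `length = intercept + slope * (stage -
#' reference_stage)` so the intercept is the (positive) length at the first
#' stage. Noise models: Gaussian for lengths and densities (truncated at a
#' small positive floor / at zero), binomial for EdU counts, truncated-normal
#' mixtures for angles.
#'
#' @param seed Master integer seed; per-table substreams are derived from it
#'   deterministically, so each table can be regenerated independently.
#' @param stages Strictly increasing embryonic-day floats.
#' @param n_embryos_growth Embryos measured per stage for axis lengths.
#' @param n_animals_density,n_animals_edu,n_animals_angles Animals per stage
#'   (per genotype for angles).
#' @param growth List with per-axis `intercept` (mm at `reference_stage`) and
#'   `slope` (mm/day), plus `noise_sd` (mm) and `reference_stage`.
#' @param density List with `curves` (per layer, per axis, one value per
#'   stage, cells per 100 um) and `noise_sd`.
#' @param edu List with `curves` (per layer, one fraction per stage) and
#'   `cells_per_animal`.
#' @param angles List with `mixtures` (named `"genotype@stage"`) and
#'   `angles_per_animal`.
#' @return An object of class `"generator_config"`.
#' @seealso [generate_tables()], [config_from_params()]
#' @examples
#' cfg <- generator_config(seed = 1)
#' names(cfg)
#' @export
generator_config <- function(
    seed = 1L,
    stages = seq(12.5, 18.5, by = 1),
    n_embryos_growth = 10L,
    n_animals_density = 5L,
    n_animals_edu = 5L,
    n_animals_angles = 5L,
    growth = list(
      sagittal = list(intercept = 9.0, slope = 2.2),
      orthogonal = list(intercept = 4.5, slope = 1.1),
      noise_sd = 0.5,
      reference_stage = 12.5
    ),
    density = list(
      curves = list(
        basal = list(
          sagittal   = c(13.5, 14.0, 14.5, 15.0, 15.0, 15.0, 15.0),
          orthogonal = 0.9 * c(13.5, 14.0, 14.5, 15.0, 15.0, 15.0, 15.0)
        ),
        suprabasal = list(
          sagittal   = c(0, 6, 11, 15, 15, 15, 15),
          orthogonal = 0.9 * c(0, 6, 11, 15, 15, 15, 15)
        )
      ),
      noise_sd = 1.0
    ),
    edu = list(
      curves = list(
        basal      = c(0.50, 0.50, 0.50, 0.45, 0.30, 0.30, 0.30),
        suprabasal = c(0.00, 0.45, 0.45, 0.35, 0.05, 0.03, 0.02)
      ),
      cells_per_animal = 100L
    ),
    angles = list(
      mixtures = default_angle_mixtures(),
      angles_per_animal = 30L
    )) {
  cfg <- structure(
    list(seed = seed, stages = stages,
         n_embryos_growth = n_embryos_growth,
         n_animals_density = n_animals_density,
         n_animals_edu = n_animals_edu,
         n_animals_angles = n_animals_angles,
         growth = growth, density = density, edu = edu, angles = angles),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the invariants the generators rely on: strictly increasing stages,
#' positive expected lengths at every stage, non-negative density knots,
#' EdU fractions in `[0, 1]`, normalized non-negative mixture weights, and
#' positive replicate counts. Called by every generator; errors identify the
#' offending field.
#'
#' @param config A [generator_config()].
#' @return `config`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_generator_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  st <- config$stages
  if (length(st) < 1L) stop("config error: `stages` is empty", call. = FALSE)
  if (length(st) > 1L && any(diff(st) <= 0)) {
    stop("config error: `stages` must be strictly increasing", call. = FALSE)
  }
  counts <- c(config$n_embryos_growth, config$n_animals_density,
              config$n_animals_edu, config$n_animals_angles)
  if (any(counts < 1L) || any(counts != round(counts))) {
    stop("config error: replicate counts must be positive integers",
         call. = FALSE)
  }
  for (ax in c("sagittal", "orthogonal")) {
    g <- config$growth[[ax]]
    if (is.null(g$intercept) || is.null(g$slope) || g$intercept <= 0 ||
        g$slope <= 0) {
      stop("config error: growth intercept and slope for axis '", ax,
           "' must be positive", call. = FALSE)
    }
    expected <- g$intercept + g$slope * (st - config$growth$reference_stage)
    if (any(expected <= 0)) {
      stop("config error: expected ", ax, " length non-positive at stage(s) ",
           paste(st[expected <= 0], collapse = ", "), call. = FALSE)
    }
  }
  if (config$growth$noise_sd < 0 || config$density$noise_sd < 0) {
    stop("config error: noise SDs must be non-negative", call. = FALSE)
  }
  for (layer in c("basal", "suprabasal")) {
    for (ax in c("sagittal", "orthogonal")) {
      v <- config$density$curves[[layer]][[ax]]
      if (length(v) != length(st)) {
        stop("config error: density curve ", layer, "/", ax,
             " must have one knot per stage", call. = FALSE)
      }
      if (any(v < 0)) {
        stop("config error: density curve ", layer, "/", ax,
             " has negative knots", call. = FALSE)
      }
    }
    f <- config$edu$curves[[layer]]
    if (length(f) != length(st)) {
      stop("config error: EdU curve for layer '", layer,
           "' must have one fraction per stage", call. = FALSE)
    }
    if (any(f < 0 | f > 1)) {
      stop("config error: EdU fractions for layer '", layer,
           "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (config$edu$cells_per_animal < 1L) {
    stop("config error: `cells_per_animal` must be a positive integer",
         call. = FALSE)
  }
  for (key in names(config$angles$mixtures)) {
    m <- config$angles$mixtures[[key]]
    if (!inherits(m, "angle_mixture")) {
      stop("config error: angle mixture '", key,
           "' is not an angle_mixture object", call. = FALSE)
    }
    if (any(m$weights < 0) || abs(sum(m$weights) - 1) > 1e-8) {
      stop("config error: angle mixture '", key,
           "' weights must be non-negative and sum to 1", call. = FALSE)
    }
  }
  invisible(config)
}

#' Generate a synthetic body-axis growth table
#'
#' Per stage and axis, draws `n_embryos_growth` lengths from the linear
#' growth law plus Gaussian noise, truncated at a small positive floor
#' (0.1 mm). The same seed always yields an identical table.
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns `embryo_id`, `stage`, `axis`,
#'   `length_mm` (validated against the `growth` schema).
#' @examples
#' g <- generate_growth_table(generator_config(seed = 7))
#' head(g)
#' @export
generate_growth_table <- function(config = generator_config()) {
  validate_generator_config(config)
  .with_seed(.table_seed(config$seed, "growth"), {
    rows <- list()
    for (stage in config$stages) {
      ids <- sprintf("E%.1f_emb%02d", stage, seq_len(config$n_embryos_growth))
      for (ax in c("sagittal", "orthogonal")) {
        g <- config$growth[[ax]]
        mu <- g$intercept + g$slope * (stage - config$growth$reference_stage)
        len <- mu + stats::rnorm(config$n_embryos_growth,
                                 sd = config$growth$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          embryo_id = ids, stage = stage, axis = ax,
          length_mm = pmax(len, 0.1))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_table(out, "growth")
  })
}

#' Generate a synthetic layer-density table
#'
#' Per stage, animal, layer and axis, draws a density around the configured
#' per-stage knot with Gaussian noise, truncated at zero. The default knots
#' put the suprabasal density at zero at E12.5 and at parity with the basal
#' layer from E15.5 onward.
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns `animal_id`, `stage`, `layer`, `axis`,
#'   `density_per_100um`.
#' @export
generate_density_table <- function(config = generator_config()) {
  validate_generator_config(config)
  .with_seed(.table_seed(config$seed, "density"), {
    rows <- list()
    for (si in seq_along(config$stages)) {
      stage <- config$stages[si]
      ids <- sprintf("E%.1f_an%02d", stage, seq_len(config$n_animals_density))
      for (layer in c("basal", "suprabasal")) {
        for (ax in c("sagittal", "orthogonal")) {
          knot <- config$density$curves[[layer]][[ax]][si]
          dens <- knot + stats::rnorm(config$n_animals_density,
                                      sd = config$density$noise_sd)
          # a zero knot means the layer does not exist yet: keep it exact
          if (knot == 0) dens <- rep(0, config$n_animals_density)
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = ids, stage = stage, layer = layer, axis = ax,
            density_per_100um = pmax(dens, 0))
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_table(out, "density")
  })
}

#' Generate a synthetic EdU incorporation table
#'
#' Per stage, animal and layer, draws `n_positive` from
#' `Binomial(cells_per_animal, fraction)` at the configured stage/layer
#' fraction. The default suprabasal fractions are high over E13.5-E15.5 and
#' collapse from E16.5 onward.
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns `animal_id`, `stage`, `layer`,
#'   `n_positive`, `n_total`.
#' @export
generate_edu_table <- function(config = generator_config()) {
  validate_generator_config(config)
  .with_seed(.table_seed(config$seed, "edu"), {
    rows <- list()
    for (si in seq_along(config$stages)) {
      stage <- config$stages[si]
      ids <- sprintf("E%.1f_an%02d", stage, seq_len(config$n_animals_edu))
      for (layer in c("basal", "suprabasal")) {
        frac <- config$edu$curves[[layer]][si]
        npos <- stats::rbinom(config$n_animals_edu,
                              size = config$edu$cells_per_animal, prob = frac)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = ids, stage = stage, layer = layer,
          n_positive = npos, n_total = config$edu$cells_per_animal)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_table(out, "edu")
  })
}

#' Generate a synthetic division-orientation angle dataset
#'
#' For every configured `"genotype@stage"` mixture, draws
#' `angles_per_animal` angles per animal from the truncated-normal mixture;
#' all angles lie in `[0, 90]` degrees.
#'
#' @param config A [generator_config()].
#' @param groups Optional character vector of `"genotype@stage"` keys to
#'   generate; defaults to every configured mixture. A requested group with
#'   no mixture is an error naming the group.
#' @return A data.frame with columns `animal_id`, `genotype`, `stage`,
#'   `angle_deg`.
#' @export
generate_angle_dataset <- function(config = generator_config(),
                                   groups = NULL) {
  validate_generator_config(config)
  if (is.null(groups)) groups <- names(config$angles$mixtures)
  missing <- setdiff(groups, names(config$angles$mixtures))
  if (length(missing) > 0L) {
    stop("no angle mixture configured for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  .with_seed(.table_seed(config$seed, "angles"), {
    rows <- list()
    for (key in groups) {
      parts <- strsplit(key, "@", fixed = TRUE)[[1L]]
      genotype <- parts[1L]
      stage <- as.numeric(parts[2L])
      mix <- config$angles$mixtures[[key]]
      for (an in seq_len(config$n_animals_angles)) {
        ang <- .rmixture(config$angles$angles_per_animal, mix)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("%s_E%.1f_an%02d", genotype, stage, an),
          genotype = genotype, stage = stage, angle_deg = ang)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_table(out, "angles")
  })
}

#' Generate all four synthetic measurement tables
#'
#' @param config A [generator_config()].
#' @return A named list with elements `growth`, `density`, `edu`, `angles`.
#' @examples
#' tabs <- generate_tables(generator_config(seed = 1))
#' sapply(tabs, nrow)
#' @export
generate_tables <- function(config = generator_config()) {
  list(
    growth = generate_growth_table(config),
    density = generate_density_table(config),
    edu = generate_edu_table(config),
    angles = generate_angle_dataset(config)
  )
}
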