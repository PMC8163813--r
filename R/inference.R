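#' Division rate implied by a fold change
#'
#' Inverts the closed-form growth laws. Without `r` (amplification phase,
#' pure duplication): `lambda = log(fold) / dt`; a 7.4-fold rise over 3
#' days gives `log(7.4)/3 = 0.667`/day (printed as 0.66). With `r`
#' (maintenance phase): the net basal exponent is `lambda * (1 - 2r)`, so
#' `lambda = log(fold) / ((1 - 2r) * dt)`; a 2-fold rise over 3 days with
#' `r = 1/3` gives `log(2) = 0.693`/day (printed as 0.7).
#'
#' @param fold Positive fold change over the interval.
#' @param dt Interval length in days (positive).
#' @param r Optional stratification probability (must differ from 1/2,
#'   where the net basal growth rate vanishes).
#' @return The division rate per day.
#' @examples
#' rate_from_fold(7.4, 3)
#' rate_from_fold(2, 3, r = 1 / 3)
#' @export
rate_from_fold <- function(fold, dt, r = NULL) {
  if (fold <= 0) stop("`fold` must be positive", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (is.null(r)) return(log(fold) / dt)
  if (r < 0 || r > 1) stop("`r` must lie in [0, 1]", call. = FALSE)
  if (abs(1 - 2 * r) < 1e-12) {
    stop("r = 1/2 gives zero net basal growth; the rate is unidentifiable ",
         "from a fold change", call. = FALSE)
  }
  log(fold) / ((1 - 2 * r) * dt)
}

#' Stratification probability from the suprabasal/basal flux ratio
#'
#' Solves the proportional-production constraint `ds/dt = c * db/dt` under
#' the maintenance-phase kinetics, i.e. `lambda * r = c * lambda * (1 - 2r)`,
#' giving `r = c / (1 + 2c)`. Equal fluxes (`c = 1`, both layers expanding
#' in proportion) give `r = 1/3`.
#'
#' @param c Non-negative flux ratio `ds/db` (default 1).
#' @return The stratification probability `r` in `[0, 1/2)`.
#' @examples
#' r_from_flux_ratio(1) # 1/3
#' @export
r_from_flux_ratio <- function(c = 1) {
  if (c < 0) stop("`c` must be non-negative", call. = FALSE)
  c / (1 + 2 * c)
}

.fit_loglinear <- function(stage, index) {
  fit <- stats::lm(log(index) ~ stage)
  unname(stats::coef(fit)[2L])
}

#' Fit the two-phase growth model to a cell-number series
#'
#' Log-linear least squares on the total index within each phase:
#' the phase-1 slope estimates the amplification rate `lambda_phase1`
#' directly; the phase-2 slope estimates the net exponent
#' `lambda * (1 - 2r)`, which combined with the proportionate-growth value
#' `r = 1/3` (see [r_from_flux_ratio()]) gives `lambda_phase2 = 3 x`
#' (phase-2 exponent). Confidence intervals come from a bootstrap over
#' animals (the replicate unit): animals are resampled with replacement
#' within each stage in the density table and embryos in the growth table,
#' the series rebuilt and the model refitted.
#'
#' @param series A cell-number series (schema `cellnumber`).
#' @param t_switch Phase boundary in embryonic days (fixed, not estimated).
#' @param n_bootstrap Number of bootstrap resamples (0 = no CIs).
#' @param seed Optional seed for the bootstrap.
#' @param densities,growth The measurement tables behind `series`; required
#'   when `n_bootstrap > 0`.
#' @param ci_level Confidence level for the percentile intervals.
#' @return A data.frame with columns `parameter`, `estimate`, `ci_low`,
#'   `ci_high`, `method`; rows `lambda_phase1`, `phase2_exponent`,
#'   `lambda_phase2`.
#' @examples
#' cfg <- generator_config(seed = 3)
#' series <- build_cell_number_series(generate_density_table(cfg),
#'                                    generate_growth_table(cfg))
#' fit_two_phase(series)
#' @export
fit_two_phase <- function(series, t_switch = 15.5, n_bootstrap = 0L,
                          seed = NULL, densities = NULL, growth = NULL,
                          ci_level = 0.95) {
  series <- validate_table(series, "cellnumber")
  point <- function(ser) {
    tot <- ser[ser$layer == "total", ]
    tot <- tot[order(tot$stage), ]
    p1 <- tot[tot$stage <= t_switch + 1e-9, ]
    p2 <- tot[tot$stage >= t_switch - 1e-9, ]
    if (nrow(p1) < 3L || nrow(p2) < 3L) {
      stop("need at least 3 stages in each phase (found ", nrow(p1), " and ",
           nrow(p2), ")", call. = FALSE)
    }
    l1 <- .fit_loglinear(p1$stage, p1$index)
    e2 <- .fit_loglinear(p2$stage, p2$index)
    c(lambda_phase1 = l1, phase2_exponent = e2, lambda_phase2 = 3 * e2)
  }
  est <- point(series)
  ci <- matrix(NA_real_, nrow = 3L, ncol = 2L)
  method <- rep("log-linear LS", 3L)
  if (n_bootstrap > 0L) {
    if (is.null(densities) || is.null(growth)) {
      stop("bootstrap CIs need the `densities` and `growth` tables",
           call. = FALSE)
    }
    densities <- validate_table(densities, "density")
    growth <- validate_table(growth, "growth")
    resample_stage <- function(tab, id_col) {
      parts <- lapply(split(tab, tab$stage), function(d) {
        ids <- unique(d[[id_col]])
        picked <- sample(ids, length(ids), replace = TRUE)
        out <- do.call(rbind, lapply(seq_along(picked), function(k) {
          rows <- d[d[[id_col]] == picked[k], ]
          rows[[id_col]] <- paste0(rows[[id_col]], "_bs", k)
          rows
        }))
        out
      })
      do.call(rbind, parts)
    }
    boot_one <- function() {
      ser <- build_cell_number_series(resample_stage(densities, "animal_id"),
                                      resample_stage(growth, "embryo_id"))
      point(ser)
    }
    draws <- .with_seed(if (is.null(seed)) sample.int(1e6, 1) else seed, {
      replicate(n_bootstrap, boot_one())
    })
    alpha <- (1 - ci_level) / 2
    ci <- t(apply(draws, 1L, stats::quantile, probs = c(alpha, 1 - alpha)))
    method <- rep(sprintf("log-linear LS + %d-rep animal bootstrap",
                          n_bootstrap), 3L)
  }
  out <- data.frame(
    parameter = names(est), estimate = unname(est),
    ci_low = ci[, 1L], ci_high = ci[, 2L], method = method)
  rownames(out) <- NULL
  out
}

#' Build a generator configuration from lineage parameters
#'
#' Calibrates the density curves of a [generator_config()] so that the
#' noise-free cell-number index reproduces the deterministic
#' [two_phase_trajectory()] of `params` exactly: with tissue area `A(t)`
#' from the linear growth law and a suprabasal share `w(t)` rising linearly
#' from 0 at `t_start` to 1/2 at `t_switch` (parity) and constant
#' thereafter, layer densities are set to
#' `sqrt(n_layer(t) / (anisotropy * A(t)))` per stage, scaled so the basal
#' sagittal density starts at `basal_density_start`. Used by
#' [recovery_experiment()] to generate data with known ground truth.
#'
#' @param params A [lineage_params()] object.
#' @param config Base configuration supplying stages, growth law, noise
#'   levels and replicate counts.
#' @param basal_density_start Basal sagittal density at the first stage
#'   (cells per 100 um).
#' @param anisotropy Orthogonal/sagittal density ratio.
#' @return A [generator_config()] with recalibrated density curves.
#' @export
config_from_params <- function(params, config = generator_config(),
                               basal_density_start = 13.5,
                               anisotropy = 0.9) {
  stopifnot(inherits(params, "lineage_params"))
  validate_generator_config(config)
  st <- config$stages
  if (any(st < params$t_start - 1e-9) || any(st > params$t_end + 1e-9)) {
    stop("config stages must lie within [t_start, t_end] of `params`",
         call. = FALSE)
  }
  traj <- two_phase_trajectory(params, n0 = 1, time_grid = st)
  area <- sapply(c("sagittal", "orthogonal"), function(ax) {
    g <- config$growth[[ax]]
    g$intercept + g$slope * (st - config$growth$reference_stage)
  })
  A <- area[, "sagittal"] * area[, "orthogonal"]
  w <- ifelse(st <= params$t_switch,
              0.5 * (st - params$t_start) /
                (params$t_switch - params$t_start),
              0.5)
  n_supra <- w * traj$total
  n_basal <- (1 - w) * traj$total
  # per-layer index = anisotropy * rho_sag^2 * A, so rho = sqrt(n / (a * A));
  # scale so the basal sagittal density at the first stage is as requested
  scale_ <- basal_density_start^2 * anisotropy * A[1L] / n_basal[1L]
  rho_b <- sqrt(scale_ * n_basal / (anisotropy * A))
  rho_s <- sqrt(scale_ * n_supra / (anisotropy * A))
  config$density$curves <- list(
    basal = list(sagittal = rho_b, orthogonal = anisotropy * rho_b),
    suprabasal = list(sagittal = rho_s, orthogonal = anisotropy * rho_s)
  )
  validate_generator_config(config)
  config
}

#' Parameter-recovery experiment on synthetic data
#'
#' Generates `n_datasets` synthetic growth/density table pairs from a
#' configuration calibrated to `true_params` (via [config_from_params()]),
#' rebuilds the cell-number series and refits the two-phase model on each,
#' and tabulates bias and root-mean-square error of the rate estimates.
#' Fully deterministic given `seed`.
#'
#' @param true_params The generating [lineage_params()].
#' @param n_datasets Number of independent datasets (at least 10).
#' @param seed Integer seed.
#' @param config Base [generator_config()]; its noise SDs define the
#'   measurement-noise conditions.
#' @param noise_scale Multiplier applied to the growth and density noise
#'   SDs (e.g. 0 for noise-free data).
#' @return A data.frame with columns `parameter`, `true`, `mean_estimate`,
#'   `bias`, `rmse`, `n_datasets`.
#' @examples
#' recovery_experiment(lineage_params(), n_datasets = 10, seed = 1)
#' @export
recovery_experiment <- function(true_params = lineage_params(),
                                n_datasets = 50L, seed = 1L,
                                config = generator_config(),
                                noise_scale = 1) {
  if (n_datasets < 10L) stop("`n_datasets` must be at least 10",
                             call. = FALSE)
  if (noise_scale < 0) stop("`noise_scale` must be non-negative",
                            call. = FALSE)
  base <- config_from_params(true_params, config)
  base$growth$noise_sd <- base$growth$noise_sd * noise_scale
  base$density$noise_sd <- base$density$noise_sd * noise_scale
  seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                       n_datasets))
  ests <- vapply(seq_len(n_datasets), function(i) {
    cfg <- base
    cfg$seed <- seeds[i]
    ser <- build_cell_number_series(generate_density_table(cfg),
                                    generate_growth_table(cfg))
    fit <- fit_two_phase(ser, t_switch = true_params$t_switch)
    stats::setNames(fit$estimate, fit$parameter)[c("lambda_phase1",
                                                   "lambda_phase2")]
  }, numeric(2L))
  truth <- c(lambda_phase1 = true_params$lambda_phase1,
             lambda_phase2 = true_params$lambda_phase2)
  out <- data.frame(
    parameter = rownames(ests),
    true = unname(truth[rownames(ests)]),
    mean_estimate = rowMeans(ests),
    bias = rowMeans(ests) - unname(truth[rownames(ests)]),
    rmse = sqrt(rowMeans((ests - truth[rownames(ests)])^2)),
    n_datasets = n_datasets)
  rownames(out) <- NULL
  out
}
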