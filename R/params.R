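#' Kinetic parameters of the two-phase lineage model
#'
#' Bundles the rate and fate parameters governing epidermal expansion. During
#' the amplification phase (from `t_start` to `t_switch`) every progenitor
#' duplicates at rate `lambda_phase1`. During the maintenance phase (from
#' `t_switch` to `t_end`) basal progenitors divide at rate `lambda_phase2` and
#' at each division either duplicate (probability `1 - r`) or commit to
#' terminal differentiation and stratify into the suprabasal layer
#' (probability `r`). Proportionate growth of the two layers requires
#' `r = 1/3` (see [r_from_flux_ratio()]).
#'
#' The two rates are deliberately kept as independent parameters: they are
#' estimated from different observables (a ~7.4-fold rise over the first three
#' days versus a ~2-fold rise over the last three) and are not harmonized.
#'
#' @param lambda_phase1 Division rate of phase-1 progenitors, per day.
#' @param lambda_phase2 Division rate of phase-2 basal progenitors, per day.
#' @param r Per-division probability of commitment/stratification, in `[0, 1]`.
#' @param t_start,t_switch,t_end Embryonic days delimiting the two phases;
#'   must satisfy `t_start < t_switch < t_end`.
#'
#' @return An object of class `"lineage_params"` (a named list).
#' @seealso [two_phase_trajectory()], [phase1_closed_form()],
#'   [phase2_closed_form()]
#' @examples
#' p <- lineage_params()
#' p$lambda_phase1
#' @export
lineage_params <- function(lambda_phase1 = 0.66, lambda_phase2 = 0.7,
                           r = 1 / 3, t_start = 12.5, t_switch = 15.5,
                           t_end = 18.5) {
  if (!is.numeric(lambda_phase1) || length(lambda_phase1) != 1L ||
      lambda_phase1 <= 0) {
    stop("`lambda_phase1` must be a single positive rate (per day)",
         call. = FALSE)
  }
  if (!is.numeric(lambda_phase2) || length(lambda_phase2) != 1L ||
      lambda_phase2 <= 0) {
    stop("`lambda_phase2` must be a single positive rate (per day)",
         call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || r < 0 || r > 1) {
    stop("`r` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!(t_start < t_switch && t_switch < t_end)) {
    stop("phase boundaries must satisfy t_start < t_switch < t_end",
         call. = FALSE)
  }
  structure(
    list(lambda_phase1 = lambda_phase1, lambda_phase2 = lambda_phase2,
         r = r, t_start = t_start, t_switch = t_switch, t_end = t_end),
    class = "lineage_params"
  )
}

#' @export
print.lineage_params <- function(x, ...) {
  cat("Two-phase lineage model parameters\n")
  cat(sprintf("  phase 1 (E%.1f-E%.1f): pure duplication, lambda = %.3g/day\n",
              x$t_start, x$t_switch, x$lambda_phase1))
  cat(sprintf(
    "  phase 2 (E%.1f-E%.1f): duplication/stratification, lambda = %.3g/day, r = %.3g\n",
    x$t_switch, x$t_end, x$lambda_phase2, x$r))
  invisible(x)
}

#' EdU pulse-labeling configuration
#'
#' Parameters for predicting the fraction of cells marked by an EdU pulse.
#' A short pulse marks the cells currently in S-phase, a fraction
#' `lambda * t_s` of a population cycling at rate `lambda` with S-phase
#' duration `t_s`. After the labeled cohort completes `n_divisions_chase`
#' rounds of division its number doubles each round.
#'
#' @param lambda Division rate, per day.
#' @param t_s S-phase duration in days (default 1/3 day = 8 h).
#' @param pulse Pulse duration in days.
#' @param n_divisions_chase Rounds of division completed by the labeled
#'   cohort during the chase (non-negative integer).
#'
#' @return An object of class `"pulse_params"`.
#' @seealso [short_pulse_fraction()], [pulse_chase_fraction()],
#'   [simulate_edu_cohort()]
#' @examples
#' pulse_params(lambda = 0.8)
#' @export
pulse_params <- function(lambda = 0.8, t_s = 1 / 3, pulse = 0,
                         n_divisions_chase = 0L) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("`lambda` must be a single non-negative rate", call. = FALSE)
  }
  if (!is.numeric(t_s) || length(t_s) != 1L || t_s < 0) {
    stop("`t_s` must be a single non-negative duration (days)", call. = FALSE)
  }
  if (!is.numeric(pulse) || length(pulse) != 1L || pulse < 0) {
    stop("`pulse` must be a single non-negative duration (days)",
         call. = FALSE)
  }
  if (length(n_divisions_chase) != 1L || n_divisions_chase < 0 ||
      n_divisions_chase != round(n_divisions_chase)) {
    stop("`n_divisions_chase` must be a non-negative integer", call. = FALSE)
  }
  if (lambda * t_s > 1) {
    warning("lambda * t_s > 1: the linear short-pulse approximation ",
            "is outside its domain of validity", call. = FALSE)
  }
  structure(
    list(lambda = lambda, t_s = t_s, pulse = pulse,
         n_divisions_chase = as.integer(n_divisions_chase)),
    class = "pulse_params"
  )
}

#' @export
print.pulse_params <- function(x, ...) {
  cat(sprintf(
    "EdU pulse parameters: lambda = %.3g/day, t_s = %.3g d (%.1f h), pulse = %.3g d, %d chase division(s)\n",
    x$lambda, x$t_s, 24 * x$t_s, x$pulse, x$n_divisions_chase))
  invisible(x)
}
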