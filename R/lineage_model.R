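#' Expected phase-1 population size (pure duplication)
#'
#' Closed-form mean of the pure-birth (Yule) process `p -> p + p` at rate
#' `lambda`: starting from `n0` cells, the expected count after `dt` days is
#' `n0 * exp(lambda * dt)`. With `lambda = 0.66`/day the three-day
#' amplification phase expands the population `exp(1.98) ~ 7.2`-fold.
#'
#' @param n0 Initial cell count (positive).
#' @param lambda Division rate per day (non-negative).
#' @param dt Elapsed time in days (non-negative).
#' @return Expected cell count (numeric, vectorized over `dt`).
#' @seealso [simulate_phase1()] for the stochastic counterpart.
#' @examples
#' phase1_closed_form(1, 0.66, 3) # ~7.24
#' @export
phase1_closed_form <- function(n0, lambda, dt) {
  if (any(n0 <= 0)) stop("`n0` must be positive", call. = FALSE)
  if (any(lambda < 0)) stop("`lambda` must be non-negative", call. = FALSE)
  if (any(dt < 0)) stop("`dt` must be non-negative", call. = FALSE)
  n0 * exp(lambda * dt)
}

#' Expected phase-2 population sizes (duplication or stratification)
#'
#' Closed-form solution of the mean-field kinetics
#' `db/dt = lambda * (1 - 2r) * b`, `ds/dt = lambda * r * b`: basal
#' progenitors divide at rate `lambda` and either duplicate (probability
#' `1 - r`) or convert to a non-proliferative suprabasal cell (probability
#' `r`). For `r != 1/2`,
#' `b(dt) = b0 * exp(k * dt)` with `k = lambda * (1 - 2r)` and
#' `s(dt) = s0 + r / (1 - 2r) * b0 * (exp(k * dt) - 1)`; at `r = 1/2` the
#' continuity limit `s(dt) = s0 + lambda * r * b0 * dt` applies and `b` is
#' constant. With `b0 = s0` and `r = 1/3` the two layers stay exactly equal
#' and the total grows by `exp(lambda * dt / 3)` (~2 for `lambda = 0.7`,
#' `dt = 3`).
#'
#' @param b0 Initial basal count (positive).
#' @param s0 Initial suprabasal count (non-negative).
#' @param lambda Division rate per day.
#' @param r Stratification probability in `[0, 1]`.
#' @param dt Elapsed time in days (non-negative, vectorized).
#' @return A data.frame with columns `b`, `s` and `total` (one row per `dt`).
#' @seealso [simulate_phase2()], [two_phase_trajectory()]
#' @examples
#' phase2_closed_form(1, 1, 0.7, 1 / 3, 3) # b = s = exp(0.7) ~ 2.01
#' @export
phase2_closed_form <- function(b0, s0, lambda, r, dt) {
  if (b0 <= 0) stop("`b0` must be positive", call. = FALSE)
  if (s0 < 0) stop("`s0` must be non-negative", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  if (r < 0 || r > 1) stop("`r` must lie in [0, 1]", call. = FALSE)
  if (any(dt < 0)) stop("`dt` must be non-negative", call. = FALSE)
  k <- lambda * (1 - 2 * r)
  b <- b0 * exp(k * dt)
  if (abs(1 - 2 * r) < 1e-12) {
    s <- s0 + lambda * r * b0 * dt
  } else {
    s <- s0 + r / (1 - 2 * r) * b0 * (exp(k * dt) - 1)
  }
  data.frame(b = b, s = s, total = b + s)
}

# sample a step-function population path onto a fixed grid:
# event_times are the (sorted) times at which the count changes to counts[i+1];
# counts has length(event_times) + 1 with counts[1] the initial value.
.step_on_grid <- function(grid, event_times, counts) {
  counts[findInterval(grid, event_times) + 1L]
}

#' Exact stochastic simulation of phase-1 duplication
#'
#' Event-driven (Gillespie) simulation of the pure-birth process
#' `p -> p + p`: with `n` cells the waiting time to the next division is
#' exponential with total rate `lambda * n`. Replicate trajectories are
#' sampled onto a fixed output grid. The replicate mean of the terminal
#' count converges to [phase1_closed_form()] as the number of replicates
#' grows.
#'
#' @param n0 Initial cell count (non-negative integer; `n0 = 0` yields a
#'   frozen all-zero trajectory).
#' @param lambda Division rate per day.
#' @param dt Simulated duration in days.
#' @param n_replicates Number of independent replicates.
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit.
#' @param grid_dt Output grid spacing in days (default 0.1).
#' @return A data.frame with columns `replicate`, `time`, `b`, `s`, `total`.
#'   Phase-1 cells are undifferentiated progenitors, reported in `b` with
#'   `s = 0`.
#' @examples
#' tr <- simulate_phase1(100, 0.66, 1, n_replicates = 3, seed = 1)
#' head(tr)
#' @export
simulate_phase1 <- function(n0, lambda, dt, n_replicates = 1L, seed = NULL,
                            grid_dt = 0.1) {
  if (n0 < 0 || n0 != round(n0)) {
    stop("`n0` must be a non-negative integer", call. = FALSE)
  }
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  if (dt < 0) stop("`dt` must be non-negative", call. = FALSE)
  run <- function() {
    grid <- unique(c(seq(0, dt, by = grid_dt), dt))
    out <- vector("list", n_replicates)
    for (rep in seq_len(n_replicates)) {
      if (n0 == 0 || lambda == 0) {
        n_grid <- rep(n0, length(grid))
        out[[rep]] <- data.frame(replicate = rep, time = grid,
                                 b = n_grid, s = 0L, total = n_grid)
        next
      }
      # pure birth: inter-event waits are Exp(lambda * n) with n = n0, n0+1, ...
      # draw in blocks until the cumulative time exceeds dt
      expect <- n0 * (exp(lambda * dt) - 1)
      block <- max(32L, ceiling(expect + 6 * sqrt(expect)))
      times <- numeric(0)
      n_cur <- n0
      t_cur <- 0
      repeat {
        waits <- stats::rexp(block, rate = lambda * (n_cur:(n_cur + block - 1L)))
        ct <- t_cur + cumsum(waits)
        keep <- ct <= dt
        times <- c(times, ct[keep])
        if (!all(keep)) break
        t_cur <- ct[block]
        n_cur <- n_cur + block
        block <- max(32L, block %/% 4L)
      }
      n_grid <- n0 + findInterval(grid, times)
      out[[rep]] <- data.frame(replicate = rep, time = grid,
                               b = n_grid, s = 0L, total = n_grid)
    }
    do.call(rbind, out)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Exact stochastic simulation of phase-2 duplication/stratification
#'
#' Event-driven simulation of the branching rules of the maintenance phase:
#' events occur at total rate `lambda * b`; each event is a duplication
#' (`b -> b + 1`) with probability `1 - r`, otherwise a conversion
#' (`b -> b - 1`, `s -> s + 1`). Conversion conserves `b + s` exactly;
#' `b = 0` is absorbing (the trajectory freezes). Replicate means match
#' [phase2_closed_form()] within Monte-Carlo error.
#'
#' @inheritParams simulate_phase1
#' @param b0 Initial basal count (positive integer).
#' @param s0 Initial suprabasal count (non-negative integer).
#' @param r Stratification probability in `[0, 1]`.
#' @param record_events If `TRUE`, attach the per-replicate event log
#'   (columns `replicate`, `time`, `event` in `{"duplication",
#'   "conversion"}`) as attribute `"events"`. Intended for small populations.
#' @return A data.frame with columns `replicate`, `time`, `b`, `s`, `total`.
#' @examples
#' tr <- simulate_phase2(50, 50, 0.7, 1 / 3, 1, n_replicates = 2, seed = 1)
#' head(tr)
#' @export
simulate_phase2 <- function(b0, s0, lambda, r, dt, n_replicates = 1L,
                            seed = NULL, grid_dt = 0.1,
                            record_events = FALSE) {
  if (b0 < 1 || b0 != round(b0)) {
    stop("`b0` must be a positive integer", call. = FALSE)
  }
  if (s0 < 0 || s0 != round(s0)) {
    stop("`s0` must be a non-negative integer", call. = FALSE)
  }
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  if (r < 0 || r > 1) stop("`r` must lie in [0, 1]", call. = FALSE)
  if (dt < 0) stop("`dt` must be non-negative", call. = FALSE)
  run <- function() {
    grid <- unique(c(seq(0, dt, by = grid_dt), dt))
    out <- vector("list", n_replicates)
    ev_out <- if (record_events) vector("list", n_replicates)
    for (rep in seq_len(n_replicates)) {
      b <- b0; s <- s0; t_cur <- 0
      cap <- 1024L
      ev_t <- numeric(cap); ev_b <- integer(cap); ev_s <- integer(cap)
      dup <- logical(cap)
      n_ev <- 0L
      # draw exponential waits and fate coins in chunks (loop stays exact:
      # each wait is Exp(1) scaled by the current total rate)
      chunk <- 4096L
      ex <- stats::rexp(chunk); un <- stats::runif(chunk); ptr <- 0L
      repeat {
        if (b == 0L || lambda == 0) break
        ptr <- ptr + 1L
        if (ptr > chunk) {
          ex <- stats::rexp(chunk); un <- stats::runif(chunk); ptr <- 1L
        }
        t_cur <- t_cur + ex[ptr] / (lambda * b)
        if (t_cur > dt) break
        is_dup <- un[ptr] < 1 - r
        if (is_dup) b <- b + 1L else { b <- b - 1L; s <- s + 1L }
        n_ev <- n_ev + 1L
        if (n_ev > cap) {
          cap <- cap * 2L
          length(ev_t) <- cap; length(ev_b) <- cap; length(ev_s) <- cap
          length(dup) <- cap
        }
        ev_t[n_ev] <- t_cur; ev_b[n_ev] <- b; ev_s[n_ev] <- s
        dup[n_ev] <- is_dup
      }
      keep <- seq_len(n_ev)
      ev_t <- ev_t[keep]; ev_b <- ev_b[keep]; ev_s <- ev_s[keep]
      ev_type <- ifelse(dup[keep], "duplication", "conversion")
      out[[rep]] <- data.frame(
        replicate = rep, time = grid,
        b = .step_on_grid(grid, ev_t, c(b0, ev_b)),
        s = .step_on_grid(grid, ev_t, c(s0, ev_s))
      )
      out[[rep]]$total <- out[[rep]]$b + out[[rep]]$s
      if (record_events) {
        ev_out[[rep]] <- data.frame(replicate = rep, time = ev_t,
                                    event = ev_type, b = ev_b, s = ev_s)
      }
    }
    res <- do.call(rbind, out)
    if (record_events) attr(res, "events") <- do.call(rbind, ev_out)
    res
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Deterministic two-phase trajectory
#'
#' Mean-field cell numbers over the full developmental window: exponential
#' expansion of an undifferentiated progenitor pool up to `t_switch`
#' (reported as `b`, with `s = 0`), then the duplication/stratification
#' kinetics of [phase2_closed_form()]. At `t_switch` the progenitor pool is
#' split into basal and suprabasal compartments according to
#' `basal_fraction_at_switch` (default 1/2, matching the observed density
#' parity between the layers at the phase boundary). The total is continuous
#' at the switch; with the default split and `r = 1/3`, `b = s` on the
#' entire phase-2 grid.
#'
#' @param params A [lineage_params()] object.
#' @param n0 Initial (relative) cell number at `t_start`.
#' @param time_grid Embryonic-day times at which to evaluate; must lie in
#'   `[t_start, t_end]`. Defaults to a 0.1-day grid.
#' @param basal_fraction_at_switch Fraction of the population assigned to
#'   the basal compartment at `t_switch`, in `(0, 1]`.
#' @return A data.frame with columns `time`, `b`, `s`, `total`.
#' @examples
#' tr <- two_phase_trajectory(lineage_params())
#' max(tr$total) / min(tr$total)
#' @export
two_phase_trajectory <- function(params = lineage_params(), n0 = 1,
                                 time_grid = NULL,
                                 basal_fraction_at_switch = 0.5) {
  stopifnot(inherits(params, "lineage_params"))
  if (n0 <= 0) stop("`n0` must be positive", call. = FALSE)
  if (basal_fraction_at_switch <= 0 || basal_fraction_at_switch > 1) {
    stop("`basal_fraction_at_switch` must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(time_grid)) {
    time_grid <- unique(c(seq(params$t_start, params$t_end, by = 0.1),
                          params$t_end))
  }
  if (any(time_grid < params$t_start - 1e-9) ||
      any(time_grid > params$t_end + 1e-9)) {
    stop("`time_grid` must lie within [t_start, t_end]", call. = FALSE)
  }
  time_grid <- sort(time_grid)
  p1 <- time_grid <= params$t_switch
  b <- s <- numeric(length(time_grid))
  tot1 <- phase1_closed_form(n0, params$lambda_phase1,
                             time_grid[p1] - params$t_start)
  b[p1] <- tot1
  s[p1] <- 0
  if (any(!p1)) {
    n_switch <- phase1_closed_form(n0, params$lambda_phase1,
                                   params$t_switch - params$t_start)
    b_sw <- basal_fraction_at_switch * n_switch
    s_sw <- (1 - basal_fraction_at_switch) * n_switch
    cf <- phase2_closed_form(b_sw, s_sw, params$lambda_phase2, params$r,
                             time_grid[!p1] - params$t_switch)
    b[!p1] <- cf$b
    s[!p1] <- cf$s
  }
  data.frame(time = time_grid, b = b, s = s, total = b + s)
}
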