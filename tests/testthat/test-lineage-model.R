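test_that("phase-1 closed form is the exponential growth law", {
  expect_equal(phase1_closed_form(5, 0, 10), 5)
  expect_equal(phase1_closed_form(1, 0.66, 3), exp(1.98))
  expect_equal(phase1_closed_form(1, log(7.4) / 3, 3), 7.4)
  expect_error(phase1_closed_form(1, 0.66, -1), "non-negative")
  # round trip: the rate is recovered from the log-fold exactly
  for (lam in c(0.1, 0.66, 1.3)) {
    for (dt in c(0.5, 3)) {
      expect_equal(log(phase1_closed_form(1, lam, dt)) / dt, lam)
    }
  }
})

test_that("phase-1 Gillespie simulation matches the closed form and its contracts", {
  # lambda = 0: frozen trajectory
  s0 <- simulate_phase1(7, 0, 2, n_replicates = 2L, seed = 1)
  expect_true(all(s0$total == 7))
  # n0 = 0 is absorbing, not an error
  expect_true(all(simulate_phase1(0, 0.66, 1, seed = 1)$total == 0))
  # determinism
  expect_identical(simulate_phase1(50, 0.66, 2, 3, seed = 9),
                   simulate_phase1(50, 0.66, 2, 3, seed = 9))
  # replicate mean within 3 SE of n0 * exp(lambda * dt)
  sim <- simulate_phase1(2000, 0.66, 3, n_replicates = 200L, seed = 42)
  term <- sim$total[sim$time == 3]
  expect_length(term, 200L)
  fold <- mean(term) / 2000
  se <- sd(term) / 2000 / sqrt(200)
  expect_lt(abs(fold - exp(1.98)), 3 * se)
  # counts never decrease in a pure-birth process
  one <- sim[sim$replicate == 1L, ]
  expect_true(all(diff(one$total) >= 0))
})

test_that("phase-2 closed form solves the duplication/stratification ODEs", {
  # r = 1/2: zero net basal growth, linear suprabasal production
  cf <- phase2_closed_form(10, 0, 0.8, 0.5, 2)
  expect_equal(cf$b, 10)
  expect_equal(cf$s, 0.8 * 0.5 * 10 * 2)
  # continuity at r = 1/2
  cf_eps <- phase2_closed_form(10, 0, 0.8, 0.5 - 1e-9, 2)
  expect_equal(cf_eps$s, cf$s, tolerance = 1e-6)
  # r = 0 reduces to pure duplication
  cf0 <- phase2_closed_form(3, 2, 0.7, 0, 1.5)
  expect_equal(cf0$b, phase1_closed_form(3, 0.7, 1.5))
  expect_equal(cf0$s, 2)
  # parity: b0 = s0 and r = 1/3 keep the layers exactly equal
  for (dt in seq(0, 3, by = 0.5)) {
    cf13 <- phase2_closed_form(1, 1, 0.7, 1 / 3, dt)
    expect_equal(cf13$b, cf13$s)
  }
  expect_equal(phase2_closed_form(1, 1, 0.7, 1 / 3, 3)$b, exp(0.7))
  expect_error(phase2_closed_form(1, 0, 0.7, 1.2, 1), "\\[0, 1\\]")
})

test_that("flux balance holds at r = 1/3: db/dt = ds/dt on the closed form", {
  r <- r_from_flux_ratio(1)
  h <- 1e-6
  for (t in c(0.5, 1.5, 2.5)) {
    up <- phase2_closed_form(1, 1, 0.7, r, t + h)
    dn <- phase2_closed_form(1, 1, 0.7, r, t - h)
    db <- (up$b - dn$b) / (2 * h)
    ds <- (up$s - dn$s) / (2 * h)
    expect_equal(db, ds, tolerance = 1e-6)
  }
})

test_that("phase-2 Gillespie events conserve cells and match the closed form", {
  # r = 1: pure conversion; b decreases monotonically and b + s is conserved
  s1 <- simulate_phase2(30, 5, 1, 1, 5, n_replicates = 3L, seed = 2)
  for (rep in 1:3) {
    one <- s1[s1$replicate == rep, ]
    expect_true(all(diff(one$b) <= 0))
    expect_true(all(one$b + one$s == 35))
  }
  # event bookkeeping: duplication adds one cell, conversion moves one
  s2 <- simulate_phase2(10, 10, 0.9, 0.4, 2, n_replicates = 5L, seed = 3,
                        record_events = TRUE)
  ev <- attr(s2, "events")
  expect_gt(nrow(ev), 0L)
  for (rep in unique(ev$replicate)) {
    e <- ev[ev$replicate == rep, ]
    tot <- c(20L, e$b + e$s)
    expect_true(all(diff(tot) %in% c(0L, 1L)))
    expect_true(all(diff(tot)[e$event == "duplication"] == 1L))
    expect_true(all(diff(tot)[e$event == "conversion"] == 0L))
  }
  # determinism
  expect_identical(simulate_phase2(20, 20, 0.7, 1 / 3, 1, 2, seed = 5),
                   simulate_phase2(20, 20, 0.7, 1 / 3, 1, 2, seed = 5))
  # replicate mean within 3 SE of the closed form
  sim <- simulate_phase2(1000, 1000, 0.7, 1 / 3, 3, n_replicates = 200L,
                         seed = 7)
  tb <- sim$b[sim$time == 3]
  ts <- sim$s[sim$time == 3]
  cf <- phase2_closed_form(1000, 1000, 0.7, 1 / 3, 3)
  expect_lt(abs(mean(tb) - cf$b), 3 * sd(tb) / sqrt(200))
  expect_lt(abs(mean(ts) - cf$s), 3 * sd(ts) / sqrt(200))
})

test_that("Gillespie means agree with closed forms across a parameter grid", {
  grid <- expand.grid(lambda = c(0.4, 0.9), r = c(0.2, 1 / 3, 0.45))
  for (i in seq_len(nrow(grid))) {
    lam <- grid$lambda[i]
    r <- grid$r[i]
    sim <- simulate_phase2(1000, 0, lam, r, 1.5, n_replicates = 200L,
                           seed = 100 + i)
    tb <- sim$b[sim$time == 1.5]
    cf <- phase2_closed_form(1000, 0, lam, r, 1.5)
    expect_lt(abs(mean(tb) - cf$b), 3 * sd(tb) / sqrt(200))
  }
})

test_that("two-phase trajectory stitches the phases continuously with the expected folds", {
  tr <- two_phase_trajectory(lineage_params())
  i_sw <- which(abs(tr$time - 15.5) < 1e-9)
  expect_equal(tr$total[i_sw] / tr$total[1L], exp(0.66 * 3))
  expect_equal(tr$total[nrow(tr)] / tr$total[i_sw], exp(0.7),
               tolerance = 1e-12)
  # equal split at the switch keeps b = s on the whole phase-2 grid
  p2 <- tr[tr$time > 15.5, ]
  expect_equal(p2$b, p2$s)
  # total is non-decreasing throughout
  expect_true(all(diff(tr$total) > -1e-12))
  expect_error(two_phase_trajectory(lineage_params(), time_grid = c(11, 13)),
               "within")
})
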