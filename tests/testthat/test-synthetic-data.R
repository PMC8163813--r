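test_that("all four generators are deterministic given the config seed", {
  cfg <- generator_config(seed = 101L)
  a <- generate_tables(cfg)
  b <- generate_tables(cfg)
  expect_identical(a, b)
  # substreams: regenerating one table alone matches its slot in the bundle
  expect_identical(generate_edu_table(cfg), a$edu)
  expect_identical(generate_angle_dataset(cfg), a$angles)
  # a different seed changes the data
  expect_false(identical(generate_growth_table(generator_config(seed = 5L)),
                         a$growth))
})

test_that("generated tables satisfy their schema invariants", {
  tabs <- generate_tables(generator_config(seed = 33L))
  expect_silent(validate_table(tabs$growth, "growth"))
  expect_silent(validate_table(tabs$density, "density"))
  expect_silent(validate_table(tabs$edu, "edu"))
  expect_silent(validate_table(tabs$angles, "angles"))
  expect_true(all(tabs$growth$length_mm > 0))
  expect_true(all(tabs$density$density_per_100um >= 0))
  expect_true(all(tabs$edu$n_positive <= tabs$edu$n_total))
  expect_true(all(tabs$angles$angle_deg >= 0 & tabs$angles$angle_deg <= 90))
})

test_that("noise-free growth lengths follow the linear law exactly", {
  cfg <- subset_stages_config(12.5)
  cfg$growth <- list(sagittal = list(intercept = 1, slope = 1),
                     orthogonal = list(intercept = 1, slope = 1),
                     noise_sd = 0, reference_stage = 0)
  g <- generate_growth_table(cfg)
  expect_equal(unique(g$length_mm), 13.5)
})

test_that("growth sample mean matches the linear law (law of large numbers)", {
  cfg <- subset_stages_config(14.5, seed = 77L)
  cfg$n_embryos_growth <- 10000L
  g <- generate_growth_table(cfg)
  sag <- g$length_mm[g$axis == "sagittal"]
  expected <- 9.0 + 2.2 * (14.5 - 12.5)
  se <- cfg$growth$noise_sd / sqrt(length(sag))
  expect_lt(abs(mean(sag) - expected), 3 * se)
})

test_that("a configuration implying non-positive lengths is rejected", {
  expect_error(
    generator_config(growth = list(
      sagittal = list(intercept = 1, slope = -0.5),
      orthogonal = list(intercept = 4.5, slope = 1.1),
      noise_sd = 0.5, reference_stage = 12.5)),
    "positive")
  expect_error(generator_config(stages = c(13.5, 12.5)), "increasing")
  expect_error(generator_config(stages = numeric(0)), "empty")
})

test_that("noise-free densities equal the configured knots; suprabasal starts at zero and reaches parity at E15.5", {
  cfg <- noise_free_config()
  d <- generate_density_table(cfg)
  at <- function(st, layer, ax) {
    d$density_per_100um[d$stage == st & d$layer == layer & d$axis == ax]
  }
  expect_equal(unique(at(12.5, "basal", "sagittal")), 13.5)
  expect_equal(unique(at(12.5, "suprabasal", "sagittal")), 0)
  expect_equal(unique(at(15.5, "suprabasal", "orthogonal")), 0.9 * 15)

  # with default noise, the suprabasal/basal ratio at E15.5 is within 10% of 1
  dn <- generate_density_table(generator_config(seed = 9L))
  ratio <- mean(dn$density_per_100um[dn$stage == 15.5 &
                                       dn$layer == "suprabasal"]) /
    mean(dn$density_per_100um[dn$stage == 15.5 & dn$layer == "basal"])
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("EdU counts are binomial draws at the configured fractions", {
  cfg <- generator_config(seed = 4L)
  cfg$edu$curves <- list(basal = rep(0, 7), suprabasal = rep(1, 7))
  e <- generate_edu_table(cfg)
  expect_true(all(e$n_positive[e$layer == "basal"] == 0L))
  expect_true(all(e$n_positive[e$layer == "suprabasal"] ==
                    e$n_total[e$layer == "suprabasal"]))
  expect_error({
    bad <- cfg
    bad$edu$curves$basal <- rep(1.5, 7)
    generate_edu_table(bad)
  }, "\\[0, 1\\]")

  # pooled positive fraction vs binomial standard-error oracle
  cfg2 <- subset_stages_config(14.5, seed = 21L)
  cfg2$n_animals_edu <- 100L
  cfg2$edu$curves <- list(basal = 0.27, suprabasal = 0.27)
  cfg2$edu$cells_per_animal <- 1000L
  e2 <- generate_edu_table(cfg2)
  e2 <- e2[e2$layer == "basal", ]
  pooled <- sum(e2$n_positive) / sum(e2$n_total)
  expect_lt(abs(pooled - 0.27), 3 * sqrt(0.27 * 0.73 / sum(e2$n_total)))
})

test_that("angle draws respect their mixtures", {
  # degenerate component at 0: everything parallel
  cfg <- generator_config(seed = 3L)
  cfg$angles$mixtures <- list(
    "g@15.5" = angle_mixture(1, 0, 1e-6))
  a <- generate_angle_dataset(cfg)
  expect_true(all(bin_angles(a$angle_deg)$counts ==
                    c(nrow(a), 0L, 0L)))

  # near-uniform mixture: equal-width bins get ~1/3 each
  cfg$angles$mixtures <- list("g@15.5" = angle_mixture(1, 45, 1e6))
  cfg$n_animals_angles <- 10L
  cfg$angles$angles_per_animal <- 900L
  u <- generate_angle_dataset(cfg)
  props <- bin_angles(u$angle_deg)$proportions
  se <- sqrt((1 / 3) * (2 / 3) / nrow(u))
  expect_true(all(abs(props - 1 / 3) < 4 * se))

  # a missing mixture is an error naming the group
  expect_error(generate_angle_dataset(cfg, groups = "mutant@16.5"),
               "mutant@16.5")
})

test_that("mutant preset perpendicular mass matches numeric integration of the mixture density", {
  cfg <- generator_config(seed = 12L)
  cfg$n_animals_angles <- 10L
  cfg$angles$angles_per_animal <- 1000L
  a <- generate_angle_dataset(cfg, groups = "mutant@16.5")
  perp <- bin_angles(a$angle_deg)$proportions["perpendicular"]
  mix <- cfg$angles$mixtures[["mutant@16.5"]]
  oracle <- integrate(tnorm_mixture_density, 60, 90,
                      weights = mix$weights, means = mix$means,
                      sds = mix$sds)$value
  expect_lt(abs(perp - oracle), 0.02)
  # and the package analytic mass agrees with the quadrature oracle
  expect_equal(mixture_bin_mass(mix, 60, 90), oracle, tolerance = 1e-6)
  # presets bracket the reported ~40% vs ~60% perpendicular proportions
  expect_gt(oracle, 0.55)
  ctrl <- cfg$angles$mixtures[["control@16.5"]]
  expect_lt(mixture_bin_mass(ctrl, 60, 90), 0.45)
})
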