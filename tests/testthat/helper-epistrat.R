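# Shared fixtures, built in code.

# a noise-free generator configuration (measurement tables equal their
# configured curves exactly)
noise_free_config <- function(seed = 1L) {
  cfg <- generator_config(seed = seed)
  cfg$growth$noise_sd <- 0
  cfg$density$noise_sd <- 0
  cfg
}

# restrict a default configuration to a subset of its stages (subsetting the
# density/EdU knots to match)
subset_stages_config <- function(stages, seed = 1L) {
  cfg <- generator_config(seed = seed)
  idx <- match(stages, cfg$stages)
  stopifnot(!anyNA(idx))
  cfg$stages <- stages
  cfg$density$curves <- lapply(cfg$density$curves, lapply,
                               function(v) v[idx])
  cfg$edu$curves <- lapply(cfg$edu$curves, function(v) v[idx])
  validate_generator_config(cfg)
}

# exact cell-number series from an arbitrary index function of stage
exact_series <- function(stages, index_fun, layer = "total") {
  data.frame(stage = stages, layer = layer, index = index_fun(stages),
             index_se = 0)
}

# per-animal bin-proportion table from fixed proportion rows
proportions_table <- function(genotypes, props) {
  out <- data.frame(genotype = genotypes,
                    animal_id = paste0("an", seq_along(genotypes)))
  out$parallel <- props[, 1L]
  out$oblique <- props[, 2L]
  out$perpendicular <- props[, 3L]
  out
}

# density of a truncated-normal mixture on [0, 90]; independent oracle for
# mixture masses (integrated numerically in the tests that use it)
tnorm_mixture_density <- function(x, weights, means, sds) {
  out <- 0
  for (i in seq_along(weights)) {
    denom <- pnorm((90 - means[i]) / sds[i]) - pnorm((0 - means[i]) / sds[i])
    out <- out + weights[i] * dnorm(x, means[i], sds[i]) / denom
  }
  out
}
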