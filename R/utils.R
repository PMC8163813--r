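# Internal RNG helpers.
#
# All stochastic entry points take an explicit seed and must neither depend
# on nor disturb the caller's RNG state, so seeded code runs inside
# .with_seed(), which restores .Random.seed on exit.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# A master seed spawns named substreams so each generated table is
# reproducible on its own, independent of generation order.
.sub_seeds <- function(seed, n = 6L) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.table_seed <- function(seed, table) {
  idx <- match(table, c("growth", "density", "edu", "angles", "extra1",
                        "extra2"))
  if (is.na(idx)) stop("unknown substream: ", table, call. = FALSE)
  .sub_seeds(seed)[idx]
}
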