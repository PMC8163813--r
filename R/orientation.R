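#' Bin division-orientation angles into parallel/oblique/perpendicular
#'
#' Angles (degrees from the basement membrane, already folded into
#' `[0, 90]`) are partitioned into parallel `[0, 30)`, oblique `[30, 60)`
#' and perpendicular `[60, 90]` divisions — the continuous realization of
#' the integer ranges 0-29, 30-59 and 60-90. Inputs outside `[0, 90]` are
#' rejected (not folded) with the offending record identified.
#'
#' @param angles Numeric vector of angles in degrees.
#' @param group Optional group label carried through to the result.
#' @return An object of class `"bin_proportions"`: a list with `group`,
#'   `counts` (named integer vector) and `proportions`.
#' @examples
#' bin_angles(c(10, 45, 80))
#' @export
bin_angles <- function(angles, group = NA_character_) {
  bad <- which(is.na(angles) | angles < 0 | angles > 90)
  if (length(bad) > 0L) {
    stop("angle(s) outside [0, 90] degrees at position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  counts <- c(
    parallel = sum(angles < 30),
    oblique = sum(angles >= 30 & angles < 60),
    perpendicular = sum(angles >= 60)
  )
  total <- sum(counts)
  structure(
    list(group = group, counts = counts,
         proportions = if (total > 0) counts / total else counts * NA_real_),
    class = "bin_proportions"
  )
}

#' @export
print.bin_proportions <- function(x, ...) {
  if (!is.na(x$group)) cat("Group:", x$group, "\n")
  cat(sprintf(
    "  parallel (0-29): %d (%.1f%%)\n  oblique (30-59): %d (%.1f%%)\n  perpendicular (60-90): %d (%.1f%%)\n",
    x$counts[1L], 100 * x$proportions[1L],
    x$counts[2L], 100 * x$proportions[2L],
    x$counts[3L], 100 * x$proportions[3L]))
  invisible(x)
}

#' Radial-histogram bin counts for orientation angles
#'
#' Counts angles in consecutive `bin_width_deg`-degree bins over `[0, 90]`,
#' half-open on the right except the last bin, which is closed at 90 so
#' counts are conserved.
#'
#' @param angles Numeric vector of angles in `[0, 90]` degrees.
#' @param bin_width_deg Bin width in degrees; must divide 90.
#' @return A data.frame with columns `bin_start`, `bin_end`, `count`.
#' @examples
#' radial_histogram(c(5, 5, 85), bin_width_deg = 10)
#' @export
radial_histogram <- function(angles, bin_width_deg = 10) {
  if (90 %% bin_width_deg != 0) {
    stop("`bin_width_deg` must divide 90", call. = FALSE)
  }
  bad <- which(is.na(angles) | angles < 0 | angles > 90)
  if (length(bad) > 0L) {
    stop("angle(s) outside [0, 90] degrees at position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  starts <- seq(0, 90 - bin_width_deg, by = bin_width_deg)
  ends <- starts + bin_width_deg
  counts <- vapply(seq_along(starts), function(i) {
    if (i == length(starts)) {
      sum(angles >= starts[i] & angles <= ends[i])
    } else {
      sum(angles >= starts[i] & angles < ends[i])
    }
  }, numeric(1L))
  data.frame(bin_start = starts, bin_end = ends, count = as.integer(counts))
}

.test_result <- function(test, statistic, df = NA_real_, p_value, n = NA,
                         note = NA_character_) {
  structure(
    list(test = test, statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), n = n, note = note),
    class = "strat_test"
  )
}

#' @export
print.strat_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g", x$test, x$statistic))
  if (!all(is.na(x$df))) cat(sprintf(", df = %s",
                                     paste(x$df, collapse = ", ")))
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Pearson chi-squared test on binned orientation counts
#'
#' Compares the (parallel, oblique, perpendicular) counts of two groups in
#' a 2 x 3 contingency table (Pearson, no continuity correction, df = 2).
#' A bin empty in both groups is dropped with the degrees of freedom
#' reduced and a warning; expected counts below 5 set a note on the result
#' rather than failing.
#'
#' @param countsA,countsB Integer vectors of 3 bin counts, each with a
#'   positive total.
#' @return A `"strat_test"` result with fields `test`, `statistic`, `df`,
#'   `p_value`, `n`, `note`.
#' @examples
#' chi_squared_bins(c(50, 30, 20), c(20, 30, 50))
#' @export
chi_squared_bins <- function(countsA, countsB) {
  if (length(countsA) != 3L || length(countsB) != 3L) {
    stop("each group must supply 3 bin counts", call. = FALSE)
  }
  if (sum(countsA) <= 0 || sum(countsB) <= 0) {
    stop("each group total must be positive", call. = FALSE)
  }
  m <- rbind(A = countsA, B = countsB)
  colnames(m) <- c("parallel", "oblique", "perpendicular")
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning("dropping bin(s) with zero total: ",
            paste(colnames(m)[empty], collapse = ", "),
            "; degrees of freedom reduced", call. = FALSE)
    m <- m[, !empty, drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  note <- if (any(ht$expected < 5)) {
    "expected count(s) below 5; chi-squared approximation may be poor"
  } else NA_character_
  .test_result("chi-squared (2x3 bins)", ht$statistic, ht$parameter,
               ht$p.value, n = rowSums(m), note = note)
}

#' Two-sample Kolmogorov-Smirnov test on angle distributions
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic two-sample distribution.
#'
#' @param anglesA,anglesB Non-empty numeric vectors.
#' @return A `"strat_test"` result.
#' @examples
#' ks_two_sample(c(10, 20, 30), c(10, 20, 30, 70))
#' @export
ks_two_sample <- function(anglesA, anglesB) {
  if (length(anglesA) == 0L || length(anglesB) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ht <- suppressWarnings(stats::ks.test(anglesA, anglesB, exact = FALSE))
  .test_result("two-sample Kolmogorov-Smirnov", ht$statistic, NA_real_,
               ht$p.value, n = c(length(anglesA), length(anglesB)))
}

#' Per-animal bin proportions from an angle dataset
#'
#' Convenience builder for [proportions_anova()]: bins each animal's angles
#' and returns one row per animal with the three bin proportions.
#'
#' @param angles An angle table (schema `angles`).
#' @param stage Optional stage filter.
#' @return A data.frame with columns `genotype`, `animal_id`, `parallel`,
#'   `oblique`, `perpendicular`.
#' @export
animal_bin_proportions <- function(angles, stage = NULL) {
  angles <- validate_table(angles, "angles")
  if (!is.null(stage)) angles <- angles[abs(angles$stage - stage) < 1e-9, ]
  if (nrow(angles) == 0L) stop("no angle records selected", call. = FALSE)
  ids <- unique(angles[, c("genotype", "animal_id")])
  props <- t(vapply(seq_len(nrow(ids)), function(i) {
    a <- angles$angle_deg[angles$animal_id == ids$animal_id[i] &
                            angles$genotype == ids$genotype[i]]
    bin_angles(a)$proportions
  }, numeric(3L)))
  out <- cbind(ids, as.data.frame(props))
  rownames(out) <- NULL
  out
}

# Interaction F statistic for proportion ~ genotype * bin computed from
# weighted cell/margin means. The design is proportionally balanced (every
# animal contributes each bin exactly once), so the sequential and marginal
# interaction sums of squares coincide and
# SS_int = SS_cells - SS_genotype - SS_bin.
.interaction_f <- function(y, genotype, bin) {
  N <- length(y)
  gm <- mean(y)
  cell <- interaction(genotype, bin, drop = TRUE)
  ss_of <- function(f) {
    m <- tapply(y, f, mean)
    n <- tapply(y, f, length)
    sum(n * (m - gm)^2)
  }
  ss_cells <- ss_of(cell)
  ss_int <- ss_cells - ss_of(genotype) - ss_of(bin)
  ss_res <- sum((y - stats::ave(y, cell))^2)
  G <- nlevels(factor(genotype)); B <- nlevels(factor(bin))
  df_int <- (G - 1L) * (B - 1L)
  df_res <- N - G * B
  list(f = (ss_int / df_int) / (ss_res / df_res),
       ss_int = ss_int, ss_res = ss_res, df_int = df_int, df_res = df_res,
       ss_tot = sum((y - gm)^2))
}

#' Two-way ANOVA on per-animal bin proportions
#'
#' Fits `proportion ~ genotype * bin` on per-animal bin proportions and
#' reports the genotype-by-bin interaction: the genotype effect on the
#' *shape* of the orientation distribution (the genotype main effect is
#' structurally null because each animal's proportions sum to 1). Degenerate
#' zero-variance designs are handled explicitly: a numerically zero
#' interaction sum of squares gives p = 1, and a non-zero interaction with
#' zero residual variance gives p = 0.
#'
#' Because each animal's three proportions sum to 1, the residuals are
#' negatively correlated within animals and the classical F reference
#' distribution is anticonservative for small animal numbers. Setting
#' `n_permutations > 0` replaces the F-distribution p-value with a
#' permutation p-value obtained by shuffling genotype labels across animals
#' (`p = (1 + #{F_perm >= F_obs}) / (n_permutations + 1)`), which is
#' calibrated under the exchangeable null.
#'
#' @param per_animal A data.frame with columns `genotype`, `animal_id`,
#'   `parallel`, `oblique`, `perpendicular` (see
#'   [animal_bin_proportions()]); every genotype needs at least 2 animals.
#' @param n_permutations If positive, number of genotype-label permutations
#'   used to calibrate the interaction p-value.
#' @param seed Optional seed for the permutations.
#' @return A `"strat_test"` result for the interaction term.
#' @export
proportions_anova <- function(per_animal, n_permutations = 0L,
                              seed = NULL) {
  need <- c("genotype", "animal_id", "parallel", "oblique", "perpendicular")
  missing <- setdiff(need, names(per_animal))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_per <- table(unique(per_animal[, c("genotype", "animal_id")])$genotype)
  if (any(n_per < 2L)) {
    stop("genotype(s) with fewer than 2 animals: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "), call. = FALSE)
  }
  long <- data.frame(
    genotype = rep(per_animal$genotype, 3L),
    animal_id = rep(per_animal$animal_id, 3L),
    bin = rep(c("parallel", "oblique", "perpendicular"),
              each = nrow(per_animal)),
    proportion = c(per_animal$parallel, per_animal$oblique,
                   per_animal$perpendicular))
  long$genotype <- factor(long$genotype)
  long$bin <- factor(long$bin, levels = c("parallel", "oblique",
                                          "perpendicular"))
  fstat <- .interaction_f(long$proportion, long$genotype, long$bin)
  tol <- 1e-12 * max(fstat$ss_tot, 1e-12)
  name <- "two-way ANOVA (genotype x bin interaction)"
  dfs <- c(fstat$df_int, fstat$df_res)
  if (fstat$ss_int <= tol) {
    return(.test_result(name, 0, dfs, 1, n = nrow(per_animal),
                        note = "interaction sum of squares numerically zero"))
  }
  if (fstat$ss_res / max(1L, fstat$df_res) <= tol) {
    return(.test_result(name, Inf, dfs, 0, n = nrow(per_animal),
                        note = "zero within-group variance"))
  }
  if (n_permutations > 0L) {
    obs <- fstat$f
    animals <- per_animal[, c("genotype", "animal_id")]
    perm_ps <- function() {
      hits <- 0L
      for (i in seq_len(n_permutations)) {
        shuffled <- sample(animals$genotype)
        g_perm <- rep(shuffled, 3L)
        f_i <- .interaction_f(long$proportion, g_perm, long$bin)$f
        if (!is.na(f_i) && f_i >= obs - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (n_permutations + 1)
    }
    p <- if (is.null(seed)) perm_ps() else .with_seed(seed, perm_ps())
    return(.test_result(name, obs, dfs, p, n = nrow(per_animal),
                        note = sprintf("%d-permutation p-value",
                                       n_permutations)))
  }
  .test_result(name, fstat$f, dfs,
               stats::pf(fstat$f, fstat$df_int, fstat$df_res,
                         lower.tail = FALSE),
               n = nrow(per_animal))
}

#' Two-tailed two-sample Student's t-test
#'
#' Pooled-variance two-sample t-test (the classical Student form). The
#' degenerate both-groups-constant case is handled explicitly: equal means
#' give p = 1, different means p = 0.
#'
#' @param groupA,groupB Numeric vectors with at least 2 values each.
#' @return A `"strat_test"` result.
#' @examples
#' compare_group_means(c(1, 2, 3), c(2, 3, 4))
#' @export
compare_group_means <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  df <- length(groupA) + length(groupB) - 2L
  pooled_var <- (sum((groupA - mean(groupA))^2) +
                   sum((groupB - mean(groupB))^2)) / df
  scale2 <- max(mean(c(groupA, groupB))^2, 1e-300)
  if (pooled_var <= 1e-24 * scale2) {
    equal <- abs(mean(groupA) - mean(groupB)) <= sqrt(1e-24 * scale2)
    return(.test_result("two-tailed Student's t (pooled variance)",
                        if (equal) 0 else Inf, df,
                        if (equal) 1 else 0,
                        n = c(length(groupA), length(groupB)),
                        note = "zero within-group variance"))
  }
  ht <- stats::t.test(groupA, groupB, var.equal = TRUE)
  .test_result("two-tailed Student's t (pooled variance)", ht$statistic,
               ht$parameter, ht$p.value,
               n = c(length(groupA), length(groupB)))
}
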