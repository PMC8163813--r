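#' Relative cell-number index from densities and axis lengths
#'
#' The total number of cells of a layer grows in proportion to the product
#' of the linear cell density and the tissue extent along each of the two
#' body axes:
#' `index = (density_sagittal * length_sagittal) * (density_orthogonal *
#' length_orthogonal)`.
#' The index is relative (arbitrary units): only ratios across stages are
#' meaningful, and no normalization constant is applied.
#'
#' @param density_sagittal,density_orthogonal Layer densities (cells per
#'   100 um) along each axis; non-negative.
#' @param length_sagittal,length_orthogonal Body-axis lengths (mm);
#'   non-negative.
#' @return The dimensionless cell-number index (vectorized).
#' @examples
#' cell_number_index(2, 1.5, 10, 8) # 240
#' @export
cell_number_index <- function(density_sagittal, density_orthogonal,
                              length_sagittal, length_orthogonal) {
  args <- list(density_sagittal, density_orthogonal, length_sagittal,
               length_orthogonal)
  if (any(vapply(args, function(a) any(a < 0), logical(1L)))) {
    stop("densities and lengths must be non-negative", call. = FALSE)
  }
  (density_sagittal * length_sagittal) *
    (density_orthogonal * length_orthogonal)
}

# stage-level mean and standard error of a vector of per-animal values
.mean_se <- function(x) {
  n <- length(x)
  se <- if (n > 1L) stats::sd(x) / sqrt(n) else 0
  c(mean = mean(x), se = se)
}

#' Build a cell-number series from density and growth tables
#'
#' For every stage shared by the two tables, combines stage-mean densities
#' (per layer and axis) with stage-mean axis lengths into the relative
#' cell-number index, per layer, plus a `total` row equal to the sum of the
#' basal and suprabasal indices. Standard errors are propagated to first
#' order (delta method) from the per-group standard errors of the means,
#' treating the group means as independent; the shared length terms of the
#' basal and suprabasal indices are accounted for in the gradient of the
#' total.
#'
#' @param densities A density table (schema `density`).
#' @param growth A growth table (schema `growth`).
#' @return A data.frame with columns `stage`, `layer`
#'   (`basal`/`suprabasal`/`total`), `index`, `index_se` (schema
#'   `cellnumber`).
#' @seealso [cell_number_index()], [summarize_phase()]
#' @examples
#' cfg <- generator_config(seed = 1)
#' series <- build_cell_number_series(generate_density_table(cfg),
#'                                    generate_growth_table(cfg))
#' subset(series, layer == "total")
#' @export
build_cell_number_series <- function(densities, growth) {
  densities <- validate_table(densities, "density")
  growth <- validate_table(growth, "growth")
  st_d <- sort(unique(densities$stage))
  st_g <- sort(unique(growth$stage))
  only_d <- setdiff(st_d, st_g)
  only_g <- setdiff(st_g, st_d)
  if (length(only_d) || length(only_g)) {
    stop("stage coverage mismatch between tables; stages missing from ",
         "growth: [", paste(only_d, collapse = ", "),
         "]; missing from densities: [", paste(only_g, collapse = ", "), "]",
         call. = FALSE)
  }
  rows <- list()
  for (stage in st_d) {
    L <- lapply(.allowed_axes, function(ax) {
      .mean_se(growth$length_mm[growth$stage == stage & growth$axis == ax])
    })
    names(L) <- .allowed_axes
    P <- list()
    for (layer in .allowed_layers) {
      P[[layer]] <- lapply(.allowed_axes, function(ax) {
        v <- densities$density_per_100um[densities$stage == stage &
                                           densities$layer == layer &
                                           densities$axis == ax]
        if (length(v) == 0L) {
          stop("no ", layer, "/", ax, " densities at stage ", stage,
               call. = FALSE)
        }
        .mean_se(v)
      })
      names(P[[layer]]) <- .allowed_axes
    }
    ls <- L$sagittal["mean"]; lo <- L$orthogonal["mean"]
    se_ls <- L$sagittal["se"]; se_lo <- L$orthogonal["se"]
    layer_stats <- lapply(.allowed_layers, function(layer) {
      ps <- P[[layer]]$sagittal["mean"]; po <- P[[layer]]$orthogonal["mean"]
      se_ps <- P[[layer]]$sagittal["se"]
      se_po <- P[[layer]]$orthogonal["se"]
      idx <- cell_number_index(ps, po, ls, lo)
      # gradient of ps*po*ls*lo wrt (ps, po, ls, lo)
      grad <- c(po * ls * lo, ps * ls * lo, ps * po * lo, ps * po * ls)
      var_ <- sum(grad^2 * c(se_ps, se_po, se_ls, se_lo)^2)
      list(index = unname(idx), se = sqrt(var_), ps = unname(ps),
           po = unname(po), se_ps = unname(se_ps), se_po = unname(se_po))
    })
    names(layer_stats) <- .allowed_layers
    for (layer in .allowed_layers) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage = stage, layer = layer,
        index = layer_stats[[layer]]$index,
        index_se = unname(layer_stats[[layer]]$se))
    }
    # total = ls*lo*(pbs*pbo + pss*pso); delta method with shared lengths
    b <- layer_stats$basal; s <- layer_stats$suprabasal
    D <- b$ps * b$po + s$ps * s$po
    tot <- unname(ls * lo) * D
    grad_tot <- c(
      unname(lo) * D, unname(ls) * D,                       # wrt ls, lo
      unname(ls * lo) * b$po, unname(ls * lo) * b$ps,       # wrt pbs, pbo
      unname(ls * lo) * s$po, unname(ls * lo) * s$ps        # wrt pss, pso
    )
    se_tot <- sqrt(sum(grad_tot^2 * c(se_ls, se_lo, b$se_ps, b$se_po,
                                      s$se_ps, s$se_po)^2))
    rows[[length(rows) + 1L]] <- data.frame(
      stage = stage, layer = "total", index = tot, index_se = unname(se_tot))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_table(out, "cellnumber")
}

#' Summarize one growth phase of a cell-number series
#'
#' Computes the fold change of the index between the first and last stage of
#' the window `[phase_start, phase_end]` and classifies the trend as
#' exponential or linear by information-criterion comparison: a log-linear
#' fit (log-normal likelihood on the raw scale) against a straight-line fit
#' (normal likelihood), both with three parameters. `trend_score` is
#' `AIC(linear) - AIC(exponential)`: positive values favour the exponential.
#' Exactly-fitting (zero-residual) models are detected and win outright; a
#' constant series fits both exactly and is reported as linear with score 0.
#'
#' @param series A cell-number series (schema `cellnumber`).
#' @param layer Which layer to summarize (`"total"`, `"basal"` or
#'   `"suprabasal"`).
#' @param phase_start,phase_end Embryonic-day window bounds; at least three
#'   stages must fall inside.
#' @return A list of class `"phase_summary"`: `phase_start`, `phase_end`,
#'   `fold_change`, `trend`, `trend_score`.
#' @examples
#' st <- seq(12.5, 15.5, by = 1)
#' series <- data.frame(stage = st, layer = "total",
#'                      index = exp(0.66 * (st - 12.5)), index_se = 0)
#' summarize_phase(series, "total", 12.5, 15.5)
#' @export
summarize_phase <- function(series, layer = "total", phase_start,
                            phase_end) {
  series <- validate_table(series, "cellnumber")
  if (phase_end <= phase_start) {
    stop("`phase_end` must exceed `phase_start`", call. = FALSE)
  }
  sub <- series[series$layer == layer &
                  series$stage >= phase_start - 1e-9 &
                  series$stage <= phase_end + 1e-9, ]
  sub <- sub[order(sub$stage), ]
  if (nrow(sub) < 3L) {
    stop("need at least 3 stages inside [", phase_start, ", ", phase_end,
         "]; found ", nrow(sub), call. = FALSE)
  }
  if (any(sub$index <= 0)) {
    stop("indices must be positive to compare exponential and linear trends",
         call. = FALSE)
  }
  y <- sub$index
  t <- sub$stage
  fold <- y[length(y)] / y[1L]
  n <- length(y)
  rss_lin <- sum(stats::resid(stats::lm(y ~ t))^2)
  rss_exp <- sum(stats::resid(stats::lm(log(y) ~ t))^2)
  exact_lin <- rss_lin / n <= (1e-9 * mean(abs(y)))^2
  exact_exp <- rss_exp / n <= (1e-9 * max(1, mean(abs(log(y)))))^2
  if (exact_lin && exact_exp) {
    trend <- "linear"; score <- 0
  } else if (exact_lin) {
    trend <- "linear"; score <- -Inf
  } else if (exact_exp) {
    trend <- "exponential"; score <- Inf
  } else {
    const <- n * (1 + log(2 * pi))
    aic_lin <- n * log(rss_lin / n) + const + 6
    # log-normal on the raw scale: Jacobian term sum(log y)
    aic_exp <- n * log(rss_exp / n) + const + 2 * sum(log(y)) + 6
    score <- aic_lin - aic_exp
    trend <- if (score > 0) "exponential" else "linear"
  }
  structure(
    list(phase_start = phase_start, phase_end = phase_end,
         layer = layer, fold_change = unname(fold), trend = trend,
         trend_score = score),
    class = "phase_summary"
  )
}

#' @export
print.phase_summary <- function(x, ...) {
  cat(sprintf(
    "Phase E%.1f-E%.1f (%s layer): fold change %.3g, %s trend (score %.3g)\n",
    x$phase_start, x$phase_end, x$layer, x$fold_change, x$trend,
    x$trend_score))
  invisible(x)
}
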