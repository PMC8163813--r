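# Tabular interchange: headered CSV, one schema per table kind.
# Units are part of the schema (documented here), not of the column names
# beyond the _mm / _per_100um / _deg suffixes.

.schemas <- list(
  growth = list(
    columns = c(embryo_id = "character", stage = "numeric",
                axis = "character", length_mm = "numeric")
  ),
  density = list(
    columns = c(animal_id = "character", stage = "numeric",
                layer = "character", axis = "character",
                density_per_100um = "numeric")
  ),
  edu = list(
    columns = c(animal_id = "character", stage = "numeric",
                layer = "character", n_positive = "integer",
                n_total = "integer")
  ),
  angles = list(
    columns = c(animal_id = "character", genotype = "character",
                stage = "numeric", angle_deg = "numeric")
  ),
  trajectory = list(
    columns = c(replicate = "integer", time = "numeric", b = "numeric",
                s = "numeric", total = "numeric")
  ),
  cellnumber = list(
    columns = c(stage = "numeric", layer = "character", index = "numeric",
                index_se = "numeric")
  )
)

.allowed_layers <- c("basal", "suprabasal")
.allowed_axes <- c("sagittal", "orthogonal")

.row_fail <- function(schema, rows, field, why) {
  stop(sprintf("%s table: %s invalid in row(s) %s: %s", schema, field,
               paste(utils::head(rows, 10L), collapse = ", "), why),
       call. = FALSE)
}

#' Validate a measurement table against a named schema
#'
#' Checks column presence, coerces types, and enforces the row-level
#' invariants of the schema (positive lengths, non-negative densities,
#' `n_positive <= n_total`, angles in `[0, 90]`, known layer/axis labels,
#' ...). Violations are reported with row numbers and field names.
#'
#' @param x A data.frame.
#' @param schema One of `"growth"`, `"density"`, `"edu"`, `"angles"`,
#'   `"trajectory"`, `"cellnumber"`.
#' @return The validated (type-coerced) data.frame, invisibly usable in
#'   pipelines.
#' @seealso [read_measurement_table()]
#' @export
validate_table <- function(x, schema) {
  if (!schema %in% names(.schemas)) {
    stop("unknown schema '", schema, "'; known schemas: ",
         paste(names(.schemas), collapse = ", "), call. = FALSE)
  }
  spec <- .schemas[[schema]]$columns
  missing <- setdiff(names(spec), names(x))
  if (length(missing) > 0L) {
    stop(schema, " table: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- x[names(spec)]
  for (col in names(spec)) {
    target <- spec[[col]]
    val <- x[[col]]
    coerced <- switch(target,
      character = as.character(val),
      numeric = suppressWarnings(as.numeric(val)),
      integer = suppressWarnings(as.integer(as.numeric(val)))
    )
    if (target != "character") {
      bad <- which(!is.na(val) & is.na(coerced) |
                     (target == "integer" &
                        suppressWarnings(as.numeric(val)) !=
                        round(suppressWarnings(as.numeric(val)))))
      bad <- bad[!is.na(bad)]
      if (length(bad) > 0L) .row_fail(schema, bad, col, "unparsable value")
      nas <- which(is.na(coerced))
      if (length(nas) > 0L) .row_fail(schema, nas, col, "missing value")
    }
    x[[col]] <- coerced
  }
  check_labels <- function(col, allowed) {
    bad <- which(!x[[col]] %in% allowed)
    if (length(bad) > 0L) {
      .row_fail(schema, bad, col,
                paste0("allowed labels: ", paste(allowed, collapse = ", ")))
    }
  }
  if (schema == "growth") {
    check_labels("axis", .allowed_axes)
    bad <- which(x$length_mm <= 0)
    if (length(bad) > 0L) .row_fail(schema, bad, "length_mm",
                                    "lengths must be strictly positive")
    key <- paste(x$embryo_id, x$axis, x$stage)
    if (anyDuplicated(key)) {
      .row_fail(schema, which(duplicated(key)), "embryo_id",
                "each (embryo, axis) pair may appear at most once per stage")
    }
  } else if (schema == "density") {
    check_labels("layer", .allowed_layers)
    check_labels("axis", .allowed_axes)
    bad <- which(x$density_per_100um < 0)
    if (length(bad) > 0L) .row_fail(schema, bad, "density_per_100um",
                                    "densities must be non-negative")
  } else if (schema == "edu") {
    check_labels("layer", .allowed_layers)
    bad <- which(x$n_positive < 0)
    if (length(bad) > 0L) .row_fail(schema, bad, "n_positive",
                                    "must be non-negative")
    bad <- which(x$n_total < 1L)
    if (length(bad) > 0L) .row_fail(schema, bad, "n_total",
                                    "must be positive")
    bad <- which(x$n_positive > x$n_total)
    if (length(bad) > 0L) .row_fail(schema, bad, "n_positive",
                                    "n_positive must not exceed n_total")
  } else if (schema == "angles") {
    bad <- which(x$angle_deg < 0 | x$angle_deg > 90)
    if (length(bad) > 0L) .row_fail(schema, bad, "angle_deg",
                                    "angles must lie in [0, 90] degrees")
  } else if (schema == "cellnumber") {
    check_labels("layer", c(.allowed_layers, "total"))
    bad <- which(x$index_se < 0)
    if (length(bad) > 0L) .row_fail(schema, bad, "index_se",
                                    "must be non-negative")
  } else if (schema == "trajectory") {
    bad <- which(x$b < 0 | x$s < 0)
    if (length(bad) > 0L) .row_fail(schema, bad, "b/s",
                                    "counts must be non-negative")
  }
  x
}

#' Read and validate a measurement table from CSV
#'
#' @param path Path to a headered CSV file.
#' @param schema Schema name; see [validate_table()].
#' @return The validated data.frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_measurement_table(generate_growth_table(generator_config()), f)
#' nrow(read_measurement_table(f, "growth"))
#' @export
read_measurement_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(x, schema)
}

#' Write a measurement table as headered CSV
#'
#' @param x A data.frame (typically one produced by this package).
#' @param path Output file path.
#' @param schema Optional schema name to validate against before writing.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(x, path, schema = NULL) {
  if (!is.null(schema)) x <- validate_table(x, schema)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
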