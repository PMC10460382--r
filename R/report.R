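#' Morphometry report for one gas cell wall
#'
#' Validated container for the per-wall quantification: the per-granule
#' table, the starch fraction (mean and SD across analysis slices), the
#' per-class number/volume percentages, and optionally wall dimensions and
#' wall class.  Construction enforces the report invariants: percentage
#' vectors sum to 100 (within 1e-6), every granule volume equals
#' `pi d^3 / 6`, and fractions lie in `[0, 1]`.
#'
#' @param per_granule Tibble with columns `id`, `z_slice`, `max_feret_um`,
#'   `volume_um3`, `size_class`.
#' @param starch_fraction_mean,starch_fraction_sd Unitless; `NA` allowed for
#'   an empty report.
#' @param class_number_pct,class_volume_pct Named numeric vectors over
#'   classes `C`, `B`, `A`; `NULL` allowed when the table is empty.
#' @param dimensions Optional [measure_gcw_dimensions()] result.
#' @param wall_class Optional `"string"` / `"intact"`.
#' @return An object of class `morphometry_report`.
#' @export
morphometry_report <- function(per_granule,
                               starch_fraction_mean = NA_real_,
                               starch_fraction_sd = NA_real_,
                               class_number_pct = NULL,
                               class_volume_pct = NULL,
                               dimensions = NULL,
                               wall_class = NA_character_) {
  per_granule <- tibble::as_tibble(per_granule)
  need <- c("id", "z_slice", "max_feret_um", "volume_um3", "size_class")
  if (!all(need %in% names(per_granule))) {
    stop_input(sprintf("`per_granule` must have columns %s",
                       paste(need, collapse = ", ")),
               class = "gcwmorph_validation_error")
  }
  if (nrow(per_granule) > 0) {
    v_expect <- sphere_volume_from_feret(per_granule$max_feret_um)
    bad <- abs(per_granule$volume_um3 - v_expect) >
      1e-8 * pmax(v_expect, 1e-12)
    if (any(bad)) {
      stop_input("granule volumes violate V = pi d^3 / 6",
                 class = "gcwmorph_validation_error")
    }
    for (nmv in list(class_number_pct, class_volume_pct)) {
      if (is.null(nmv) || abs(sum(nmv) - 100) > 1e-6) {
        stop_input("class percentages must sum to 100 (within 1e-6)",
                   class = "gcwmorph_validation_error")
      }
    }
  }
  if (!is.na(starch_fraction_mean) &&
      (starch_fraction_mean < 0 || starch_fraction_mean > 1)) {
    stop_input("`starch_fraction_mean` must be in [0, 1]",
               class = "gcwmorph_validation_error")
  }
  structure(list(per_granule = per_granule,
                 starch_fraction_mean = starch_fraction_mean,
                 starch_fraction_sd = starch_fraction_sd,
                 class_number_pct = class_number_pct,
                 class_volume_pct = class_volume_pct,
                 dimensions = dimensions,
                 wall_class = wall_class),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("<morphometry_report> %d granule(s)", nrow(x$per_granule)))
  if (!is.na(x$starch_fraction_mean)) {
    cat(sprintf(", starch fraction %.1f%% +/- %.1f%%",
                100 * x$starch_fraction_mean, 100 * x$starch_fraction_sd))
  }
  if (!is.na(x$wall_class)) cat(", wall class:", x$wall_class)
  cat("\n")
  invisible(x)
}

#' @describeIn morphometry_report Per-granule table as a tibble.
#' @param x A `morphometry_report`.
#' @param ... Unused.
#' @export
tidy.morphometry_report <- function(x, ...) x$per_granule

#' @describeIn morphometry_report One-row summary tibble.
#' @export
glance.morphometry_report <- function(x, ...) {
  dims <- x$dimensions
  tibble::tibble(
    n_granules = nrow(x$per_granule),
    starch_fraction_mean = x$starch_fraction_mean,
    starch_fraction_sd = x$starch_fraction_sd,
    number_pct_C = pct_or_na(x$class_number_pct, "C"),
    number_pct_B = pct_or_na(x$class_number_pct, "B"),
    number_pct_A = pct_or_na(x$class_number_pct, "A"),
    volume_pct_C = pct_or_na(x$class_volume_pct, "C"),
    volume_pct_B = pct_or_na(x$class_volume_pct, "B"),
    volume_pct_A = pct_or_na(x$class_volume_pct, "A"),
    length_um = if (is.null(dims)) NA_real_ else dims$length_um,
    width_um = if (is.null(dims)) NA_real_ else dims$width_um,
    depth_um = if (is.null(dims)) NA_real_ else dims$depth_um,
    wall_class = x$wall_class)
}

pct_or_na <- function(v, cl) {
  if (is.null(v) || !cl %in% names(v)) NA_real_ else unname(v[cl])
}

#' Write / read a morphometry report
#'
#' Writes the per-granule table as RFC-4180 CSV (`granules.csv`) and the
#' summary as JSON (`summary.json`) into a directory; values round-trip to
#' better than 1e-9 relative precision.  Report invariants are re-validated
#' before writing and after reading.
#'
#' @param report A [morphometry_report()].
#' @param dir Output directory (created if needed).
#' @return `write_report()` returns `dir` invisibly; `read_report()` the
#'   reconstructed [morphometry_report()].
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "morphometry_report"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop_input(sprintf("cannot write into '%s'", dir),
               class = "gcwmorph_io_error")
  }
  write.csv(report$per_granule, file.path(dir, "granules.csv"),
            row.names = FALSE)
  dims <- report$dimensions
  summary <- list(
    starch_fraction_mean = report$starch_fraction_mean,
    starch_fraction_sd = report$starch_fraction_sd,
    class_number_pct = as.list(report$class_number_pct),
    class_volume_pct = as.list(report$class_volume_pct),
    dimensions = if (is.null(dims)) NULL else
      list(length_um = dims$length_um, width_um = dims$width_um,
           width_min_um = dims$width_min_um, width_max_um = dims$width_max_um,
           depth_um = dims$depth_um, mid_slice = dims$mid_slice),
    wall_class = report$wall_class,
    n_granules = nrow(report$per_granule))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  per_granule <- tibble::as_tibble(
    read.csv(file.path(dir, "granules.csv"),
             colClasses = c(id = "integer", z_slice = "integer",
                            max_feret_um = "numeric", volume_um3 = "numeric",
                            size_class = "character")))
  s <- jsonlite::read_json(file.path(dir, "summary.json"),
                           simplifyVector = TRUE)
  dims <- NULL
  if (!is.null(s$dimensions)) {
    dims <- structure(as.list(s$dimensions), class = "gcw_dimensions")
  }
  morphometry_report(
    per_granule = per_granule,
    starch_fraction_mean = null_to_na(s$starch_fraction_mean),
    starch_fraction_sd = null_to_na(s$starch_fraction_sd),
    class_number_pct = unlist(s$class_number_pct),
    class_volume_pct = unlist(s$class_volume_pct),
    dimensions = dims,
    wall_class = null_to_na(s$wall_class, NA_character_))
}

null_to_na <- function(x, na = NA_real_) if (is.null(x)) na else x
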