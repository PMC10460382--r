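#' Quantify a polarized SHG + EF stack end to end
#'
#' Runs the full analysis chain on one gas cell wall stack: fuse the
#' polarized SHG channels ([combine_polarizations()]), delimit the SHG and
#' EF analyzable depths ([determine_analyzable_depth()]), segment granules
#' ([segment_granules()]), delimit the EF envelope ([segment_envelope()]),
#' and compute the morphometrics: starch fraction, size distribution with
#' A/B/C typing, wall dimensions and string/intact classification, plus an
#' optional envelope-threshold sensitivity sweep.
#'
#' @param stack An [image_stack()] with >= 1 SHG channel and one EF channel.
#' @param method Polarization fusion method, `"sum"` or `"max"`.
#' @param contrast_floor Contrast floor for the analyzable depth.
#' @param envelope_threshold EF envelope threshold; `NULL` uses
#'   [default_envelope_threshold()].
#' @param sweep Relative envelope-threshold variation for the sensitivity
#'   sweep (e.g. 0.4), or `NULL` to skip it.
#' @param n_slices,span_um,discard_first Starch-fraction slice protocol, see
#'   [starch_fraction()].  `discard_first = "auto"` (the default) skips the
#'   leading envelope slices whose segmented starch content sits clearly
#'   below the plateau of the usable depth — the border region where granule
#'   content is not yet representative — subject to the span still fitting;
#'   an integer fixes the discard count explicitly.
#' @param bins Size-distribution bin edges, see [size_distribution()].
#' @param segment_args List of extra arguments for [segment_granules()].
#' @return An object of class `gcw_quantification` with elements `combined`,
#'   `shg_range`, `ef_range`, `labels`, `envelope`, `fraction`, `sizes`,
#'   `dimensions`, `wall_class`, `sweep` and `report` (a
#'   [morphometry_report()]).
#' @export
quantify_stack <- function(stack, method = "sum", contrast_floor = 0.1,
                           envelope_threshold = NULL, sweep = NULL,
                           n_slices = 5, span_um = 6, discard_first = "auto",
                           bins = default_size_bins(),
                           segment_args = list()) {
  stopifnot(inherits(stack, "image_stack"))
  geometry <- stack$geometry
  ef_name <- ef_channel_name(stack)
  if (length(ef_name) != 1) {
    stop_input("stack must contain exactly one EF channel",
               class = "gcwmorph_input_error")
  }
  ef <- stack$voxels[[ef_name]]

  combined <- combine_polarizations(stack, method = method)
  shg_range <- determine_analyzable_depth(combined, contrast_floor, geometry)
  ef_range <- determine_analyzable_depth(ef, contrast_floor, geometry)

  labels <- do.call(segment_granules,
                    c(list(combined = combined, z_range = shg_range,
                           geometry = geometry), segment_args))

  if (is.null(envelope_threshold)) {
    envelope_threshold <- default_envelope_threshold(ef)
  }
  envelope <- segment_envelope(ef, envelope_threshold, geometry)

  if (identical(discard_first, "auto")) {
    discard_first <- auto_discard(labels, envelope, geometry,
                                  z_max = shg_range$z_end, span_um = span_um)
  }
  fraction <- starch_fraction(labels, envelope, n_slices = n_slices,
                              span_um = span_um,
                              discard_first = discard_first,
                              geometry = geometry,
                              z_max = shg_range$z_end)
  sizes <- size_distribution(labels, geometry = geometry, bins = bins,
                             z_range = shg_range)
  dims <- measure_gcw_dimensions(envelope, geometry)
  wc <- classify_wall_type(dims, stack_depth_um(stack))

  sweep_res <- NULL
  if (!is.null(sweep) && sweep > 0) {
    sweep_res <- sweep_envelope_threshold(
      ef, labels, envelope_threshold, rel_variation = sweep,
      geometry = geometry, n_slices = n_slices, span_um = span_um,
      discard_first = discard_first, z_max = shg_range$z_end)
  }

  report <- morphometry_report(
    per_granule = if (sizes$empty) empty_granule_table() else sizes$per_granule,
    starch_fraction_mean = fraction$mean,
    starch_fraction_sd = fraction$sd,
    class_number_pct = if (sizes$empty) NULL else
      setNames(sizes$by_class$number_pct, sizes$by_class$size_class),
    class_volume_pct = if (sizes$empty) NULL else
      setNames(sizes$by_class$volume_pct, sizes$by_class$size_class),
    dimensions = dims,
    wall_class = wc$wall_class)

  structure(list(combined = combined, shg_range = shg_range,
                 ef_range = ef_range, labels = labels, envelope = envelope,
                 fraction = fraction, sizes = sizes, dimensions = dims,
                 wall_class = wc$wall_class,
                 wall_class_indeterminate = wc$indeterminate,
                 sweep = sweep_res, report = report,
                 envelope_threshold = envelope_threshold,
                 geometry = geometry),
            class = "gcw_quantification")
}

# Leading-slice discard for the starch-fraction band: skip envelope slices
# whose segmented starch area is clearly below the plateau of the usable
# depth (the granule border effect), keeping at least one discarded slice
# and never pushing the span out of the usable range.
auto_discard <- function(labels, envelope, geometry, z_max, span_um) {
  if (envelope$empty) return(1L)
  z0 <- envelope$z_start
  cap <- min(envelope$z_end, z_max)
  span_slices <- round(span_um / geometry$z_step)
  max_discard <- cap - span_slices - z0
  if (max_discard < 1L) return(1L)
  window <- z0:cap
  a <- vapply(window, function(k)
    sum(labels$labels[, , k] > 0L & envelope$mask[, , k]), numeric(1))
  med <- stats::median(a)
  k_rep <- which(a >= 0.6 * med)[1]
  if (is.na(k_rep)) k_rep <- 1L
  min(max(k_rep - 1L, 1L), max_discard)
}

#' @export
print.gcw_quantification <- function(x, ...) {
  cat("<gcw_quantification>\n")
  cat(sprintf("  SHG analyzable depth: %.1f um (slices %d..%d); EF: %.1f um\n",
              x$shg_range$depth_um, x$shg_range$z_start, x$shg_range$z_end,
              x$ef_range$depth_um))
  cat(sprintf("  %d granule label(s); starch fraction %.1f%% +/- %.1f%%\n",
              x$labels$n_labels, 100 * x$fraction$mean, 100 * x$fraction$sd))
  cat(sprintf("  wall L x W x D = %.1f x %.1f x %.1f um -> %s%s\n",
              x$dimensions$length_um, x$dimensions$width_um,
              x$dimensions$depth_um, x$wall_class,
              if (x$wall_class_indeterminate) " (indeterminate)" else ""))
  invisible(x)
}

#' @describeIn quantify_stack Per-granule table of the quantification.
#' @param x A `gcw_quantification`.
#' @param ... Unused.
#' @export
tidy.gcw_quantification <- function(x, ...) tidy(x$report)

#' @describeIn quantify_stack One-row summary (adds depth ranges to the
#'   report summary).
#' @export
glance.gcw_quantification <- function(x, ...) {
  out <- glance(x$report)
  out$shg_depth_um <- x$shg_range$depth_um
  out$ef_depth_um <- x$ef_range$depth_um
  out$envelope_threshold <- x$envelope_threshold
  out$sweep_spread <- if (is.null(x$sweep)) NA_real_ else x$sweep$spread
  out
}

#' Match segmented granules to ground truth
#'
#' Greedy one-to-one matching of predicted labels to ground-truth granules
#' by 3D voxel overlap within the analyzable depth, reporting per-truth IoU
#' and centre offsets.  Used to validate segmentation against the synthetic
#' scene generator.
#'
#' @param labels A [label_map()] from [segment_granules()].
#' @param scene The [build_scene()] scene that generated the stack.
#' @param z_range Optional [determine_analyzable_depth()] range; matching is
#'   restricted to these slices.
#' @return A tibble: `truth_id`, `pred_id` (NA if unmatched), `iou`,
#'   `center_offset_um` (in-plane), `truth_diameter_um`.
#' @export
match_granules <- function(labels, scene, z_range = NULL) {
  stopifnot(inherits(labels, "label_map"), inherits(scene, "gcw_scene"))
  arr <- labels$labels
  truth <- scene$truth_labels
  d <- dim(arr)
  zs <- if (is.null(z_range)) 1L else z_range$z_start
  ze <- if (is.null(z_range)) d[3] else z_range$z_end
  sub_p <- arr[, , zs:ze, drop = FALSE]
  sub_t <- truth[, , zs:ze, drop = FALSE]
  nt <- max(sub_t); np <- max(sub_p)
  gr <- scene$granules
  if (nt == 0 || np == 0) {
    return(tibble::tibble(truth_id = gr$id, pred_id = NA_integer_,
                          iou = 0, center_offset_um = NA_real_,
                          truth_diameter_um = gr$true_diameter_um))
  }
  size_t <- tabulate(sub_t[sub_t > 0L], nbins = nt)
  size_p <- tabulate(sub_p[sub_p > 0L], nbins = np)
  both <- sub_t > 0L & sub_p > 0L
  key <- (as.integer(sub_t[both]) - 1L) * np + as.integer(sub_p[both])
  ov <- tabulate(key, nbins = nt * np)
  pairs <- which(ov > 0L)
  ord <- pairs[order(-ov[pairs])]
  used_p <- logical(np); matched <- rep(NA_integer_, nt); iou <- numeric(nt)
  for (hk in ord) {
    ti <- (hk - 1L) %/% np + 1L
    pi <- (hk - 1L) %% np + 1L
    if (!is.na(matched[ti]) || used_p[pi]) next
    matched[ti] <- pi; used_p[pi] <- TRUE
    iou[ti] <- ov[hk] / (size_t[ti] + size_p[pi] - ov[hk])
  }
  # in-plane centroid offsets for matched pairs
  px <- scene$geometry$pixel_size_xy
  offs <- rep(NA_real_, nt)
  for (ti in which(!is.na(matched))) {
    pi <- matched[ti]
    idx <- which(sub_p == pi, arr.ind = TRUE)
    cx_p <- mean(idx[, 2]) * px - 0.5 * px
    cy_p <- mean(idx[, 1]) * px - 0.5 * px
    offs[ti] <- sqrt((cx_p - gr$x_um[ti])^2 + (cy_p - gr$y_um[ti])^2)
  }
  present <- gr$id[gr$id <= nt]
  tibble::tibble(truth_id = present,
                 pred_id = matched[present],
                 iou = iou[present],
                 center_offset_um = offs[present],
                 truth_diameter_um = gr$true_diameter_um[match(present, gr$id)])
}
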