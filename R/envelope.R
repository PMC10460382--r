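#' Default EF envelope threshold
#'
#' A small fraction (default 0.12) of the robust maximum of the positive EF
#' voxels.  Sitting well below the gluten level keeps the dim starch-granule
#' interiors inside the envelope across the analyzable depth, while the gas
#' background (essentially zero signal) stays excluded.
#'
#' @param ef 3D EF intensity array.
#' @param rel Fraction of the robust (99th percentile) positive intensity.
#' @return A single intensity threshold.
#' @export
default_envelope_threshold <- function(ef, rel = 0.12) {
  pos <- ef[ef > 0]
  if (length(pos) == 0) return(Inf)
  rel * quantile(pos, 0.99, names = FALSE)
}

#' Delimit the gas cell wall envelope from the EF channel
#'
#' Per slice: threshold the EF image, keep the largest connected component
#' (one wall per field of view), close and fill it morphologically to obtain
#' a smooth outline that overlaps the granules and extends just beyond the
#' outermost ones.  The depth extent of the envelope is the range of slices
#' with a non-empty mask — for a string the EF signal ends with the wall,
#' for an intact wall it spans essentially the whole stack.
#'
#' @param ef 3D EF intensity array.
#' @param threshold Intensity threshold (> 0); see
#'   [default_envelope_threshold()].
#' @param geometry A [voxel_geometry()].
#' @param close_radius_px Radius of the morphological closing brush.
#' @param min_area_px Slices whose largest component is smaller than this are
#'   treated as empty (noise in the gas cavity).
#' @return An object of class `gcw_envelope`: `mask` (logical array),
#'   `z_start`, `z_end`, `threshold`, `empty` flag, `geometry`.
#' @export
segment_envelope <- function(ef, threshold, geometry = voxel_geometry(),
                             close_radius_px = 7, min_area_px = 20) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop_input("`threshold` must be a positive intensity",
               class = "gcwmorph_input_error")
  }
  d <- dim(ef)
  mask <- array(FALSE, dim = d)
  brush <- EBImage::makeBrush(2L * close_radius_px + 1L, shape = "disc")
  nonempty <- logical(d[3])
  for (k in seq_len(d[3])) {
    bw <- ef[, , k] > threshold
    if (sum(bw) < min_area_px) next
    lab <- EBImage::bwlabel(bw)
    sizes <- tabulate(lab[lab > 0])
    big <- which.max(sizes)
    if (sizes[big] < min_area_px) next
    m <- lab == big
    m <- EBImage::closing(m, brush)
    m <- EBImage::fillHull(m)
    mask[, , k] <- as.logical(m)
    nonempty[k] <- TRUE
  }
  if (!any(nonempty)) {
    warn("nothing above the envelope threshold: empty envelope")
    return(structure(list(mask = mask, z_start = NA_integer_,
                          z_end = NA_integer_, threshold = threshold,
                          empty = TRUE, geometry = geometry),
                     class = "gcw_envelope"))
  }
  structure(list(mask = mask,
                 z_start = as.integer(which(nonempty)[1]),
                 z_end = as.integer(max(which(nonempty))),
                 threshold = threshold, empty = FALSE, geometry = geometry),
            class = "gcw_envelope")
}

#' @export
print.gcw_envelope <- function(x, ...) {
  if (x$empty) cat("<gcw_envelope> empty\n")
  else cat(sprintf("<gcw_envelope> slices %d..%d, threshold %.4g\n",
                   x$z_start, x$z_end, x$threshold))
  invisible(x)
}

#' Starch-fraction sensitivity to the envelope threshold
#'
#' Recomputes the envelope and the starch fraction at
#' `base_threshold * (1 - rel_variation)`, the base threshold, and
#' `base_threshold * (1 + rel_variation)`, and reports the spread
#' (max - min) of the three mean fractions.  This propagates the manual
#' thresholding uncertainty of the envelope into the starch fraction.
#'
#' @param ef 3D EF intensity array.
#' @param labels A [label_map()] of segmented granules.
#' @param base_threshold Base envelope threshold.
#' @param rel_variation Relative threshold variation in (0, 1); 0 is allowed
#'   and yields a zero spread.  Default 0.4.
#' @param geometry A [voxel_geometry()].
#' @param z_max Cap slice index for the fraction slices (end of the SHG
#'   analyzable depth).
#' @inheritParams starch_fraction
#' @return A list: `fractions` (tibble with `level`, `threshold`,
#'   `fraction_mean`, `fraction_sd`), `spread`, `flagged` (TRUE when a sweep
#'   point yielded an empty envelope, in which case `spread` is `NA`).
#' @export
sweep_envelope_threshold <- function(ef, labels, base_threshold,
                                     rel_variation = 0.4,
                                     geometry = voxel_geometry(),
                                     n_slices = 5, span_um = 6,
                                     discard_first = 1, z_max = NULL) {
  if (rel_variation < 0 || rel_variation >= 1) {
    stop_input("`rel_variation` must be in [0, 1)")
  }
  thrs <- base_threshold * c(1 - rel_variation, 1, 1 + rel_variation)
  levels <- c("low", "base", "high")
  rows <- vector("list", 3)
  flagged <- FALSE
  for (i in 1:3) {
    env <- segment_envelope(ef, thrs[i], geometry)
    if (env$empty) {
      flagged <- TRUE
      rows[[i]] <- tibble::tibble(level = levels[i], threshold = thrs[i],
                                  fraction_mean = NA_real_,
                                  fraction_sd = NA_real_)
      next
    }
    fr <- starch_fraction(labels, env, n_slices = n_slices, span_um = span_um,
                          discard_first = discard_first, geometry = geometry,
                          z_max = z_max)
    rows[[i]] <- tibble::tibble(level = levels[i], threshold = thrs[i],
                                fraction_mean = fr$mean, fraction_sd = fr$sd)
  }
  fractions <- dplyr::bind_rows(rows)
  spread <- if (flagged) NA_real_ else
    max(fractions$fraction_mean) - min(fractions$fraction_mean)
  list(fractions = fractions, spread = spread, flagged = flagged)
}
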