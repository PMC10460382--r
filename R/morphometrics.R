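#' Max-Feret diameter of a 2D mask
#'
#' Maximum Euclidean distance between pixel centres of the mask, in um —
#' the longest caliper dimension.  Computed on the convex hull for large
#' masks (the Feret pair always lies on the hull), by direct enumeration of
#' all pairs for small ones; both routes are exact.  A single-pixel mask is
#' below resolution and returns 0 um with a `sub_resolution` attribute.
#'
#' @param mask 2D logical (or 0/1) matrix.
#' @param geometry A [voxel_geometry()].
#' @return Length in um; attribute `sub_resolution` is TRUE for singletons.
#' @examples
#' m <- matrix(FALSE, 5, 15); m[3, 3:13] <- TRUE  # 11-px run
#' max_feret_diameter(m, voxel_geometry())        # (11 - 1) * 0.17 = 1.7
#' @export
max_feret_diameter <- function(mask, geometry = voxel_geometry()) {
  pxl <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(pxl)
  if (n == 0) {
    stop_input("`mask` is empty", class = "gcwmorph_input_error")
  }
  if (n == 1) {
    return(structure(0, sub_resolution = TRUE))
  }
  pts <- cbind(pxl[, 2], pxl[, 1])  # (x, y) in pixel units
  if (n > 400) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  dmax <- sqrt(max(as.vector(stats::dist(pts))^2))
  structure(dmax * geometry$pixel_size_xy, sub_resolution = FALSE)
}

#' Classify granule diameters into wheat-starch size types
#'
#' C-type below 5 um, B-type from 5 to 15 um inclusive, A-type above 15 um.
#' The B interval is closed on both ends: the strict inequalities belong to
#' the A ("> 15 um") and C ("< 5 um") classes.
#'
#' @param d Numeric vector of Max-Feret diameters, um (>= 0).
#' @return An ordered factor with levels `C < B < A`.
#' @examples
#' classify_granule_size(c(4, 6, 22, 5, 15))
#' @export
classify_granule_size <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_input("diameters must be finite and >= 0",
               class = "gcwmorph_input_error")
  }
  cls <- ifelse(d < 5, "C", ifelse(d <= 15, "B", "A"))
  factor(cls, levels = c("C", "B", "A"), ordered = TRUE)
}

#' Spherical-equivalent granule volume from the Max-Feret diameter
#'
#' `V = pi * d^3 / 6`, the classical spherical assumption used to convert 2D
#' granule sizes into a volume-weighted distribution.
#'
#' @param d Diameter(s), um (>= 0).
#' @return Volume(s), um^3.
#' @examples
#' sphere_volume_from_feret(22)  # ~5575.28
#' @export
sphere_volume_from_feret <- function(d) {
  if (any(d < 0)) stop_input("`d` must be >= 0")
  pi * d^3 / 6
}

#' Histogram bin edges for granule size distributions
#'
#' Near-logarithmic diameter bins (um) resolving the three wheat-starch
#' modes; bins are half-open `[lo, hi)`.
#'
#' @return Numeric vector of bin edges.
#' @export
default_size_bins <- function() {
  c(0, 1.5, 2.5, 3.5, 4.5, 5.5, 7, 9, 12, 15, 19, 25, 32, 45)
}

#' Granule size distribution on a representative slice
#'
#' For every granule present on the representative slice, measures the
#' Max-Feret diameter of its slice mask, assigns the A/B/C size class and
#' the spherical-equivalent volume, and aggregates number- and
#' volume-weighted percentages per class and per histogram bin.  The
#' representative slice defaults to the slice carrying the most granule
#' labels within the considered range (ties to the shallower slice).
#'
#' @param labels A [label_map()].
#' @param representative_z Slice index; `NULL` picks automatically.
#' @param geometry A [voxel_geometry()].
#' @param bins Histogram bin edges (um), half-open `[lo, hi)`.
#' @param z_range Optional [determine_analyzable_depth()] range (or integer
#'   vector of slices) to restrict the representative-slice search.
#' @return An object of class `gcw_size_distribution`: `per_granule` tibble
#'   (`id`, `z_slice`, `max_feret_um`, `volume_um3`, `size_class`),
#'   `by_class` and `by_bin` percentage tibbles (each percentage column sums
#'   to 100), `representative_z`, `empty` flag.
#' @export
size_distribution <- function(labels, representative_z = NULL,
                              geometry = NULL, bins = default_size_bins(),
                              z_range = NULL) {
  stopifnot(inherits(labels, "label_map"))
  if (is.null(geometry)) geometry <- labels$geometry
  arr <- labels$labels
  nz <- dim(arr)[3]
  slices <- if (is.null(z_range)) seq_len(nz)
            else if (inherits(z_range, "depth_range")) z_range$z_start:z_range$z_end
            else as.integer(z_range)
  if (is.null(representative_z)) {
    counts <- vapply(slices, function(k) {
      sl <- arr[, , k]
      length(unique(sl[sl > 0L]))
    }, integer(1))
    if (all(counts == 0L)) {
      warn("no granules on any candidate slice: empty size distribution")
      return(structure(list(per_granule = empty_granule_table(),
                            by_class = NULL, by_bin = NULL,
                            representative_z = NA_integer_, empty = TRUE),
                       class = "gcw_size_distribution"))
    }
    representative_z <- slices[which.max(counts)]  # ties -> shallower
  }
  sl <- arr[, , representative_z]
  ids <- sort(unique(sl[sl > 0L]))
  if (length(ids) == 0L) {
    warn("no granules on the representative slice: empty size distribution")
    return(structure(list(per_granule = empty_granule_table(),
                          by_class = NULL, by_bin = NULL,
                          representative_z = representative_z, empty = TRUE),
                     class = "gcw_size_distribution"))
  }
  d <- vapply(ids, function(id) as.numeric(max_feret_diameter(sl == id, geometry)),
              numeric(1))
  per_granule <- tibble::tibble(
    id = as.integer(ids),
    z_slice = as.integer(representative_z),
    max_feret_um = d,
    volume_um3 = sphere_volume_from_feret(d),
    size_class = as.character(classify_granule_size(d)))
  by_class <- summarize_classes(per_granule)
  by_bin <- summarize_bins(per_granule, bins)
  structure(list(per_granule = per_granule, by_class = by_class,
                 by_bin = by_bin, representative_z = representative_z,
                 empty = FALSE),
            class = "gcw_size_distribution")
}

empty_granule_table <- function() {
  tibble::tibble(id = integer(), z_slice = integer(), max_feret_um = numeric(),
                 volume_um3 = numeric(), size_class = character())
}

summarize_classes <- function(per_granule) {
  tot_v <- sum(per_granule$volume_um3)
  out <- lapply(c("C", "B", "A"), function(cl) {
    sub <- per_granule[per_granule$size_class == cl, ]
    tibble::tibble(size_class = cl, n = nrow(sub),
                   number_pct = 100 * nrow(sub) / nrow(per_granule),
                   volume_pct = if (tot_v > 0) 100 * sum(sub$volume_um3) / tot_v
                                else 0)
  })
  dplyr::bind_rows(out)
}

summarize_bins <- function(per_granule, bins) {
  lo <- bins[-length(bins)]; hi <- bins[-1]
  idx <- findInterval(per_granule$max_feret_um, bins,
                      rightmost.closed = FALSE, left.open = FALSE)
  idx[idx == length(bins)] <- length(bins) - 1L  # clamp overflow to last bin
  tot_v <- sum(per_granule$volume_um3)
  n <- vapply(seq_along(lo), function(b) sum(idx == b), numeric(1))
  v <- vapply(seq_along(lo), function(b)
    sum(per_granule$volume_um3[idx == b]), numeric(1))
  tibble::tibble(bin_lo = lo, bin_hi = hi, mid = (lo + hi) / 2,
                 n = as.integer(n),
                 number_pct = 100 * n / nrow(per_granule),
                 volume_pct = if (tot_v > 0) 100 * v / tot_v else 0 * v)
}

#' Local maxima (modes) of a binned size distribution
#'
#' Bins whose number percentage strictly exceeds both neighbours
#' (zero-padded at the edges), annotated with the size class of the bin
#' midpoint.  A trimodal wheat distribution yields one mode per class.
#'
#' @param dist A [size_distribution()] result (or its `by_bin` tibble).
#' @return Tibble of mode bins: `bin_lo`, `bin_hi`, `mid`, `number_pct`,
#'   `size_class`.
#' @export
distribution_modes <- function(dist) {
  by_bin <- if (inherits(dist, "gcw_size_distribution")) dist$by_bin else dist
  v <- c(0, by_bin$number_pct, 0)
  is_max <- vapply(seq_len(nrow(by_bin)), function(i)
    v[i + 1] > v[i] && v[i + 1] > v[i + 2], logical(1))
  out <- by_bin[is_max, c("bin_lo", "bin_hi", "mid", "number_pct")]
  out$size_class <- as.character(classify_granule_size(out$mid))
  out
}

#' Areal starch fraction of a gas cell wall
#'
#' The fraction of envelope pixels occupied by segmented starch, evaluated
#' on `n_slices` slices evenly spread over a `span_um`-deep band starting
#' `discard_first` slices below the top of the envelope (border slices are
#' discarded as unrepresentative), and summarized as mean and sample SD
#' across slices.
#'
#' @param labels A [label_map()] of segmented granules.
#' @param envelope A [segment_envelope()] result.
#' @param n_slices Number of analysis slices (>= 2; default 5).
#' @param span_um Total depth spanned by the analysis slices, um (default 6).
#' @param discard_first Number of leading envelope slices discarded.
#' @param geometry A [voxel_geometry()].
#' @param z_max Optional cap on the slice index (typically the end of the
#'   SHG analyzable depth).
#' @return An object of class `starch_fraction`: `mean`, `sd`, `per_slice`
#'   tibble (`z`, `starch_px`, `envelope_px`, `fraction`), `n_used`.
#' @export
starch_fraction <- function(labels, envelope, n_slices = 5, span_um = 6,
                            discard_first = 1, geometry = NULL,
                            z_max = NULL) {
  stopifnot(inherits(labels, "label_map"), inherits(envelope, "gcw_envelope"))
  if (is.null(geometry)) geometry <- labels$geometry
  if (envelope$empty) {
    stop_input("envelope is empty", class = "gcwmorph_input_error")
  }
  if (n_slices < 2) stop_input("`n_slices` must be >= 2")
  dz <- geometry$z_step
  z0 <- envelope$z_start + discard_first
  m <- round(span_um / dz)
  z_last <- z0 + m
  cap <- envelope$z_end
  if (!is.null(z_max)) cap <- min(cap, z_max)
  if (z_last > cap) {
    stop_input(sprintf(
      "a %g um span starting at slice %d does not fit the usable depth (max slice %d)",
      span_um, z0, cap), class = "gcwmorph_input_error")
  }
  zs <- unique(round(seq(z0, z_last, length.out = n_slices)))
  arr <- labels$labels
  rows <- lapply(zs, function(k) {
    env_px <- sum(envelope$mask[, , k])
    if (env_px == 0) {
      warn(sprintf("empty envelope on slice %d: slice skipped", k))
      return(NULL)
    }
    starch <- sum(arr[, , k] > 0L & envelope$mask[, , k])
    tibble::tibble(z = as.integer(k), starch_px = starch,
                   envelope_px = env_px, fraction = starch / env_px)
  })
  per_slice <- dplyr::bind_rows(rows)
  if (nrow(per_slice) < 2) {
    stop_input("fewer than 2 usable slices for the starch fraction",
               class = "gcwmorph_input_error")
  }
  structure(list(mean = mean(per_slice$fraction),
                 sd = sd(per_slice$fraction),
                 per_slice = per_slice, n_used = nrow(per_slice)),
            class = "starch_fraction")
}

#' @export
print.starch_fraction <- function(x, ...) {
  cat(sprintf("<starch_fraction> %.1f%% +/- %.1f%% over %d slices\n",
              100 * x$mean, 100 * x$sd, x$n_used))
  invisible(x)
}

#' Wall dimensions L x W x D from the envelope
#'
#' Length is the Max-Feret diameter of the mid-depth envelope slice; width
#' is the extent perpendicular to the length axis, measured in a one-pixel
#' band at the midpoint of the length (with the min/max width along the
#' central 90 % of the length also reported, since wall width varies);
#' depth is the slice extent of the envelope times the z-step.
#'
#' @param envelope A non-empty [segment_envelope()] result.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `gcw_dimensions`: `length_um`, `width_um`,
#'   `width_min_um`, `width_max_um`, `depth_um`, `mid_slice`.
#' @export
measure_gcw_dimensions <- function(envelope, geometry = NULL) {
  stopifnot(inherits(envelope, "gcw_envelope"))
  if (envelope$empty) {
    stop_input("envelope is empty", class = "gcwmorph_input_error")
  }
  if (is.null(geometry)) geometry <- envelope$geometry
  px <- geometry$pixel_size_xy
  mid <- as.integer(floor((envelope$z_start + envelope$z_end) / 2))
  mask <- envelope$mask[, , mid]
  if (!any(mask)) {  # fall back to the nearest non-empty slice
    cand <- which(vapply(seq_len(dim(envelope$mask)[3]),
                         function(k) any(envelope$mask[, , k]), logical(1)))
    mid <- cand[which.min(abs(cand - mid))]
    mask <- envelope$mask[, , mid]
  }
  pxl <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = pxl[, 2], y = pxl[, 1])
  hull <- if (nrow(pts) > 3) pts[grDevices::chull(pts), , drop = FALSE] else pts
  dmat <- as.matrix(stats::dist(hull))
  far <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  p1 <- hull[far[1], ]; p2 <- hull[far[2], ]
  L <- sqrt(sum((p2 - p1)^2)) * px
  e <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  perp <- c(-e[2], e[1])
  proj_l <- pts %*% e
  proj_w <- pts %*% perp
  mid_l <- (sum(p1 * e) + sum(p2 * e)) / 2
  near <- abs(proj_l - mid_l) <= 1
  W <- if (any(near)) (max(proj_w[near]) - min(proj_w[near]) + 1) * px else px
  # width profile along the central 90 % of the length
  lo <- quantile(proj_l, 0.05); hi <- quantile(proj_l, 0.95)
  bins <- floor(proj_l)
  keep <- proj_l >= lo & proj_l <= hi
  prof <- tapply((proj_w[keep]), bins[keep],
                 function(v) (max(v) - min(v) + 1) * px)
  structure(list(length_um = as.numeric(L),
                 width_um = as.numeric(W),
                 width_min_um = as.numeric(min(prof)),
                 width_max_um = as.numeric(max(prof)),
                 depth_um = (envelope$z_end - envelope$z_start + 1) *
                   geometry$z_step,
                 mid_slice = mid),
            class = "gcw_dimensions")
}

#' @export
print.gcw_dimensions <- function(x, ...) {
  cat(sprintf("<gcw_dimensions> L x W x D = %.1f x %.1f x %.1f um (W range %.1f-%.1f)\n",
              x$length_um, x$width_um, x$depth_um,
              x$width_min_um, x$width_max_um))
  invisible(x)
}

#' Classify a wall as string or intact
#'
#' A string — the remnant of a partially ruptured wall — occupies well under
#' the full stack depth (D <= 0.6 x stack depth) with a depth comparable to
#' its width (D <= 1.5 W); an intact wall spans nearly the whole stack
#' (D >= 0.85 x stack depth).  Walls matching neither rule are flagged
#' indeterminate and assigned to the nearer class.
#'
#' @param dims A [measure_gcw_dimensions()] result.
#' @param stack_depth_um Full depth of the image stack, um.
#' @return A list: `wall_class` (`"string"` or `"intact"`), `indeterminate`.
#' @export
classify_wall_type <- function(dims, stack_depth_um) {
  stopifnot(inherits(dims, "gcw_dimensions"))
  D <- dims$depth_um; W <- dims$width_um
  if (D <= 0.6 * stack_depth_um && D <= 1.5 * W) {
    list(wall_class = "string", indeterminate = FALSE)
  } else if (D >= 0.85 * stack_depth_um) {
    list(wall_class = "intact", indeterminate = FALSE)
  } else {
    list(wall_class = if (D < 0.725 * stack_depth_um) "string" else "intact",
         indeterminate = TRUE)
  }
}
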