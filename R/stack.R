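#' Multi-channel 3D image stack
#'
#' Container for a multi-channel multiphoton acquisition.  Each channel is a
#' numeric array indexed `[y, x, z]` (rows, columns, slices), all channels
#' share the same dimensions, and intensities are finite, non-negative and
#' stored on the 16-bit integer grid `0..65535` (the assumed acquisition bit
#' depth).
#'
#' @param voxels Named list of 3D numeric arrays, one per channel, all with
#'   identical `dim`.
#' @param channels List of [channel_spec()] objects, same length and order as
#'   `voxels`.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, channels, geometry = voxel_geometry()) {
  if (!is.list(voxels) || length(voxels) == 0) {
    stop_input("`voxels` must be a non-empty list of 3D arrays",
               class = "gcwmorph_validation_error")
  }
  if (length(voxels) != length(channels)) {
    stop_input("`voxels` and `channels` must have the same length",
               class = "gcwmorph_validation_error")
  }
  d <- dim(voxels[[1]])
  if (length(d) != 3) {
    stop_input("each channel must be a 3D array [y, x, z]",
               class = "gcwmorph_validation_error")
  }
  for (i in seq_along(voxels)) {
    if (!identical(dim(voxels[[i]]), d)) {
      stop_input("all channels must share identical (y, x, z) dimensions",
                 class = "gcwmorph_validation_error")
    }
    v <- voxels[[i]]
    if (anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
      stop_input("intensities must be finite and non-negative",
                 class = "gcwmorph_validation_error")
    }
  }
  channels <- lapply(channels, function(ch) {
    if (!inherits(ch, "channel_spec")) {
      stop_input("`channels` must be a list of channel_spec objects",
                 class = "gcwmorph_validation_error")
    }
    ch
  })
  names(voxels) <- vapply(channels, channel_name, character(1))
  names(channels) <- names(voxels)
  structure(list(voxels = voxels, channels = channels, geometry = geometry),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels[[1]])
  cat(sprintf("<image_stack> %d channel(s), %d x %d px, %d slices (%.4g um/px, %.4g um z-step)\n",
              length(x$voxels), d[2], d[1], d[3],
              x$geometry$pixel_size_xy, x$geometry$z_step))
  cat("  channels:", paste(names(x$voxels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels[[1]])

stack_n_slices <- function(stack) dim(stack$voxels[[1]])[3]

stack_depth_um <- function(stack) stack_n_slices(stack) * stack$geometry$z_step

shg_channel_names <- function(stack) {
  keep <- vapply(stack$channels, function(ch) ch$modality == "SHG", logical(1))
  names(stack$channels)[keep]
}

ef_channel_name <- function(stack) {
  keep <- vapply(stack$channels, function(ch) ch$modality == "EF", logical(1))
  names(stack$channels)[keep]
}

#' Write / read a multi-channel stack as multi-page TIFF plus sidecar metadata
#'
#' Pages are written slice-major within channel (channel 1 slices 1..nz, then
#' channel 2, ...), as 16-bit unsigned grey TIFF. The sidecar is a small YAML
#' key-value file declaring image dimensions, voxel geometry and the modality
#' of every channel; it is the authoritative source for channel order.
#' Intensities are rounded to the 16-bit grid on write, so a stack already on
#' that grid round-trips voxel-for-voxel.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param metadata_path Sidecar YAML path; defaults to `path` with a `.yml`
#'   extension appended.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path, metadata_path = paste0(path, ".yml")) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels[[1]])
  if (max(vapply(stack$voxels, max, numeric(1))) > 65535) {
    stop_input("stack intensities exceed the 16-bit range 0..65535",
               class = "gcwmorph_validation_error")
  }
  pages <- list()
  for (ch in names(stack$voxels)) {
    v <- stack$voxels[[ch]]
    for (k in seq_len(d[3])) {
      pages[[length(pages) + 1L]] <- v[, , k] / 65535
    }
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop_input(sprintf("cannot write TIFF to '%s'", path),
               class = "gcwmorph_io_error")
  }
  meta <- list(
    format = "gcwmorph-stack",
    ny = d[1], nx = d[2], nz = d[3],
    pixel_size_xy_um = stack$geometry$pixel_size_xy,
    z_step_um = stack$geometry$z_step,
    channels = lapply(stack$channels, function(ch) {
      list(modality = ch$modality, direction = ch$direction,
           polarization_deg = if (is.na(ch$polarization_deg)) "not_applicable"
                              else ch$polarization_deg)
    })
  )
  yaml::write_yaml(meta, metadata_path)
  invisible(path)
}

read_stack_metadata <- function(metadata_path) {
  if (!file.exists(metadata_path)) {
    stop_input(sprintf("metadata file '%s' not found", metadata_path),
               class = "gcwmorph_format_error")
  }
  meta <- yaml::read_yaml(metadata_path)
  need <- c("ny", "nx", "nz", "pixel_size_xy_um", "z_step_um", "channels")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop_input(sprintf("metadata is missing field(s): %s",
                       paste(miss, collapse = ", ")),
               class = "gcwmorph_format_error")
  }
  if (meta$pixel_size_xy_um <= 0 || meta$z_step_um <= 0) {
    stop_input("metadata declares a non-positive voxel size",
               class = "gcwmorph_validation_error")
  }
  meta
}

#' @rdname write_stack
#' @export
read_stack <- function(path, metadata_path = paste0(path, ".yml")) {
  meta <- read_stack_metadata(metadata_path)
  if (!file.exists(path)) {
    stop_input(sprintf("TIFF file '%s' not found", path),
               class = "gcwmorph_format_error")
  }
  pages <- try(tiff::readTIFF(path, all = TRUE, as.is = FALSE), silent = TRUE)
  if (inherits(pages, "try-error")) {
    stop_input(sprintf("'%s' is not a readable TIFF", path),
               class = "gcwmorph_format_error")
  }
  n_ch <- length(meta$channels)
  if (length(pages) != n_ch * meta$nz) {
    stop_input(sprintf(
      "metadata declares %d channel(s) x %d slice(s) but TIFF has %d page(s)",
      n_ch, meta$nz, length(pages)), class = "gcwmorph_format_error")
  }
  channels <- lapply(meta$channels, function(ch) {
    pol <- ch$polarization_deg
    if (identical(pol, "not_applicable")) pol <- NULL
    channel_spec(ch$modality,
                 direction = if (ch$direction == "not_applicable") NULL
                             else ch$direction,
                 polarization_deg = pol)
  })
  voxels <- vector("list", n_ch)
  for (i in seq_len(n_ch)) {
    arr <- array(0, dim = c(meta$ny, meta$nx, meta$nz))
    for (k in seq_len(meta$nz)) {
      pg <- pages[[(i - 1L) * meta$nz + k]]
      if (!identical(dim(pg)[1:2], c(as.integer(meta$ny), as.integer(meta$nx)))) {
        stop_input("TIFF page dimensions contradict metadata",
                   class = "gcwmorph_format_error")
      }
      arr[, , k] <- round(pg * 65535)
    }
    voxels[[i]] <- arr
  }
  image_stack(voxels, channels,
              voxel_geometry(meta$pixel_size_xy_um, meta$z_step_um))
}

#' Labelled 3D segmentation map
#'
#' Integer-labelled granule segmentation: 0 is background, labels `1..K`
#' identify granules. Labels must form a contiguous id set. Connectivity is
#' 8-neighbour in-plane and 26-neighbour in 3D (slices linked by overlap).
#'
#' @param labels 3D integer array `[y, x, z]`.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, geometry = voxel_geometry()) {
  if (length(dim(labels)) != 3) {
    stop_input("`labels` must be a 3D array", class = "gcwmorph_validation_error")
  }
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0]
  if (length(ids) > 0 && !identical(as.integer(ids), seq_len(max(ids)))) {
    stop_input("label ids must form the contiguous set {1..K}",
               class = "gcwmorph_validation_error")
  }
  structure(list(labels = labels, n_labels = length(ids), geometry = geometry),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d granule label(s) in %d x %d x %d\n",
              x$n_labels, d[2], d[1], d[3]))
  invisible(x)
}

#' Write / read a label map as 16-bit multi-page TIFF
#'
#' One page per slice; label ids are stored directly as 16-bit grey values
#' (at most 65535 labels).
#'
#' @param x A [label_map()].
#' @param path Output TIFF path.
#' @param metadata_path Sidecar YAML path.
#' @return `write_label_map()` returns `path` invisibly; `read_label_map()`
#'   a [label_map()].
#' @export
write_label_map <- function(x, path, metadata_path = paste0(path, ".yml")) {
  stopifnot(inherits(x, "label_map"))
  if (x$n_labels > 65535) {
    stop_input("more than 65535 labels cannot be stored as 16-bit TIFF",
               class = "gcwmorph_io_error")
  }
  d <- dim(x$labels)
  pages <- lapply(seq_len(d[3]), function(k) x$labels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  yaml::write_yaml(list(format = "gcwmorph-labels",
                        ny = d[1], nx = d[2], nz = d[3],
                        pixel_size_xy_um = x$geometry$pixel_size_xy,
                        z_step_um = x$geometry$z_step),
                   metadata_path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path, metadata_path = paste0(path, ".yml")) {
  meta <- yaml::read_yaml(metadata_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = c(meta$ny, meta$nx, meta$nz))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(round(pages[[k]] * 65535))
  label_map(arr, voxel_geometry(meta$pixel_size_xy_um, meta$z_step_um))
}
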