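#' Voxel geometry of an image stack
#'
#' Lateral pixel size and axial step of a multiphoton acquisition, in
#' micrometres.  The defaults correspond to a typical high-resolution GCW
#' acquisition (0.17 um lateral sampling, 0.5 um z-step).
#'
#' Slices are indexed from 1 in R; slice `k` covers the physical depth
#' interval `[(k - 1) * z_step, k * z_step)` (half-open), and its intensity
#' is attributed to the mid-depth `(k - 0.5) * z_step`.
#'
#' @param pixel_size_xy Lateral size of one pixel in um. Must be > 0.
#' @param z_step Axial distance between consecutive slices in um. Must be > 0.
#' @return An object of class `voxel_geometry`.
#' @examples
#' voxel_geometry()
#' voxel_geometry(pixel_size_xy = 0.34, z_step = 1)
#' @export
voxel_geometry <- function(pixel_size_xy = 0.17, z_step = 0.5) {
  if (!is.numeric(pixel_size_xy) || length(pixel_size_xy) != 1 ||
      !is.finite(pixel_size_xy) || pixel_size_xy <= 0) {
    stop_input("`pixel_size_xy` must be a single positive number (um)",
               class = "gcwmorph_validation_error")
  }
  if (!is.numeric(z_step) || length(z_step) != 1 ||
      !is.finite(z_step) || z_step <= 0) {
    stop_input("`z_step` must be a single positive number (um)",
               class = "gcwmorph_validation_error")
  }
  structure(list(pixel_size_xy = pixel_size_xy, z_step = z_step),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> %.4g um/px lateral, %.4g um z-step\n",
              x$pixel_size_xy, x$z_step))
  invisible(x)
}

#' Channel specification
#'
#' Declares the modality of one acquisition channel: polarized SHG
#' (backward or forward detection at one of the four linear polarization
#' angles 0/45/90/135 degrees) or endogenous fluorescence (EF), which
#' carries neither a detection direction nor a polarization angle.
#'
#' @param modality `"SHG"` or `"EF"`.
#' @param direction `"backward"` or `"forward"` for SHG; ignored for EF.
#' @param polarization_deg One of 0, 45, 90, 135 for SHG; ignored for EF.
#' @return An object of class `channel_spec`.
#' @examples
#' channel_spec("SHG", "backward", 45)
#' channel_spec("EF")
#' @export
channel_spec <- function(modality, direction = NULL, polarization_deg = NULL) {
  modality <- match.arg(modality, c("SHG", "EF"))
  if (modality == "SHG") {
    if (is.null(direction) || is.null(polarization_deg)) {
      stop_input("SHG channels must declare `direction` and `polarization_deg`",
                 class = "gcwmorph_validation_error")
    }
    direction <- match.arg(direction, c("backward", "forward"))
    if (!polarization_deg %in% c(0, 45, 90, 135)) {
      stop_input("`polarization_deg` must be one of 0, 45, 90, 135",
                 class = "gcwmorph_validation_error")
    }
  } else {
    direction <- "not_applicable"
    polarization_deg <- NA_real_
  }
  structure(list(modality = modality, direction = direction,
                 polarization_deg = polarization_deg),
            class = "channel_spec")
}

channel_name <- function(spec) {
  if (spec$modality == "EF") return("EF")
  sprintf("SHG_%s_%03d",
          if (spec$direction == "backward") "B" else "F",
          as.integer(spec$polarization_deg))
}

#' The standard nine-channel polarized SHG + EF layout
#'
#' Backward and forward SHG at the four linear polarization angles,
#' plus one EF channel.
#'
#' @return A list of nine [channel_spec()] objects.
#' @export
default_channels <- function() {
  specs <- list()
  for (dir in c("backward", "forward")) {
    for (ang in c(0, 45, 90, 135)) {
      specs[[length(specs) + 1L]] <- channel_spec("SHG", dir, ang)
    }
  }
  specs[[length(specs) + 1L]] <- channel_spec("EF")
  names(specs) <- vapply(specs, channel_name, character(1))
  specs
}
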