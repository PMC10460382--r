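#' Simulation parameters for synthetic GCW scenes
#'
#' Parameters of the synthetic multiphoton scene generator. The granule
#' diameter distribution is a three-component lognormal mixture whose default
#' modes (4, 6 and 22 um for C-, B- and A-type wheat starch) reproduce the
#' trimodal size distribution typical of wheat flour. SHG is rendered with a
#' two-lobe polarization response on concentric shells, a dark hilum, and a
#' shorter attenuation length than EF, so the analyzable depth of SHG is
#' always smaller than that of EF. An axial elongation factor emulates the
#' z-stretching artifact of granules in SHG stacks.
#'
#' @param mixture Data frame / tibble with columns `class` (`"C"`, `"B"`,
#'   `"A"`), `mode_um` (modal diameter, um), `sdlog` (lognormal sigma) and
#'   `weight` (number proportions, summing to 1).
#' @param target_starch_fraction Areal starch fraction targeted in the wall's
#'   central slices, in `[0, 1]`.
#' @param hilum_radius_frac Fraction of the granule radius occupied by the
#'   SHG-dark hilum core.
#' @param lobe_exponent Sharpness `p` of the `|cos(theta)|^p` two-lobe
#'   polarization response.
#' @param atten_length_shg_um,atten_length_ef_um 1/e attenuation depths (um);
#'   SHG must attenuate faster than EF.
#' @param z_elongation_factor Axial stretch factor (>= 1) of the granule SHG
#'   signal emulating the tubular z-elongation artifact.
#' @param psf_sigma_um Lateral Gaussian PSF sigma (um); the axial PSF sigma is
#'   `z_elongation_factor` times larger.
#' @param noise_scale Scale of the signal-dependent (Poisson-like) noise,
#'   relative to full scale.
#' @param gluten_ef_level,granule_ef_level,ef_texture_amp Mean EF intensity of
#'   the gluten network and of granule interiors (relative units), and the
#'   relative amplitude of the fibrillar band-pass texture.
#' @param seed Integer seed making every draw of the generator deterministic.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(mixture = default_mixture(),
                              target_starch_fraction = 0.55,
                              hilum_radius_frac = 0.15,
                              lobe_exponent = 2,
                              atten_length_shg_um = 2.5,
                              atten_length_ef_um = 20,
                              z_elongation_factor = 1.4,
                              psf_sigma_um = 0.25,
                              noise_scale = 0.02,
                              gluten_ef_level = 0.8,
                              granule_ef_level = 0.25,
                              ef_texture_amp = 0.3,
                              seed = 1L) {
  mixture <- tibble::as_tibble(mixture)
  need <- c("class", "mode_um", "sdlog", "weight")
  if (!all(need %in% names(mixture))) {
    stop_input(sprintf("`mixture` must have columns %s",
                       paste(need, collapse = ", ")),
               class = "gcwmorph_parameter_error")
  }
  if (any(mixture$weight < 0) || abs(sum(mixture$weight) - 1) > 1e-8) {
    stop_input("mixture weights must be non-negative and sum to 1",
               class = "gcwmorph_parameter_error")
  }
  if (any(mixture$mode_um <= 0) || any(mixture$sdlog < 0)) {
    stop_input("mixture modes must be positive and sdlog non-negative",
               class = "gcwmorph_parameter_error")
  }
  if (target_starch_fraction < 0 || target_starch_fraction > 1) {
    stop_input("`target_starch_fraction` must be in [0, 1]",
               class = "gcwmorph_parameter_error")
  }
  if (atten_length_shg_um >= atten_length_ef_um) {
    stop_input("SHG must attenuate faster than EF: `atten_length_shg_um` < `atten_length_ef_um`",
               class = "gcwmorph_parameter_error")
  }
  if (z_elongation_factor < 1) {
    stop_input("`z_elongation_factor` must be >= 1",
               class = "gcwmorph_parameter_error")
  }
  structure(list(mixture = mixture,
                 target_starch_fraction = target_starch_fraction,
                 hilum_radius_frac = hilum_radius_frac,
                 lobe_exponent = lobe_exponent,
                 atten_length_shg_um = atten_length_shg_um,
                 atten_length_ef_um = atten_length_ef_um,
                 z_elongation_factor = z_elongation_factor,
                 psf_sigma_um = psf_sigma_um,
                 noise_scale = noise_scale,
                 gluten_ef_level = gluten_ef_level,
                 granule_ef_level = granule_ef_level,
                 ef_texture_amp = ef_texture_amp,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Default trimodal wheat-starch diameter mixture
#'
#' Lognormal modes at 4, 6 and 22 um for C-, B- and A-type granules, with
#' number weights dominated by the smallest class.
#'
#' @return A tibble with columns `class`, `mode_um`, `sdlog`, `weight`.
#' @export
default_mixture <- function() {
  tibble::tibble(
    class = c("C", "B", "A"),
    mode_um = c(4, 6, 22),
    sdlog = c(0.18, 0.12, 0.25),
    weight = c(0.50, 0.38, 0.12)
  )
}

#' Wall geometry of a synthetic gas cell wall
#'
#' In-plane box dimensions and depth of the simulated dough lamella. A
#' `"string"` (partially ruptured wall remnant) has a depth comparable to its
#' width and well below the stack depth; an `"intact"` wall spans nearly the
#' full stack.  `"bulk"` is an unconstrained slab for bulk-dough scenes.
#'
#' @param kind `"string"`, `"intact"` or `"bulk"`.
#' @param length_um,width_um,depth_um Wall dimensions in um.
#' @param z_offset_um Depth of the top face of the wall; `NA` centres the wall
#'   in the stack.
#' @param angle_deg In-plane rotation of the wall's long axis, degrees.
#' @return An object of class `wall_geometry`.
#' @export
wall_geometry <- function(kind = c("string", "intact", "bulk"),
                          length_um = 40, width_um = NULL, depth_um = NULL,
                          z_offset_um = NA_real_, angle_deg = 0) {
  kind <- match.arg(kind)
  if (is.null(depth_um)) {
    depth_um <- switch(kind, string = 10, intact = 19, bulk = 19)
  }
  if (is.null(width_um)) {
    width_um <- switch(kind, string = 11, intact = 24, bulk = 34)
  }
  if (length_um <= 0 || width_um <= 0 || depth_um <= 0) {
    stop_input("wall dimensions must be positive",
               class = "gcwmorph_parameter_error")
  }
  structure(list(kind = kind, length_um = length_um, width_um = width_um,
                 depth_um = depth_um, z_offset_um = z_offset_um,
                 angle_deg = angle_deg),
            class = "wall_geometry")
}

validate_wall_in_stack <- function(wall, stack_depth_um) {
  if (wall$depth_um > stack_depth_um) {
    stop_input("wall depth exceeds the stack depth",
               class = "gcwmorph_parameter_error")
  }
  if (wall$kind == "string") {
    if (wall$depth_um >= 0.6 * stack_depth_um) {
      stop_input("a string wall must be shallower than 0.6 x stack depth",
                 class = "gcwmorph_parameter_error")
    }
    if (abs(wall$depth_um - wall$width_um) > 0.5 * wall$width_um) {
      stop_input("a string wall must have depth comparable to its width",
                 class = "gcwmorph_parameter_error")
    }
  }
  if (wall$kind == "intact" && wall$depth_um < 0.9 * stack_depth_um) {
    stop_input("an intact wall must span at least 0.9 x stack depth",
               class = "gcwmorph_parameter_error")
  }
  invisible(wall)
}
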