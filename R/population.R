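#' Sample a ground-truth granule population
#'
#' Draws granule diameters from the trimodal lognormal mixture of
#' [simulation_params()] and attaches ellipsoidal shape parameters: A-type
#' granules are oblate (lenticular, polar semi-axis ~0.4 of the equatorial
#' one), B- and C-type granules near-spherical. Centres are left unset until
#' the granules are placed into a scene by [build_scene()].
#'
#' The lognormal components are parameterized by their mode: a component with
#' mode `m` and log-sd `s` draws from `meanlog = log(m) + s^2`.
#'
#' @param params A [simulation_params()].
#' @param n Number of granules (>= 0).
#' @param seed Seed; defaults to `params$seed`.
#' @return A tibble with one row per granule: `id`, `true_diameter_um`,
#'   semi-axes `a_um`, `b_um`, `c_um`, in-plane `orientation_rad`, and
#'   `size_class` (consistent with [classify_granule_size()]), plus unset
#'   centre columns `x_um`, `y_um`, `z_um`.
#' @examples
#' pop <- sample_granule_population(simulation_params(), 5)
#' pop$size_class
#' @export
sample_granule_population <- function(params, n, seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  if (n < 0) stop_input("`n` must be >= 0")
  if (n == 0) {
    return(tibble::tibble(id = integer(), true_diameter_um = numeric(),
                          a_um = numeric(), b_um = numeric(), c_um = numeric(),
                          orientation_rad = numeric(),
                          size_class = character(),
                          x_um = numeric(), y_um = numeric(), z_um = numeric()))
  }
  mix <- params$mixture
  with_seed(seed, {
    comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
    meanlog <- log(mix$mode_um[comp]) + mix$sdlog[comp]^2
    d <- rlnorm(n, meanlog = meanlog, sdlog = mix$sdlog[comp])
    cls <- as.character(classify_granule_size(d))
    a <- d / 2
    # A-type lenticular; B/C near-spherical with mild flattening jitter
    c_ax <- ifelse(cls == "A", 0.4 * a, a * runif(n, 0.85, 1))
    orient <- runif(n, 0, pi)
    tibble::tibble(id = seq_len(n), true_diameter_um = d,
                   a_um = a, b_um = a, c_um = c_ax,
                   orientation_rad = orient, size_class = cls,
                   x_um = NA_real_, y_um = NA_real_, z_um = NA_real_)
  })
}
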