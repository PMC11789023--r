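# Parameter containers. Internal units: um, s, counts.

#' Single-cell motility parameters
#'
#' Bundles the parameters of the stochastic single-cell model: overdamped
#' self-propulsion at speed `speed`, Poisson-timed complete reorientations at
#' rate `tumble_rate` (run-and-tumble mode), rotational white noise of
#' intensity `rot_diffusion`, a gravitactic righting time `reorientation_time`
#' (the time scale B on which a tilted cell realigns with the vertical), a
#' passive sedimentation speed and the cell radius (used by the optional
#' steric repulsion and by rendering).
#'
#' @param speed swimming speed u (um/s).
#' @param tumble_rate Poisson tumble rate (1/s); the reciprocal of the target
#'   velocity correlation time for pure run-and-tumble motion.
#' @param rot_diffusion rotational diffusion constant Dr (rad^2/s).
#' @param reorientation_time gravitactic reorientation time B (s); `NA` turns
#'   gravitaxis off.
#' @param sediment_speed passive sinking speed (um/s, positive = downward).
#' @param cell_radius cell radius (um).
#' @return An object of class `"motility_params"`.
#' @examples
#' motility_params(speed = 46, tumble_rate = 1 / 15)
#' @export
motility_params <- function(speed,
                            tumble_rate = 0,
                            rot_diffusion = 0,
                            reorientation_time = NA_real_,
                            sediment_speed = 0,
                            cell_radius = 4) {
  check_nonnegative(speed, "speed")
  check_nonnegative(tumble_rate, "tumble_rate")
  check_nonnegative(rot_diffusion, "rot_diffusion")
  if (!is.na(reorientation_time)) check_positive(reorientation_time, "reorientation_time")
  check_nonnegative(sediment_speed, "sediment_speed")
  check_positive(cell_radius, "cell_radius")
  structure(list(
    speed = speed, tumble_rate = tumble_rate, rot_diffusion = rot_diffusion,
    reorientation_time = reorientation_time, sediment_speed = sediment_speed,
    cell_radius = cell_radius
  ), class = "motility_params")
}

#' Rectangular 2D simulation domain
#'
#' The (x, z) plane of either geometry: the horizontal plane of a shallow
#' top-view compartment or the vertical mid-plane of a thin side-view
#' compartment. Walls are reflective for positions; gravity points along -z.
#'
#' @param width,height extents (um).
#' @return An object of class `"domain_spec"`.
#' @export
domain_spec <- function(width, height) {
  check_positive(width, "width")
  check_positive(height, "height")
  structure(list(width = width, height = height, gravity = c(0, -1)),
            class = "domain_spec")
}

#' Transmitted-light rendering parameters
#'
#' Forward Beer--Lambert image formation: each cell in a pixel column
#' attenuates the incident intensity by a factor `exp(-attenuation_per_cell)`,
#' the resulting image is blurred by a Gaussian PSF, noise is added, and the
#' image is quantized to the camera bit depth.
#'
#' @param incident_intensity incident intensity I0 (counts).
#' @param attenuation_per_cell optical density contributed by one cell
#'   (unitless; lumps the attenuation coefficient and the light path length).
#' @param psf_sigma Gaussian point-spread sigma (um); 0 disables blurring.
#' @param noise one of `"none"`, `"gaussian"`, `"poisson"`.
#' @param noise_sigma Gaussian noise standard deviation (counts); ignored for
#'   the other noise models.
#' @param pixel_size pixel size (um).
#' @param bit_depth camera bit depth (8 or 16).
#' @return An object of class `"render_params"`.
#' @export
render_params <- function(incident_intensity = 200,
                          attenuation_per_cell = 0.05,
                          psf_sigma = 0,
                          noise = c("none", "gaussian", "poisson"),
                          noise_sigma = 1,
                          pixel_size = 10,
                          bit_depth = 8L) {
  check_positive(incident_intensity, "incident_intensity")
  check_nonnegative(attenuation_per_cell, "attenuation_per_cell")
  check_nonnegative(psf_sigma, "psf_sigma")
  check_positive(pixel_size, "pixel_size")
  noise <- match.arg(noise)
  if (!bit_depth %in% c(8L, 16L)) stop_invalid("'bit_depth' must be 8 or 16")
  if (incident_intensity > 2^bit_depth - 1)
    stop_invalid("'incident_intensity' exceeds the bit-depth range")
  structure(list(
    incident_intensity = incident_intensity,
    attenuation_per_cell = attenuation_per_cell,
    psf_sigma = psf_sigma, noise = noise, noise_sigma = noise_sigma,
    pixel_size = pixel_size, bit_depth = as.integer(bit_depth)
  ), class = "render_params")
}

#' Physical parameters of the suspension
#'
#' Parameters of the gyrotactic continuum description. Units follow the
#' field's reporting conventions and are converted internally to um/s:
#' depths in mm, kinematic viscosity in m^2/s, gravity in m/s^2, diffusion in
#' um^2/s, speeds in um/s.
#'
#' Either `volume_fraction` or the pair (`mean_density`, `cell_volume`) must
#' be given; when all three are present they must satisfy
#' `volume_fraction = mean_density * cell_volume` to within 1e-6 relative.
#'
#' @param volume_fraction cell volume fraction (unitless), e.g. 0.021.
#' @param density_contrast relative cell-medium density contrast
#'   (rho_cell - rho)/rho, e.g. 0.05.
#' @param kinematic_viscosity nu (m^2/s).
#' @param cell_diffusion D (um^2/s).
#' @param cell_speed v (um/s).
#' @param reorientation_time B (s); may be `NA` (unknown).
#' @param depth compartment height h (mm).
#' @param gravity g (m/s^2).
#' @param cell_volume single-cell volume (um^3), optional.
#' @param mean_density mean cell number density (cells/mL), optional.
#' @return An object of class `"suspension_params"`.
#' @examples
#' suspension_params(volume_fraction = 0.021, density_contrast = 0.05,
#'                   kinematic_viscosity = 1e-6, cell_diffusion = 1.6e4,
#'                   cell_speed = 46, depth = 1)
#' @export
suspension_params <- function(volume_fraction = NULL,
                              density_contrast,
                              kinematic_viscosity,
                              cell_diffusion,
                              cell_speed,
                              reorientation_time = NA_real_,
                              depth,
                              gravity = 9.8,
                              cell_volume = NULL,
                              mean_density = NULL) {
  if (is.null(volume_fraction)) {
    if (is.null(cell_volume) || is.null(mean_density))
      stop_invalid("give 'volume_fraction' or both 'mean_density' and 'cell_volume'")
    # cells/mL * um^3: 1 mL = 1e12 um^3
    volume_fraction <- mean_density * cell_volume / 1e12
  } else if (!is.null(cell_volume) && !is.null(mean_density)) {
    phi2 <- mean_density * cell_volume / 1e12
    if (abs(phi2 - volume_fraction) > 1e-6 * max(volume_fraction, phi2))
      stop_invalid("inconsistent volume_fraction vs mean_density * cell_volume")
  }
  check_nonnegative(volume_fraction, "volume_fraction")
  check_nonnegative(density_contrast, "density_contrast")
  check_positive(kinematic_viscosity, "kinematic_viscosity")
  check_positive(cell_diffusion, "cell_diffusion")
  check_nonnegative(cell_speed, "cell_speed")
  if (!is.na(reorientation_time)) check_positive(reorientation_time, "reorientation_time")
  check_positive(depth, "depth")
  check_positive(gravity, "gravity")
  structure(list(
    volume_fraction = volume_fraction,
    density_contrast = density_contrast,
    kinematic_viscosity = kinematic_viscosity,
    cell_diffusion = cell_diffusion,
    cell_speed = cell_speed,
    reorientation_time = reorientation_time,
    depth = depth,
    gravity = gravity,
    cell_volume = cell_volume,
    mean_density = mean_density
  ), class = "suspension_params")
}

#' @export
print.suspension_params <- function(x, ...) {
  cat("Suspension parameters\n")
  cat(sprintf("  phi = %g, dRho/rho = %g, nu = %g m^2/s\n",
              x$volume_fraction, x$density_contrast, x$kinematic_viscosity))
  cat(sprintf("  D = %g um^2/s, v = %g um/s, B = %s s, h = %g mm, g = %g m/s^2\n",
              x$cell_diffusion, x$cell_speed,
              if (is.na(x$reorientation_time)) "unknown" else format(x$reorientation_time),
              x$depth, x$gravity))
  invisible(x)
}
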