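# Forward Beer--Lambert rendering of trajectories / density fields into
# transmitted-light image stacks, plus a parametric growing-pattern generator.

# Separable Gaussian blur with replicate edge padding.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  pad_apply <- function(a) {   # smooth along rows of a
    n <- nrow(a)
    idx <- c(rep(1L, r), seq_len(n), rep(n, r))
    ap <- a[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(a))
    for (s in -r:r)
      out <- out + k[s + r + 1L] * ap[(r + 1 + s):(r + n + s), , drop = FALSE]
    out
  }
  t(pad_apply(t(pad_apply(m))))
}

#' Project trajectory positions onto a pixel grid as per-pixel cell counts
#'
#' Bins the cell positions of each frame into pixels of size `pixel_size`
#' covering the trajectory domain. The total count in every frame equals the
#' number of cells present in that frame (cells are never lost by binning).
#'
#' @param traj a [trajectory_set()] carrying a domain.
#' @param pixel_size pixel size (um).
#' @param domain optional [domain_spec()] overriding the trajectory domain.
#' @return List of integer count matrices (nx-by-nz), one per frame.
#' @export
project_counts <- function(traj, pixel_size, domain = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  domain <- domain %||% traj$domain
  if (is.null(domain)) stop_invalid("no domain attached to the trajectories")
  nx <- max(1L, ceiling(domain$width / pixel_size))
  nz <- max(1L, ceiling(domain$height / pixel_size))
  d <- traj$data
  if (any(d$x_um < 0 | d$x_um > domain$width |
          d$z_um < 0 | d$z_um > domain$height))
    stop_invalid("positions outside the domain")
  ix <- pmin(nx, pmax(1L, floor(d$x_um / pixel_size) + 1L))
  iz <- pmin(nz, pmax(1L, floor(d$z_um / pixel_size) + 1L))
  frames <- sort(unique(d$frame))
  lapply(frames, function(fr) {
    sel <- d$frame == fr
    matrix(tabulate((iz[sel] - 1L) * nx + ix[sel], nbins = nx * nz), nx, nz)
  })
}

#' Render a transmitted-light image stack
#'
#' Forward Beer--Lambert image formation: with `k` cells in a pixel column the
#' transmitted intensity before blur and noise is
#' `I_T = I0 * exp(-attenuation_per_cell * k)`, a strictly decreasing function
#' of the local cell count. The intensity field is then blurred by the
#' Gaussian PSF, noise is added and the frame is quantized to the bit depth.
#'
#' @param traj a [trajectory_set()] (projected along the viewing axis by pixel
#'   binning), or a list of per-frame density matrices interpreted directly as
#'   per-pixel column counts.
#' @param rp a [render_params()].
#' @param domain optional [domain_spec()] overriding the trajectory domain.
#' @param frame_interval frame interval (s); required when `traj` is a plain
#'   list of density matrices.
#' @param seed integer seed for the noise draws.
#' @return An [image_stack()].
#' @examples
#' rp <- render_params(incident_intensity = 200, attenuation_per_cell = 0.2,
#'                     pixel_size = 50)
#' ts <- simulate_run_and_tumble(motility_params(46, tumble_rate = 1/15),
#'                               domain_spec(1000, 1000), 20, 1, seed = 1)
#' stk <- render_transmission_stack(ts, rp)
#' @export
render_transmission_stack <- function(traj, rp, domain = NULL,
                                      frame_interval = NULL, seed = NULL) {
  stopifnot(inherits(rp, "render_params"))
  if (inherits(traj, "trajectory_set")) {
    frame_interval <- frame_interval %||% traj$frame_interval
    if (nrow(traj$data) == 0) {
      warning("empty trajectory set: rendering uniform frames at I0")
      counts <- list(matrix(0, 16, 16))
    } else {
      counts <- project_counts(traj, rp$pixel_size, domain)
    }
  } else if (is.list(traj)) {
    counts <- traj
    if (is.null(frame_interval))
      stop_invalid("'frame_interval' is required for density-field input")
  } else stop_invalid("'traj' must be a trajectory_set or a list of matrices")

  sig_px <- rp$psf_sigma / rp$pixel_size
  qmax <- 2^rp$bit_depth - 1
  with_seed(seed, {
    frames <- lapply(counts, function(k) {
      it <- rp$incident_intensity * exp(-rp$attenuation_per_cell * k)
      it <- gaussian_blur(it, sig_px)
      if (rp$noise == "gaussian")
        it <- it + rnorm(length(it), sd = rp$noise_sigma)
      else if (rp$noise == "poisson")
        it <- matrix(rpois(length(it), lambda = it), nrow(it), ncol(it))
      matrix(pmin(qmax, pmax(0, round(it))), nrow(it), ncol(it))
    })
    image_stack(frames, rp$pixel_size, frame_interval, rp$bit_depth)
  })
}

#' Generate a synthetic growing-pattern image stack
#'
#' Produces the canonical fixture for the spectral pipeline: frames are
#' uniform (plus noise) before `onset_time`; afterwards a sinusoidal
#' modulation of the requested wavelength appears whose amplitude grows as
#' `exp(growth_rate * (t - onset_time))` from `amplitude0` until it saturates
#' at `amplitude_sat`. Defaults mirror a typical 3D-compartment observation:
#' wavelength 1.7 mm, growth rate 0.04 1/s, onset 220 s, recorded at 3 fps.
#'
#' @param wavelength pattern wavelength (mm).
#' @param growth_rate exponential growth rate (1/s).
#' @param onset_time pattern onset (s).
#' @param duration recording length (s).
#' @param frame_interval frame interval (s).
#' @param noise_sigma additive Gaussian noise SD (counts).
#' @param seed integer seed.
#' @param size frame size (px, square).
#' @param pixel_size pixel size (um).
#' @param baseline mean intensity (counts).
#' @param amplitude0 modulation amplitude right at onset (counts).
#' @param amplitude_sat saturation (plateau) amplitude (counts).
#' @param bit_depth camera bit depth.
#' @return An [image_stack()].
#' @export
generate_growing_pattern <- function(wavelength = 1.7, growth_rate = 0.04,
                                     onset_time = 220, duration = 900,
                                     frame_interval = 1 / 3, noise_sigma = 1,
                                     seed = NULL, size = 256, pixel_size = 50,
                                     baseline = 128, amplitude0 = 2,
                                     amplitude_sat = 40, bit_depth = 8L) {
  check_positive(wavelength, "wavelength")
  check_positive(duration, "duration")
  check_positive(frame_interval, "frame_interval")
  lam_px <- wavelength * 1000 / pixel_size
  if (lam_px < 2) stop_invalid("wavelength below the 2-pixel Nyquist limit")
  if (lam_px < 4) warning("wavelength barely resolved (< 4 px)")
  times <- seq(0, duration, by = frame_interval)
  x_um <- (seq_len(size) - 0.5) * pixel_size
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    carrier <- matrix(sin(2 * pi * x_um / (wavelength * 1000) + phase),
                      size, size)
    qmax <- 2^bit_depth - 1
    frames <- lapply(times, function(t) {
      a <- if (t < onset_time) 0 else
        min(amplitude0 * exp(growth_rate * (t - onset_time)), amplitude_sat)
      f <- baseline + a * carrier
      if (noise_sigma > 0) f <- f + rnorm(size * size, sd = noise_sigma)
      matrix(pmin(qmax, pmax(0, round(f))), size, size)
    })
    image_stack(frames, pixel_size, frame_interval, bit_depth)
  })
}
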