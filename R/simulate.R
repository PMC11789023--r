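# Stochastic single-cell simulators: run-and-tumble and gyrotactic swimmers.
#
# Both integrate overdamped Langevin dynamics with an explicit Euler scheme.
# Orientations are evolved as a single angle (2D), which keeps |p| = 1 exactly
# at every step; the angle equation is the exact 2D reduction of the vector
# orientation dynamics with rotational white noise of intensity 2*Dr.

# Reflect positions into [0, L]; orientation is left unchanged (swimmers
# re-enter the bulk when their heading turns away from the wall).
reflect_into <- function(x, L) {
  # two reflections cover steps < 2 L, ample for any sane dt
  x <- abs(x)
  x <- ifelse(x > L, 2 * L - x, x)
  x <- abs(x)
  ifelse(x > L, 2 * L - x, x)
}

sim_precheck <- function(params, domain, n_cells, duration, dt) {
  stopifnot(inherits(params, "motility_params"), inherits(domain, "domain_spec"))
  if (!is.numeric(dt) || dt <= 0) stop_invalid("'dt' must be positive")
  if (!is.numeric(duration) || duration <= 0) stop_invalid("'duration' must be positive")
  if (n_cells < 1) stop_invalid("'n_cells' must be >= 1")
  if (params$tumble_rate > 0 && dt >= 1 / params$tumble_rate)
    stop_invalid("'dt' must be smaller than the mean run time 1/tumble_rate")
}

# Truncated-parabola steric repulsion: displacement rate f0 * (1 - d/(2r))^2
# along the separation direction within one cell diameter. O(n^2); intended
# for small ensembles and off by default.
steric_displacement <- function(x, z, radius, f0 = 50) {
  n <- length(x)
  dx <- outer(x, x, "-"); dz <- outer(z, z, "-")
  d <- sqrt(dx^2 + dz^2)
  cut <- 2 * radius
  w <- ifelse(d > 0 & d < cut, f0 * (1 - d / cut)^2 / pmax(d, 1e-9), 0)
  diag(w) <- 0
  list(vx = rowSums(w * dx), vz = rowSums(w * dz))
}

run_sim_core <- function(params, domain, n_cells, duration, dt, seed,
                         theta_dot = NULL, flow = NULL, steric = FALSE,
                         record_every = 1L) {
  n_steps <- ceiling(duration / dt)
  record_every <- max(1L, as.integer(record_every))
  u <- params$speed
  rate <- params$tumble_rate
  Dr <- params$rot_diffusion
  sed <- params$sediment_speed
  p_tumble <- if (rate > 0) 1 - exp(-rate * dt) else 0
  sig_rot <- sqrt(2 * Dr * dt)

  with_seed(seed, {
    x <- runif(n_cells, 0, domain$width)
    z <- runif(n_cells, 0, domain$height)
    theta <- runif(n_cells, -pi, pi)   # tilt from +z: p = (sin, cos)

    rec <- seq(0L, n_steps, by = record_every)
    n_rec <- length(rec)
    X <- matrix(NA_real_, n_cells, n_rec)
    Z <- matrix(NA_real_, n_cells, n_rec)
    TH <- matrix(NA_real_, n_cells, n_rec)
    X[, 1L] <- x; Z[, 1L] <- z; TH[, 1L] <- theta
    ri <- 1L

    for (k in seq_len(n_steps)) {
      px <- sin(theta); pz <- cos(theta)
      vx <- u * px; vz <- u * pz - sed
      om <- 0
      if (!is.null(flow)) {
        vx <- vx + flow$vx(x, z)
        vz <- vz + flow$vz(x, z)
        if (!is.null(flow$vorticity)) om <- flow$vorticity(x, z)
      }
      if (steric) {
        st <- steric_displacement(x, z, params$cell_radius)
        vx <- vx + st$vx; vz <- vz + st$vz
      }
      x <- reflect_into(x + vx * dt, domain$width)
      z <- reflect_into(z + vz * dt, domain$height)

      if (!is.null(theta_dot)) theta <- theta + theta_dot(theta, om) * dt
      if (Dr > 0) theta <- theta + sig_rot * rnorm(n_cells)
      if (p_tumble > 0) {
        tum <- runif(n_cells) < p_tumble
        if (any(tum)) theta[tum] <- runif(sum(tum), -pi, pi)
      }
      if (k %% record_every == 0L) {
        ri <- ri + 1L
        X[, ri] <- x; Z[, ri] <- z; TH[, ri] <- theta
      }
    }

    d <- data.frame(
      track_id = rep(seq_len(n_cells), each = n_rec),
      frame = rep(seq_len(n_rec) - 1L, n_cells),
      time_s = rep(rec * dt, n_cells),
      x_um = as.vector(t(X)), z_um = as.vector(t(Z)),
      px = sin(as.vector(t(TH))), pz = cos(as.vector(t(TH)))
    )
    trajectory_set(d, frame_interval = dt * record_every, domain = domain)
  })
}

#' Simulate run-and-tumble swimmers
#'
#' Ballistic runs at constant speed interrupted by Poisson-timed complete
#' reorientations (new heading uniform on the circle), optionally with
#' rotational diffusion between tumbles. The velocity autocorrelation of this
#' process decays exponentially with correlation time
#' `1 / (tumble_rate + rot_diffusion)`.
#'
#' @param params a [motility_params()].
#' @param domain a [domain_spec()]; walls reflect positions.
#' @param n_cells number of cells.
#' @param duration simulated time (s).
#' @param dt integration and recording step (s); must resolve the mean run
#'   time.
#' @param seed integer seed; identical seeds give identical output.
#' @param steric add short-range pairwise steric repulsion (truncated-parabola
#'   force within one cell diameter). Off by default.
#' @param record_every record every k-th integration step (thins the output
#'   while integrating at full resolution).
#' @return A [trajectory_set()] sampled every `dt * record_every`.
#' @examples
#' ts <- simulate_run_and_tumble(motility_params(46, tumble_rate = 1/15),
#'                               domain_spec(5000, 5000),
#'                               n_cells = 10, duration = 5, seed = 1)
#' @export
simulate_run_and_tumble <- function(params, domain, n_cells, duration,
                                    dt = 1 / 30, seed = NULL, steric = FALSE,
                                    record_every = 1L) {
  sim_precheck(params, domain, n_cells, duration, dt)
  run_sim_core(params, domain, n_cells, duration, dt, seed, steric = steric,
               record_every = record_every)
}

#' Simulate gyrotactic swimmers
#'
#' Swimmers whose heading relaxes toward the vertical on the gravitactic time
#' scale B and is rotated by the local flow vorticity: the tilt angle theta
#' (from +z) obeys `dtheta/dt = -sin(theta)/(2B) + omega/2` plus rotational
#' noise. In a uniform vorticity the stable equilibrium tilt satisfies
#' `sin(theta) = B * omega` (gyrotactic balance); for `|B * omega| > 1` the
#' cells tumble continuously. Positions are advanced with the swimming
#' velocity, the prescribed flow and passive sedimentation.
#'
#' @inheritParams simulate_run_and_tumble
#' @param flow `NULL` (quiescent fluid) or a list of vectorized functions
#'   `vx(x, z)`, `vz(x, z)` and optionally `vorticity(x, z)` (1/s), defined
#'   everywhere in the domain.
#' @return A [trajectory_set()].
#' @export
simulate_gyrotactic_swimmers <- function(params, domain, flow = NULL, n_cells,
                                         duration, dt = 1 / 30, seed = NULL,
                                         steric = FALSE, record_every = 1L) {
  sim_precheck(params, domain, n_cells, duration, dt)
  B <- params$reorientation_time
  if (is.na(B) || B <= 0)
    stop_invalid("gyrotactic simulation requires a positive reorientation_time B")
  if (!is.null(flow) && (!is.function(flow$vx) || !is.function(flow$vz)))
    stop_invalid("'flow' must provide vectorized functions vx(x, z) and vz(x, z)")
  theta_dot <- function(theta, om) -sin(theta) / (2 * B) + om / 2
  run_sim_core(params, domain, n_cells, duration, dt, seed,
               theta_dot = theta_dot, flow = flow, steric = steric,
               record_every = record_every)
}

#' Constant-vorticity prescribed flow
#'
#' Convenience wrapper: zero translational velocity with a uniform vorticity,
#' useful for probing the gyrotactic equilibrium tilt.
#'
#' @param omega vorticity (1/s).
#' @return A flow list usable by [simulate_gyrotactic_swimmers()].
#' @export
uniform_vorticity_flow <- function(omega) {
  list(vx = function(x, z) rep(0, length(x)),
       vz = function(x, z) rep(0, length(x)),
       vorticity = function(x, z) rep(omega, length(x)))
}
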