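# Nonlinear 2D bioconvection solver: stream-function--vorticity formulation
# with Boussinesq buoyancy, quasi-static gyrotactic swimming and conservative
# upwind cell transport.
#
# Dimensionless units (length h, time h^2/D, velocity D/h, density n0):
#   (1/Sc) D omega/Dt = lap omega + R dn/dx   ->  domega/dt =
#        -u.grad omega + Sc lap omega + Sc R dn/dx
#   dn/dt = -div( n (u + w p) - grad n ),  p = (G*omega clamped, sqrt(1-px^2))
#   lap psi = omega,  u = dpsi/dz, w_vel = -dpsi/dx
# Periodic laterally, no-slip top/bottom (wall vorticity treated implicitly
# through the psi-omega coupling), no-flux cell boundaries. Diffusion is
# integrated implicitly per lateral Fourier mode (backward Euler), advection
# and buoyancy explicitly (donor-cell upwind fluxes), which conserves the
# total cell number to machine precision and keeps n >= 0 under the CFL cap.

# per-mode z operators, cell-centered grid with nz cells
make_mode_ops <- function(nx, nz, Lx, dt, Sc) {
  dz <- 1 / nz
  kx <- 2 * pi / Lx * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1))
  k2 <- kx^2

  d2_dirichlet <- function() {
    m <- diag(-2, nz)
    for (j in seq_len(nz - 1)) { m[j, j + 1] <- 1; m[j + 1, j] <- 1 }
    m[1, 1] <- -3; m[nz, nz] <- -3          # ghost = -first (psi = 0 at wall)
    m / dz^2
  }
  d2_neumann <- function() {
    m <- diag(-2, nz)
    for (j in seq_len(nz - 1)) { m[j, j + 1] <- 1; m[j + 1, j] <- 1 }
    m[1, 1] <- -1; m[nz, nz] <- -1          # zero-flux walls
    m / dz^2
  }
  D2d <- d2_dirichlet(); D2n <- d2_neumann()
  I <- diag(nz)
  psi_inv <- vector("list", nx)
  om_inv <- vector("list", nx)
  n_inv <- vector("list", nx)
  for (m in seq_len(nx)) {
    Apsi <- D2d - k2[m] * I
    Pinv <- solve(Apsi)
    psi_inv[[m]] <- Pinv
    # omega diffusion with implicit Thom wall vorticity:
    # lap omega|_1 gains 16/dz^4 * psi_1, psi = Pinv omega
    Lom <- D2d - k2[m] * I
    Lom[1, ] <- Lom[1, ] + (16 / dz^4) * Pinv[1, ]
    Lom[nz, ] <- Lom[nz, ] + (16 / dz^4) * Pinv[nz, ]
    om_inv[[m]] <- solve(I - dt * Sc * Lom)
    n_inv[[m]] <- solve(I - dt * (D2n - k2[m] * I))
  }
  list(kx = kx, psi_inv = psi_inv, om_inv = om_inv, n_inv = n_inv, dz = dz)
}

# apply a list of per-mode nz x nz matrices to the x-spectrum of a field
apply_mode_ops <- function(field, ops_list) {
  fh <- mvfft(field)                 # columns = x-vectors per z: [mode, z]
  for (m in seq_len(nrow(fh))) fh[m, ] <- ops_list[[m]] %*% fh[m, ]
  Re(mvfft(fh, inverse = TRUE)) / nrow(fh)
}

ddx_periodic <- function(f, dx) {
  nx <- nrow(f)
  (f[c(2:nx, 1), ] - f[c(nx, 1:(nx - 1)), ]) / (2 * dx)
}

# conservative donor-cell divergence of the flux n * vel, periodic in x,
# zero-flux walls in z. velx/velz are cell-centered transport velocities.
upwind_div <- function(n, velx, velz, dx, dz) {
  nx <- nrow(n); nz <- ncol(n)
  # x faces between i and i+1 (periodic)
  vfx <- 0.5 * (velx + velx[c(2:nx, 1), ])
  Fx <- ifelse(vfx > 0, vfx * n, vfx * n[c(2:nx, 1), ])
  divx <- (Fx - Fx[c(nx, 1:(nx - 1)), ]) / dx
  # z faces between j and j+1 (interior only; wall faces carry zero flux)
  divz <- matrix(0, nx, nz)
  if (nz > 1) {
    vfz <- 0.5 * (velz[, -nz, drop = FALSE] + velz[, -1, drop = FALSE])
    Fz <- ifelse(vfz > 0, vfz * n[, -nz, drop = FALSE],
                 vfz * n[, -1, drop = FALSE])
    divz[, 1] <- Fz[, 1] / dz
    if (nz > 2) divz[, 2:(nz - 1)] <-
      (Fz[, 2:(nz - 1), drop = FALSE] - Fz[, 1:(nz - 2), drop = FALSE]) / dz
    divz[, nz] <- -Fz[, nz - 1] / dz
  }
  divx + divz
}

# discrete steady 1D profile of the upwind swim/diffusion balance, mean 1
discrete_base_profile <- function(w, nz) {
  dz <- 1 / nz
  prof <- cumprod(c(1, rep(1 + w * dz, nz - 1)))
  prof / mean(prof)
}

#' Simulate 2D bioconvection (nonlinear continuum model)
#'
#' Integrates the gyrotactic continuum system in a vertical slice: periodic
#' laterally, rigid no-slip top and bottom, no-flux cell boundaries. The
#' suspension starts from the discrete inverse-sedimentation steady state
#' plus a seeded perturbation; below the critical Rayleigh number the
#' perturbation decays, above it plumes develop in which cells accumulate in
#' downwelling regions (gyrotactic focusing).
#'
#' @param p a [suspension_params()] (B may be `NA`; gyrotactic drift is then
#'   omitted).
#' @param nx,nz lateral/vertical grid cells.
#' @param aspect lateral extent in units of the depth h.
#' @param duration simulated physical time (s).
#' @param dt time step in dimensionless units (`h^2/D`); `NULL` chooses a CFL
#'   cap automatically. The step is halved (and the implicit operators
#'   refactored) whenever the advective CFL number exceeds 0.9.
#' @param rayleigh optional override of the Rayleigh number from `p`.
#' @param perturbation `"random"` (seeded broadband noise) or `"mode"` (a
#'   single lateral Fourier mode, for comparisons with [linear_growth_rate()]).
#' @param mode_q lateral wavenumber (cycles/mm) of the seeded mode; rounded to
#'   the nearest harmonic of the box.
#' @param amplitude relative perturbation amplitude.
#' @param seed integer seed for the random perturbation.
#' @param n_snapshots number of stored field snapshots (evenly spaced).
#' @return An object of class `"fields2d"`: grids `x_um`, `z_um`, snapshot
#'   `times_s`, arrays `n` (relative density n/n0), `psi`, `vorticity`,
#'   `vx_um_s`, `vz_um_s`, and per-step `diagnostics` (time, total cells,
#'   min/max density, max speed, seeded-mode amplitude).
#' @export
simulate_bioconvection_2d <- function(p, nx = 64, nz = 64, aspect = 2,
                                      duration, dt = NULL, rayleigh = NULL,
                                      perturbation = c("random", "mode"),
                                      mode_q = NULL, amplitude = 1e-3,
                                      seed = NULL, n_snapshots = 6) {
  stopifnot(inherits(p, "suspension_params"))
  perturbation <- match.arg(perturbation)
  dn <- compute_dimensionless_numbers(p)
  R <- rayleigh %||% dn$rayleigh
  w <- dn$scaled_speed; Sc <- dn$schmidt
  G <- if (is.na(dn$gyrotactic)) 0 else dn$gyrotactic
  h_um <- p$depth * 1e3
  t_scale <- h_um^2 / p$cell_diffusion     # s per dimensionless time unit
  T_end <- duration / t_scale
  Lx <- aspect
  dx <- Lx / nx; dz <- 1 / nz
  if (is.null(dt)) dt <- min(2e-3, 0.3 * min(dx, dz) / (w + 1))

  ops <- make_mode_ops(nx, nz, Lx, dt, Sc)
  xc <- (seq_len(nx) - 0.5) * dx
  zc <- (seq_len(nz) - 0.5) * dz

  nfield <- matrix(rep(discrete_base_profile(w, nz), each = nx), nx, nz)
  mode_m <- NA_integer_
  with_seed(seed, {
    if (perturbation == "random") {
      eps <- matrix(rnorm(nx * nz), nx, nz)
      eps <- eps - mean(eps)
      nfield <- nfield * (1 + amplitude * eps)
    } else {
      if (is.null(mode_q)) stop_invalid("'mode_q' required for mode perturbation")
      Lx_mm <- Lx * h_um / 1000
      mode_m <- max(1L, as.integer(round(mode_q * Lx_mm)))
      shape <- outer(cos(2 * pi * mode_m * xc / Lx), sin(pi * zc))
      nfield <- nfield * (1 + amplitude * shape)
    }
  })
  total0 <- sum(nfield)
  omega <- matrix(0, nx, nz)

  n_steps <- max(2L, ceiling(T_end / dt))
  dt <- T_end / n_steps
  ops <- make_mode_ops(nx, nz, Lx, dt, Sc)

  snap_at <- unique(round(seq(1, n_steps, length.out = n_snapshots)))
  snaps <- list(); snap_t <- numeric(0)
  diag_rows <- vector("list", n_steps)

  mode_amp <- function(n) {
    if (is.na(mode_m)) return(NA_real_)
    mean(Mod(mvfft(n)[mode_m + 1L, ])) / (nx / 2)
  }

  step <- 1L
  t_now <- 0
  while (step <= n_steps) {
    psi <- apply_mode_ops(omega, ops$psi_inv)
    # velocities: u = dpsi/dz (ghost psi = -psi_1 at walls), w_vel = -dpsi/dx
    u <- matrix(0, nx, nz)
    u[, 2:(nz - 1)] <- (psi[, 3:nz] - psi[, 1:(nz - 2)]) / (2 * dz)
    u[, 1] <- (psi[, 2] + psi[, 1]) / (2 * dz)
    u[, nz] <- (-psi[, nz] - psi[, nz - 1]) / (2 * dz)
    wvel <- -ddx_periodic(psi, dx)

    px <- pmin(1, pmax(-1, G * omega))
    pz <- sqrt(pmax(0, 1 - px^2))

    vmax <- max(abs(u) + w, abs(wvel) + w, 1e-12)
    if (vmax * dt / min(dx, dz) > 0.9) {
      dt <- dt / 2
      n_steps <- step - 1L + ceiling((T_end - t_now) / dt)
      ops <- make_mode_ops(nx, nz, Lx, dt, Sc)
      snap_at <- unique(c(snap_at[snap_at < step],
                          round(seq(step, n_steps,
                                    length.out = max(1, sum(snap_at >= step))))))
      next
    }

    adv_n <- upwind_div(nfield, u + w * px, wvel + w * pz, dx, dz)
    adv_om <- upwind_div(omega, u, wvel, dx, dz)
    buoy <- Sc * R * ddx_periodic(nfield, dx)

    nfield <- apply_mode_ops(nfield - dt * adv_n, ops$n_inv)
    omega <- apply_mode_ops(omega + dt * (-adv_om + buoy), ops$om_inv)

    if (!all(is.finite(nfield)) || max(abs(nfield)) > 1e6)
      stop("bioconvection solver blew up at t = ", signif(t_now * t_scale, 4),
           " s; reduce dt or the grid spacing")

    t_now <- t_now + dt
    diag_rows[[step]] <- c(time_s = t_now * t_scale,
                           total_cells_rel = sum(nfield) / total0,
                           min_n = min(nfield), max_n = max(nfield),
                           max_speed_um_s = vmax * p$cell_diffusion / h_um,
                           mode_amplitude = mode_amp(nfield))
    if (step %in% snap_at) {
      snaps[[length(snaps) + 1L]] <-
        list(n = nfield, psi = psi, omega = omega, u = u, wvel = wvel)
      snap_t <- c(snap_t, t_now * t_scale)
    }
    step <- step + 1L
  }

  vel_scale <- p$cell_diffusion / h_um
  arr <- function(what) {
    a <- array(0, c(nx, nz, length(snaps)))
    for (i in seq_along(snaps)) a[, , i] <- snaps[[i]][[what]]
    a
  }
  diagnostics <- as.data.frame(do.call(rbind, diag_rows[!vapply(diag_rows, is.null, TRUE)]))
  structure(list(
    x_um = xc * h_um, z_um = zc * h_um, times_s = snap_t,
    n = arr("n"),
    psi = arr("psi") * p$cell_diffusion,
    vorticity = arr("omega") * p$cell_diffusion / h_um^2,
    vx_um_s = arr("u") * vel_scale,
    vz_um_s = arr("wvel") * vel_scale,
    diagnostics = diagnostics,
    params = list(R = R, w = w, G = G, Sc = Sc, mode_m = mode_m,
                  aspect = aspect, nx = nx, nz = nz, dt = dt,
                  t_scale_s = t_scale)
  ), class = "fields2d")
}

#' @export
print.fields2d <- function(x, ...) {
  cat(sprintf("2D bioconvection fields: %d x %d grid, %d snapshots, t <= %.4g s\n",
              length(x$x_um), length(x$z_um), length(x$times_s),
              max(x$diagnostics$time_s)))
  cat(sprintf("  R = %.4g, w = %.3g, G = %.3g, Sc = %.3g\n",
              x$params$R, x$params$w, x$params$G, x$params$Sc))
  invisible(x)
}

#' @export
plot.fields2d <- function(x, snapshot = dim(x$n)[3], ...) {
  image(x$x_um, x$z_um, x$n[, , snapshot],
        col = gray(seq(1, 0, length.out = 256)),
        xlab = "x (um)", ylab = "z (um)", useRaster = TRUE, ...)
  invisible(x)
}
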