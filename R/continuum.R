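# Gyrotactic continuum theory: dimensionless numbers, inverse-sedimentation
# base state, linear stability (normal modes about the exponential profile)
# and the critical Rayleigh number.
#
# Dimensionless convention: lengths scaled by the depth h, time by h^2/D,
# velocity by D/h, cell density by its column mean n0. The governing system
# in these units is
#   (1/Sc) (du/dt + u.grad u) = -grad p + lap u - R n e_z
#   dn/dt = -div( n u + w n p - grad n ),   p: quasi-static gyrotactic tilt
# with R = g phi dRho h^3 / (rho nu D), w = v h / D, G = B D / h^2,
# Sc = nu / D.

# Unit-agnostic Rayleigh number; caller must supply a coherent unit system
# (the result is invariant under coherent rescaling, e.g. m <-> um).
rayleigh_number <- function(g, phi, drho_rel, h, nu, D) {
  g * phi * drho_rel * h^3 / (nu * D)
}

#' Dimensionless numbers of a suspension
#'
#' Computes the bioconvective Rayleigh number
#' `R = g phi (dRho/rho) h^3 / (nu D)`, the scaled cell speed `w = v h / D`,
#' the gyrotactic number `G = B D / h^2` and the Schmidt number `Sc = nu / D`.
#' Units are made coherent internally (um/s). When the reorientation time B is
#' unknown, G is reported as `NA` and the other numbers are still computed.
#'
#' @param p a [suspension_params()].
#' @return An object of class `"dimensionless_numbers"` with fields
#'   `rayleigh`, `scaled_speed`, `gyrotactic`, `schmidt`.
#' @examples
#' p <- suspension_params(volume_fraction = 0.021, density_contrast = 0.05,
#'                        kinematic_viscosity = 1e-6, cell_diffusion = 1.6e4,
#'                        cell_speed = 46, depth = 1)
#' compute_dimensionless_numbers(p)  # R close to 640
#' @export
compute_dimensionless_numbers <- function(p) {
  stopifnot(inherits(p, "suspension_params"))
  g_um <- p$gravity * 1e6          # m/s^2  -> um/s^2
  nu_um <- p$kinematic_viscosity * 1e12  # m^2/s -> um^2/s
  h_um <- p$depth * 1e3            # mm    -> um
  R <- rayleigh_number(g_um, p$volume_fraction, p$density_contrast,
                       h_um, nu_um, p$cell_diffusion)
  w <- p$cell_speed * h_um / p$cell_diffusion
  G <- if (is.na(p$reorientation_time)) NA_real_ else
    p$reorientation_time * p$cell_diffusion / h_um^2
  Sc <- nu_um / p$cell_diffusion
  structure(list(rayleigh = R, scaled_speed = w, gyrotactic = G, schmidt = Sc),
            class = "dimensionless_numbers")
}

#' @export
print.dimensionless_numbers <- function(x, ...) {
  cat(sprintf("R = %.4g, w = %.4g, G = %s, Sc = %.4g\n", x$rayleigh,
              x$scaled_speed,
              if (is.na(x$gyrotactic)) "undefined (B unknown)"
              else format(x$gyrotactic, digits = 4), x$schmidt))
  invisible(x)
}

#' Critical-Rayleigh ratio implied by the quartic speed scaling
#'
#' For deep layers with no-slip walls and an inverted sedimentation base
#' state the critical Rayleigh number scales as the fourth power of the
#' scaled cell speed, so changing w from `w_low` to `w_high` changes Rc by
#' `(w_high / w_low)^4`.
#'
#' @param w_low,w_high scaled cell speeds (positive).
#' @return The ratio `Rc(w_high) / Rc(w_low)`.
#' @examples
#' critical_rayleigh_ratio(5.8, 11.5)  # about 15
#' @export
critical_rayleigh_ratio <- function(w_low, w_high) {
  check_positive(w_low, "w_low")
  check_positive(w_high, "w_high")
  (w_high / w_low)^4
}

#' Steady inverse-sedimentation profile
#'
#' The one-dimensional flux balance between up-swimming (flux `v n`) and
#' diffusion (`-D dn/dz`) gives `n(z)` proportional to `exp(v z / D)`: cells
#' accumulate at the top with decay length `D/v` toward deeper regions. The
#' discrete profile is normalized so its trapezoidal column mean equals the
#' mean density.
#'
#' @param p a [suspension_params()].
#' @param z vector of heights from the compartment bottom (um); default: a
#'   uniform 200-point grid over the depth.
#' @param n0 mean density used for normalization (default: `p$mean_density`,
#'   or 1 for a relative profile).
#' @return Data frame `z_um`, `density`, with attribute `decay_length_um`.
#' @export
steady_sedimentation_profile <- function(p, z = NULL, n0 = NULL) {
  stopifnot(inherits(p, "suspension_params"))
  h_um <- p$depth * 1e3
  z <- z %||% seq(0, h_um, length.out = 200)
  n0 <- n0 %||% (p$mean_density %||% 1)
  v <- p$cell_speed; D <- p$cell_diffusion
  if (v == 0) {
    prof <- rep(n0, length(z))
  } else {
    raw <- exp(v * (z - h_um) / D)    # shifted to avoid overflow at large w
    prof <- raw * n0 * (max(z) - min(z)) / trapz(z, raw)
  }
  out <- data.frame(z_um = z, density = prof)
  attr(out, "decay_length_um") <- if (v > 0) D / v else Inf
  out
}

# ---- linear stability --------------------------------------------------

# Dimensionless exponential base state on [0, 1], column mean 1.
base_state <- function(w, zh) {
  if (w == 0) return(rep(1, length(zh)))
  w * exp(w * (zh - 1)) / (1 - exp(-w))
}

# Build the generalized eigenproblem A x = sigma B x for normal modes
# e^{i k x + sigma t} about the exponential base state. Unknowns: W at
# interior nodes (clamped: W = W' = 0 at walls), N at all nodes (no-flux:
# N' = w N at walls). k is the radian horizontal wavenumber (units 1/h).
stability_matrices <- function(k, R, w, G, Sc, nz = 64) {
  M <- nz
  hm <- 1 / M
  zi <- (1:(M - 1)) * hm      # interior nodes (W)
  zn <- (0:M) * hm            # all nodes (N)
  nW <- M - 1; nN <- M + 1
  ns_i <- base_state(w, zi)
  ns_n <- base_state(w, zn)

  # second derivative on interior nodes, Dirichlet W=0 at walls
  L2 <- matrix(0, nW, nW)
  for (j in seq_len(nW)) {
    L2[j, j] <- -2
    if (j > 1) L2[j, j - 1] <- 1
    if (j < nW) L2[j, j + 1] <- 1
  }
  L2 <- L2 / hm^2
  # fourth derivative with clamped ghosts (W' = 0: W_{-1} = W_1)
  L4 <- matrix(0, nW, nW)
  for (j in seq_len(nW)) {
    st <- c(1, -4, 6, -4, 1)
    for (s in -2:2) {
      jj <- j + s
      if (jj >= 1 && jj <= nW) L4[j, jj] <- L4[j, jj] + st[s + 3]
    }
  }
  L4[1, 1] <- L4[1, 1] + 1          # ghost W_{-1} = W_1
  L4[nW, nW] <- L4[nW, nW] + 1      # ghost W_{M+1} = W_{M-1}
  L4 <- L4 / hm^4

  # (D^2 - k^2) acting on W, evaluated at ALL nodes (for the vorticity /
  # gyrotaxis source in the cell equation); boundary rows use the clamp
  # ghosts and W = 0 at the wall.
  D2W_all <- matrix(0, nN, nW)
  for (jn in seq_len(nN)) {
    j <- jn - 1L               # node index 0..M
    if (j == 0) {
      D2W_all[jn, 1] <- 2 / hm^2
    } else if (j == M) {
      D2W_all[jn, nW] <- 2 / hm^2
    } else {
      D2W_all[jn, j] <- -2 / hm^2 - k^2
      if (j - 1 >= 1) D2W_all[jn, j - 1] <- 1 / hm^2
      if (j + 1 <= nW) D2W_all[jn, j + 1] <- 1 / hm^2   # W = 0 at the wall
    }
  }

  # first/second derivative on N nodes with flux ghosts N' = w N
  DN <- matrix(0, nN, nN); D2N <- matrix(0, nN, nN)
  for (jn in seq_len(nN)) {
    j <- jn - 1L
    if (j == 0) {
      # ghost N_{-1} = N_1 - 2 hm w N_0
      DN[jn, jn] <- w
      D2N[jn, jn] <- (-2 - 2 * hm * w) / hm^2
      D2N[jn, jn + 1] <- 2 / hm^2
    } else if (j == M) {
      DN[jn, jn] <- w
      D2N[jn, jn] <- (-2 + 2 * hm * w) / hm^2
      D2N[jn, jn - 1] <- 2 / hm^2
    } else {
      DN[jn, jn - 1] <- -1 / (2 * hm); DN[jn, jn + 1] <- 1 / (2 * hm)
      D2N[jn, jn - 1] <- 1 / hm^2; D2N[jn, jn + 1] <- 1 / hm^2
      D2N[jn, jn] <- -2 / hm^2
    }
  }

  A <- matrix(0, nW + nN, nW + nN)
  B <- matrix(0, nW + nN, nW + nN)
  iW <- seq_len(nW); iN <- nW + seq_len(nN)

  # momentum: sigma (1/Sc)(D^2-k^2) W = (D^2-k^2)^2 W + R k^2 N  (interior)
  A[iW, iW] <- L4 - 2 * k^2 * L2 + k^4 * diag(nW)
  A[iW, iN] <- 0
  A[iW, nW + 1 + seq_len(nW)] <- R * k^2 * diag(nW)  # N at interior nodes
  B[iW, iW] <- (L2 - k^2 * diag(nW)) / Sc

  # cells: sigma N = -w ns W + w G ns (D^2-k^2)W - w N' + (D^2 - k^2) N
  AdvW <- matrix(0, nN, nW)
  AdvW[2:M, ] <- diag(-w * ns_i, nW)    # -W dns/dz, dns/dz = w ns; W=0 at walls
  Ggain <- if (is.na(G)) 0 else G
  A[iN, iW] <- AdvW + w * Ggain * (ns_n * D2W_all)
  A[iN, iN] <- -w * DN + D2N - k^2 * diag(nN)
  B[iN, iN] <- diag(nN)
  list(A = A, B = B, nW = nW, nN = nN)
}

#' Linear growth rate of a normal mode
#'
#' Linearizes the continuum system about the exponential inverse-sedimentation
#' base state with normal modes `exp(i q x + sigma t)` (quasi-static
#' gyrotactic orientation closure), discretized by second-order central
#' differences on a vertical grid with no-slip walls and no-flux cell
#' boundary conditions, and returns the eigenvalue of largest real part.
#'
#' @param q horizontal wavenumber in cycles/mm (the reciprocal of the pattern
#'   wavelength).
#' @param p a [suspension_params()] (B may be `NA`: gyrotaxis then drops from
#'   the perturbation equations).
#' @param nz number of vertical grid intervals.
#' @param rayleigh optional override of the Rayleigh number computed from `p`
#'   (used for stability scans).
#' @return Complex growth rate sigma in units of `D/h^2` (1/s after
#'   multiplying by `D/h^2`); attribute `"sigma_per_s"` carries the
#'   dimensional value.
#' @export
linear_growth_rate <- function(q, p, nz = 64, rayleigh = NULL) {
  stopifnot(inherits(p, "suspension_params"))
  dn <- compute_dimensionless_numbers(p)
  h_um <- p$depth * 1e3
  k <- 2 * pi * q / 1000 * h_um       # cycles/mm -> radian, scaled by h
  if (k <= 0) stop_invalid("'q' must be positive")
  R <- rayleigh %||% dn$rayleigh
  m <- stability_matrices(k, R, dn$scaled_speed, dn$gyrotactic, dn$schmidt, nz)
  sig <- max_growth_eigenvalue(m)
  attr(sig, "sigma_per_s") <- sig * p$cell_diffusion / h_um^2
  sig
}

max_growth_eigenvalue <- function(m) {
  # B is block diagonal: invert the W block, N block is the identity
  iW <- seq_len(m$nW); iN <- m$nW + seq_len(m$nN)
  T <- m$A
  T[iW, ] <- solve(m$B[iW, iW], m$A[iW, ])
  ev <- eigen(T, only.values = TRUE)$values
  ev[which.max(Re(ev))]
}

growth_at <- function(k, R, w, G, Sc, nz) {
  Re(max_growth_eigenvalue(stability_matrices(k, R, w, G, Sc, nz)))
}

# Find the R where Re sigma = 0 at fixed k, by bracketing + bisection.
critical_R_at_k <- function(k, w, G, Sc, nz, tol = 1e-3, R_max = 1e10) {
  f <- function(R) growth_at(k, R, w, G, Sc, nz)
  R_lo <- 0
  f_lo <- f(R_lo)
  if (f_lo >= 0) return(0)            # unstable even without buoyancy: degenerate
  R_hi <- 100
  while (f(R_hi) < 0) {
    R_lo <- R_hi
    R_hi <- R_hi * 8
    if (R_hi > R_max) return(Inf)     # stable in the scanned range
  }
  while ((R_hi - R_lo) > tol * R_hi) {
    Rm <- 0.5 * (R_lo + R_hi)
    if (f(Rm) < 0) R_lo <- Rm else R_hi <- Rm
  }
  0.5 * (R_lo + R_hi)
}

#' Critical Rayleigh number and critical wavenumber
#'
#' Minimizes over the horizontal wavenumber the Rayleigh number at which the
#' largest linear growth rate crosses zero (bisection in R at each q, then a
#' local refinement of the q grid around the minimum).
#'
#' @param p a [suspension_params()]; its Rayleigh number is ignored (only w,
#'   G, Sc matter).
#' @param q_range scanned wavenumber range (cycles/mm).
#' @param n_q number of (log-spaced) scan points.
#' @param nz vertical grid intervals.
#' @param tol relative bisection tolerance in R.
#' @return List with `Rc`, `q_critical_per_mm`, `lambda_critical_mm` and the
#'   scan table `scan` (`q`, `Rc_q`). If no instability exists in the scanned
#'   range, `stable = TRUE` and `Rc = Inf`.
#' @export
critical_rayleigh <- function(p, q_range = c(0.1, 20), n_q = 9, nz = 48,
                              tol = 1e-3) {
  stopifnot(inherits(p, "suspension_params"))
  dn <- compute_dimensionless_numbers(p)
  h_um <- p$depth * 1e3
  w <- dn$scaled_speed; G <- dn$gyrotactic; Sc <- dn$schmidt
  q_to_k <- function(q) 2 * pi * q / 1000 * h_um

  scan_q <- exp(seq(log(q_range[1]), log(q_range[2]), length.out = n_q))
  rc <- vapply(scan_q, function(q)
    critical_R_at_k(q_to_k(q), w, G, Sc, nz, tol = tol), 0)
  if (all(!is.finite(rc)))
    return(list(stable = TRUE, Rc = Inf, q_critical_per_mm = NA_real_,
                lambda_critical_mm = NA_real_,
                scan = data.frame(q = scan_q, Rc_q = rc)))
  i <- which.min(rc)
  # local refinement around the coarse minimum
  lo <- scan_q[max(1, i - 1)]; hi <- scan_q[min(length(scan_q), i + 1)]
  fine_q <- exp(seq(log(lo), log(hi), length.out = 7))
  rc_f <- vapply(fine_q, function(q)
    critical_R_at_k(q_to_k(q), w, G, Sc, nz, tol = tol), 0)
  j <- which.min(rc_f)
  list(stable = FALSE, Rc = rc_f[j], q_critical_per_mm = fine_q[j],
       lambda_critical_mm = 1 / fine_q[j],
       scan = data.frame(q = c(scan_q, fine_q), Rc_q = c(rc, rc_f)))
}
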