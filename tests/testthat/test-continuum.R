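test_that("dimensionless numbers evaluate the defining formulas", {
  p <- reference_suspension(v = 46, h = 1)
  dn <- compute_dimensionless_numbers(p)
  expect_equal(signif(dn$rayleigh, 2), 640)
  expect_equal(dn$schmidt, 62.5)
  expect_true(is.na(dn$gyrotactic))        # B unknown -> undefined marker
  p2 <- reference_suspension(v = 92, h = 2)
  expect_equal(compute_dimensionless_numbers(p2)$scaled_speed, 11.5)
  p3 <- reference_suspension(v = 46, h = 2)
  expect_equal(compute_dimensionless_numbers(p3)$scaled_speed, 5.75)
  # phi = 0 -> R = 0
  p0 <- suspension_params(volume_fraction = 0, density_contrast = 0.05,
                          kinematic_viscosity = 1e-6, cell_diffusion = 1.6e4,
                          cell_speed = 46, depth = 1)
  expect_equal(compute_dimensionless_numbers(p0)$rayleigh, 0)
  pB <- reference_suspension(v = 46, B = 3, h = 1)
  expect_equal(compute_dimensionless_numbers(pB)$gyrotactic, 3 * 1.6e4 / 1e6^1)
})

test_that("the Rayleigh number is invariant under coherent unit rescaling", {
  rn <- bioconvect:::rayleigh_number
  # SI (m) vs micrometre unit systems
  R_m <- rn(9.8, 0.021, 0.05, 1e-3, 1e-6, 1.6e4 * 1e-12)
  R_um <- rn(9.8e6, 0.021, 0.05, 1e3, 1e6, 1.6e4)
  expect_equal(R_m, R_um, tolerance = 1e-12)
})

test_that("inconsistent phi vs n0 * vc is rejected", {
  expect_error(suspension_params(volume_fraction = 0.021,
                                 density_contrast = 0.05,
                                 kinematic_viscosity = 1e-6,
                                 cell_diffusion = 1.6e4, cell_speed = 46,
                                 depth = 1, cell_volume = 270,
                                 mean_density = 8e7), "inconsistent")
  p <- suspension_params(density_contrast = 0.05, kinematic_viscosity = 1e-6,
                         cell_diffusion = 1.6e4, cell_speed = 46, depth = 1,
                         cell_volume = 262.5, mean_density = 8e7)
  expect_equal(p$volume_fraction, 0.021)
})

test_that("the quartic critical-ratio arithmetic and its edge cases hold", {
  expect_equal(critical_rayleigh_ratio(5.8, 11.5), (11.5 / 5.8)^4)
  expect_equal(round(critical_rayleigh_ratio(5.8, 11.5)), 15)
  expect_equal(critical_rayleigh_ratio(3.3, 3.3), 1)
  expect_equal(critical_rayleigh_ratio(1, 2), 16)
  expect_error(critical_rayleigh_ratio(0, 2), "w_low")
})

test_that("the steady sedimentation profile has the right decay and mass", {
  p <- reference_suspension(v = 46, h = 1)
  prof <- steady_sedimentation_profile(p, n0 = 5)
  expect_equal(attr(prof, "decay_length_um"), 1.6e4 / 46, tolerance = 1e-12)
  expect_equal(attr(prof, "decay_length_um"), 347.8, tolerance = 1e-3)
  # discrete column mean equals n0 to 1e-9 relative
  total <- bioconvect:::trapz(prof$z_um, prof$density)
  expect_lt(abs(total - 5 * 1000) / (5 * 1000), 1e-9)
  # local decay matches exp(v z / D) exactly
  lr <- diff(log(prof$density)) / diff(prof$z_um)
  expect_equal(unname(lr[1]), 46 / 1.6e4, tolerance = 1e-9)
  # v -> 0 limit: uniform at n0
  p0 <- reference_suspension(v = 0, h = 1)
  prof0 <- steady_sedimentation_profile(p0, n0 = 3)
  expect_true(all(prof0$density == 3))
})

test_that("without buoyancy every normal mode decays", {
  p <- reference_suspension(v = 46, B = 3, h = 2)
  for (q in c(0.2, 0.7, 2, 5))
    expect_lt(Re(linear_growth_rate(q, p, rayleigh = 0)), 0)
})

test_that("the growth rate crosses zero exactly once as R increases", {
  p <- reference_suspension(v = 46, B = 3, h = 2)
  Rs <- c(10, 50, 150, 300, 500, 800, 1500, 4000, 1e4, 1e5)
  gr <- vapply(Rs, function(R) Re(linear_growth_rate(0.5, p, rayleigh = R)), 0)
  signs <- sign(gr)
  expect_equal(sum(diff(signs) != 0), 1)   # single crossing
  expect_lt(gr[1], 0)
  expect_gt(gr[length(gr)], 0)
})

test_that("the w -> 0 limit recovers fixed-flux Rayleigh-Benard onset", {
  # no-flux cell boundaries make the analogue of insulating walls, whose
  # rigid-rigid critical Rayleigh number is ~720 with qc -> 0
  p <- reference_suspension(v = 0.8, B = NA, h = 2)       # w = 0.1
  cr <- critical_rayleigh(p, q_range = c(0.02, 0.5), n_q = 7, nz = 64)
  w <- compute_dimensionless_numbers(p)$scaled_speed
  expect_equal(cr$Rc * w, 720, tolerance = 0.03)
  expect_lt(cr$q_critical_per_mm, 0.06)
})

test_that("critical Rayleigh results are self-consistent and monotone in w", {
  rcs <- vapply(c(46, 92, 184), function(v) {
    p <- reference_suspension(v = v, B = 3, h = 2)
    cr <- critical_rayleigh(p, nz = 48)
    # marginal mode: growth at (qc, Rc) vanishes within bisection tolerance
    g <- Re(linear_growth_rate(cr$q_critical_per_mm, p, nz = 48,
                               rayleigh = cr$Rc))
    gscale <- abs(Re(linear_growth_rate(cr$q_critical_per_mm, p, nz = 48,
                                        rayleigh = 2 * cr$Rc)))
    expect_lt(abs(g), 0.05 * gscale)
    cr$Rc
  }, 0)
  expect_true(all(diff(rcs) > 0))          # Rc grows with w for w > 1
})

test_that("the nonlinear solver conserves cells and matches linear theory", {
  p <- reference_suspension(v = 46, B = 3, h = 2)
  # subcritical: seeded mode decays monotonically after a transient
  f <- simulate_bioconvection_2d(p, nx = 32, nz = 32, duration = 40,
                                 rayleigh = 200, perturbation = "mode",
                                 mode_q = 0.5, seed = 1)
  d <- f$diagnostics
  expect_lt(max(abs(d$total_cells_rel - 1)), 1e-6)
  n <- nrow(d)
  amp <- d$mode_amplitude
  expect_lt(amp[n], amp[ceiling(n / 4)])
  expect_true(all(diff(amp[ceiling(n / 4):n]) <= 1e-12))
  expect_true(all(d$min_n >= 0))
})

test_that("plumes at 5 Rc couple density to downwelling flow", {
  p <- reference_suspension(v = 46, B = 3, h = 2)
  f <- simulate_bioconvection_2d(p, nx = 48, nz = 48, duration = 120,
                                 rayleigh = 2500, perturbation = "random",
                                 amplitude = 0.01, seed = 2)
  k <- dim(f$n)[3]
  expect_lt(cor(as.vector(f$vz_um_s[, , k]), as.vector(f$n[, , k])), -0.3)
  expect_lt(max(abs(f$diagnostics$total_cells_rel - 1)), 1e-6)
})

test_that("linear growth-rate signs predict nonlinear mode fate", {
  p <- reference_suspension(v = 46, B = 3, h = 2)
  cases <- list(list(R = 200, q = 0.5), list(R = 1500, q = 0.5),
                list(R = 150, q = 1), list(R = 5000, q = 1))
  for (cs in cases) {
    sig <- Re(linear_growth_rate(cs$q, p, rayleigh = cs$R))
    f <- simulate_bioconvection_2d(p, nx = 32, nz = 32, duration = 25,
                                   rayleigh = cs$R, perturbation = "mode",
                                   mode_q = cs$q, seed = 3)
    amp <- f$diagnostics$mode_amplitude
    n <- length(amp)
    grew <- amp[n] > amp[ceiling(n / 3)]
    expect_equal(grew, sig > 0,
                 label = sprintf("R=%g q=%g: sigma=%.3g grew=%s",
                                 cs$R, cs$q, sig, grew))
  }
})

test_that("the unstable mode at the 3D conditions is millimetre scale", {
  # R ~ 640 at h = 1 mm: the fastest-growing wavelength lands near the
  # observed millimetre scale
  p <- reference_suspension(v = 46, B = 3, h = 1)
  qs <- exp(seq(log(0.2), log(4), length.out = 20))
  g <- vapply(qs, function(q) Re(linear_growth_rate(q, p, nz = 48)), 0)
  expect_gt(max(g), 0)                     # unstable at R = 640
  lam <- 1 / qs[which.max(g)]
  expect_gt(lam, 0.5); expect_lt(lam, 3)   # mm
})
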