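test_that("parameter validation rejects unusable inputs", {
  mp <- motility_params(46, tumble_rate = 1 / 15)
  dom <- domain_spec(1000, 1000)
  expect_error(simulate_run_and_tumble(mp, dom, 1, duration = -1, seed = 1),
               "duration")
  expect_error(simulate_run_and_tumble(mp, dom, 1, duration = 1, dt = 0),
               "dt")
  expect_error(simulate_run_and_tumble(mp, dom, 1, duration = 1, dt = 20),
               "run time")
  expect_error(motility_params(-5), "speed")
  expect_error(domain_spec(0, 10), "width")
})

test_that("a non-tumbling noiseless swimmer moves in a straight line at speed u", {
  ts <- simulate_run_and_tumble(motility_params(50), domain_spec(20000, 20000),
                                n_cells = 1, duration = 10, dt = 1 / 30,
                                seed = 1)
  d <- ts$data
  # per-step displacement is exactly u * dt
  step <- sqrt(diff(d$x_um)^2 + diff(d$z_um)^2) / (1 / 30)
  expect_true(all(abs(step - 50) < 1e-9))
  # total path is a straight 500 um segment
  len <- sqrt((d$x_um[nrow(d)] - d$x_um[1])^2 + (d$z_um[nrow(d)] - d$z_um[1])^2)
  expect_equal(len, 500, tolerance = 1e-9)
})

test_that("identical seeds give bitwise-identical trajectories", {
  mp <- motility_params(46, tumble_rate = 1 / 15, rot_diffusion = 0.05)
  dom <- domain_spec(3000, 3000)
  a <- simulate_run_and_tumble(mp, dom, 20, 5, seed = 99)
  b <- simulate_run_and_tumble(mp, dom, 20, 5, seed = 99)
  expect_identical(a$data, b$data)
  c <- simulate_run_and_tumble(mp, dom, 20, 5, seed = 100)
  expect_false(identical(a$data, c$data))
})

test_that("orientations stay exactly on the unit circle", {
  mp <- motility_params(46, tumble_rate = 0.2, rot_diffusion = 0.3,
                        reorientation_time = 2)
  ts <- simulate_gyrotactic_swimmers(mp, domain_spec(2000, 2000),
                                     n_cells = 30, duration = 5, seed = 3)
  expect_true(all(abs(ts$data$px^2 + ts$data$pz^2 - 1) < 1e-9))
})

test_that("gravitaxis drives a horizontal swimmer to the vertical fixed point", {
  B <- 2
  mp <- motility_params(speed = 0, reorientation_time = B)
  ts <- simulate_gyrotactic_swimmers(mp, domain_spec(1000, 1000),
                                     n_cells = 5, duration = 30 * B,
                                     dt = 0.01, seed = 1)
  final <- ts$data[ts$data$frame == max(ts$data$frame), ]
  expect_true(all(abs(final$px) < 1e-6))
  at20B <- ts$data[abs(ts$data$time_s - 20 * B) < 0.005, ]
  expect_true(all(abs(at20B$px) < 1e-3))
})

test_that("uniform vorticity tilts swimmers to sin(theta) = B*omega", {
  B <- 2; omega <- 0.3    # B*omega = 0.6
  mp <- motility_params(speed = 0, reorientation_time = B)
  ts <- simulate_gyrotactic_swimmers(mp, domain_spec(1000, 1000),
                                     flow = uniform_vorticity_flow(omega),
                                     n_cells = 8, duration = 60, dt = 0.005,
                                     seed = 2)
  final <- ts$data[ts$data$frame == max(ts$data$frame), ]
  expect_equal(final$px, rep(0.6, 8), tolerance = 1e-4)
})

test_that("B*omega > 1 produces tumbling, not an error", {
  mp <- motility_params(speed = 0, reorientation_time = 2)
  ts <- simulate_gyrotactic_swimmers(mp, domain_spec(1000, 1000),
                                     flow = uniform_vorticity_flow(2),
                                     n_cells = 3, duration = 20, dt = 0.005,
                                     seed = 2)
  # tilt angle keeps advancing: orientation never settles
  d <- ts$data[ts$data$track_id == 1, ]
  expect_gt(diff(range(d$px)), 1)
})

test_that("gravitactic drift against diffusion builds an exponential profile", {
  # weak-bias swimmer engineered for drift 20 um/s and D ~ 1.6e4 um^2/s:
  # decay length D/v ~ 800 um in a closed 2 mm column
  u <- 80; Dr <- 0.2
  kappa_target <- function(B) u * besselI(1 / (2 * B * Dr), 1) /
    besselI(1 / (2 * B * Dr), 0) - 20
  B <- uniroot(kappa_target, c(0.5, 50))$root
  mp <- motility_params(speed = u, rot_diffusion = Dr, reorientation_time = B)
  ts <- simulate_gyrotactic_swimmers(mp, domain_spec(500, 2000),
                                     n_cells = 700, duration = 450, dt = 0.05,
                                     seed = 3, record_every = 20L)
  d <- ts$data[ts$data$time_s > 250, ]
  h <- hist(d$z_um, breaks = seq(0, 2000, by = 100), plot = FALSE)
  # fit away from the walls (one persistence length u/Dr = 400 um)
  sel <- h$mids > 400 & h$mids < 1600
  slope <- coef(lm(log(h$counts[sel]) ~ h$mids[sel]))[2]
  expect_equal(unname(1 / slope), 800, tolerance = 0.15)
})

test_that("steric repulsion pushes overlapping cells apart", {
  mp <- motility_params(speed = 0, cell_radius = 5)
  dom <- domain_spec(200, 200)
  # two cells closer than one diameter: distance must grow under repulsion
  ts <- with_two_cells <- local({
    set.seed(1)
    st <- bioconvect:::steric_displacement(c(100, 104), c(100, 100), radius = 5)
    st
  })
  expect_lt(ts$vx[1], 0)   # left cell pushed further left
  expect_gt(ts$vx[2], 0)
})
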