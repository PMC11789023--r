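test_that("circular Hough detection finds rendered cells accurately", {
  set.seed(5)
  n <- 200; ncell <- 25
  centers <- cbind(runif(ncell, 15, n - 15), runif(ncell, 15, n - 15))
  # enforce separation so ground truth is unambiguous
  keep <- rep(TRUE, ncell)
  for (i in 2:ncell)
    if (min(sqrt(colSums((t(centers[1:(i - 1), , drop = FALSE]) - centers[i, ])^2))) < 12)
      keep[i] <- FALSE
  centers <- centers[keep, , drop = FALSE]
  img <- disk_frame(centers, n = n, radius = 4)
  det <- detect_cells(img, pixel_size = 1, radius_range = c(2.6, 5.5))
  d <- det$frames[[1]]
  err <- vapply(seq_len(nrow(centers)), function(k)
    min(sqrt((d$x_um - (centers[k, 1] - 0.5))^2 +
             (d$y_um - (centers[k, 2] - 0.5))^2)), 0)
  expect_gte(mean(err < 1), 0.98)           # recall at 1 px
  expect_lt(max(err), 1)                    # localization
  expect_lte(nrow(d), nrow(centers) + 1)    # essentially no false positives
})

test_that("blank frames and tight pairs behave as specified", {
  blank <- detect_cells(matrix(7, 64, 64), pixel_size = 1)
  expect_equal(nrow(blank$frames[[1]]), 0)
  pair <- disk_frame(rbind(c(24, 32), c(36, 32)), n = 64, radius = 4)
  d <- detect_cells(pair, pixel_size = 1, radius_range = c(2.6, 5.5))$frames[[1]]
  expect_equal(nrow(d), 2)
  expect_error(detect_cells(matrix(0, 8, 8), pixel_size = 10,
                            radius_range = c(2.6, 5.5)), "1 pixel")
})

test_that("the assignment solver matches brute-force enumeration", {
  set.seed(2)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    a <- bioconvect:::assign_min_cost(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), brute_force_assignment(cost),
                 tolerance = 1e-12)
  }
})

test_that("linking respects the displacement gate", {
  # slow cell: one unbroken track
  fr <- lapply(0:49, function(k) data.frame(x_um = 10 + 2 * k, y_um = 25,
                                            score = 1))
  ts <- link_trajectories(detection_set(fr, 1), max_disp = 7,
                          frame_interval = 1 / 30)
  expect_equal(length(unique(ts$data$track_id)), 1)
  expect_equal(nrow(ts$data), 50)
  # 10 um jumps exceed the 7 um gate: the track fragments every frame
  fr2 <- lapply(0:9, function(k) data.frame(x_um = 10 + 10 * k, y_um = 10,
                                            score = 1))
  ts2 <- link_trajectories(detection_set(fr2, 1), max_disp = 7,
                           frame_interval = 1 / 30)
  expect_equal(length(unique(ts2$data$track_id)), 10)
})

test_that("parallel neighbours never swap identities", {
  fr <- lapply(0:99, function(k)
    data.frame(x_um = c(10 + 0.2 * k, 10 + 0.2 * k), y_um = c(10, 30),
               score = 1))
  ts <- link_trajectories(detection_set(fr, 1), max_disp = 7,
                          frame_interval = 1 / 30)
  expect_equal(length(unique(ts$data$track_id)), 2)
  expect_true(all(tapply(ts$data$z_um, ts$data$track_id, sd) == 0))
  # no detection appears in two tracks
  expect_false(any(duplicated(ts$data[, c("frame", "x_um", "z_um")])))
})

test_that("the VACF of a straight constant-speed track is flat at s^2", {
  s <- 30; dt <- 1 / 30
  d <- data.frame(track_id = 1, frame = 0:89, time_s = (0:89) * dt,
                  x_um = (0:89) * s * dt * 0.6, z_um = (0:89) * s * dt * 0.8)
  cv <- velocity_autocorrelation(trajectory_set(d, dt), max_lag = 2)
  expect_true(all(abs(cv$cv_um2_s2 - s^2) < 1e-9))
})

test_that("Cv(0) equals the mean squared speed estimator exactly", {
  ts <- simulate_run_and_tumble(motility_params(46, tumble_rate = 1 / 15),
                                domain_spec(20000, 20000), 40, 10, seed = 6)
  cv <- velocity_autocorrelation(ts, max_lag = 5)
  d <- ts$data
  v2 <- unlist(lapply(split(d, d$track_id), function(tr)
    (diff(tr$x_um)^2 + diff(tr$z_um)^2) / (1 / 30)^2))
  expect_equal(cv$cv_um2_s2[1], mean(v2), tolerance = 1e-12)
})

test_that("destroying temporal order destroys the correlation", {
  ts <- simulate_run_and_tumble(motility_params(46, tumble_rate = 1 / 2),
                                domain_spec(50000, 50000), 150, 20, seed = 8)
  cv <- velocity_autocorrelation(ts, max_lag = 10)
  d <- ts$data
  set.seed(1)
  perm <- sample(unique(d$frame))
  d$x_um <- d$x_um[order(d$track_id, match(d$frame, perm))]
  d$z_um <- d$z_um[order(d$track_id, match(d$frame, perm))]
  cvs <- velocity_autocorrelation(trajectory_set(d, ts$frame_interval),
                                  max_lag = 10)
  late <- cvs$cv_um2_s2[cvs$lag_s > 0.5]
  # the intact process retains ~80% correlation at these lags; the shuffled
  # one is noise around zero
  expect_lt(max(abs(late)) / cvs$cv_um2_s2[1], 0.2)
  expect_lt(abs(mean(late)) / cvs$cv_um2_s2[1], 0.02)
})

test_that("motility fits reproduce the closed-form diffusion constants", {
  lag <- seq(0, 120, by = 1 / 30)
  cv <- data.frame(lag_s = lag, cv_um2_s2 = 46^2 * exp(-lag / 15))
  fit <- fit_motility(cv)
  expect_equal(fit$v_um_s, 46, tolerance = 1e-6)
  expect_equal(fit$tau_c_s, 15, tolerance = 1e-6)
  expect_equal(fit$diffusion_um2_s, 1.587e4, tolerance = 1e-3)
  expect_equal(signif(fit$diffusion_um2_s, 2), 1.6e4)
  # Green-Kubo quadrature agrees with v^2 tau / 2 within 1%
  expect_lt(abs(fit$diffusion_integral_um2_s - fit$diffusion_um2_s) /
            fit$diffusion_um2_s, 0.01)
  expect_false(fit$flagged)
  # aerobic parameter set
  cv2 <- data.frame(lag_s = lag, cv_um2_s2 = 92^2 * exp(-lag / 2.4))
  expect_equal(fit_motility(cv2)$diffusion_um2_s, 1.016e4, tolerance = 1e-3)
  # non-decaying correlation yields a bounded-below marker
  cv3 <- data.frame(lag_s = seq(0, 5, by = 0.1),
                    cv_um2_s2 = rep(100, 51))
  f3 <- fit_motility(cv3)
  expect_true(is.na(f3$tau_c_s))
  expect_equal(f3$tau_lower_bound_s, 5)
})

test_that("motility estimates are invariant under translation, linear in scale", {
  ts <- simulate_run_and_tumble(motility_params(50, tumble_rate = 1 / 4),
                                domain_spec(50000, 50000), 120, 25, seed = 9)
  f0 <- fit_motility(velocity_autocorrelation(ts, max_lag = 12))
  d <- ts$data
  d$x_um <- d$x_um + 500; d$z_um <- d$z_um - 200
  f1 <- fit_motility(velocity_autocorrelation(
    trajectory_set(d, ts$frame_interval), max_lag = 12))
  expect_equal(f1$v_um_s, f0$v_um_s, tolerance = 1e-8)
  expect_equal(f1$tau_c_s, f0$tau_c_s, tolerance = 1e-8)
  d2 <- ts$data
  d2$x_um <- 2 * d2$x_um; d2$z_um <- 2 * d2$z_um
  f2 <- fit_motility(velocity_autocorrelation(
    trajectory_set(d2, ts$frame_interval), max_lag = 12))
  expect_equal(f2$v_um_s, 2 * f0$v_um_s, tolerance = 1e-9)
})

test_that("parameter recovery bias is small across a 3x3 (u, tau) grid", {
  us <- c(30, 46, 92); taus <- c(2.4, 8, 15)
  for (u in us) for (tau in taus) {
    ts <- simulate_run_and_tumble(motility_params(u, tumble_rate = 1 / tau),
                                  domain_spec(40000, 40000), 350, 45,
                                  seed = round(u * 100 + tau))
    fit <- fit_motility(velocity_autocorrelation(ts, max_lag = min(3 * tau, 30)))
    expect_lt(abs(fit$v_um_s - u) / u, 0.05)
    expect_lt(abs(fit$tau_c_s - tau) / tau, 0.15)
  }
})
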