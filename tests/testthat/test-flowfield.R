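test_that("CLAHE is deterministic and near-identity on equalized frames", {
  ramp <- matrix(rep(seq(0, 255, length.out = 256), each = 256), 256, 256)
  g <- suppressWarnings(clahe_preprocess(ramp, pixel_size = 100,
                                         tile_size = 30000))
  expect_lt(max(abs(g - ramp)) / 255, 0.02)
  set.seed(1)
  noisy <- matrix(runif(128 * 128, 0, 255), 128, 128)
  expect_identical(clahe_preprocess(noisy, 100, 3200),
                   clahe_preprocess(noisy, 100, 3200))
  expect_error(clahe_preprocess(noisy, pixel_size = 100, tile_size = 500),
               "8 px")
})

test_that("CLAHE expands the dynamic range of low-contrast plume images", {
  set.seed(2)
  lc <- matrix(110 + 30 * sin(outer(1:256, 1:256, "+") / 25) +
                 rnorm(256 * 256, 0, 2), 256, 256)
  out <- clahe_preprocess(pmax(lc, 0), pixel_size = 100, tile_size = 6400,
                          limit = 16)
  expect_gte(diff(range(out)) / 255, 0.9)
  # default clip limit still enhances, more conservatively
  out2 <- clahe_preprocess(pmax(lc, 0), pixel_size = 100, tile_size = 6400)
  expect_gt(diff(range(out2)), diff(range(lc)))
})

test_that("PIV recovers a uniform subpixel shift", {
  img <- speckle_image()
  imgB <- fourier_shift(img, 3.0, -1.5)
  vf <- piv_flow_field(img, imgB, pixel_size = 10, dt = 1,
                       windows = c(0.64, 0.48, 0.32),
                       steps = c(0.32, 0.24, 0.16))
  v <- vf$vectors[vf$vectors$valid, ]
  expect_gt(nrow(v), 0.9 * nrow(vf$vectors))
  dx <- v$vx_um_s / 10; dz <- v$vz_um_s / 10
  expect_lt(abs(mean(dx) - 3.0), 0.1)
  expect_lt(abs(mean(dz) + 1.5), 0.1)
  expect_lt(median(abs(dx - 3.0)), 0.1)
  expect_lt(median(abs(dz + 1.5)), 0.1)
})

test_that("identical frames give an identically zero field", {
  img <- speckle_image(n = 128, n_part = 800)
  vf <- piv_flow_field(img, img, pixel_size = 10, dt = 1,
                       windows = c(0.64, 0.32), steps = c(0.32, 0.16))
  expect_lt(max(abs(vf$vectors$vx_um_s)), 1e-9)
  expect_lt(max(abs(vf$vectors$vz_um_s)), 1e-9)
})

test_that("rotating the image pair rotates the recovered field", {
  img <- speckle_image(n = 192, n_part = 1800, seed = 6)
  imgB <- fourier_shift(img, 2.0, 1.0)
  rot90 <- function(m) t(m)[ncol(m):1, ]   # (x, z) -> (-z, x)
  vf <- piv_flow_field(img, imgB, pixel_size = 10, dt = 1,
                       windows = c(0.64, 0.32), steps = c(0.32, 0.16))
  vr <- piv_flow_field(rot90(img), rot90(imgB), pixel_size = 10, dt = 1,
                       windows = c(0.64, 0.32), steps = c(0.32, 0.16))
  m <- colMeans(vf$vectors[vf$vectors$valid, c("vx_um_s", "vz_um_s")])
  mr <- colMeans(vr$vectors[vr$vectors$valid, c("vx_um_s", "vz_um_s")])
  expect_lt(abs(mr[["vx_um_s"]] - (-m[["vz_um_s"]])), 1)   # 0.1 px at dt=1
  expect_lt(abs(mr[["vz_um_s"]] - m[["vx_um_s"]]), 1)
})

test_that("PIV tracks a smooth nonuniform displacement field", {
  img <- speckle_image(n = 256, n_part = 4000, seed = 11)
  nx <- 256
  # sinusoidal x-displacement, amplitude 2 px, wavelength = frame width
  ux_true <- function(x) 2 * sin(2 * pi * x / nx)
  warped <- matrix(0, nx, nx)
  xi <- (1:nx)
  for (j in 1:nx) {
    src <- xi - ux_true(xi)
    i0 <- floor(src); tfrac <- src - i0
    i0 <- ((i0 - 1) %% nx) + 1; i1 <- (i0 %% nx) + 1
    warped[, j] <- (1 - tfrac) * img[i0, j] + tfrac * img[i1, j]
  }
  vf <- piv_flow_field(img, warped, pixel_size = 10, dt = 1,
                       windows = c(0.64, 0.48, 0.32),
                       steps = c(0.32, 0.24, 0.16))
  v <- vf$vectors[vf$vectors$valid, ]
  err <- v$vx_um_s / 10 - ux_true(v$x_um / 10)
  rms_field <- sqrt(mean((ux_true(v$x_um / 10))^2))
  expect_lt(mean(abs(err)), 0.1 * rms_field)
})

test_that("the coupling curve reproduces a constructed linear relation", {
  set.seed(7)
  nx <- 40; nz <- 40; ps <- 10
  dens_vals <- matrix(runif(nx * nz, -2, 2), nx, nz)
  map <- structure(list(values = dens_vals,
                        mask = matrix(TRUE, nx, nz), frame_index = 1L),
                   class = "relative_density_map")
  kslope <- 4
  centers_x <- rep((1:nx) * ps - ps / 2, times = nz)
  centers_z <- rep((1:nz) * ps - ps / 2, each = nx)
  vf <- structure(list(vectors = data.frame(
    x_um = centers_x, z_um = centers_z,
    vx_um_s = 0, vz_um_s = -kslope * as.vector(dens_vals),
    quality = 1, valid = TRUE),
    grid_x = 1:nx, grid_z = 1:nz, pixel_size = ps, dt = 1),
    class = "velocity_field")
  cc <- vz_density_coupling(vf, map, pixel_size = ps, bin_width = 0.25)
  fit <- lm(mean_vz ~ bin_center, data = cc, weights = cc$n)
  expect_lt(abs(unname(coef(fit)[2]) + kslope) / kslope, 0.02)
  # constant vz -> flat curve
  vf2 <- vf; vf2$vectors$vz_um_s <- 5
  cc2 <- vz_density_coupling(vf2, map, pixel_size = ps, bin_width = 0.25)
  expect_true(all(abs(cc2$mean_vz - 5) < 1e-12))
  # frame-order permutation invariance of the pooled curve
  cc3 <- vz_density_coupling(list(vf2, vf), list(map, map), pixel_size = ps,
                             bin_width = 0.25)
  cc4 <- vz_density_coupling(list(vf, vf2), list(map, map), pixel_size = ps,
                             bin_width = 0.25)
  expect_equal(cc3$mean_vz, cc4$mean_vz, tolerance = 1e-12)
  expect_equal(sum(cc$n), sum(vf$vectors$valid))
})
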