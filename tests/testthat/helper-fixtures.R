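# Shared fixtures, all generated in code.

reference_suspension <- function(v = 46, B = NA_real_, h = 1) {
  suspension_params(volume_fraction = 0.021, density_contrast = 0.05,
                    kinematic_viscosity = 1e-6, cell_diffusion = 1.6e4,
                    cell_speed = v, reorientation_time = B, depth = h)
}

# dense speckle image for PIV (continuous suspensions give speckle-like
# transmitted-light texture at the pixel scale)
speckle_image <- function(n = 256, n_part = 3000, sigma = 1.2, seed = 4,
                          background = 10, amplitude = 60) {
  set.seed(seed)
  img <- matrix(background, n, n)
  xs <- runif(n_part, 8, n - 8); zs <- runif(n_part, 8, n - 8)
  for (k in seq_len(n_part)) {
    ii <- round(xs[k]) + (-3:3); jj <- round(zs[k]) + (-3:3)
    g <- exp(-(outer((ii - xs[k])^2, (jj - zs[k])^2, "+")) / (2 * sigma^2))
    img[ii, jj] <- img[ii, jj] + amplitude * g
  }
  img
}

# exact periodic subpixel shift of image content by (+dx, +dz) pixels
fourier_shift <- function(m, dx, dz) {
  nx <- nrow(m); nz <- ncol(m)
  kx <- 2 * pi * c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  kz <- 2 * pi * c(0:(nz %/% 2), -((nz - nz %/% 2 - 1):1)) / nz
  ph <- exp(-1i * outer(kx * dx, kz * dz, "+"))
  Re(fft(fft(m) * ph, inverse = TRUE)) / (nx * nz)
}

# frame of dark disks (cells) on a bright background at given centers (px)
disk_frame <- function(centers, n = 128, radius = 4, bg = 200, fg = 40) {
  img <- matrix(bg, n, n)
  for (k in seq_len(nrow(centers))) {
    ii <- pmax(1, pmin(n, round(centers[k, 1]) + (-(radius + 2)):(radius + 2)))
    jj <- pmax(1, pmin(n, round(centers[k, 2]) + (-(radius + 2)):(radius + 2)))
    for (a in ii) for (b in jj)
      if ((a - centers[k, 1])^2 + (b - centers[k, 2])^2 <= radius^2)
        img[a, b] <- fg
  }
  img
}

# brute-force minimal assignment cost by permutation enumeration
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  min(vapply(perms(seq_len(n)), function(p) sum(cost[cbind(seq_len(n), p)]), 0))
}
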