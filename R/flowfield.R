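# PIV: CLAHE preprocessing, multipass FFT cross-correlation with subpixel
# Gaussian peak fitting, and the vertical-velocity / density coupling curve.

#' CLAHE contrast enhancement
#'
#' Contrast-limited adaptive histogram equalization with a physical tile
#' size, applied before PIV so that dim plume interiors contribute texture to
#' the correlation. Output intensities span the input bit depth.
#'
#' @param frame intensity matrix (counts).
#' @param pixel_size pixel size (um).
#' @param tile_size tile size (um); tiles larger than the frame fall back to
#'   a single tile with a warning.
#' @param bit_depth output bit depth.
#' @param limit clip limit (multiples of the uniform histogram height).
#' @param bins histogram bins per tile.
#' @return Matrix of the same dimension, range `[0, 2^bit_depth - 1]`.
#' @export
clahe_preprocess <- function(frame, pixel_size, tile_size = 1500,
                             bit_depth = 8L, limit = 2, bins = 256) {
  if (!is.matrix(frame)) stop_invalid("'frame' must be a matrix")
  check_positive(pixel_size, "pixel_size")
  tile_px <- tile_size / pixel_size
  if (tile_px < 8) stop_invalid("tile size below 8 px")
  ntx <- floor(nrow(frame) / tile_px)
  ntz <- floor(ncol(frame) / tile_px)
  rng <- 2^bit_depth - 1
  x01 <- frame / rng
  if (ntx < 2 || ntz < 2) {
    # fewer than 2x2 tiles: global clipped histogram equalization
    if (ntx < 1 || ntz < 1)
      warning("tile larger than the frame: single-tile fallback")
    b <- pmin(bins, pmax(1L, ceiling(x01 * bins)))
    h <- tabulate(b, nbins = bins)
    cap <- limit * length(x01) / bins
    excess <- sum(pmax(h - cap, 0))
    h <- pmin(h, cap) + excess / bins
    cdf <- cumsum(h) / sum(h)
    out <- matrix(cdf[b], nrow(frame), ncol(frame))
  } else {
    out <- as.matrix(EBImage::clahe(x01, nx = ntx, ny = ntz, bins = bins,
                                    limit = limit))
  }
  pmin(rng, pmax(0, out * rng))
}

# Linear (zero-padded) cross-correlation of two equally sized windows via
# FFT, divided by the exact pixel-overlap count. Zero padding suppresses the
# circular wraparound of periodogram correlation and the overlap division
# removes the triangular weighting that would otherwise bias broad
# correlation peaks toward zero displacement. The search is restricted to a
# quarter window downstream, where the overlap correction is benign.
# Displacement index 0 sits at [1, 1] (circular layout on the 2w grid).
xcorr2 <- function(a, b, overlap) {
  w <- nrow(a); P <- 2L * w
  ap <- matrix(0, P, P); bp <- matrix(0, P, P)
  ap[1:w, 1:ncol(a)] <- a
  bp[1:w, 1:ncol(b)] <- b
  Re(fft(Conj(fft(ap)) * fft(bp), inverse = TRUE)) / (P * P) / overlap
}

# pixel-overlap count of two w x w windows at every padded displacement
overlap_counts <- function(w) {
  P <- 2L * w
  mk <- matrix(0, P, P); mk[1:w, 1:w] <- 1
  nn <- Re(fft(Conj(fft(mk)) * fft(mk), inverse = TRUE)) / (P * P)
  pmax(round(nn), 1)
}

# map circular FFT index (1-based) to signed displacement
fft_shift_index <- function(i, n) ifelse(i - 1 <= n / 2, i - 1, i - 1 - n)

# 3-point Gaussian subpixel refinement along one axis
gauss_subpx <- function(cm1, c0, cp1) {
  if (!is.finite(cm1) || !is.finite(c0) || !is.finite(cp1)) return(0)
  if (cm1 > 0 && c0 > 0 && cp1 > 0) {
    den <- 2 * (log(cm1) - 2 * log(c0) + log(cp1))
    if (den < 0) return((log(cm1) - log(cp1)) / den)
  }
  den <- 2 * (cm1 - 2 * c0 + cp1)     # parabolic fallback
  if (den < 0) (cm1 - cp1) / den else 0
}

#' PIV flow field from an image pair
#'
#' Multipass FFT cross-correlation with progressive refinement of the
#' interrogation window (discrete window offsetting between passes) and
#' 3-point Gaussian subpixel peak localization. Vectors whose correlation
#' peak ratio is low are replaced by the local median and flagged; vectors
#' displaced beyond half the final window are flagged invalid.
#'
#' @param frameA,frameB intensity matrices of identical dimension.
#' @param pixel_size pixel size (um).
#' @param dt time between the frames (s).
#' @param windows interrogation window sizes per pass (mm).
#' @param steps window spacings per pass (mm).
#' @param min_peak_ratio peak-to-second-peak ratio below which a vector is
#'   median-replaced.
#' @return An object of class `"velocity_field"`: data frame `vectors`
#'   (`x_um`, `z_um`, `vx_um_s`, `vz_um_s`, `quality`, `valid`) plus grid
#'   metadata. Quality is `1 - 1/peak_ratio`, in `[0, 1]`.
#' @export
piv_flow_field <- function(frameA, frameB, pixel_size, dt,
                           windows = c(0.24, 0.19, 0.15),
                           steps = c(0.12, 0.10, 0.07),
                           min_peak_ratio = 1.2) {
  if (!identical(dim(frameA), dim(frameB)))
    stop_invalid("frames must have identical dimensions")
  check_positive(dt, "dt")
  nx <- nrow(frameA); nz <- ncol(frameA)
  win_px <- pmax(8L, as.integer(round(windows * 1000 / pixel_size)))
  step_px <- pmax(4L, as.integer(round(steps * 1000 / pixel_size)))

  prev <- NULL   # previous-pass displacement field (for window offsetting)
  for (pass in seq_along(win_px)) {
    wp <- win_px[pass]; sp <- step_px[pass]
    cx <- seq(wp %/% 2 + 1L, nx - wp %/% 2, by = sp)
    cz <- seq(wp %/% 2 + 1L, nz - wp %/% 2, by = sp)
    if (!length(cx) || !length(cz))
      stop_invalid("interrogation window larger than the frame")
    ux <- matrix(0, length(cx), length(cz))
    uz <- matrix(0, length(cx), length(cz))
    qual <- matrix(0, length(cx), length(cz))
    ok <- matrix(TRUE, length(cx), length(cz))
    half <- wp %/% 2
    quarter <- max(3L, wp %/% 4)
    overlap <- overlap_counts(wp)

    for (i in seq_along(cx)) for (j in seq_along(cz)) {
      off <- c(0L, 0L)
      if (!is.null(prev)) {
        off <- round(c(prev$fx(cx[i], cz[j]), prev$fz(cx[i], cz[j])))
        off[!is.finite(off)] <- 0L
      }
      ax <- (cx[i] - half):(cx[i] + half - 1L)
      az <- (cz[j] - half):(cz[j] + half - 1L)
      bx <- pmin(nx, pmax(1L, ax + off[1]))
      bz <- pmin(nz, pmax(1L, az + off[2]))
      a <- frameA[ax, az]; b <- frameB[bx, bz]
      a <- a - mean(a); b <- b - mean(b)
      if (sd(a) == 0 || sd(b) == 0) { ok[i, j] <- FALSE; next }
      cc <- xcorr2(a, b, overlap)
      P <- 2L * wp
      # quarter-window search rule: larger residuals go to the next pass
      # or are flagged invalid at the final pass
      sgn <- fft_shift_index(seq_len(P), P)
      far <- abs(sgn) > quarter
      cc[far, ] <- -Inf; cc[, far] <- -Inf
      pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      dxi <- fft_shift_index(pk[1], P); dzi <- fft_shift_index(pk[2], P)
      # subpixel
      im <- ((pk[1] - 2) %% P) + 1L; ip <- (pk[1] %% P) + 1L
      jm <- ((pk[2] - 2) %% P) + 1L; jp <- (pk[2] %% P) + 1L
      sx <- gauss_subpx(cc[im, pk[2]], cc[pk[1], pk[2]], cc[ip, pk[2]])
      sz <- gauss_subpx(cc[pk[1], jm], cc[pk[1], pk[2]], cc[pk[1], jp])
      ux[i, j] <- off[1] + dxi + sx
      uz[i, j] <- off[2] + dzi + sz
      # peak ratio vs second peak outside the main correlation lobe
      cc2 <- cc
      rex <- max(3L, wp %/% 8)
      ii <- (pk[1] + (-rex:rex) - 1) %% P + 1
      jjn <- (pk[2] + (-rex:rex) - 1) %% P + 1
      cc2[ii, jjn] <- -Inf
      second <- max(cc2)
      pr <- if (second > 0) cc[pk[1], pk[2]] / second else Inf
      qual[i, j] <- max(0, min(1, 1 - 1 / pr))
      if (pr < min_peak_ratio) ok[i, j] <- FALSE
      if (pass == length(win_px) && (abs(dxi + sx) > half || abs(dzi + sz) > half))
        ok[i, j] <- FALSE
    }

    # replace low-quality vectors by the local median
    for (i in seq_along(cx)) for (j in seq_along(cz)) {
      if (ok[i, j]) next
      ii <- max(1, i - 1):min(length(cx), i + 1)
      jj <- max(1, j - 1):min(length(cz), j + 1)
      nb <- ok[ii, jj]
      if (any(nb)) {
        ux[i, j] <- median(ux[ii, jj][nb])
        uz[i, j] <- median(uz[ii, jj][nb])
      }
    }

    # bilinear interpolators of this pass's displacement for the next pass
    fx <- make_bilinear(cx, cz, ux)
    fz <- make_bilinear(cx, cz, uz)
    prev <- list(fx = fx, fz = fz)
  }

  vectors <- data.frame(
    x_um = rep((cx - 0.5) * pixel_size, times = length(cz)),
    z_um = rep((cz - 0.5) * pixel_size, each = length(cx)),
    vx_um_s = as.vector(ux) * pixel_size / dt,
    vz_um_s = as.vector(uz) * pixel_size / dt,
    quality = as.vector(qual),
    valid = as.vector(ok)
  )
  structure(list(vectors = vectors, grid_x = cx, grid_z = cz,
                 window_mm = windows[length(windows)],
                 step_mm = steps[length(steps)],
                 pixel_size = pixel_size, dt = dt),
            class = "velocity_field")
}

# bilinear interpolation on a regular (possibly single-point) grid
make_bilinear <- function(gx, gz, val) {
  function(x, z) {
    if (length(gx) == 1L && length(gz) == 1L) return(val[1, 1])
    i <- findInterval(x, gx, all.inside = TRUE)
    j <- findInterval(z, gz, all.inside = TRUE)
    i2 <- min(i + 1L, length(gx)); j2 <- min(j + 1L, length(gz))
    tx <- if (i2 > i) (x - gx[i]) / (gx[i2] - gx[i]) else 0
    tz <- if (j2 > j) (z - gz[j]) / (gz[j2] - gz[j]) else 0
    tx <- min(1, max(0, tx)); tz <- min(1, max(0, tz))
    (1 - tx) * (1 - tz) * val[i, j] + tx * (1 - tz) * val[i2, j] +
      (1 - tx) * tz * val[i, j2] + tx * tz * val[i2, j2]
  }
}

#' @export
print.velocity_field <- function(x, ...) {
  v <- x$vectors
  cat(sprintf("PIV field: %d x %d vectors, |v| up to %.3g um/s, %d flagged\n",
              length(x$grid_x), length(x$grid_z),
              max(sqrt(v$vx_um_s^2 + v$vz_um_s^2)), sum(!v$valid)))
  invisible(x)
}

#' @export
plot.velocity_field <- function(x, scale = 1, ...) {
  v <- x$vectors
  plot(v$x_um, v$z_um, type = "n", xlab = "x (um)", ylab = "z (um)", ...)
  graphics::arrows(v$x_um, v$z_um,
                   v$x_um + scale * v$vx_um_s, v$z_um + scale * v$vz_um_s,
                   length = 0.03)
  invisible(x)
}

#' Vertical-velocity vs density coupling curve
#'
#' Pools co-located (vertical velocity, relative density) samples over one or
#' more frame pairs and bins them by relative density. Gyrotactic plumes show
#' a negative coupling: cells accumulate where the flow descends. Positive
#' `vz` is upward. Empty bins are omitted (never zero-filled).
#'
#' @param fields a [piv_flow_field()] result or list of them.
#' @param maps a [relative_density_map()] or list of them, co-registered with
#'   the velocity fields (density sampled at the nearest pixel under each
#'   vector).
#' @param pixel_size pixel size of the density maps (um).
#' @param bin_width density bin width (in units of `(n - n0)/alpha`); the
#'   classic reporting choice is 0.5, 0.05 resolves the curve more finely.
#' @return Data frame of class `"coupling_curve"`: `bin_center`, `mean_vz`,
#'   `sd_vz`, `n`.
#' @export
vz_density_coupling <- function(fields, maps, pixel_size, bin_width = 0.5) {
  if (inherits(fields, "velocity_field")) fields <- list(fields)
  if (inherits(maps, "relative_density_map")) maps <- list(maps)
  if (length(fields) != length(maps))
    stop_invalid("need one density map per velocity field")
  vz <- numeric(0); dens <- numeric(0)
  for (k in seq_along(fields)) {
    v <- fields[[k]]$vectors
    m <- maps[[k]]$values
    i <- pmax(1L, pmin(nrow(m), round(v$x_um / pixel_size + 0.5)))
    j <- pmax(1L, pmin(ncol(m), round(v$z_um / pixel_size + 0.5)))
    if (any(v$x_um > nrow(m) * pixel_size + pixel_size) ||
        any(v$z_um > ncol(m) * pixel_size + pixel_size))
      stop_invalid("velocity grid lies outside the density map (registration)")
    d <- m[cbind(i, j)]
    keep <- v$valid & is.finite(d)
    vz <- c(vz, v$vz_um_s[keep]); dens <- c(dens, d[keep])
  }
  if (!length(vz)) stop_invalid("no co-located samples")
  bin <- round(dens / bin_width)
  agg <- split(vz, bin)
  centers <- as.numeric(names(agg)) * bin_width
  out <- data.frame(bin_center = centers,
                    mean_vz = vapply(agg, mean, 0),
                    sd_vz = vapply(agg, function(x) if (length(x) > 1) sd(x) else NA_real_, 0),
                    n = lengths(agg))
  out <- out[order(out$bin_center), ]
  rownames(out) <- NULL
  class(out) <- c("coupling_curve", "data.frame")
  out
}
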