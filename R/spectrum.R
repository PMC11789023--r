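# Hamming-windowed Fourier quantification of bioconvection patterns.
#
# Per frame the intensity J is multiplied by a Hamming window H and Fourier
# transformed; the spectrum is |F[J * H]| normalized by the scalar window gain
# sum(H) (a pointwise division by |F[H]| would be singular away from DC; the
# scalar gain preserves peak locations and relative amplitudes). Wavenumbers
# are in cycles per mm, so the pattern wavelength is simply 1/qmax.

hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * seq_len(n) / (n + 1))

#' Windowed power spectrum of an image stack
#'
#' @param stack an [image_stack()].
#' @param mode `"azimuthal_2d"`: the 2D spectrum is averaged over annuli of
#'   constant radial wavenumber (top-view geometry); `"column_1d"`: columns
#'   are averaged first, `J(x) = <J(x, z)>_z`, and a 1D window/transform is
#'   applied (side-view geometry).
#' @return An object of class `"power_spectrum_series"` with fields `q`
#'   (cycles/mm, strictly increasing, DC excluded), `S` (matrix, one column
#'   per frame), `t` (s), `counts` (pixels per annulus; 1 in 1D mode) and
#'   `mode`.
#' @examples
#' stk <- generate_growing_pattern(duration = 30, onset_time = 5, seed = 1)
#' ps <- windowed_power_spectrum(stk)
#' @export
windowed_power_spectrum <- function(stack, mode = c("azimuthal_2d", "column_1d")) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  d <- dim(stack$frames[[1]])
  nx <- d[1]; nz <- d[2]
  px_mm <- stack$pixel_size / 1000
  t <- (seq_along(stack$frames) - 1) * stack$frame_interval

  if (mode == "column_1d") {
    h <- hamming(nx)
    gain <- sum(h)
    nq <- floor(nx / 2)
    q <- (1:nq) / (nx * px_mm)
    S <- vapply(stack$frames, function(f) {
      j <- rowMeans(f)
      Mod(fft((j - mean(j)) * h))[2:(nq + 1)] / gain
    }, numeric(nq))
    counts <- rep(1L, nq)
  } else {
    if (mode == "azimuthal_2d" && nx != nz)
      warning("azimuthal averaging on a non-square frame")
    h2 <- outer(hamming(nx), hamming(nz))
    gain <- sum(h2)
    # radial wavenumber of every FFT bin, in cycles/mm
    fx <- c(0:(nx %/% 2), -((ceiling(nx / 2) - 1):1)) / (nx * px_mm)
    fz <- c(0:(nz %/% 2), -((ceiling(nz / 2) - 1):1)) / (nz * px_mm)
    qr <- sqrt(outer(fx^2, fz^2, "+"))
    dq <- 1 / (max(nx, nz) * px_mm)          # fundamental as annulus width
    ring <- matrix(pmax(1L, as.integer(round(qr / dq))), nx, nz)
    ring[1, 1] <- NA                          # exclude DC
    nq <- max(ring, na.rm = TRUE)
    ok <- !is.na(ring)
    ridx <- ring[ok]
    counts <- tabulate(ridx, nbins = nq)
    q <- (1:nq) * dq
    S <- vapply(stack$frames, function(f) {
      sp <- Mod(fft((f - mean(f)) * h2)) / gain
      out <- numeric(nq)
      rs <- rowsum(sp[ok], ridx)
      out[as.integer(rownames(rs))] <- rs[, 1]
      out / pmax(counts, 1L)
    }, numeric(nq))
    keep <- counts > 0 & q <= max(fx)         # drop empty/corner annuli
    q <- q[keep]; S <- S[keep, , drop = FALSE]; counts <- counts[keep]
  }
  structure(list(q = q, S = S, t = t, counts = counts, mode = mode,
                 pixel_size = stack$pixel_size, n_px = d),
            class = "power_spectrum_series")
}

#' @export
print.power_spectrum_series <- function(x, ...) {
  cat(sprintf("Power spectrum series (%s): %d frames, q in [%.3g, %.3g] /mm\n",
              x$mode, ncol(x$S), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
plot.power_spectrum_series <- function(x, frames = ncol(x$S), ...) {
  matplot(x$q, x$S[, frames, drop = FALSE], type = "l", lty = 1,
          xlab = "q (1/mm)", ylab = "S(q)", ...)
  invisible(x)
}

# Peak-search band: window leakage excluded below 2 / (image extent),
# and the upper half of the resolved band excluded (near-Nyquist bins).
search_band <- function(ps) {
  width_mm <- ps$n_px[1] * ps$pixel_size / 1000
  ps$q >= 2 / width_mm & ps$q <= max(ps$q) / 2
}

#' Extract the dominant pattern wavelength
#'
#' The spectra of the selected frames are averaged, the wavenumber `qmax` of
#' the highest peak inside the search band is located, and the wavelength is
#' reported as `lambda = 1/qmax`. A peak prominence (peak over the median of
#' the band) below `prominence` classifies the stack as patternless
#' (homogeneous state).
#'
#' @param ps a [windowed_power_spectrum()] result.
#' @param frame_range integer vector of frame indices to average (default:
#'   the final quarter of the recording).
#' @param prominence minimal peak-to-median ratio for a detectable pattern.
#' @return List with `lambda_mm`, `qmax_per_mm`, `prominence`, `no_pattern`.
#' @export
extract_wavelength <- function(ps, frame_range = NULL, prominence = 4) {
  stopifnot(inherits(ps, "power_spectrum_series"))
  nf <- ncol(ps$S)
  frame_range <- frame_range %||% seq.int(max(1L, floor(0.75 * nf)), nf)
  if (!length(frame_range)) stop_invalid("empty frame range")
  sbar <- rowMeans(ps$S[, frame_range, drop = FALSE])
  band <- search_band(ps)
  sb <- sbar[band]; qb <- ps$q[band]
  med <- median(sb)
  i <- which.max(sb)
  prom <- if (med > 0) sb[i] / med else ifelse(sb[i] > 0, Inf, 0)
  if (!is.finite(prom) && sb[i] == 0) prom <- 0
  if (prom < prominence) {
    return(list(lambda_mm = NA_real_, qmax_per_mm = NA_real_,
                prominence = prom, no_pattern = TRUE))
  }
  list(lambda_mm = 1 / qb[i], qmax_per_mm = qb[i], prominence = prom,
       no_pattern = FALSE)
}

#' Pattern dynamics: onset time and growth rate
#'
#' Tracks `Smax(t)`, the in-band spectral maximum per frame. The onset `ton`
#' is the first time `Smax` exceeds (baseline mean + k * baseline SD) for `m`
#' consecutive frames, with the baseline estimated from the earliest frames.
#' The growth rate is the least-squares slope of `log Smax` between onset and
#' the frame where `Smax` first reaches half its final plateau (beyond which
#' nonlinear saturation bends the curve).
#'
#' @param ps a [windowed_power_spectrum()] result with at least 20 frames.
#' @param k,m onset-rule constants: threshold in baseline SDs and number of
#'   consecutive frames required.
#' @param baseline_frames number of initial frames used for the baseline
#'   (default: 10% of the recording, at least 5).
#' @return An object of class `"pattern_metrics"`: `lambda_mm`, `qmax_per_mm`,
#'   `smax` (data frame `t`, `smax`), `t_on_s`, `omega_per_s` and `fit`
#'   diagnostics (`window`, `r_squared`, `n_points`). Onset and growth rate
#'   are `NA` for stacks that never leave the baseline.
#' @export
characterize_dynamics <- function(ps, k = 5, m = 5, baseline_frames = NULL) {
  stopifnot(inherits(ps, "power_spectrum_series"))
  nf <- ncol(ps$S)
  if (nf < 20) stop_invalid("need at least 20 frames")
  band <- search_band(ps)
  smax <- apply(ps$S[band, , drop = FALSE], 2, max)
  iq <- apply(ps$S[band, , drop = FALSE], 2, which.max)
  nb <- baseline_frames %||% max(5L, floor(0.1 * nf))
  base_mu <- mean(smax[seq_len(nb)])
  base_sd <- sd(smax[seq_len(nb)])
  thr <- base_mu + k * max(base_sd, .Machine$double.eps)
  above <- smax > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  hit <- which(runs$values & runs$lengths >= m)
  wl <- extract_wavelength(ps)

  if (!length(hit)) {
    return(structure(list(lambda_mm = wl$lambda_mm, qmax_per_mm = wl$qmax_per_mm,
                          smax = data.frame(t = ps$t, smax = smax),
                          t_on_s = NA_real_, omega_per_s = NA_real_,
                          fit = list(window = c(NA_real_, NA_real_),
                                     r_squared = NA_real_, n_points = 0L)),
                     class = "pattern_metrics"))
  }
  i_on <- ends[hit[1]] - runs$lengths[hit[1]] + 1L
  t_on <- ps$t[i_on]
  plateau <- median(tail(smax, max(5L, floor(0.1 * nf))))
  i_half <- which(smax >= plateau / 2 & seq_len(nf) >= i_on)[1]
  if (is.na(i_half) || i_half - i_on < 4L) i_half <- min(nf, i_on + 4L)
  sel <- i_on:i_half
  sel <- sel[smax[sel] > 0]
  fit <- lm(log(smax[sel]) ~ ps$t[sel])
  omega <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(lambda_mm = wl$lambda_mm, qmax_per_mm = wl$qmax_per_mm,
                 smax = data.frame(t = ps$t, smax = smax),
                 t_on_s = t_on, omega_per_s = omega,
                 fit = list(window = c(ps$t[i_on], ps$t[i_half]),
                            r_squared = r2, n_points = length(sel))),
            class = "pattern_metrics")
}

#' @export
print.pattern_metrics <- function(x, ...) {
  cat("Pattern metrics\n")
  cat(sprintf("  lambda = %s mm (qmax = %s /mm)\n",
              format(x$lambda_mm, digits = 3), format(x$qmax_per_mm, digits = 3)))
  cat(sprintf("  t_on = %s s, omega = %s 1/s (R^2 = %s, n = %d)\n",
              format(x$t_on_s, digits = 3), format(x$omega_per_s, digits = 3),
              format(x$fit$r_squared, digits = 3), x$fit$n_points))
  invisible(x)
}
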