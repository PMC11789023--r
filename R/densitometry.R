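# Beer--Lambert densitometry: relative cell density from transmitted light.
#
# With I_T = I0 * exp(-n/alpha') per pixel column, the relative density
# (n - n0)/alpha = <log I_T> - log I_T follows without knowing either I0 or
# the attenuation scale: the incident intensity cancels in the difference of
# logs. Natural logarithms are used throughout; the base only rescales alpha.

#' Relative cell density map from a transmitted-light frame
#'
#' Computes `<log I_T>_mask - log I_T` pixelwise: positive values mark pixels
#' denser than the mask average. The masked-area mean of every map is zero by
#' construction, and the map is invariant under global intensity rescaling.
#'
#' Pixels quantized to zero counts are clipped to 0.5 counts before the log
#' (with a warning); negative intensities are an error.
#'
#' @param frame numeric intensity matrix (or an [image_stack()] together with
#'   `frame_index`).
#' @param mask logical matrix of the same dimension selecting the analysis
#'   region; default: the whole frame.
#' @param frame_index frame to use when `frame` is an image stack.
#' @return An object of class `"relative_density_map"` with fields `values`
#'   (NA outside the mask), `mask`, `frame_index`.
#' @examples
#' m <- matrix(100, 32, 32); m[1:16, ] <- 100 * exp(-1)
#' map <- relative_density_map(m)
#' range(map$values)  # -0.5 in the bright half, +0.5 in the dim half
#' @export
relative_density_map <- function(frame, mask = NULL, frame_index = 1L) {
  if (inherits(frame, "image_stack")) frame <- frame$frames[[frame_index]]
  if (!is.matrix(frame)) stop_invalid("'frame' must be a matrix")
  mask <- mask %||% matrix(TRUE, nrow(frame), ncol(frame))
  if (!identical(dim(mask), dim(frame)))
    stop_invalid("mask dimension does not match the frame")
  it <- frame[mask]
  n_neg <- sum(it < 0)
  if (n_neg > 0)
    stop_invalid(n_neg, " masked pixel(s) have negative intensity")
  n_zero <- sum(it == 0)
  if (n_zero > 0) {
    warning(sprintf("%d masked pixel(s) at zero counts clipped to 0.5", n_zero))
    frame[frame == 0 & mask] <- 0.5
  }
  lg <- log(frame)
  values <- mean(lg[mask]) - lg
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, frame_index = frame_index),
            class = "relative_density_map")
}

#' @export
print.relative_density_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("Relative density map (frame %d): %d px, range [%.3g, %.3g]\n",
              x$frame_index, sum(x$mask), min(v), max(v)))
  invisible(x)
}

#' Vertical relative-density profile
#'
#' Row-wise (constant-z) means of one or more relative density maps from
#' side-view frames, averaged over frames. z is measured from the compartment
#' bottom in um.
#'
#' @param maps a [relative_density_map()] or a list of them (same geometry).
#' @param pixel_size pixel size (um).
#' @return Data frame with columns `z_um` and `rel_density`.
#' @export
vertical_profile <- function(maps, pixel_size) {
  if (inherits(maps, "relative_density_map")) maps <- list(maps)
  check_positive(pixel_size, "pixel_size")
  dims <- dim(maps[[1]]$values)
  acc <- matrix(0, dims[1], dims[2]); cnt <- matrix(0, dims[1], dims[2])
  for (m in maps) {
    stopifnot(inherits(m, "relative_density_map"))
    if (!identical(dim(m$values), dims)) stop_invalid("map geometries differ")
    v <- m$values
    acc <- acc + ifelse(m$mask, v, 0)
    cnt <- cnt + m$mask
  }
  colsum <- colSums(acc)
  coln <- colSums(cnt)
  prof <- ifelse(coln > 0, colsum / pmax(coln, 1), NA_real_)
  data.frame(z_um = (seq_len(dims[2]) - 0.5) * pixel_size, rel_density = prof)
}

#' Fit the sedimentation decay length of a vertical profile
#'
#' Up-swimming cells accumulate at the top so their density grows as
#' `exp(z / L)` with decay length `L = D/v`. The profile values are linear in
#' the density, hence the model `a * exp(z/L) + b` is fitted by nonlinear
#' least squares (the offset absorbs the unknown mean level; the attenuation
#' scale is treated as unity). Flat profiles return an infinite length.
#'
#' @param profile data frame from [vertical_profile()] (columns `z_um`,
#'   `rel_density`), or any data frame with those columns.
#' @return List with `length_um`, `r_squared`, `monotone` (logical trend
#'   diagnostic) and the `fit` object (`NULL` for flat profiles).
#' @export
fit_sedimentation_length <- function(profile) {
  z <- profile$z_um; y <- profile$rel_density
  ok <- is.finite(z) & is.finite(y)
  z <- z[ok]; y <- y[ok]
  if (length(z) < 4) stop_invalid("need at least 4 profile points")
  dy <- diff(y)
  monotone <- all(dy >= 0) || all(dy <= 0)
  if (sd(y) < 1e-12 * max(abs(y), 1)) {
    return(list(length_um = Inf, r_squared = NA_real_, monotone = monotone,
                fit = NULL))
  }
  # starting values from a log-linear fit after shifting above zero
  b0 <- min(y) - 0.05 * diff(range(y)) - 1e-12
  lf <- lm(log(y - b0) ~ z)
  start <- list(a = exp(unname(coef(lf)[1])), L = 1 / unname(coef(lf)[2]),
                b = b0)
  if (!is.finite(start$L) || start$L <= 0) start$L <- diff(range(z))
  fit <- try(minpack.lm::nlsLM(y ~ a * exp(z / L) + b, start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(length_um = NA_real_, r_squared = NA_real_,
                monotone = monotone, fit = NULL))
  }
  res <- y - stats::predict(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(length_um = unname(coef(fit)["L"]), r_squared = r2,
       monotone = monotone, fit = fit)
}
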