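# image_stack: time series of 2D intensity frames.
#
# Frame convention: a frame is an nx-by-nz numeric matrix whose FIRST index
# runs along the horizontal (x) axis and whose SECOND index runs along the
# vertical axis measured from the compartment bottom (side view) or along y
# (top view). TIFF files store rows top-to-bottom; the readers/writers below
# convert between the two conventions.

#' Construct an image stack
#'
#' @param frames list of numeric matrices, all the same dimension, with
#'   non-negative intensities (camera counts). See the package conventions:
#'   `frame[i, j]` is pixel `i` along x and `j` along z-from-bottom (or y).
#' @param pixel_size pixel size (um).
#' @param frame_interval frame interval (s).
#' @param bit_depth camera bit depth used for quantization/IO (8 or 16).
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval, bit_depth = 8L) {
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames)) stop_invalid("'frames' must contain at least one frame")
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims))
      stop_invalid("all frames must be matrices of identical dimension")
    if (any(f < 0) || any(!is.finite(f)))
      stop_invalid("frame intensities must be finite and non-negative")
  }
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  if (!bit_depth %in% c(8L, 16L)) stop_invalid("'bit_depth' must be 8 or 16")
  if (max(vapply(frames, max, 0)) > 2^bit_depth - 1)
    stop_invalid("intensities exceed the bit-depth range")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "Image stack: %d frames of %d x %d px (%.3g x %.3g mm), dt = %g s, %d-bit\n",
    length(x$frames), d[1], d[2], d[1] * x$pixel_size / 1000,
    d[2] * x$pixel_size / 1000, x$frame_interval, x$bit_depth))
  invisible(x)
}

#' @export
plot.image_stack <- function(x, frame = 1, ...) {
  f <- x$frames[[frame]]
  nx <- nrow(f); nz <- ncol(f)
  image(x = (seq_len(nx) - 0.5) * x$pixel_size,
        y = (seq_len(nz) - 0.5) * x$pixel_size,
        z = f, col = gray(seq(0, 1, length.out = 256)),
        xlab = "x (um)", ylab = "z (um)", useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are stored relative to the bit-depth range. The sidecar
#' `<path>.json` records `pixel_size_um`, `frame_interval_s` and `bit_depth`.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @return `write_image_stack` returns `path` invisibly; `read_image_stack`
#'   returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- 2^stack$bit_depth - 1
  pages <- lapply(stack$frames, function(f) {
    # to TIFF row-major top-down: rows = image rows (top first), cols = x
    t(f)[rev(seq_len(ncol(f))), , drop = FALSE] / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  meta <- list(pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval,
               bit_depth = stack$bit_depth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @param pixel_size,frame_interval,bit_depth metadata overrides used when no
#'   sidecar file is present.
#' @export
read_image_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                             bit_depth = NULL) {
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% meta$pixel_size_um
    frame_interval <- frame_interval %||% meta$frame_interval_s
    bit_depth <- bit_depth %||% meta$bit_depth
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop_invalid("no sidecar metadata; supply pixel_size and frame_interval")
  bit_depth <- as.integer(bit_depth %||% 8L)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  scale <- 2^bit_depth - 1
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra channels
    t(p[rev(seq_len(nrow(p))), , drop = FALSE]) * scale
  })
  image_stack(frames, pixel_size, frame_interval, bit_depth)
}
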