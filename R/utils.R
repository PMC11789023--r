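# Shared internal helpers: argument checking, seeds, small numerics.

stop_invalid <- function(...) {
  stop(structure(
    class = c("bioconvect_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("'", name, "' must be a single positive finite number")
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_invalid("'", name, "' must be a single non-negative finite number")
  invisible(x)
}

#' Evaluate an expression under a local, restorable RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Per-stage seed expansion: documented counter scheme. Global seed s and a
# stage index k map to (s * 101 + k) mod 2^31-1, keeping results independent
# of stage order changes elsewhere in a config.
stage_seed <- function(seed, k) {
  as.integer((as.double(seed) * 101 + k) %% 2147483647)
}

# Trapezoidal integral on a possibly non-uniform grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Signif-style two-significant-figure rounding used in reports.
signif2 <- function(x) signif(x, 2)

# md5 of a serialized R object (base tools only; used for run manifests).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 2 keeps hashes stable across R >= 3.5
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
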