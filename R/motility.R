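# Cell detection (circular Hough), trajectory linking (optimal assignment),
# velocity autocorrelation and motility-statistics fitting.


#' Construct a detection set
#'
#' Per-frame lists of detected cell centers, the exchange format between
#' [detect_cells()] and [link_trajectories()].
#'
#' @param frames list of data frames with columns `x_um`, `y_um`, `score`.
#' @param pixel_size pixel size (um).
#' @param radius_range detection radius range (um), metadata only.
#' @return An object of class `"detection_set"`.
#' @export
detection_set <- function(frames, pixel_size, radius_range = c(NA, NA)) {
  for (f in frames)
    if (!all(c("x_um", "y_um") %in% names(f)))
      stop_invalid("each frame needs columns x_um, y_um")
  structure(list(frames = frames, pixel_size = pixel_size,
                 radius_range = radius_range), class = "detection_set")
}

#' @export
print.detection_set <- function(x, ...) {
  n <- vapply(x$frames, nrow, 0L)
  cat(sprintf("Detection set: %d frames, %d detections (%.1f per frame)\n",
              length(n), sum(n), mean(n)))
  invisible(x)
}

#' Detect cells by circular Hough transform
#'
#' Gradient-direction Hough voting: edge pixels (gradient magnitude above a
#' fraction of its maximum) vote for circle centers along their gradient
#' direction, at every radius in the search range and in both senses (cells
#' may be darker or brighter than the background). The smoothed accumulator
#' is normalized by the expected perimeter vote count and maximized over
#' radii; local maxima above `threshold` are kept after non-maximum
#' suppression with a minimum separation. Direction voting suppresses the
#' tangency artifacts of plain ring convolution.
#'
#' @param frame intensity matrix or [image_stack()] (all frames processed).
#' @param pixel_size pixel size (um); taken from the stack when available.
#' @param radius_range circle radius search range (um); the classic
#'   *Chlamydomonas* setting is 2.6--5.5 um.
#' @param threshold minimal normalized accumulator score (roughly the
#'   fraction of circle perimeter supported by edges).
#' @param min_separation minimal center separation (um); default: the mean
#'   search radius.
#' @param edge_frac edge threshold as a fraction of the peak gradient.
#' @return A [detection_set()].
#' @export
detect_cells <- function(frame, pixel_size = NULL, radius_range = c(2.6, 5.5),
                         threshold = 0.5, min_separation = NULL,
                         edge_frac = 0.25) {
  if (inherits(frame, "image_stack")) {
    pixel_size <- pixel_size %||% frame$pixel_size
    frames <- frame$frames
  } else frames <- list(frame)
  if (is.null(pixel_size)) stop_invalid("'pixel_size' is required")
  r_px <- radius_range / pixel_size
  if (min(r_px) < 1) stop_invalid("smallest search radius is below 1 pixel")
  radii <- seq(min(r_px), max(r_px), by = max(0.5, diff(range(r_px)) / 6))
  min_sep_px <- (min_separation %||% mean(radius_range)) / pixel_size

  detect_one <- function(f) {
    nx <- nrow(f); nz <- ncol(f)
    gx <- matrix(0, nx, nz); gz <- matrix(0, nx, nz)
    gx[2:(nx - 1), ] <- (f[3:nx, ] - f[1:(nx - 2), ]) / 2
    gz[, 2:(nz - 1)] <- (f[, 3:nz] - f[, 1:(nz - 2)]) / 2
    mag <- sqrt(gx^2 + gz^2)
    if (max(mag) <= 0)
      return(data.frame(x_um = numeric(0), y_um = numeric(0),
                        score = numeric(0)))
    sel <- which(mag >= edge_frac * max(mag))
    ex <- ((sel - 1L) %% nx) + 1L
    ez <- ((sel - 1L) %/% nx) + 1L
    uxn <- gx[sel] / mag[sel]; uzn <- gz[sel] / mag[sel]
    acc <- matrix(-Inf, nx, nz)
    for (r in radii) {
      votes <- matrix(0, nx, nz)
      for (s in c(-1, 1)) {
        ix <- round(ex + s * r * uxn); iz <- round(ez + s * r * uzn)
        keep <- ix >= 1 & ix <= nx & iz >= 1 & iz <= nz
        tab <- tabulate((iz[keep] - 1L) * nx + ix[keep], nbins = nx * nz)
        votes <- votes + matrix(tab, nx, nz)
      }
      # pool subpixel vote scatter, normalize by the expected perimeter count
      votes <- gaussian_blur(votes, 1) * (2 * pi * 1^2)  # restore peak height
      acc <- pmax(acc, votes / (2 * pi * r))
    }
    # non-maximum suppression, greedy by score
    cand <- which(acc >= threshold, arr.ind = TRUE)
    if (!nrow(cand))
      return(data.frame(x_um = numeric(0), y_um = numeric(0),
                        score = numeric(0)))
    sc <- acc[cand]
    o <- order(sc, decreasing = TRUE)
    cand <- cand[o, , drop = FALSE]; sc <- sc[o]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      sel <- which(keep)
      d2 <- (cand[sel, 1] - cand[i, 1])^2 + (cand[sel, 2] - cand[i, 2])^2
      if (all(d2 >= min_sep_px^2)) keep[i] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]; sc <- sc[keep]
    # centroid refinement on the 3x3 accumulator neighborhood
    cx <- numeric(nrow(cand)); cz <- numeric(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      i0 <- cand[i, 1]; j0 <- cand[i, 2]
      ii <- max(1, i0 - 1):min(nx, i0 + 1)
      jj <- max(1, j0 - 1):min(nz, j0 + 1)
      wgt <- pmax(acc[ii, jj, drop = FALSE], 0)
      if (sum(wgt) <= 0) { cx[i] <- i0; cz[i] <- j0 } else {
        cx[i] <- sum(outer(ii, rep(1, length(jj))) * wgt) / sum(wgt)
        cz[i] <- sum(outer(rep(1, length(ii)), jj) * wgt) / sum(wgt)
      }
    }
    data.frame(x_um = (cx - 0.5) * pixel_size, y_um = (cz - 0.5) * pixel_size,
               score = sc)
  }
  detection_set(lapply(frames, detect_one), pixel_size, radius_range)
}

# --- optimal assignment (Jonker-Volgenant successive shortest paths) --------
# Minimizes total cost of a perfect matching on a square cost matrix.
# Returns the column assigned to each row.
assign_min_cost <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      js <- which(!used[2:(n + 1)])
      cur <- cost[i0, js] - u[i0 + 1L] - v[js + 1L]
      upd <- cur < minv[js + 1L]
      if (any(upd)) {
        minv[js[upd] + 1L] <- cur[upd]
        way[js[upd] + 1L] <- j0
      }
      k <- which.min(minv[js + 1L])
      delta <- minv[js[k] + 1L]
      j1 <- js[k]
      usedj <- which(used)
      u[p[usedj] + 1L] <- u[p[usedj] + 1L] + delta
      v[usedj] <- v[usedj] - delta
      minv[-usedj] <- minv[-usedj] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  ans[p[2:(n + 1)]] <- seq_len(n)
  ans
}

# simple union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(par, i) { while (par[i] != i) i <- par[i]; i }

#' Link detections into trajectories
#'
#' Frame-to-frame assignment minimizing the total displacement, subject to a
#' hard per-link gate: no cell may move more than `max_disp` between
#' consecutive frames. Candidate pairs are grouped into connected components
#' by the gate and each component is solved exactly (optimal assignment with
#' a non-assignment cost of `max_disp`, so feasible links are always
#' preferred). Unmatched detections start new tracks; a detection never
#' appears in two tracks.
#'
#' @param dets a [detection_set()].
#' @param max_disp maximal frame-to-frame displacement (um); 7 um is the
#'   classic gate for 30 fps *Chlamydomonas* assays.
#' @param frame_interval frame interval (s).
#' @return A [trajectory_set()] (columns `track_id`, `frame`, `time_s`,
#'   `x_um`, `z_um`; the image y axis maps to `z_um`).
#' @export
link_trajectories <- function(dets, max_disp = 7, frame_interval = 1 / 30) {
  stopifnot(inherits(dets, "detection_set"))
  if (length(dets$frames) < 2) stop_invalid("need at least 2 frames")
  check_positive(max_disp, "max_disp")
  BIG <- 1e9

  next_id <- 0L
  # active track state
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  rows <- vector("list", length(dets$frames))

  start_tracks <- function(xs, ys) {
    ids <- next_id + seq_along(xs)
    next_id <<- next_id + length(xs)
    ids
  }

  for (k in seq_along(dets$frames)) {
    det <- dets$frames[[k]]
    nB <- nrow(det)
    if (k == 1L || length(act_id) == 0L) {
      ids <- if (nB) start_tracks(det$x_um, det$y_um) else integer(0)
    } else {
      nA <- length(act_id)
      ids <- integer(nB)
      dx <- outer(act_x, det$x_um, "-")
      dy <- outer(act_y, det$y_um, "-")
      dist <- sqrt(dx^2 + dy^2)
      feas <- dist <= max_disp
      matched_A <- rep(FALSE, nA)
      if (any(feas)) {
        # connected components over the feasibility graph (A nodes 1..nA,
        # B nodes nA+1..nA+nB)
        par <- uf_new(nA + nB)
        idx <- which(feas, arr.ind = TRUE)
        for (e in seq_len(nrow(idx))) {
          ra <- uf_find(par, idx[e, 1]); rb <- uf_find(par, nA + idx[e, 2])
          if (ra != rb) par[ra] <- rb
        }
        roots_A <- vapply(seq_len(nA), function(i) uf_find(par, i), 0L)
        roots_B <- vapply(seq_len(nB), function(j) uf_find(par, nA + j), 0L)
        for (root in unique(c(roots_A, roots_B))) {
          As <- which(roots_A == root); Bs <- which(roots_B == root)
          if (!length(As) || !length(Bs)) next
          na <- length(As); nb <- length(Bs); n <- na + nb
          cost <- matrix(0, n, n)
          sub <- dist[As, Bs, drop = FALSE]
          sub[sub > max_disp] <- BIG
          cost[seq_len(na), seq_len(nb)] <- sub
          cost[seq_len(na), nb + seq_len(na)] <-
            `diag<-`(matrix(BIG, na, na), max_disp)
          cost[na + seq_len(nb), seq_len(nb)] <-
            `diag<-`(matrix(BIG, nb, nb), max_disp)
          asg <- assign_min_cost(cost)
          for (a in seq_len(na)) {
            j <- asg[a]
            if (j <= nb && sub[a, j] <= max_disp) {
              ids[Bs[j]] <- act_id[As[a]]
              matched_A[As[a]] <- TRUE
            }
          }
        }
      }
      new <- which(ids == 0L)
      if (length(new)) ids[new] <- start_tracks(det$x_um[new], det$y_um[new])
    }
    rows[[k]] <- if (nB) data.frame(track_id = ids, frame = k - 1L,
                                    x_um = det$x_um, z_um = det$y_um)
                 else NULL
    act_id <- ids; act_x <- det$x_um; act_y <- det$y_um
  }
  d <- do.call(rbind, rows)
  if (is.null(d) || !nrow(d))
    stop_invalid("no detections to link")
  d$time_s <- d$frame * frame_interval
  trajectory_set(d[, c("track_id", "frame", "time_s", "x_um", "z_um")],
                 frame_interval)
}

#' Velocity autocorrelation function
#'
#' Velocities are frame-to-frame displacements divided by the frame interval.
#' The correlation `Cv(t) = <v(t0) . v(t0 + t)>` is averaged over all cells
#' and (assuming stationarity) over all time origins within each track,
#' weighting every velocity-pair sample equally. Tracks with frame gaps are
#' split into contiguous segments first.
#'
#' @param traj a [trajectory_set()].
#' @param max_lag largest lag (s).
#' @return A data frame of class `"vacf"` with columns `lag_s`,
#'   `cv_um2_s2` and `n_pairs`, and attributes `n_tracks`, `frame_interval`.
#' @export
velocity_autocorrelation <- function(traj, max_lag = 45) {
  stopifnot(inherits(traj, "trajectory_set"))
  dt <- traj$frame_interval
  n_lags_want <- floor(max_lag / dt) + 1L
  d <- traj$data
  trk <- split(d[, c("frame", "x_um", "z_um")], d$track_id)

  sums <- numeric(0); cnts <- numeric(0)
  grow <- function(v, n) { length(v) <- n; v[is.na(v)] <- 0; v }
  n_used <- 0L
  for (tr in trk) {
    if (nrow(tr) < 2) next
    brk <- c(0, which(diff(tr$frame) != 1L), nrow(tr))
    for (s in seq_len(length(brk) - 1L)) {
      seg <- tr[(brk[s] + 1L):brk[s + 1L], , drop = FALSE]
      nv <- nrow(seg) - 1L
      if (nv < 1L) next
      vx <- diff(seg$x_um) / dt
      vz <- diff(seg$z_um) / dt
      nfft <- 2^ceiling(log2(2 * nv))
      fx <- fft(c(vx, rep(0, nfft - nv)))
      fz <- fft(c(vz, rep(0, nfft - nv)))
      ac <- Re(fft(Mod(fx)^2 + Mod(fz)^2, inverse = TRUE))[seq_len(nv)] / nfft
      if (length(sums) < nv) { sums <- grow(sums, nv); cnts <- grow(cnts, nv) }
      sums[seq_len(nv)] <- sums[seq_len(nv)] + ac
      cnts[seq_len(nv)] <- cnts[seq_len(nv)] + (nv - 0:(nv - 1L))
      n_used <- n_used + 1L
    }
  }
  if (!length(sums)) stop_invalid("no track has at least 2 frames")
  n_lags <- min(n_lags_want, length(sums))
  if (n_lags < n_lags_want)
    warning("tracks shorter than max_lag: lag grid truncated")
  out <- data.frame(lag_s = (0:(n_lags - 1L)) * dt,
                    cv_um2_s2 = sums[seq_len(n_lags)] / cnts[seq_len(n_lags)],
                    n_pairs = cnts[seq_len(n_lags)])
  attr(out, "n_tracks") <- n_used
  attr(out, "frame_interval") <- dt
  class(out) <- c("vacf", "data.frame")
  out
}

#' Fit motility statistics to a velocity autocorrelation
#'
#' Nonlinear least squares of `Cv(t) = v^2 exp(-t / tau_c)` over lags up to
#' three times an initial 1/e-crossing estimate of `tau_c`. The diffusion
#' constant is reported two ways: the closed form `v^2 tau_c / d` and the
#' Green--Kubo numerical integral `(1/d) * trapz(Cv)` over the measured lags;
#' a relative discrepancy above 10% is flagged.
#'
#' @param cv a [velocity_autocorrelation()] result (or any data frame with
#'   columns `lag_s`, `cv_um2_s2`).
#' @param dims dimensionality d of the assay (2 for quasi-2D chambers).
#' @return An object of class `"motility_fit"`: `v_um_s`, `tau_c_s`,
#'   `diffusion_um2_s` (closed form), `diffusion_integral_um2_s`,
#'   `discrepancy`, `flagged`, `n_tracks`.
#' @examples
#' lag <- seq(0, 75, by = 1/30)
#' cv <- data.frame(lag_s = lag, cv_um2_s2 = 46^2 * exp(-lag / 15))
#' fit_motility(cv)
#' @export
fit_motility <- function(cv, dims = 2) {
  lag <- cv$lag_s; y <- cv$cv_um2_s2
  cv0 <- y[1]
  if (!is.finite(cv0) || cv0 <= 0) stop_invalid("Cv(0) must be positive")
  below <- which(y < cv0 / exp(1))
  if (!length(below)) {
    return(structure(list(v_um_s = sqrt(cv0), tau_c_s = NA_real_,
                          tau_lower_bound_s = max(lag),
                          diffusion_um2_s = NA_real_,
                          diffusion_integral_um2_s = trapz(lag, y) / dims,
                          discrepancy = NA_real_, flagged = TRUE,
                          n_tracks = attr(cv, "n_tracks"), cv = cv,
                          fit = NULL),
                     class = "motility_fit"))
  }
  tau0 <- lag[below[1]]
  sel <- lag <= 3 * tau0
  dfit <- data.frame(lag = lag[sel], y = y[sel])
  fit <- minpack.lm::nlsLM(y ~ v2 * exp(-lag / tau),
                           data = dfit,
                           start = list(v2 = cv0, tau = max(tau0, lag[2])),
                           lower = c(v2 = 0, tau = lag[2] / 10))
  v2 <- unname(coef(fit)["v2"]); tau <- unname(coef(fit)["tau"])
  d_closed <- v2 * tau / dims
  d_int <- trapz(lag, y) / dims
  disc <- abs(d_int - d_closed) / d_closed
  structure(list(v_um_s = sqrt(v2), tau_c_s = tau,
                 tau_lower_bound_s = NA_real_,
                 diffusion_um2_s = d_closed,
                 diffusion_integral_um2_s = d_int,
                 discrepancy = disc, flagged = disc > 0.1,
                 n_tracks = attr(cv, "n_tracks"), cv = cv, fit = fit),
            class = "motility_fit")
}

#' @export
print.motility_fit <- function(x, ...) {
  cat("Motility statistics (VACF fit)\n")
  cat(sprintf("  v = %.3g um/s, tau_c = %.3g s\n", x$v_um_s, x$tau_c_s))
  cat(sprintf("  D = %.4g um^2/s (closed form), %.4g um^2/s (Green-Kubo)%s\n",
              x$diffusion_um2_s, x$diffusion_integral_um2_s,
              if (isTRUE(x$flagged)) "  [discrepancy > 10%]" else ""))
  if (!is.null(x$n_tracks)) cat(sprintf("  tracks: %d\n", x$n_tracks))
  invisible(x)
}

#' @export
coef.motility_fit <- function(object, ...) {
  c(v_um_s = object$v_um_s, tau_c_s = object$tau_c_s,
    D_um2_s = object$diffusion_um2_s)
}
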