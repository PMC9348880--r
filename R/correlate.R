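#' Two-time correlation map of a Q ring
#'
#' Correlates the speckle intensities of one Q ring pixelwise between all
#' pairs of frames:
#' \deqn{C(t_1, t_2) = \frac{\langle I_p(t_1) I_p(t_2)\rangle_p}
#'   {\langle I_p(t_1)\rangle_p \langle I_p(t_2)\rangle_p},}
#' with \eqn{\langle\cdot\rangle_p} the average over the mask pixels. The
#' result is symmetric by construction; its diagonal carries the speckle
#' contrast (2 for fully coherent static speckle with Gaussian statistics)
#' and the width of the band around the diagonal encodes the instantaneous
#' correlation time of the dynamics.
#'
#' @param frames Either a 3D array (\code{n_t x n x n}) of centred speckle
#'   intensities or a list of \code{speckle_frame} objects.
#' @param mask Integer vector of linear pixel indices (see
#'   \code{\link{ring_mask}}).
#' @param times Optional frame time stamps (defaults to frame index - 1).
#' @param q_center,dq Ring metadata recorded on the result.
#' @param source One of \code{"simulated"}, \code{"experimental"},
#'   \code{"fixture"}.
#' @return A \code{ttc_map}: list with \code{values} (symmetric matrix),
#'   \code{times}, \code{ring_intensity} (per-frame mask mean),
#'   \code{q_center}, \code{dq}, \code{source}, \code{crop_index} (NULL
#'   until cropped).
#' @export
compute_ttc <- function(frames, mask, times = NULL, q_center = NA_real_,
                        dq = NA_real_, source = "simulated") {
  if (is.list(frames) && !is.array(frames)) {
    mat <- t(vapply(frames, function(f) f$intensity[mask], numeric(length(mask))))
    if (is.null(times)) times <- vapply(frames, `[[`, numeric(1), "time")
  } else {
    stopifnot(length(dim(frames)) == 3)
    n_t <- dim(frames)[1]
    flat <- matrix(frames, nrow = n_t)  # n_t x (n*n), frame-major rows
    mat <- flat[, mask, drop = FALSE]
  }
  n_t <- nrow(mat)
  if (n_t < 2) {
    stop(errorCondition("need at least 2 frames for a TTC",
                        class = "specklematch_input_error"))
  }
  if (length(mask) < 1) {
    stop(errorCondition("empty pixel mask", class = "specklematch_input_error"))
  }
  mi <- rowMeans(mat)
  if (any(mi <= 0)) {
    stop(errorCondition("zero mean intensity in at least one frame",
                        class = "specklematch_degenerate_error"))
  }
  cross <- tcrossprod(mat) / ncol(mat)
  values <- cross / outer(mi, mi)
  values <- (values + t(values)) / 2  # enforce exact symmetry vs round-off
  if (is.null(times)) times <- seq_len(n_t) - 1
  new_ttc_map(values, times, ring_intensity = mi, q_center = q_center,
              dq = dq, source = source)
}

new_ttc_map <- function(values, times, ring_intensity, q_center, dq, source,
                        crop_index = NULL, beta = NULL) {
  structure(list(values = values, times = times,
                 ring_intensity = ring_intensity,
                 q_center = q_center, dq = dq, source = source,
                 crop_index = crop_index, beta = beta),
            class = "ttc_map")
}

#' @export
print.ttc_map <- function(x, ...) {
  cat(sprintf("<ttc_map> %dx%d frames, q = %g (dq = %g), source = %s\n",
              nrow(x$values), ncol(x$values), x$q_center, x$dq, x$source))
  if (!is.null(x$crop_index)) cat(sprintf("  cropped at frame %d\n", x$crop_index))
  invisible(x)
}

#' TTC maps for a simulated trajectory, one per Q ring
#'
#' Converts every snapshot to a speckle pattern and computes one TTC per
#' ring. Ring centres are \code{n_rings} (near-)evenly spaced integer radii
#' across the ramp domain, with widths from the ramp.
#'
#' @param traj A \code{ch_trajectory}.
#' @param n_rings Number of Q rings (production default 20).
#' @param ramp A \code{\link{ring_ramp}} delimiting the usable radius range.
#' @return List of \code{ttc_map}, ordered by increasing \code{q_center}.
#' @export
ttc_from_trajectory <- function(traj, n_rings = 20, ramp = ring_ramp()) {
  q_centers <- unique(round(seq(ramp$q_lo, ramp$q_hi, length.out = n_rings)))
  n_snap <- dim(traj$psi)[1]
  n <- dim(traj$psi)[2]
  stack <- array(NA_real_, c(n_snap, n, n))
  for (i in seq_len(n_snap)) {
    stack[i, , ] <- speckle_pattern(trajectory_field(traj, i))$intensity
  }
  lapply(q_centers, function(qc) {
    mask <- ring_mask(qc, n, ramp)
    compute_ttc(stack, mask, times = traj$times, q_center = qc,
                dq = ring_width(qc, ramp), source = "simulated")
  })
}

#' Crop a TTC at the ring-intensity maximum
#'
#' Simulated TTCs show a broad slow block at early times, reflecting the
#' still-homogeneous solution before droplets form; experimental maps lack
#' it because the quench precedes acquisition. Cropping both at the time
#' where the ring intensity peaks removes that block and aligns the
#' coarsening stages. Ties in the maximum resolve to the earliest frame.
#'
#' @param ttc A \code{ttc_map}.
#' @param ring_intensity Per-frame mean ring intensity; defaults to the
#'   series recorded on the map.
#' @param min_frames Minimum number of frames that must survive the crop.
#' @param rel_tol With the default 0, crop exactly at the (first) maximum.
#'   A positive value crops at the first frame where the intensity reaches
#'   \code{(1 - rel_tol)} of its maximum, which is robust when the series
#'   plateaus (arrested coarsening) and speckle noise scatters the argmax.
#' @param smooth_window Odd width of a centred moving average applied to
#'   the intensity series before peak detection (1 = no smoothing).
#' @param cap If TRUE, never crop later than \code{n - min_frames + 1}
#'   frames from the end, instead of raising a too-short error; intended
#'   for library generation where plateaued rings would otherwise abort a
#'   whole run.
#' @return The cropped \code{ttc_map} with \code{crop_index} set to the
#'   first retained frame (1-based).
#' @export
crop_at_intensity_peak <- function(ttc, ring_intensity = NULL, min_frames = 8,
                                   rel_tol = 0, smooth_window = 1,
                                   cap = FALSE) {
  if (is.null(ring_intensity)) ring_intensity <- ttc$ring_intensity
  n_t <- nrow(ttc$values)
  stopifnot(length(ring_intensity) == n_t)
  ri <- ring_intensity
  if (smooth_window > 1) ri <- moving_average(ri, smooth_window)
  t_peak <- if (rel_tol > 0) {
    which(ri >= (1 - rel_tol) * max(ri))[1]
  } else {
    which.max(ri)  # first occurrence on ties
  }
  if (cap) t_peak <- min(t_peak, n_t - min_frames + 1L)
  keep <- t_peak:n_t
  if (length(keep) < min_frames) {
    stop(errorCondition(
      sprintf("cropping at frame %d would leave %d < %d frames",
              t_peak, length(keep), min_frames),
      class = "specklematch_too_short_error"))
  }
  new_ttc_map(ttc$values[keep, keep, drop = FALSE], ttc$times[keep],
              ring_intensity[keep], ttc$q_center, ttc$dq, ttc$source,
              crop_index = t_peak, beta = ttc$beta)
}

#' Replace the TTC diagonal by its neighbouring off-diagonals
#'
#' The equal-time values of an experimental TTC are inflated by shot
#' noise (and carry no dynamical information beyond the contrast, which
#' the off-diagonals already provide). This replaces each diagonal entry
#' with the mean of its adjacent off-diagonal values, a convention
#' applied to both experimental and simulated maps before encoding so
#' the network never learns from the distorted diagonal.
#'
#' @param ttc A \code{ttc_map} with at least 2 frames.
#' @return The \code{ttc_map} with a smoothed diagonal.
#' @export
smooth_diagonal <- function(ttc) {
  v <- ttc$values
  n <- nrow(v)
  stopifnot(n >= 2)
  up <- c(v[cbind(1:(n - 1), 2:n)], v[n - 1, n])
  lo <- c(v[2, 1], v[cbind(2:n, 1:(n - 1))])
  diag(v) <- (up + lo) / 2
  out <- ttc
  out$values <- v
  out
}

# Centred moving average with shrinking windows at the edges.
moving_average <- function(x, w) {
  h <- w %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Crop a TTC to a time window
#'
#' Retains frames with time stamps inside \code{[t_start, t_end]}. Used by
#' the matcher to map the experimental time axis onto the simulation
#' timescale.
#'
#' @param ttc A \code{ttc_map}.
#' @param t_start,t_end Window bounds in the map's own time units.
#' @param min_frames Minimum surviving frame count.
#' @return The cropped \code{ttc_map}.
#' @export
crop_time_window <- function(ttc, t_start, t_end, min_frames = 8) {
  keep <- which(ttc$times >= t_start & ttc$times <= t_end)
  if (length(keep) < min_frames) {
    stop(errorCondition(
      sprintf("window [%g, %g] keeps %d < %d frames", t_start, t_end,
              length(keep), min_frames),
      class = "specklematch_too_short_error"))
  }
  new_ttc_map(ttc$values[keep, keep, drop = FALSE], ttc$times[keep],
              ttc$ring_intensity[keep], ttc$q_center, ttc$dq, ttc$source,
              crop_index = keep[1], beta = ttc$beta)
}

#' Normalize a TTC to unit speckle visibility
#'
#' Experimental TTCs have contrast \eqn{\beta < 1} because the beam is
#' only partially coherent, while the simulation assumes fully coherent
#' scattering. The visibility is estimated from the mean of the two first
#' off-diagonals of \eqn{C - 1} -- the diagonal itself is unusable because
#' shot noise inflates it -- and the map is rescaled as
#' \eqn{C' = 1 + (C - 1)/\beta} so that off-diagonal contrast matches the
#' coherent simulation scale.
#'
#' @param ttc A \code{ttc_map} with at least 3 frames.
#' @return The normalized \code{ttc_map}; the estimated \code{beta} is
#'   recorded on the result.
#' @export
normalize_visibility <- function(ttc) {
  v <- ttc$values
  n_t <- nrow(v)
  if (n_t < 3) {
    stop(errorCondition("need >= 3 frames to estimate visibility",
                        class = "specklematch_input_error"))
  }
  off1 <- v[cbind(1:(n_t - 1), 2:n_t)]
  off2 <- v[cbind(2:n_t, 1:(n_t - 1))]
  beta <- mean(c(off1, off2)) - 1
  if (!is.finite(beta) || beta <= 0) {
    stop(errorCondition("non-positive off-diagonal contrast; cannot normalize",
                        class = "specklematch_no_contrast_error"))
  }
  new_ttc_map(1 + (v - 1) / beta, ttc$times, ttc$ring_intensity,
              ttc$q_center, ttc$dq, ttc$source, crop_index = ttc$crop_index,
              beta = beta)
}

# Area-average resampling matrix mapping n samples onto s bins: entry
# (i, j) is the fraction of output cell i covered by input cell j.
resample_weights <- function(n, s) {
  w <- matrix(0, s, n)
  edges_out <- seq(0, n, length.out = s + 1)
  for (i in seq_len(s)) {
    lo <- edges_out[i]
    hi <- edges_out[i + 1]
    j0 <- floor(lo) + 1
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n)) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) w[i, j] <- overlap
    }
  }
  w / (n / s)
}

#' Downsample a TTC to the network input resolution
#'
#' Area-average resampling of the (cropped) map to \code{s x s}. The
#' kernel is separable and symmetric, so symmetric maps stay symmetric.
#' Upscaling is refused: the auto-encoder input must not contain invented
#' detail.
#'
#' @param ttc A \code{ttc_map}.
#' @param s Output side length (default 64).
#' @return A \code{preprocessed_ttc}: list with \code{values} (s x s) and
#'   provenance (\code{crop_index}, original size, visibility \code{beta}
#'   if one was estimated, ring metadata).
#' @export
rescale_ttc <- function(ttc, s = 64) {
  n_t <- nrow(ttc$values)
  if (s > n_t) {
    stop(errorCondition(
      sprintf("refusing to upscale a %d-frame TTC to %d pixels", n_t, s),
      class = "specklematch_input_error"))
  }
  w <- resample_weights(n_t, s)
  values <- w %*% ttc$values %*% t(w)
  structure(list(
    values = values,
    s = s,
    crop_index = ttc$crop_index,
    original_n = n_t,
    beta = ttc$beta,
    q_center = ttc$q_center,
    dq = ttc$dq,
    source = ttc$source
  ), class = "preprocessed_ttc")
}

#' @export
print.preprocessed_ttc <- function(x, ...) {
  cat(sprintf("<preprocessed_ttc> %dx%d (from %d frames), q = %g, source = %s\n",
              x$s, x$s, x$original_n, x$q_center, x$source))
  invisible(x)
}

#' Average preprocessed TTCs elementwise
#'
#' Used to average maps from simulations that differ only in their initial
#' noise realization, improving robustness of the training library.
#'
#' @param ttcs List of \code{preprocessed_ttc} of identical size.
#' @return A single \code{preprocessed_ttc}.
#' @export
average_preprocessed <- function(ttcs) {
  stopifnot(length(ttcs) >= 1)
  s <- ttcs[[1]]$s
  stopifnot(all(vapply(ttcs, `[[`, numeric(1), "s") == s))
  out <- ttcs[[1]]
  out$values <- Reduce(`+`, lapply(ttcs, `[[`, "values")) / length(ttcs)
  out
}
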