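#' Speckle pattern of an order-parameter field
#'
#' Under fully coherent illumination the far-field scattering intensity is
#' the squared modulus of the Fourier transform of the density field. This
#' returns \eqn{|\mathcal{F}\Psi|^2} with the zero-frequency (DC) pixel
#' shifted to the array centre, mimicking a detector image centred on the
#' direct beam.
#'
#' @param field A \code{ch_field} (square lattice).
#' @return A \code{speckle_frame}: list with \code{intensity} (non-negative
#'   matrix, DC at centre) and \code{time}.
#' @export
speckle_pattern <- function(field) {
  psi <- field$values
  stopifnot(nrow(psi) == ncol(psi))
  intensity <- fftshift2(Mod(fft2(psi))^2)
  structure(list(intensity = intensity, time = field$time),
            class = "speckle_frame")
}

# Move the zero-frequency component to the centre pixel (n/2 + 1, n/2 + 1).
fftshift2 <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  x[c((n / 2 + 1):n, 1:(n / 2)), c((m / 2 + 1):m, 1:(m / 2))]
}

# Euclidean distance of each pixel from the DC pixel of a centred frame.
radius_matrix <- function(n) {
  centre <- n / 2 + 1
  d <- (seq_len(n) - centre)
  sqrt(outer(d^2, d^2, `+`))
}

#' Azimuthal intensity profile
#'
#' Averages a centred speckle frame over rings of constant pixel radius:
#' for each integer radius \code{q_sim}, the mean intensity over pixels
#' whose rounded distance from the DC pixel equals \code{q_sim}. The DC
#' pixel is always excluded. This is the standard isotropic
#' structure-factor estimator; during spinodal decomposition it develops a
#' peak that moves to smaller \code{q_sim} as domains coarsen.
#'
#' @param frame A \code{speckle_frame}.
#' @return A tibble with columns \code{q_sim} (integer radii from 1 to
#'   \code{grid_n/2 - 1}), \code{intensity} and \code{time}.
#' @export
azimuthal_profile <- function(frame) {
  intens <- frame$intensity
  n <- nrow(intens)
  r <- round(radius_matrix(n))
  centre <- n / 2 + 1
  r[centre, centre] <- -1  # exclude DC from every bin
  radii <- 1:(n / 2 - 1)
  keep <- r >= 1 & r <= max(radii)
  means <- tapply(intens[keep], factor(r[keep], levels = radii), mean)
  tibble::tibble(
    q_sim = radii,
    intensity = as.numeric(means),
    time = frame$time
  )
}

#' Azimuthal profiles for a whole trajectory
#'
#' @param traj A \code{ch_trajectory}.
#' @return A long tibble with columns \code{q_sim}, \code{intensity},
#'   \code{time}, one row per (snapshot, radius).
#' @export
intensity_profiles <- function(traj) {
  n_snap <- dim(traj$psi)[1]
  purrr::map_dfr(seq_len(n_snap), function(i) {
    azimuthal_profile(speckle_pattern(trajectory_field(traj, i)))
  })
}

#' Ring-width ramp
#'
#' Experimental XPCS analyses widen the Q integration rings linearly with
#' Q to compensate for the lower photon counts at higher Q. The ramp is a
#' linear map from width \code{w_lo} at radius \code{q_lo} to \code{w_hi}
#' at \code{q_hi} (defaults 0.7 and 3 pixels).
#'
#' @param q_lo,q_hi Radii (pixels) where the ramp is anchored.
#' @param w_lo,w_hi Ring widths (pixels) at the anchors.
#' @return A \code{ring_ramp} object.
#' @export
ring_ramp <- function(q_lo = 5, q_hi = 60, w_lo = 0.7, w_hi = 3.0) {
  stopifnot(q_hi > q_lo, w_lo > 0, w_hi > 0)
  structure(list(q_lo = q_lo, q_hi = q_hi, w_lo = w_lo, w_hi = w_hi),
            class = "ring_ramp")
}

#' Ring width at a given radius
#'
#' @param q_center Radius (pixels), within \code{[q_lo, q_hi]}.
#' @param ramp A \code{\link{ring_ramp}}.
#' @return Ring width \eqn{\Delta q} in pixels.
#' @export
ring_width <- function(q_center, ramp) {
  if (any(q_center < ramp$q_lo - 1e-9) || any(q_center > ramp$q_hi + 1e-9)) {
    stop(errorCondition("q_center outside the ring-ramp domain",
                        class = "specklematch_config_error"))
  }
  ramp$w_lo + (ramp$w_hi - ramp$w_lo) *
    (q_center - ramp$q_lo) / (ramp$q_hi - ramp$q_lo)
}

#' Pixel mask of a Q ring
#'
#' Selects the pixels of a centred frame whose Euclidean distance from the
#' DC pixel lies within \eqn{\Delta q/2} of \code{q_center}, with
#' \eqn{\Delta q} given by the ramp. The DC pixel is never included; the
#' mask is symmetric under point inversion about the centre.
#'
#' @param q_center Ring centre radius in pixels (may be fractional).
#' @param grid_n Lattice side length.
#' @param ramp A \code{\link{ring_ramp}}.
#' @return Integer vector of linear pixel indices into the centred frame.
#' @export
ring_mask <- function(q_center, grid_n, ramp = ring_ramp()) {
  dq <- ring_width(q_center, ramp)
  r <- radius_matrix(grid_n)
  centre <- grid_n / 2 + 1
  r[centre, centre] <- Inf  # DC excluded
  idx <- which(abs(r - q_center) <= dq / 2)
  if (length(idx) == 0) {
    stop(errorCondition(
      sprintf("ring mask at q = %g with width %g contains no pixels", q_center, dq),
      class = "specklematch_config_error"))
  }
  idx
}
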