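#' Simulate a TTC training library
#'
#' Generates the simulation side of the matching problem: parameter pairs
#' \code{(eps, psi_gel)} drawn over the training intervals, one
#' Cahn--Hilliard run per pair and noise realization, TTCs for every Q
#' ring, cropping at the ring-intensity maximum, downsampling to the
#' network input size, and averaging of the preprocessed maps over the
#' noise realizations. The production-scale design is 12000 parameter
#' pairs times 5 noise realizations with 20 rings on a 256x256 grid; all
#' sizes are arguments so the library can be scaled to the problem at
#' hand.
#'
#' @param n_pairs Number of \code{(eps, psi_gel)} parameter pairs.
#' @param n_noise Noise realizations averaged per pair (default 5).
#' @param n_rings Number of Q rings (default 20).
#' @param eps_range,psi_gel_range Sampling intervals for the quench depth
#'   and gelation point.
#' @param sampling \code{"uniform"} (random pairs, the production design)
#'   or \code{"grid"} (regular grid, useful for small libraries where
#'   coverage matters more than randomisation).
#' @param s Preprocessed TTC side length.
#' @param ramp A \code{\link{ring_ramp}} delimiting the ring radii.
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @param n_augment Number of extra training-only variants per map, each
#'   preprocessed from a jittered sub-window of the cropped range. The
#'   variants teach the encoder to represent the dynamics rather than the
#'   acquisition window, which stabilises the time-window calibration of
#'   the matcher; they never enter the latent lookup table.
#' @param min_frames Minimum frames surviving the intensity-peak crop.
#' @param ... Simulation settings forwarded to \code{\link{sim_config}}
#'   (e.g. \code{grid_n}, \code{dt}, \code{n_steps}, \code{snapshot_every}).
#' @return A \code{ttc_library}: list with \code{params} (tibble of
#'   \code{eps}, \code{psi_gel}), \code{rings}, \code{ttcs} (per pair, a
#'   list of \code{preprocessed_ttc} per ring), and the generation
#'   settings.
#' @export
simulate_ttc_library <- function(n_pairs = 12000, n_noise = 5, n_rings = 20,
                                 eps_range = c(0.4, 0.9),
                                 psi_gel_range = c(0.55, 1.0),
                                 sampling = c("uniform", "grid"),
                                 s = 64, ramp = ring_ramp(), seed = 1L,
                                 n_augment = 0, min_frames = 8, ...) {
  sampling <- match.arg(sampling)
  sim_args <- list(...)
  proto <- do.call(sim_config, c(list(epsilon = mean(eps_range),
                                      psi_gel = mean(psi_gel_range)), sim_args))
  if (min(psi_gel_range) <= proto$psi0_mean + 0.1) {
    stop(errorCondition(
      "psi_gel range must stay above psi0_mean + 0.1 to avoid arrest before droplet formation",
      class = "specklematch_config_error"))
  }
  params <- withr_seed(seed, {
    if (sampling == "uniform") {
      tibble::tibble(
        eps = stats::runif(n_pairs, eps_range[1], eps_range[2]),
        psi_gel = stats::runif(n_pairs, psi_gel_range[1], psi_gel_range[2])
      )
    } else {
      n_e <- ceiling(sqrt(n_pairs))
      n_p <- ceiling(n_pairs / n_e)
      g <- expand.grid(
        eps = seq(eps_range[1], eps_range[2], length.out = n_e),
        psi_gel = seq(psi_gel_range[1], psi_gel_range[2], length.out = n_p)
      )
      tibble::as_tibble(g[seq_len(min(n_pairs, nrow(g))), ])
    }
  })

  q_centers <- unique(round(seq(ramp$q_lo, ramp$q_hi, length.out = n_rings)))
  min_frames <- max(min_frames, s)  # the downsampler refuses upscaling
  preprocess <- function(m) {
    # same conventions as the experimental path: diagonal replaced by its
    # neighbours, then unit off-diagonal contrast. Finite rings make the
    # coherent contrast ring-dependent, and the encoder must see both
    # sides on one scale.
    rescale_ttc(normalize_visibility(smooth_diagonal(m)), s)
  }
  ttcs <- vector("list", nrow(params))
  augmented <- list()
  for (i in seq_len(nrow(params))) {
    per_rep <- vector("list", n_noise)
    for (r in seq_len(n_noise)) {
      cfg <- do.call(sim_config, c(list(
        epsilon = params$eps[i], psi_gel = params$psi_gel[i],
        seed = derive_seed(seed, i, r)
      ), sim_args))
      traj <- run_simulation(cfg)
      maps <- ttc_from_trajectory(traj, n_rings = n_rings, ramp = ramp)
      cropped <- lapply(maps, function(m) {
        crop_at_intensity_peak(m, min_frames = min_frames, rel_tol = 0.05,
                               smooth_window = 5, cap = TRUE)
      })
      per_rep[[r]] <- lapply(cropped, preprocess)
      if (n_augment > 0) {
        for (j in seq_along(cropped)) {
          n_c <- nrow(cropped[[j]]$values)
          for (a in seq_len(n_augment)) {
            # deterministic window jitter per (pair, rep, ring, variant)
            u0 <- ((i * 131L + r * 17L + j * 7L + a * 37L) %% 97L) / 97
            u1 <- ((i * 113L + r * 29L + j * 11L + a * 41L) %% 89L) / 89
            a0 <- 1L + as.integer(floor(u0 * 0.35 * n_c))
            a1 <- n_c - as.integer(floor(u1 * 0.25 * n_c))
            a0 <- min(a0, max(1L, n_c - s + 1L))
            a1 <- min(max(a1, a0 + s - 1L), n_c)
            sub <- crop_time_window(cropped[[j]],
                                    cropped[[j]]$times[a0],
                                    cropped[[j]]$times[a1],
                                    min_frames = s)
            augmented[[length(augmented) + 1]] <- preprocess(sub)
          }
        }
      }
    }
    ttcs[[i]] <- lapply(seq_along(q_centers), function(j) {
      average_preprocessed(lapply(per_rep, `[[`, j))
    })
  }
  structure(list(params = params, rings = q_centers, ttcs = ttcs,
                 augmented = augmented, s = s,
                 ramp = ramp, n_noise = n_noise, n_augment = n_augment,
                 sim_args = sim_args, seed = seed),
            class = "ttc_library")
}

# Deterministic per-run seed below 2^31.
derive_seed <- function(seed, i, r) {
  as.integer((as.numeric(seed) * 2654435L + i * 7919L + r * 104729L) %% 2147483647L)
}

#' @export
print.ttc_library <- function(x, ...) {
  cat(sprintf("<ttc_library> %d parameter pairs x %d rings (s = %d, %d noise reps)\n",
              nrow(x$params), length(x$rings), x$s, x$n_noise))
  invisible(x)
}

#' Flatten a TTC library into a training list
#'
#' @param library A \code{ttc_library}.
#' @param include_augmented Also include the training-only window-jittered
#'   variants, if the library was built with them.
#' @return A flat list of \code{preprocessed_ttc}, pairs varying slowest.
#' @export
library_ttcs <- function(library, include_augmented = TRUE) {
  out <- unlist(library$ttcs, recursive = FALSE)
  if (include_augmented && length(library$augmented) > 0) {
    out <- c(out, library$augmented)
  }
  out
}
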