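#' Specification of a pseudo-experimental quench series
#'
#' Defines the ground truth and degradation model for a synthetic stand-in
#' for an XPCS quench series: several quench temperatures, each measured
#' at several Q values, with reduced speckle contrast and a shot-noise
#' distorted diagonal. Conditions are ordered by increasing nominal quench
#' temperature, so the true quench depth \code{eps_true} must be
#' non-increasing (shallower quenches at higher temperature) while the
#' true gelation point rises, mirroring gelation at higher concentration
#' for shallow quenches.
#'
#' @param n_conditions Number of quench temperatures (default 6).
#' @param q_values_um Q values per condition in inverse micrometres
#'   (default 5 values evenly spaced in \code{[7.02, 8.2]}).
#' @param eps_true True quench depths, ordered by increasing temperature
#'   (non-increasing values).
#' @param psi_gel_true True gelation points per condition.
#' @param c_q_true True pixel-to-inverse-micrometre conversion,
#'   \code{Q_um = c_q * q_pixel}.
#' @param beta_true Speckle visibility in \code{(0, 1]} applied to the
#'   coherent simulated contrast.
#' @param diag_noise Amplitude of the positive uniform noise added to the
#'   TTC diagonal (emulating shot-noise distortion).
#' @param exposure_s,period_s Frame exposure and repetition period of the
#'   emulated acquisition (0.02 s exposures every 0.12 s).
#' @param n_frames_exp Nominal number of acquired frames (bookkeeping for
#'   the experimental time axis; default 4000, i.e. 480 s).
#' @param seed Master seed.
#' @return A \code{fixture_spec} object.
#' @export
fixture_spec <- function(n_conditions = 6,
                         q_values_um = seq(7.02, 8.2, length.out = 5),
                         eps_true = seq(0.9, 0.4, length.out = n_conditions),
                         psi_gel_true = seq(0.6, 0.95, length.out = n_conditions),
                         c_q_true = 0.35,
                         beta_true = 0.3,
                         diag_noise = 0.3,
                         exposure_s = 0.02,
                         period_s = 0.12,
                         n_frames_exp = 4000,
                         seed = 1L) {
  if (length(eps_true) != n_conditions || length(psi_gel_true) != n_conditions) {
    stop(errorCondition("need one (eps, psi_gel) truth pair per condition",
                        class = "specklematch_config_error"))
  }
  if (any(diff(eps_true) > 1e-12)) {
    stop(errorCondition(
      "eps_true must be non-increasing with quench temperature",
      class = "specklematch_config_error"))
  }
  if (beta_true <= 0 || beta_true > 1) {
    stop(errorCondition("beta_true must lie in (0, 1]",
                        class = "specklematch_config_error"))
  }
  if (anyDuplicated(q_values_um)) {
    stop(errorCondition("duplicate Q values requested",
                        class = "specklematch_config_error"))
  }
  structure(list(n_conditions = as.integer(n_conditions),
                 q_values_um = q_values_um, eps_true = eps_true,
                 psi_gel_true = psi_gel_true, c_q_true = c_q_true,
                 beta_true = beta_true, diag_noise = diag_noise,
                 exposure_s = exposure_s, period_s = period_s,
                 n_frames_exp = as.integer(n_frames_exp),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a pseudo-experimental TTC dataset
#'
#' For each condition, runs the simulator at the true parameters, computes
#' TTCs at the ring radii implied by the true Q calibration
#' (\code{q_pixel = Q_um / c_q_true}), reduces the contrast by
#' \code{beta_true}, corrupts the diagonal with positive noise, and
#' relabels the time axis to the experimental acquisition schedule. The
#' truth block is kept separate from the observable inputs so the matcher
#' can be evaluated blind.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param ramp A \code{\link{ring_ramp}}; all implied ring radii must fall
#'   inside its domain.
#' @param ... Simulation settings forwarded to \code{\link{sim_config}}.
#' @return A \code{fixture_dataset}: list with \code{ttcs} (list of
#'   \code{ttc_map}, source \code{"fixture"}), \code{meta} (tibble of
#'   condition index and Q value per map), \code{times}, and a
#'   \code{truth} list (\code{eps}, \code{psi_gel}, \code{c_q},
#'   \code{beta}, per-condition crop frame of the source simulation).
#' @export
make_fixtures <- function(spec = fixture_spec(), ramp = ring_ramp(), ...) {
  q_sim <- spec$q_values_um / spec$c_q_true
  if (any(q_sim < ramp$q_lo) || any(q_sim > ramp$q_hi)) {
    stop(errorCondition(
      sprintf("implied ring radii [%.2f, %.2f] fall outside the ramp domain [%g, %g]",
              min(q_sim), max(q_sim), ramp$q_lo, ramp$q_hi),
      class = "specklematch_config_error"))
  }
  sim_args <- list(...)
  ttcs <- list()
  meta <- list()
  peak_index <- integer(spec$n_conditions)
  times <- NULL
  for (ci in seq_len(spec$n_conditions)) {
    cfg <- do.call(sim_config, c(list(
      epsilon = spec$eps_true[ci], psi_gel = spec$psi_gel_true[ci],
      seed = derive_seed(spec$seed, ci, 0L)
    ), sim_args))
    traj <- run_simulation(cfg)
    n_snap <- dim(traj$psi)[1]
    n <- cfg$grid_n
    stack <- array(NA_real_, c(n_snap, n, n))
    for (i in seq_len(n_snap)) {
      stack[i, , ] <- speckle_pattern(trajectory_field(traj, i))$intensity
    }
    t_exp <- seq(0, (spec$n_frames_exp - 1) * spec$period_s,
                 length.out = n_snap)
    times <- t_exp
    peaks <- integer(length(spec$q_values_um))
    cond_ttcs <- withr_seed(derive_seed(spec$seed, ci, 17L), {
      lapply(seq_along(spec$q_values_um), function(qi) {
        qc <- q_sim[qi]
        mask <- ring_mask(qc, n, ramp)
        ttc <- compute_ttc(stack, mask, times = t_exp, q_center = qc,
                           dq = ring_width(qc, ramp), source = "fixture")
        peaks[qi] <<- which.max(ttc$ring_intensity)
        v <- 1 + (ttc$values - 1) * spec$beta_true
        dn <- stats::runif(n_snap, 0, spec$diag_noise)
        diag(v) <- diag(v) + dn
        new_ttc_map(v, t_exp, ttc$ring_intensity, q_center = NA_real_,
                    dq = NA_real_, source = "fixture")
      })
    })
    peak_index[ci] <- as.integer(stats::median(peaks))
    for (qi in seq_along(cond_ttcs)) {
      ttcs[[length(ttcs) + 1]] <- cond_ttcs[[qi]]
      meta[[length(meta) + 1]] <- tibble::tibble(
        condition = ci, q_um = spec$q_values_um[qi])
    }
  }
  structure(list(
    ttcs = ttcs,
    meta = dplyr::bind_rows(meta),
    times = times,
    truth = list(eps = spec$eps_true, psi_gel = spec$psi_gel_true,
                 c_q = spec$c_q_true, beta = spec$beta_true,
                 peak_index = peak_index),
    spec = spec
  ), class = "fixture_dataset")
}

#' @export
print.fixture_dataset <- function(x, ...) {
  cat(sprintf("<fixture_dataset> %d TTCs: %d conditions x %d Q values, %d frames\n",
              length(x$ttcs), x$spec$n_conditions,
              length(x$spec$q_values_um), length(x$times)))
  invisible(x)
}

#' Strip the hidden truth from a fixture dataset
#'
#' Returns the observable inputs only, enforcing the blind-evaluation
#' protocol: the matcher never sees the generating parameters.
#'
#' @param dataset A \code{fixture_dataset}.
#' @return The dataset with the \code{truth} block removed.
#' @export
fixture_inputs <- function(dataset) {
  dataset$truth <- NULL
  dataset
}

#' Assemble an ordered experimental TTC set
#'
#' Flattens per-condition TTC collections into the ordered list consumed
#' by the matcher: one map per (condition, Q) pair, conditions ordered by
#' quench temperature, Q values as requested. Missing pairs and duplicate
#' Q requests are rejected.
#'
#' @param dataset A \code{fixture_dataset} (or compatible list with
#'   \code{ttcs} and \code{meta}).
#' @param q_values Q values to select per condition; defaults to all
#'   present.
#' @return List with \code{ttcs} (ordered list) and \code{meta} (tibble of
#'   condition and \code{q_um}).
#' @export
assemble_experimental_set <- function(dataset, q_values = NULL) {
  meta <- dataset$meta
  if (is.null(q_values)) q_values <- sort(unique(meta$q_um))
  if (anyDuplicated(q_values)) {
    stop(errorCondition("duplicate Q values requested",
                        class = "specklematch_input_error"))
  }
  conditions <- sort(unique(meta$condition))
  sel <- list()
  out_meta <- list()
  for (ci in conditions) {
    for (q in q_values) {
      j <- which(meta$condition == ci & abs(meta$q_um - q) < 1e-9)
      if (length(j) != 1) {
        stop(errorCondition(
          sprintf("missing TTC for condition %s at Q = %g", ci, q),
          class = "specklematch_input_error"))
      }
      sel[[length(sel) + 1]] <- dataset$ttcs[[j]]
      out_meta[[length(out_meta) + 1]] <- tibble::tibble(condition = ci, q_um = q)
    }
  }
  list(ttcs = sel, meta = dplyr::bind_rows(out_meta))
}
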