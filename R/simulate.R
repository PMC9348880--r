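#' Simulation configuration for spinodal decomposition with gelation
#'
#' Bundles every parameter of the two-dimensional Cahn--Hilliard model with
#' concentration-dependent mobility. The order parameter \eqn{\Psi} is a
#' rescaled local protein concentration: \eqn{\Psi = 0} is the critical
#' composition and positive values denote the dense phase. The free-energy
#' density is the Ginzburg--Landau quartic
#' \deqn{f(\Psi) = -\tfrac{\epsilon}{2}\Psi^2 + \tfrac14 \Psi^4 +
#'   \tfrac{\kappa}{2}|\nabla\Psi|^2,}
#' where \eqn{\epsilon > 0} is the reduced quench depth (proportional to
#' \eqn{(T_c - T)/T_c}) and \eqn{\kappa} penalises interfaces. Gelation of
#' the dense phase enters through the mobility \code{\link{mobility}}, which
#' collapses from \code{m_max} to \code{m_min} once \eqn{\Psi} exceeds the
#' gelation point \code{psi_gel}.
#'
#' @param epsilon Reduced quench depth, dimensionless, must be positive.
#'   Deeper quenches (larger \code{epsilon}) give denser droplets.
#' @param psi_gel Order parameter at which the mobility has dropped to the
#'   midpoint of its range; models the onset of dynamical arrest.
#' @param alpha Steepness of the sigmoidal mobility drop (dimensionless).
#'   Large values give the abrupt arrest characteristic of gelation.
#' @param kappa Gradient-energy coefficient; sets the interface width.
#' @param m_max,m_min Upper and lower mobility bounds, \code{m_max > m_min >= 0}.
#' @param grid_n Lattice side length in pixels; must be even and at least 16.
#' @param dt Integrator time step (simulation time units).
#' @param n_steps Number of integrator steps; the production default is
#'   10000.
#' @param psi0_mean Conserved spatial mean of the order parameter. The
#'   positive default places the system off-critical so that the minority
#'   dilute phase forms droplets rather than a bicontinuous network, while
#'   staying inside the spinodal (\code{psi0_mean < sqrt(epsilon/3)}) for
#'   every quench depth in the training interval.
#' @param noise_amp Amplitude of the uniform initial noise seeding the
#'   instability; must be positive.
#' @param seed Integer RNG seed; fixes the initial noise realization.
#' @param snapshot_every Interval, in steps, between stored field snapshots.
#'
#' @return An object of class \code{sim_config} (a validated list).
#' @seealso \code{\link{run_simulation}}, \code{\link{mobility}}
#' @export
#' @examples
#' cfg <- sim_config(epsilon = 0.9, psi_gel = 0.7, grid_n = 64, n_steps = 200)
#' cfg
sim_config <- function(epsilon,
                       psi_gel,
                       alpha = 30,
                       kappa = 1,
                       m_max = 1,
                       m_min = 1e-6,
                       grid_n = 256,
                       dt = 0.02,
                       n_steps = 10000,
                       psi0_mean = 0.3,
                       noise_amp = 0.01,
                       seed = 1L,
                       snapshot_every = 50L) {
  cfg <- list(
    epsilon = as.numeric(epsilon), psi_gel = as.numeric(psi_gel),
    alpha = as.numeric(alpha), kappa = as.numeric(kappa),
    m_max = as.numeric(m_max), m_min = as.numeric(m_min),
    grid_n = as.integer(grid_n), dt = as.numeric(dt),
    n_steps = as.integer(n_steps), psi0_mean = as.numeric(psi0_mean),
    noise_amp = as.numeric(noise_amp), seed = as.integer(seed),
    snapshot_every = as.integer(snapshot_every)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop(errorCondition(msg, class = "specklematch_config_error"))
  if (!is.finite(cfg$epsilon) || cfg$epsilon <= 0) stop_cfg("`epsilon` must be a positive number")
  if (!is.finite(cfg$alpha) || cfg$alpha <= 0) stop_cfg("`alpha` must be positive")
  if (!is.finite(cfg$kappa) || cfg$kappa <= 0) stop_cfg("`kappa` must be positive")
  if (cfg$m_min < 0 || cfg$m_max <= cfg$m_min) stop_cfg("need m_max > m_min >= 0")
  if (is.na(cfg$grid_n) || cfg$grid_n < 16 || cfg$grid_n %% 2 != 0) {
    stop_cfg("`grid_n` must be an even integer >= 16")
  }
  if (!is.finite(cfg$dt) || cfg$dt <= 0) stop_cfg("`dt` must be positive")
  if (is.na(cfg$n_steps) || cfg$n_steps < 1) stop_cfg("`n_steps` must be >= 1")
  if (!is.finite(cfg$noise_amp) || cfg$noise_amp <= 0) stop_cfg("`noise_amp` must be positive")
  if (is.na(cfg$snapshot_every) || cfg$snapshot_every < 1) stop_cfg("`snapshot_every` must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  epsilon = %g, psi_gel = %g, alpha = %g, kappa = %g\n",
              x$epsilon, x$psi_gel, x$alpha, x$kappa))
  cat(sprintf("  mobility in (%g, %g); grid %dx%d, dt = %g, %d steps\n",
              x$m_min, x$m_max, x$grid_n, x$grid_n, x$dt, x$n_steps))
  cat(sprintf("  psi0_mean = %g, noise_amp = %g, seed = %d, snapshot every %d steps\n",
              x$psi0_mean, x$noise_amp, x$seed, x$snapshot_every))
  invisible(x)
}

new_field <- function(values, time, config) {
  structure(list(values = values, time = time, config = config),
            class = "ch_field")
}

#' @export
print.ch_field <- function(x, ...) {
  cat(sprintf("<ch_field> %dx%d at t = %g, mean(psi) = %.6f\n",
              nrow(x$values), ncol(x$values), x$time, mean(x$values)))
  invisible(x)
}

#' Initial order-parameter field
#'
#' Builds the starting configuration: a uniform background at
#' \code{psi0_mean} plus uniform noise in \code{[-noise_amp, +noise_amp]}.
#' The noise is mean-subtracted so the spatial mean equals \code{psi0_mean}
#' to machine precision, which the conservative dynamics then preserve.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{ch_field}: list with \code{values} (matrix), \code{time},
#'   and the originating \code{config}.
#' @export
initialize_field <- function(config) {
  validate_sim_config(config)
  n <- config$grid_n
  eta <- withr_seed(config$seed, {
    matrix(stats::runif(n * n, -config$noise_amp, config$noise_amp), n, n)
  })
  eta <- eta - mean(eta)
  new_field(config$psi0_mean + eta, time = 0, config = config)
}

# Evaluate thunk under a temporary RNG state so package calls do not
# perturb the caller's random stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Concentration-dependent mobility
#'
#' Sigmoidal mobility modelling gelation of the dense phase:
#' \deqn{M(\Psi) = m_{\min} + (m_{\max} - m_{\min})
#'   \frac{1 - \tanh[\alpha(\Psi - \Psi_{gel})]}{2}.}
#' It decreases strictly with \eqn{\Psi}, approaches \code{m_max} in the
#' dilute phase and \code{m_min} deep in the gel, and equals the midpoint
#' \code{(m_max + m_min)/2} exactly at \code{psi_gel} (0.5 for bounds 1 and
#' 0) -- the defining property of the gelation point.
#'
#' @param psi Numeric scalar, vector or matrix of order-parameter values.
#' @param config A \code{\link{sim_config}} supplying \code{psi_gel},
#'   \code{alpha}, \code{m_max}, \code{m_min}.
#' @return Mobility values with the shape of \code{psi}.
#' @export
#' @examples
#' cfg <- sim_config(epsilon = 0.9, psi_gel = 0.7, m_max = 1, m_min = 0,
#'                   grid_n = 64, n_steps = 10)
#' mobility(0.7, cfg)  # exactly 0.5
mobility <- function(psi, config) {
  config$m_min + (config$m_max - config$m_min) *
    (1 - tanh(config$alpha * (psi - config$psi_gel))) / 2
}

# Spectral grids for a periodic lattice of side n (unit spacing).
# kx varies along the first array index, ky along the second.
spectral_plan <- function(config) {
  n <- config$grid_n
  k1 <- 2 * pi * c(0:(n / 2), -((n / 2 - 1):1)) / n
  kx <- matrix(k1, n, n)
  ky <- t(kx)
  k2 <- kx^2 + ky^2
  stab <- config$kappa * config$m_max
  list(
    kx = kx, ky = ky, k2 = k2, k4 = k2^2,
    denom = 1 + config$dt * stab * k2^2,
    stab = stab,
    const_m = isTRUE(all.equal(config$m_min, config$m_max, tolerance = 0))
  )
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Chemical potential of the Landau free energy
#'
#' Evaluates \eqn{\mu = -\epsilon\Psi + \Psi^3 - \kappa\nabla^2\Psi} with
#' the Laplacian computed spectrally under periodic boundary conditions.
#' The uniform binodal compositions \eqn{\Psi = \pm\sqrt{\epsilon}} give
#' \eqn{\mu \equiv 0}.
#'
#' @param field A \code{ch_field}.
#' @param config A \code{\link{sim_config}}.
#' @return Matrix of \eqn{\mu} values on the lattice.
#' @export
chemical_potential <- function(field, config) {
  psi <- field$values
  if (!all(is.finite(psi))) {
    stop(errorCondition("field contains non-finite values",
                        class = "specklematch_numeric_error"))
  }
  plan <- spectral_plan(config)
  lap <- Re(ifft2(-plan$k2 * fft2(psi)))
  -config$epsilon * psi + psi^3 - config$kappa * lap
}

#' Landau free energy of a field
#'
#' Lattice sum of the free-energy density
#' \eqn{-\tfrac{\epsilon}{2}\Psi^2 + \tfrac14\Psi^4 +
#' \tfrac{\kappa}{2}|\nabla\Psi|^2} with the gradient evaluated
#' spectrally. A Lyapunov functional of the dynamics: it is non-increasing
#' along trajectories for any positive mobility.
#'
#' @inheritParams chemical_potential
#' @return Scalar free energy (extensive, summed over pixels).
#' @export
free_energy <- function(field, config) {
  psi <- field$values
  plan <- spectral_plan(config)
  ph <- fft2(psi)
  gx <- Re(ifft2(1i * plan$kx * ph))
  gy <- Re(ifft2(1i * plan$ky * ph))
  sum(-config$epsilon / 2 * psi^2 + psi^4 / 4 +
        config$kappa / 2 * (gx^2 + gy^2))
}

# One semi-implicit pseudo-spectral update. The stiff linear term
# -kappa*m_max*k^4 is treated implicitly (standard stabilized splitting);
# the variable-mobility flux is evaluated as grad(mu) in Fourier space ->
# multiply by M(psi) in real space -> divergence back in Fourier space.
# The divergence vanishes identically at k = 0, so the spatial mean of psi
# is conserved exactly (we pin the DC mode to remove FFT round-off drift).
ch_step_spectral <- function(psi, psi_hat, config, plan) {
  mu_hat <- fft2(psi^3 - config$epsilon * psi) + config$kappa * plan$k2 * psi_hat
  if (plan$const_m) {
    rhs_hat <- -config$m_max * plan$k2 * mu_hat
  } else {
    gx <- Re(ifft2(1i * plan$kx * mu_hat))
    gy <- Re(ifft2(1i * plan$ky * mu_hat))
    m <- mobility(psi, config)
    rhs_hat <- 1i * plan$kx * fft2(m * gx) + 1i * plan$ky * fft2(m * gy)
  }
  rhs_hat[1, 1] <- 0 + 0i
  psi_hat_new <- (psi_hat + config$dt * (rhs_hat + plan$stab * plan$k4 * psi_hat)) /
    plan$denom
  psi_hat_new[1, 1] <- psi_hat[1, 1]
  psi_hat_new
}

#' Advance a field by one Cahn--Hilliard step
#'
#' Single semi-implicit pseudo-spectral update of
#' \eqn{\partial_t\Psi = \nabla\cdot[M(\Psi)\nabla\mu]} on the periodic
#' lattice. The update conserves the spatial mean of \eqn{\Psi} exactly.
#' Mainly useful for inspection; \code{\link{run_simulation}} drives whole
#' trajectories.
#'
#' @param field A \code{ch_field}.
#' @param config A \code{\link{sim_config}}.
#' @return The advanced \code{ch_field} at time \code{field$time + dt}.
#' @export
ch_step <- function(field, config) {
  plan <- spectral_plan(config)
  psi <- field$values
  psi_hat <- fft2(psi)
  psi_hat <- ch_step_spectral(psi, psi_hat, config, plan)
  psi <- Re(ifft2(psi_hat))
  check_stability(psi, config)
  new_field(psi, field$time + config$dt, config)
}

check_stability <- function(psi, config) {
  if (!all(is.finite(psi)) || max(abs(psi)) > 10) {
    stop(errorCondition(
      sprintf("order parameter blew up (max |psi| > 10); reduce dt (currently %g)",
              config$dt),
      class = "specklematch_instability"))
  }
  invisible(TRUE)
}

#' Integrate a Cahn--Hilliard trajectory
#'
#' Runs \code{n_steps} integrator steps from the seeded initial condition
#' and stores field snapshots every \code{snapshot_every} steps, always
#' including the initial (t = 0) and final fields. Trajectories are
#' bit-reproducible for a given configuration and seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{ch_trajectory}: list with \code{psi} (array
#'   \code{n_snap x grid_n x grid_n}), \code{times}, \code{n_steps_executed}
#'   and the originating \code{config}.
#' @export
#' @examples
#' traj <- run_simulation(sim_config(epsilon = 0.9, psi_gel = 0.8,
#'                                   grid_n = 32, n_steps = 100,
#'                                   snapshot_every = 25, seed = 3))
#' traj$times
run_simulation <- function(config) {
  validate_sim_config(config)
  plan <- spectral_plan(config)
  field0 <- initialize_field(config)
  psi <- field0$values
  psi_hat <- fft2(psi)

  snap_steps <- unique(c(0L, seq(config$snapshot_every, config$n_steps,
                                 by = config$snapshot_every), config$n_steps))
  snap_steps <- sort(snap_steps)
  n <- config$grid_n
  snaps <- array(NA_real_, c(length(snap_steps), n, n))
  snaps[1, , ] <- psi
  si <- 2L

  for (step in seq_len(config$n_steps)) {
    psi_hat <- ch_step_spectral(psi, psi_hat, config, plan)
    psi <- Re(ifft2(psi_hat))
    if (step %% 200L == 0L || step == config$n_steps) check_stability(psi, config)
    if (si <= length(snap_steps) && step == snap_steps[si]) {
      snaps[si, , ] <- psi
      si <- si + 1L
    }
  }
  check_stability(psi, config)
  structure(list(
    psi = snaps,
    times = snap_steps * config$dt,
    n_steps_executed = config$n_steps,
    config = config
  ), class = "ch_trajectory")
}

#' @export
print.ch_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ch_trajectory> %d snapshots of %dx%d, t in [%g, %g] (%d steps)\n",
    dim(x$psi)[1], dim(x$psi)[2], dim(x$psi)[3],
    min(x$times), max(x$times), x$n_steps_executed))
  cat(sprintf("  epsilon = %g, psi_gel = %g, seed = %d\n",
              x$config$epsilon, x$config$psi_gel, x$config$seed))
  invisible(x)
}

#' Extract one snapshot from a trajectory as a field
#'
#' @param traj A \code{ch_trajectory}.
#' @param i Snapshot index (1-based).
#' @return A \code{ch_field}.
#' @export
trajectory_field <- function(traj, i) {
  stopifnot(i >= 1, i <= dim(traj$psi)[1])
  new_field(traj$psi[i, , ], traj$times[i], traj$config)
}
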