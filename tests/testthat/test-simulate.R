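test_that("seeded initialization is reproducible, mean-exact and bounded", {
  cfg <- small_sim_config(seed = 7, noise_amp = 0.01)
  f1 <- initialize_field(cfg)
  f2 <- initialize_field(cfg)
  expect_identical(f1$values, f2$values)
  expect_lt(abs(mean(f1$values) - cfg$psi0_mean), 1e-12)
  # the exact mean subtraction can push single pixels marginally past the
  # raw amplitude, by at most the magnitude of the subtracted mean
  expect_lte(max(abs(f1$values - cfg$psi0_mean)), 0.01 * 1.01)

  f3 <- initialize_field(small_sim_config(seed = 8, noise_amp = 0.01))
  expect_false(identical(f1$values, f3$values))

  expect_error(sim_config(epsilon = 0.9, psi_gel = 0.8, grid_n = 33),
               class = "specklematch_config_error")
  expect_error(sim_config(epsilon = 0.9, psi_gel = 0.8, noise_amp = 0),
               class = "specklematch_config_error")
  expect_error(sim_config(epsilon = -1, psi_gel = 0.8),
               class = "specklematch_config_error")
  expect_error(sim_config(epsilon = 0.9, psi_gel = 0.8, m_max = 0, m_min = 0),
               class = "specklematch_config_error")
})

test_that("mobility is the half-drop sigmoid with the right limits", {
  cfg <- small_sim_config(psi_gel = 0.7, m_max = 1, m_min = 0, alpha = 30)
  expect_identical(mobility(0.7, cfg), 0.5)
  expect_equal(mobility(-1e6, cfg), 1)
  expect_equal(mobility(1e6, cfg), 0)
  # three steepness units past the gelation point: (1 - tanh 3) / 2
  expect_equal(mobility(0.7 + 3 / 30, cfg), (1 - tanh(3)) / 2,
               tolerance = 1e-12)
  expect_equal(mobility(0.7 + 3 / 30, cfg), 0.002472623, tolerance = 1e-6)

  # decreasing everywhere, strictly so away from tanh saturation;
  # midpoint exact for general bounds
  cfg2 <- small_sim_config(psi_gel = 0.6, m_max = 0.8, m_min = 0.2, alpha = 12)
  wide <- seq(-2, 2, length.out = 400)
  expect_true(all(diff(mobility(wide, cfg2)) <= 0))
  core <- seq(0.25, 0.95, length.out = 200)
  expect_true(all(diff(mobility(core, cfg2)) < 0))
  expect_equal(mobility(0.6, cfg2), (0.8 + 0.2) / 2)
  expect_true(all(mobility(core, cfg2) > 0.2 & mobility(core, cfg2) < 0.8))
  expect_true(all(mobility(wide, cfg2) >= 0.2 & mobility(wide, cfg2) <= 0.8))
})

test_that("chemical potential matches closed forms", {
  cfg <- small_sim_config(epsilon = 0.64, grid_n = 32)
  n <- cfg$grid_n
  uni <- new_field_for_test(matrix(0.5, n, n), cfg)
  mu <- chemical_potential(uni, cfg)
  expect_equal(max(abs(mu - (-0.64 * 0.5 + 0.125))), 0, tolerance = 1e-12)

  # binodal compositions are stationary: mu = 0
  for (sgn in c(-1, 1)) {
    bin <- new_field_for_test(matrix(sgn * sqrt(0.64), n, n), cfg)
    expect_lt(max(abs(chemical_potential(bin, cfg))), 1e-12)
  }

  # linearization around 0: mu = (q^2 - eps) * a * cos(qx) + O(a^3)
  a <- 1e-4
  m <- 3  # mode number
  q <- 2 * pi * m / n
  x <- matrix(rep(seq_len(n) - 1, n), n, n)
  psi <- a * cos(q * x)
  fld <- new_field_for_test(psi, cfg)
  mu <- chemical_potential(fld, cfg)
  expect_equal(mu, (q^2 - 0.64) * psi, tolerance = 1e-6)

  bad <- new_field_for_test(matrix(c(NaN, rep(0, n * n - 1)), n, n), cfg)
  expect_error(chemical_potential(bad, cfg),
               class = "specklematch_numeric_error")
})

test_that("the integrator conserves the mean and detects blow-up", {
  cfg <- small_sim_config(n_steps = 100, grid_n = 32)
  traj <- run_simulation(cfg)
  means <- apply(traj$psi, 1, mean)
  expect_true(all(abs(means - cfg$psi0_mean) < 1e-10))
  expect_equal(traj$n_steps_executed, 100L)

  # same seed twice: identical trajectories
  traj2 <- run_simulation(cfg)
  expect_identical(traj$psi, traj2$psi)

  # grotesquely large time step blows up and is reported as instability
  boom <- small_sim_config(n_steps = 5000, dt = 50, grid_n = 32,
                           noise_amp = 0.5, epsilon = 2)
  expect_error(run_simulation(boom), class = "specklematch_instability")
})

test_that("the Landau free energy is a Lyapunov functional of the flow", {
  # constant-mobility control run, energy evaluated by an independent
  # spectral-gradient oracle
  cfg <- small_sim_config(n_steps = 500, grid_n = 48, psi_gel = 50,
                          snapshot_every = 1, dt = 0.05)
  traj <- run_simulation(cfg)
  oracle_energy <- function(psi) {
    n <- nrow(psi)
    k1 <- 2 * pi * c(0:(n / 2), -((n / 2 - 1):1)) / n
    kx <- matrix(k1, n, n); ky <- t(kx)
    ph <- stats::fft(psi)
    gx <- Re(stats::fft(1i * kx * ph, inverse = TRUE)) / n^2
    gy <- Re(stats::fft(1i * ky * ph, inverse = TRUE)) / n^2
    sum(-cfg$epsilon / 2 * psi^2 + psi^4 / 4 +
          cfg$kappa / 2 * (gx^2 + gy^2))
  }
  fe <- vapply(seq_len(dim(traj$psi)[1]),
               function(i) oracle_energy(traj$psi[i, , ]), numeric(1))
  expect_true(all(diff(fe) <= 1e-8))
  # and the packaged evaluator agrees with the oracle
  expect_equal(free_energy(trajectory_field(traj, 10), cfg), fe[10],
               tolerance = 1e-10)
})

test_that("early-time mode growth matches the linear dispersion relation", {
  # symmetric quench (psi0 = 0), uniform mobility: omega(q) = M q^2 (eps - kappa q^2)
  n <- 128
  eps <- 0.6
  cfg <- sim_config(epsilon = eps, psi_gel = 100, grid_n = n, dt = 0.05,
                    n_steps = 300, psi0_mean = 0, noise_amp = 1e-4,
                    snapshot_every = 10, seed = 5, m_min = 1 - 1e-12)
  traj <- run_simulation(cfg)
  expect_lt(max(abs(traj$psi[dim(traj$psi)[1], , ])), 0.05)  # still linear

  k1 <- 2 * pi * c(0:(n / 2), -((n / 2 - 1):1)) / n
  kx <- matrix(k1, n, n); ky <- t(kx)
  kr <- sqrt(kx^2 + ky^2)
  r_star <- round(sqrt(eps / 2) * n / (2 * pi))  # fastest-growing radius
  for (r in c(r_star - 2, r_star, r_star + 2)) {
    q <- 2 * pi * r / n
    sel <- abs(kr - q) < 1e-9 & kr > 0
    amp <- vapply(seq_len(dim(traj$psi)[1]), function(i) {
      mean(Mod(stats::fft(traj$psi[i, , ]))[sel])
    }, numeric(1))
    fit <- stats::lm(log(amp) ~ traj$times)
    omega_hat <- unname(stats::coef(fit)[2])
    omega <- q^2 * (eps - q^2)
    expect_lt(abs(omega_hat - omega) / omega, 0.05)
  }
})

test_that("coarsening slows when the gelation point approaches the mean", {
  # fixed eps, lower psi_gel => arrested coarsening: the structure-factor
  # peak ends at larger q than in the mobile run
  peak_q <- function(psi_gel) {
    cfg <- small_sim_config(epsilon = 0.9, psi_gel = psi_gel, grid_n = 64,
                            n_steps = 4000, snapshot_every = 4000, seed = 3)
    traj <- run_simulation(cfg)
    prof <- azimuthal_profile(speckle_pattern(
      trajectory_field(traj, dim(traj$psi)[1])))
    prof$q_sim[which.max(prof$intensity)]
  }
  expect_gte(peak_q(0.5), peak_q(5))
})

test_that("trajectories include endpoints and strictly increasing times", {
  cfg <- small_sim_config(n_steps = 105, snapshot_every = 20, grid_n = 32)
  traj <- run_simulation(cfg)
  expect_equal(traj$times[1], 0)
  expect_equal(max(traj$times), 105 * cfg$dt)
  expect_true(all(diff(traj$times) > 0))
  # one ch_step advances time by dt and agrees with the batch integrator
  f0 <- initialize_field(cfg)
  f1 <- ch_step(f0, cfg)
  expect_equal(f1$time, cfg$dt)
  expect_lt(abs(mean(f1$values) - cfg$psi0_mean), 1e-12)
})
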