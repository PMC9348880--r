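# Shared generators for fast, deterministic test inputs.

# Small simulation config for unit tests (seconds, not minutes).
small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(epsilon = 0.9, psi_gel = 0.8, grid_n = 48, dt = 0.05,
                   n_steps = 400, snapshot_every = 20, noise_amp = 0.05,
                   seed = 42L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Memoised small trajectory shared across test files.
.test_cache <- new.env(parent = emptyenv())

cached_small_traj <- function() {
  if (is.null(.test_cache$traj)) {
    # mobile control (gelation point far above the binodal), long enough
    # (t = 200) that coarsening is well developed at 48^2
    .test_cache$traj <- run_simulation(small_sim_config(n_steps = 4000,
                                                        psi_gel = 5))
  }
  .test_cache$traj
}

# Exponential-band surrogate for a preprocessed TTC: contrast beta, frame
# correlation time tau (in frame units), optional additive noise.
banded_ttc <- function(s, tau, beta = 1, noise = 0, seed = NULL) {
  idx <- seq_len(s)
  v <- 1 + beta * exp(-abs(outer(idx, idx, `-`)) / tau)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    e <- matrix(stats::rnorm(s * s, sd = noise), s, s)
    v <- v + (e + t(e)) / 2
  }
  structure(list(values = v, s = s, crop_index = NULL, original_n = s,
                 beta = NULL, q_center = NA_real_, dq = NA_real_,
                 source = "synthetic"),
            class = "preprocessed_ttc")
}

# A bundle of banded TTCs with graded correlation times.
banded_ttc_set <- function(n, s, tau_range = c(2, s / 2), noise = 0,
                           seed = 1) {
  set.seed(seed)
  taus <- seq(tau_range[1], tau_range[2], length.out = n)
  lapply(seq_len(n), function(i) {
    banded_ttc(s, taus[i], noise = noise, seed = seed + i)
  })
}

# Synthetic latent table with smoothly varying components across rings.
synthetic_latent_table <- function(n_samples = 10, rings = 4:9, d = 8,
                                   seed = 1) {
  set.seed(seed)
  eps <- runif(n_samples, 0.4, 0.9)
  psi <- runif(n_samples, 0.55, 1.0)
  z <- array(0, c(n_samples, length(rings), d))
  for (i in seq_len(n_samples)) {
    base <- rnorm(d)
    slope <- rnorm(d, sd = 0.3)
    for (j in seq_along(rings)) {
      z[i, j, ] <- base + slope * rings[j] + 0.2 * sin(rings[j] + seq_len(d))
    }
  }
  structure(list(eps = eps, psi_gel = psi, rings = rings, z = z,
                 latent_dim = d),
            class = "latent_table")
}

# Bare field constructor for closed-form checks.
new_field_for_test <- function(values, cfg, time = 0) {
  structure(list(values = values, time = time, config = cfg),
            class = "ch_field")
}

# Small auto-encoder trained once on banded surrogates, shared by tests.
cached_trained_ae <- function() {
  if (is.null(.test_cache$ae)) {
    cfg <- ae_config(latent_dim = 8, channels = c(4, 8, 16), hidden = 16,
                     s = 16, epochs = 150, batch_size = 32, lr = 2e-3,
                     seed = 11)
    # lightly noisy training inputs teach the bottleneck to discard pixel
    # noise, as the simulation library's residual speckle noise does
    ttcs <- banded_ttc_set(160, 16, tau_range = c(1.5, 10), noise = 0.04,
                           seed = 21)
    fit <- ae_train(build_autoencoder(cfg), ttcs)
    .test_cache$ae <- list(model = fit$model, history = fit$history,
                           ttcs = ttcs)
  }
  .test_cache$ae
}
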