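# specklematch

Classify two-time X-ray speckle correlation maps from phase-separating
protein solutions by matching them to Cahn–Hilliard phase-field
simulations with an auto-encoder and differential evolution — entirely in
R.

## The problem

In an XPCS (X-ray photon correlation spectroscopy) experiment on a
protein solution undergoing liquid–liquid phase separation, the dynamics
at momentum transfer *Q* are summarised by the two-time correlation map

    C(t1, t2) = <I_p(t1) I_p(t2)>_p / ( <I_p(t1)>_p <I_p(t2)>_p ),

the pixel-averaged intensity correlation within a *Q* ring. The shape of
the band around the diagonal encodes spinodal decomposition, droplet
coarsening, and gelation-induced dynamical arrest. A beamtime yields
thousands of such maps; `specklematch` assigns them physical parameters
automatically:

1. **Simulate** — 2D Cahn–Hilliard dynamics
   `∂Ψ/∂t = ∇·[M(Ψ) ∇(−εΨ + Ψ³ − κ∇²Ψ)]` with the gelation mobility
   `M(Ψ) = m_min + (m_max − m_min)(1 − tanh[α(Ψ − Ψ_gel)])/2`, on a
   periodic grid with a pseudo-spectral, semi-implicit, exactly
   mass-conserving integrator. `ε` is the reduced quench depth
   (∝ (T_c − T)/T_c); `Ψ_gel` is the order parameter at which the
   mobility has dropped half-way — the gelation point.
2. **Scatter / correlate** — coherent speckle `|FFT Ψ|²`, azimuthal
   intensity profiles, TTC maps per *Q* ring, cropping at the
   ring-intensity maximum, visibility normalisation, area-average
   downsampling.
3. **Encode** — a from-scratch convolutional auto-encoder (three stride-2
   stages, adaptive 2×2 pooling, 32-dimensional latent code) with
   hand-written, finite-difference-verified backpropagation.
4. **Match** — differential evolution maximising the mean normalized dot
   product *D* between encoded experimental maps and ring-interpolated
   simulated latents, fitting per-condition `(ε, Ψ_gel)` plus the global
   time window `(t_start, t_end)` and pixel→µm⁻¹ conversion `c_Q`.
5. **Phase diagram** — binodal `±√ε`, spinodal `±√(ε/3)` and the fitted
   gel line in `(Φ, ε)` coordinates, `Φ = (1+Ψ)/2`.

Because the underlying beamline data are not public, the package includes
a pseudo-experiment generator (`make_fixtures()`) that produces a blind
quench series with known ground truth — the basis for all end-to-end
recovery claims.

## Worked example

The scaled study from the test suite, spelled out (about 15 minutes on
one CPU; the methods vignette documents every size choice):

```r
library(specklematch)

ramp     <- ring_ramp(q_lo = 8, q_hi = 16, w_lo = 2, w_hi = 6)
sim_args <- list(grid_n = 96, dt = 0.05, n_steps = 5000,
                 snapshot_every = 25, noise_amp = 0.08)

# simulation library: 5x4 grid of (eps, psi_gel), 2 noise realizations,
# 9 rings, preprocessed to 32x32
lib <- do.call(simulate_ttc_library, c(list(
  n_pairs = 20, n_noise = 2, n_rings = 9,
  eps_range = c(0.65, 0.9), psi_gel_range = c(0.55, 0.95),
  sampling = "grid", s = 32, ramp = ramp, seed = 100,
  n_augment = 1), sim_args))

# auto-encoder and latent lookup table
fit <- ae_train(build_autoencoder(
  ae_config(channels = c(8, 16, 32), hidden = 48, s = 32, pool_out = 2,
            epochs = 50, batch_size = 32, seed = 5)),
  library_ttcs(lib))
tab <- build_latent_table(fit$model, lib)

# blind pseudo-experimental quench series (truth withheld from the fit)
spec <- fixture_spec(n_conditions = 6,
                     eps_true = seq(0.87, 0.67, length.out = 6),
                     psi_gel_true = seq(0.58, 0.78, length.out = 6),
                     c_q_true = 0.6, beta_true = 0.3, seed = 77)
fx <- do.call(make_fixtures, c(list(spec = spec, ramp = ramp), sim_args))

res <- match_ttcs(fixture_inputs(fx), tab, fit$model,
                  max_iter = 150, pop_size = 20, seed = 1)
res
#> <match_result> 6 conditions, D = 0.7701 (3020 evaluations)
#>   calibration: t_start = 107, t_end = 513, c_q = 0.5808
#> # A tibble: 6 × 3
#>   condition   eps psi_gel
#>       <int> <dbl>   <dbl>
#> 1         1 0.9     0.55
#> 2         2 0.9     0.683
#> 3         3 0.838   0.817
#> 4         4 0.712   0.95
#> 5         5 0.65    0.817
#> 6         6 0.65    0.817

glance(res)
#> # A tibble: 1 × 7
#>       D t_start t_end   c_q n_conditions n_evals n_iter
#>   <dbl>   <dbl> <dbl> <dbl>        <int>   <int>  <int>
#> 1 0.770    107.  513. 0.581            6    3020    150

plot_phase_diagram(gel_line(res))
```

Reading the output: the six conditions were generated at true quench
depths 0.87 … 0.67 (deep to shallow) with gelation points 0.58 … 0.78 and
a true Q calibration `c_q = 0.6`. The blind fit recovers the quench-depth
ordering and magnitudes (median absolute error 0.042 across conditions
and seeds in the test suite), the rising gelation point trend (median
error 0.070), and the calibration factor within ~3%. `D = 0.77` is the
mean cosine between the encoded experimental maps and their matched
simulated latents; `t_start`/`t_end` (seconds) map the experimental clock
onto the simulated coarsening stage.

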