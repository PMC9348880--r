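---
title: "Matching two-time speckle correlation maps to phase-field simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching two-time speckle correlation maps to phase-field simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(specklematch)
```

## The problem

X-ray photon correlation spectroscopy (XPCS) observes the dynamics of a
phase-separating protein solution through time series of coherent speckle
patterns. The standard reduction of such a series is the two-time
correlation map (TTC)

$$C(t_1, t_2) \;=\;
\frac{\langle I_p(t_1)\, I_p(t_2)\rangle_p}
     {\langle I_p(t_1)\rangle_p\,\langle I_p(t_2)\rangle_p},$$

with $\langle\cdot\rangle_p$ an average over detector pixels in a ring of
constant momentum transfer $Q$. The width of the band around the diagonal
is the instantaneous correlation time, so a TTC is a compact fingerprint
of non-equilibrium dynamics: spinodal decomposition, coarsening, and
dynamical arrest (gelation) each leave a characteristic shape. A single
beamtime produces thousands of such maps; assigning them to points of a
physical model by eye does not scale.

`specklematch` implements a complete, self-contained pipeline that
classifies TTC maps against a minimal physical model:

1. **simulate** -- a 2D Cahn--Hilliard phase-field model with a
   concentration-dependent mobility that arrests the dense phase
   (gelation), parameterised by the reduced quench depth $\epsilon$ and
   the gelation point $\Psi_{gel}$;
2. **scatter / correlate** -- coherent speckle synthesis by Fourier
   transform, azimuthal intensity profiles, per-ring TTCs, cropping and
   downsampling;
3. **encode** -- a convolutional auto-encoder that compresses each
   preprocessed map into a 32-component latent vector;
4. **match** -- differential evolution that matches encoded experimental
   maps to a library of encoded simulations, estimating per-condition
   $(\epsilon, \Psi_{gel})$ plus a global time window $(t_{start},
   t_{end})$ and a pixel-to-$\mu m^{-1}$ conversion $c_Q$;
5. **phasediagram** -- binodal, spinodal and the estimated gel line on
   the Landau phase diagram.

Because raw beamline data for the IgG/PEG system this workflow targets
are not publicly deposited, the package ships a pseudo-experiment
generator (`make_fixtures()`) that plays the role of the measurements: it
runs the simulator at hidden ground-truth parameters and degrades the
maps the way an experiment would (partial coherence, shot noise on the
diagonal, an experimental frame clock). All end-to-end claims about the
matcher are therefore statements about recovery of known truth.

## The phase-field model

The order parameter $\Psi(\mathbf r, t)$ is a rescaled local protein
concentration ($\Psi = 0$ is the critical composition; we map
concentration as $\Phi = (1+\Psi)/2$). Its dynamics follow the
Cahn--Hilliard equation with variable mobility,

$$\frac{\partial \Psi}{\partial t} =
\nabla\cdot\Bigl[M(\Psi)\,\nabla\mu\Bigr],
\qquad
\mu = -\epsilon\,\Psi + \Psi^3 - \kappa\,\nabla^2\Psi,$$

the functional derivative of the Ginzburg--Landau quartic free energy
$f = -\tfrac{\epsilon}{2}\Psi^2 + \tfrac14\Psi^4 +
\tfrac{\kappa}{2}|\nabla\Psi|^2$. The quench depth $\epsilon > 0$ is
proportional to $(T_c - T)/T_c$; the binodal sits at
$\Psi = \pm\sqrt{\epsilon}$ and the spinodal at
$\Psi = \pm\sqrt{\epsilon/3}$.

Gelation enters through the mobility sigmoid

$$M(\Psi) = m_{min} + (m_{max}-m_{min})\,
\frac{1 - \tanh[\alpha\,(\Psi - \Psi_{gel})]}{2},$$

which collapses transport in regions denser than $\Psi_{gel}$ and equals
the midpoint of its range exactly at $\Psi_{gel}$ -- for bounds 1 and 0
the mobility at the gelation point is exactly $0.5$. Large $\alpha$
(default 30) makes the drop steep, as required for an arrest rather than
a gradual slowdown; $m_{min}$ defaults to $10^{-6}$ rather than zero so
the flux never vanishes identically.

### Numerical scheme

The solver is pseudo-spectral and semi-implicit on a periodic grid with
unit lattice spacing:

* $\nabla\mu$ is formed in Fourier space, multiplied by $M(\Psi)$ in real
  space, and the divergence is taken back in Fourier space -- the
  standard treatment of a variable-mobility flux;
* the stiff linear term $-\kappa\, m_{max}\, k^4 \hat\Psi$ is added and
  subtracted so it can be treated implicitly (stabilised splitting),
  which keeps the scheme stable at $\Delta t = 0.02$--$0.05$;
* the $k = 0$ mode is pinned each step, so the spatial mean of $\Psi$ is
  conserved exactly (well below the $10^{-10}$ documented tolerance),
  matching the conservation law of the continuous equation.

Three properties are enforced by tests rather than assumed: mean
conservation, monotone decay of the Landau free energy (a Lyapunov
functional for any positive mobility), and agreement of early-time mode
growth with the linearised dispersion $\omega(q) = M q^2(\epsilon -
\kappa q^2)$ to within 5%.

### Parameter conventions and defaults

| parameter | default | meaning |
|---|---|---|
| `epsilon` | -- | reduced quench depth, training interval $[0.4, 0.9]$ |
| `psi_gel` | -- | gelation point, training interval $[0.55, 1.0]$ |
| `alpha` | 30 | mobility steepness |
| `kappa` | 1 | gradient-energy coefficient |
| `m_max`, `m_min` | 1, $10^{-6}$ | mobility bounds |
| `grid_n` | 256 | lattice side |
| `dt`, `n_steps` | 0.02, 10000 | production integration schedule |
| `psi0_mean` | 0.3 | conserved mean order parameter |
| `noise_amp` | 0.01 | initial uniform noise amplitude |

Two of these deserve comment.

*The mean order parameter* is $+0.3$, not a larger value: the system must
sit inside the spinodal ($\Psi_0 < \sqrt{\epsilon/3}$) for every quench
depth in the training interval, otherwise the shallow quenches would be
metastable rather than unstable and no spontaneous decomposition would
occur. With $\Psi_0 = 0.3$ the whole interval $\epsilon \ge 0.4$ is
unstable, the majority phase is dense, and the minority dilute phase
forms droplets (not a bicontinuous network), which is the morphology the
workflow assumes. The lower end of the `psi_gel` interval is kept above
$\Psi_0 + 0.1$ so that arrest cannot pre-empt droplet formation.

*The initial noise* seeds the instability; there is no thermal noise in
the dynamics. Its amplitude matters only through the duration of the
linear growth stage (the time to reach saturation grows like
$\log(1/\text{noise})/\omega_{max}$).

## From fields to TTC maps

Speckle intensity is $|\mathcal F \Psi|^2$ with the zero-frequency pixel
centred -- fully coherent scattering, so the simulated speckle contrast
is 1 (TTC diagonal near 2, the Gaussian-statistics value). The azimuthal
profile (the mean of $|\mathcal F\Psi|^2$ over integer pixel radii,
`azimuthal_profile()`) develops the structure-factor peak whose position
moves to smaller radii as droplets coarsen.

TTCs are computed on rings whose width grows linearly from 0.7 pixels at
the inner radius to 3 pixels at the outer radius (`ring_ramp()`), the
same compensation for falling photon counts that experimental analyses
use. Ring centres are integer radii on the falling slope of the
structure-factor peak; at the production grid of $256^2$ the default
window is radii 5--60 with 20 rings.

Three preprocessing steps align simulation and experiment:

* **Cropping at the ring-intensity maximum.** Simulated maps begin with a
  broad slow block from the still-homogeneous early stage; experiments
  do not show it because acquisition starts after the quench. Cropping
  both at the time the ring intensity peaks compares coarsening with
  coarsening. Peak detection takes the *first* frame at the maximum (ties
  resolve early). For small grids and arrested runs the series can
  plateau, in which case the argmax is dominated by speckle noise; the
  implementation therefore offers a smoothed detector (`smooth_window`),
  a relative tolerance (crop at the first frame within `rel_tol` of the
  maximum -- plateau onset), and a cap that guarantees a minimum number
  of surviving frames. The library generator uses `rel_tol = 0.05`,
  `smooth_window = 5`, `cap = TRUE`; the strict uncapped behaviour
  remains the default of `crop_at_intensity_peak()`.
* **Diagonal replacement.** Equal-time values are replaced by the mean of
  their adjacent off-diagonals (`smooth_diagonal()`) on both the
  experimental and the simulated side: experimentally the diagonal is
  inflated by shot noise, and it carries no dynamical information the
  off-diagonals lack, so the encoder should never learn from it.
* **Visibility normalisation.** Experimental contrast $\beta < 1$ is
  estimated from the two first off-diagonals of $C - 1$ (the diagonal
  itself is inflated by shot noise) and divided out:
  $C' = 1 + (C-1)/\beta$. The *simulated* library maps pass through the
  same normalisation: although coherent speckle nominally has unit
  contrast, the realised off-diagonal contrast of a finite ring is
  ring-dependent (non-Gaussian tail statistics), and matching requires
  both sides on one scale.
* **Downsampling.** Cropped maps are area-average resampled to the fixed
  network input size $s \times s$ ($s = 64$ by default; upscaling is
  refused). Area averaging is separable and symmetric, so TTC symmetry
  survives to round-off.

Maps from simulations differing only in their initial noise are averaged
*after* cropping and downsampling (each realization's peak is its own),
five realizations per parameter pair at production scale.

## The auto-encoder

The encoder applies three stride-2 $3\times3$ convolution + ReLU stages,
adaptive average pooling (default output $2\times2$ per channel), and a
two-layer fully connected head ending in a 32-component latent code. The decoder mirrors
it with a dense expansion and three (nearest-neighbour upsample +
convolution) stages; the loss is reconstruction MSE on $C - 1$. The
engine is written directly in R as cached-index im2col convolutions over
BLAS, with manual backpropagation verified against finite differences in
the test suite, and Adam optimisation; training and encoding are
bit-deterministic for a given seed.

Design notes:

* Upsample-plus-convolution replaces transposed convolution in the
  decoder; the two are equally expressive here and the former avoids
  checkerboard artefacts.
* The pooling output size matters physically: pooling all the way to
  $1\times1$ discards absolute position along the diagonal -- the ageing
  axis of a TTC -- and with it much of the gelation-point signal. The
  default $2\times2$ keeps a coarse position grid; `pool_out = 1`
  restores pure global pooling.
* Training can include window-jittered variants of each map
  (`n_augment` in `simulate_ttc_library()`): extra crops whose start and
  end are randomly displaced within the cropped range. They never enter
  the latent lookup table; their only purpose is to make the latent code
  insensitive to the acquisition window, which removes a near-degeneracy
  between the fitted time window and the $Q$ calibration.
* Latent vectors of neighbouring $Q$ rings of the same simulation vary
  smoothly, so a map at an arbitrary fractional ring coordinate is
  represented by per-component piecewise-linear interpolation across the
  ring axis (`interpolate_latent()`); this underpins the $c_Q$
  calibration during matching.

## Matching by differential evolution

For each quench condition $i$ the matcher fits $(\epsilon_i,
\Psi_{gel,i})$; globally it fits the crop window $(t_{start}, t_{end})$
mapping the experimental clock onto the simulation timescale and the
conversion $c_Q$ ($Q_{exp} = c_Q\, q_{sim}$). The objective is the mean
normalized dot product over the experimental set (30 maps in the default
layout: 6 conditions $\times$ 5 $Q$ values in $[7.02, 8.2]\,\mu m^{-1}$),

$$D = \frac{1}{N}\sum_j \hat z^{exp}_j \cdot \hat z^{sim}_j,$$

maximised by rand/1/bin differential evolution (defaults $F = 0.7$,
$CR = 0.9$, 1500 generations at production scale) under box constraints
derived from the library ranges: $c_Q$ is bounded by requiring all
queried rings to lie inside the stored ring window; the window length is
bounded below by a fixed fraction (0.75) of the post-onset record,
because the experiment outlasts the simulated coarsening and a free
window length is otherwise nearly degenerate with $c_Q$.

The default fit topology (`method = "profile"`) exploits the structure
of the problem: differential evolution searches only the three
calibration parameters, and inside every evaluation the per-condition
$(\epsilon_i, \Psi_{gel,i})$ are chosen *exactly* by scoring all library
samples against that condition's maps, with the physical requirement
that $\epsilon$ be non-increasing in quench temperature imposed by an
exact dynamic programme over the candidate chains (verified against
brute-force enumeration in the tests). This profiling collapses a
15-dimensional search (six conditions) to three dimensions and makes the
fit reproducible run-to-run; the returned physics parameters live on the
library grid, whose spacing is finer than the reported uncertainties. A
literal joint optimisation over all parameters at once, with the
monotonicity as a penalty $\propto \sum_i \max(0,
\epsilon_{i+1}-\epsilon_i)$, remains available as `method = "joint"`.

Four implementation choices matter for the optimisation landscape:

* Experimental maps are cropped, normalized, downsampled and encoded once
  per *distinct* crop window after rounding to the frame grid, and
  cached; DE evaluations then reduce to table lookups.
* The continuous $(\epsilon, \Psi_{gel})$ query is resolved against the
  discrete library by inverse-squared-distance blending of the $k = 4$
  nearest samples (in range-normalised parameter space) before ring
  interpolation. With plain nearest-neighbour lookup the objective would
  be piecewise constant in the physical parameters and DE could wander
  freely within each Voronoi cell; blending makes it continuous.
* Latent vectors are centred on the library's mean latent before the
  cosine is taken. ReLU networks produce codes with a large shared
  positive component; without centring, all cosines crowd into a narrow
  band just below 1 and the objective loses most of its contrast.
* Each experimental map is cropped at its *own* ring-intensity peak
  whenever that peak lies inside the fitted window -- the same crop rule
  the library maps receive -- so the global window acts as a bound and
  timescale anchor rather than overriding per-ring alignment; and the
  `t_start` search interval itself is anchored at the observable median
  peak time ($\pm 10\%$ of the measurement span). Both counter the
  near-degeneracy between the window and the physical parameters.

A per-map mode (`match_ttcs_per_map()`) reproduces the alternative fit
topology -- each map fitted independently, calibration averaged over the
30 outcomes -- and exposes the between-map scatter.

## The pseudo-experiment generator

`make_fixtures()` emulates a quench series: six conditions ordered by
increasing nominal quench temperature, with true quench depth
non-increasing and true gelation point increasing (gelation at higher
concentration for shallower quenches -- the trend the gel line encodes);
five $Q$ values per condition evenly spaced in $[7.02, 8.2]\,\mu m^{-1}$;
frame clock of 4000 exposures of 0.02 s every 0.12 s (480 s total)
emulated by index bookkeeping. Degradations: $(C-1)$ scaled by a true
contrast $\beta^* = 0.3$, and positive uniform noise added to the
diagonal (shot-noise distortion). The truth block is stored separately
and `fixture_inputs()` strips it, so matching runs blind.

What the fixtures deliberately do **not** model: detector pixel response,
gaps and flat field, photon (Poisson) counting in individual pixels,
partial-coherence speckle blurring beyond a global contrast factor, and
any drift of the sample. Recovery results on fixtures therefore
demonstrate the *pipeline's* correctness and identifiability of
$(\epsilon, \Psi_{gel}, c_Q)$ under in-model data, not robustness to
every artefact of a real beamline.

## Scaled problem sizes

The production-scale design (12000 parameter pairs $\times$ 5 noise
realizations on $256^2$ grids, 20 rings, 240000 training maps) is the
package's default configuration but is far beyond a desk-scale R
session. The shipped tests and the end-to-end acceptance check use a
scaled study whose sizes were fixed once, from pilot phenomenology,
before the recovery experiments were scored:

* grid $96^2$, $\Delta t = 0.05$, 5000 steps (time horizon 250),
  `noise_amp = 0.08` (a shorter linear stage at small grids), snapshots
  every 25 steps (201 frames);
* library: a regular $5\times4$ grid over $\epsilon \in [0.65, 0.9]$,
  $\Psi_{gel} \in [0.55, 0.95]$, two noise realizations per pair, 9 rings
  at every integer radius 8--16 (dense ring sampling sharpens the ring
  interpolation that the $c_Q$ calibration rests on), input size
  $s = 32$, one window-jittered training variant per map;
* ring widths 2--6 pixels instead of the production 0.7--3: ring pixel
  count scales with the grid side, and at $96^2$ the production ramp
  leaves so few speckles per ring that realization noise swamps the
  latent signal -- the wider ramp restores production-like per-ring
  statistics;
* fixtures: 6 conditions with $\epsilon^*$ from 0.87 to 0.67,
  $\Psi^*_{gel}$ from 0.58 to 0.78, $c_Q^* = 0.6$, $\beta^* = 0.3$;
* auto-encoder: channels (8, 16, 32), hidden width 48, latent 32,
  $2\times2$ pooling, trained 50 epochs; profile-method differential
  evolution with population 20 for 150 generations, five seeds.

The narrower $\epsilon$ interval is a property of the scaled horizon:
below $\epsilon \approx 0.6$ the linear stage of spinodal decomposition
does not complete within the shortened run, so there is no coarsening
stage to crop to. At production scale the full interval $[0.4, 0.9]$
applies. Equally, at $96^2$ the structure factor occupies few pixels and
single-realization ring intensities are noisy -- the robust peak
detector above exists for exactly this regime.

## Known limitations

* The model is 2D and droplet-morphology only; hydrodynamics,
  viscoelasticity and thermal fluctuations in the dynamics are out of
  scope.
* The mobility sigmoid and the quartic free energy are the minimal
  choices reproducing arrest phenomenology; neither is calibrated to an
  absolute temperature or concentration scale, so the phase diagram's
  axes are $\epsilon$ and the affine concentration map $\Phi=(1+\Psi)/2$.
* $\Psi_{gel}$ is identifiable only where the dense phase actually
  reaches it ($\Psi_{gel} \lesssim \sqrt{\epsilon}$); above that the
  dynamics are mobility-independent and the matcher can only return an
  unconstrained value in that region.
* Latent matching inherits the library's coverage: queries outside the
  stored $(\epsilon, \Psi_{gel})$ rectangle or ring window are refused
  rather than extrapolated.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes the
machine-checkable headline quantity (the mobility at the gelation point
for bounds 1 and 0) by running the package; the full scaled end-to-end
recovery lives in `tests/testthat/test-acceptance.R` and runs with the
ordinary test suite.
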