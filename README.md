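# glidebuckle

Quantifying the gliding forces of filamentous cyanobacteria from their
self-buckling behaviour.

Filamentous cyanobacteria (e.g. *Oscillatoria lutea*, *Kamptonema animale*)
glide along surfaces, driven by a propulsion force distributed along the
filament. When a gliding filament collides head-on with an obstacle, the
distributed thrust acts as a compressive follower load: filaments longer
than a critical length

&nbsp;&nbsp;&nbsp;&nbsp; L_c = (30.5722 · B / f)^(1/3)

buckle and reorient, shorter ones stall. Here B is the bending modulus and
f the active force density; 30.5722 is the critical activity coefficient
Γ = L³f/B of the pinned-head, tangentially driven elastica (the analogue of
Euler's 7.837 for the gravity-loaded clamped column). Observing which
filaments buckle therefore measures f; the post-buckling shape dynamics
additionally measures the substrate friction coefficient η, and with
overdamped co-linear friction f = η·v₀ links force to the free-gliding
speed.

The package implements the full analysis chain, for researchers in
biophysics and active matter:

- **Elastica stability theory** — the buckling threshold by two independent
  routes (closed-form hypergeometric root condition; shooting + boundary
  determinant), critical-length conversions in experimental units.
- **Kirchhoff shape dynamics** — method-of-lines integration of the
  nonlinear follower-load beam equation with isotropic friction; a library
  of buckling profiles continuously interpolable in (Γ, t).
- **Profile fitting** — per-frame and global fits of observed contour
  tracks to the profile library, yielding per-filament f and η, with a
  coarse bootstrap for spreads.
- **Buckling statistics** — weighted maximum-likelihood logistic regression
  of collision outcomes (weights 1/Nᵢ per individual), length-only
  p = sig((L−L_c)/ΔL_c) and velocity-coupled with
  L_c(v₀) = (η v₀ / (30.5722 B))^(−1/3).
- **Bending analysis** — micropipette three-point bending: Hooke's-law
  force conversion and B = Δx³/48 · ∂P/∂d.
- **Bead-chain simulation** — an overdamped Langevin bead-spring filament
  (C++ core) colliding with a WCA V-trap, reproducing the threshold from
  particle-based dynamics.
- **Synthetic data** — seeded generators for collision-event tables,
  contour tracks and force–deflection curves, with embedded ground truth.

Functions take data frames first and return tibbles; fitted objects have
`tidy()`/`glance()` and `autoplot()` methods.

## Worked example

Generate a synthetic collision ensemble at the *O. lutea* population
parameters and recover them by weighted logistic regression:

```r
library(glidebuckle)

ev <- gen_events(
  population_spec(truth = list(Lc_um = 161, dLc_um = 35)),
  n_events = 388, seed = 42
)
fit_logistic_length(ev)
#> Weighted logistic regression (length model)
#>   events: 388  individuals: 196
#>   Lc_um        161.4 (se 9.1)
#>   dLc_um       29.59 (se 5.25)
#>   log-likelihood: -34.6934
```

The fitted median critical length (161.4 ± 9.1 µm) recovers the generating
161 µm; ΔL_c is the width of the critical-length distribution. Converting
with the species-median bending modulus gives the force density:

```r
f <- force_from_critical_length(B = 1.4e-16, Lc = um_to_m(161.4))
N_per_m_to_nN_per_um(f)
#> [1] 1.018
```

about 1 nN of propulsion per µm of filament. The velocity-coupled model
(`fit_logistic_velocity()`) instead returns the friction coefficient η in
nN s µm⁻², and `fit_global()` extracts per-filament (f, η) from contour
tracks via the Kirchhoff profile library:

```r
lib   <- build_profile_library()               # ~90 s, reusable
track <- gen_contour_track(gamma = 150, t0_s = 6857, L_um = 200,
                           noise_um = 0.3, n_frames = 8, seed = 1)
fit_global(track, lib)
#> Kirchhoff profile fit (8 frames)
#>   gamma = 151.1   t0 = 6899 s   offset = 0.0003722 s
#>   f = 2.64 nN/um   eta = 0.604 nN s um^-2
#>   mean residual = 0.198 um^2
```

The generating track had Γ = 150 and t0 = η L⁴/B = 6857 s (i.e.
η = 0.6 nN s µm⁻² at L = 200 µm, B = 1.4×10⁻¹⁶ J m); the fit recovers both
within 1%, and the derived f and η are the per-filament mechanics.

A thin command-line wrapper over the same functions is at
`inst/cli/glidebuckle.R` (subcommands `theory`, `synth`, `fit-events`,
`fit-bending`, `simulate`, `run`).

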