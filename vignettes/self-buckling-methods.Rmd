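---
title: "Measuring gliding forces by self-buckling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring gliding forces by self-buckling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glidebuckle)
```

## The physical problem

Filamentous cyanobacteria glide along surfaces, propelled by a force that is
distributed along their whole contour. When the leading tip ("head") of a
gliding filament runs head-on into an obstacle, the distributed propulsion
becomes a compressive follower load. Short filaments simply stall; filaments
longer than a critical length $L_c$ buckle, their head pivots, and they
escape the obstacle in a new direction. Because the buckling threshold
depends only on the bending modulus $B$, the active force density $f$, and
the length $L$, observing which filaments buckle turns every collision into
a force measurement: with $B$ measured independently (micropipette
three-point bending), the ensemble of collision outcomes yields $f$, and the
dynamics of the post-buckling shape yields the substrate friction
coefficient $\eta$.

`glidebuckle` implements this entire analysis chain on synthetic data:

1. **beam theory** — the critical load of the self-propelled elastica;
2. **Kirchhoff dynamics** — nonlinear shape evolution after buckling;
3. **profile fitting** — matching observed contour tracks to theory;
4. **buckling statistics** — weighted logistic regression of outcomes;
5. **bending analysis** — modulus extraction from force–deflection curves;
6. **bead-chain simulation** — an independent particle-based check;
7. **synthetic data** — seeded generators for all inputs.

## Linear stability of the self-propelled elastica

The filament is a planar Kirchhoff rod parametrized by its tangent angle
$\phi(s)$, $s \in [0, L]$, with curvature $\kappa = \partial_s \phi$. It is
driven by a tangential force density $f$ and damped by isotropic friction
$\eta$ per unit length; bulk hydrodynamics is neglected (the thin lubricating
slime layer dominates). Scaling $s$ by $L$ and time by $t_0 = L^4 \eta / B$
leaves one control parameter, the **activity coefficient**
$$\Gamma = \frac{L^3 f}{B},$$
a flexure number. The head is pinned by the obstacle; both ends are
torque-free. Seeking rotor solutions $\phi(s,t) = \phi(s) + \omega t$ of the
linearized dynamics gives
$$\kappa'' + \Gamma (1 - s)\,\kappa + \omega s = 0, \qquad
  \kappa(0) = \kappa(1) = \kappa'(1) = 0 .$$

Two independent routes to the critical $\Gamma_c$ are implemented:

- `hypergeom_threshold()` evaluates the closed-form condition — a
  combination of generalized hypergeometric functions ${}_pF_q$ at argument
  $-k/9$ — by direct power-series summation and bracketed root search. The
  series are summed with a term-ratio tolerance of $10^{-15}$; at
  $|z| \approx 3.4$ they converge in a few dozen terms. The trivial root
  $k = 0$ (where every ${}_pF_q$ equals 1) is excluded by bracketing in
  $(1, 100)$.
- `linear_threshold_numeric()` solves the boundary-value problem by
  shooting: two homogeneous and one particular initial-value solutions are
  integrated with `deSolve` at `rtol = 1e-10` (tight, because the boundary
  determinant is differenced), the $3{\times}3$ boundary system in
  $(c_1, c_2, \omega)$ is assembled, and the smallest $\Gamma$ with vanishing
  determinant is located on a logarithmic grid of 64 points in $(1, 100)$
  and refined by `uniroot()`.

Both give $\Gamma_c \approx 30.5722$, hence
$L_c = (30.5722\,B/f)^{1/3}$. The same solver with clamped-base,
free-top boundary conditions (`"clamped_free_gravity"`) reproduces Euler's
heavy-column constant $7.837$, a useful independent sanity check of the
machinery. The returned null mode is normalized to $\max|\kappa| = 1$ with
$\kappa'(0) > 0$; amplitude and sign are not physical (they are set by the
perturbation).

Whether $\omega$ should be treated as a free unknown of the boundary system
(rather than fixed to zero as on the trivial branch) is settled empirically:
with $\omega$ free, the shooting determinant reproduces the closed-form
root to eight digits, so that reading is adopted.

```{r theory}
hypergeom_threshold()
linear_threshold_numeric("clamped_free_gravity")$gamma_c
m_to_um(critical_length(B = 1.4e-16, f = 1e-3)) # um
```

## Nonlinear shape dynamics

Beyond threshold the shape evolution follows the full nonlinear balance: the
local bending moment gradient balances the integrated propulsion and
friction loads downstream of each point. In scaled units,
$$\partial_s^2\phi(s) =
  \Gamma \int_s^1 \sin(\phi(s') - \phi(s))\,ds'
  + \int_s^1 (1 - s') \cos(\phi(s') - \phi(s))\, \dot\phi(s')\,ds'
  + (1 - s) \int_0^s \cos(\phi(s') - \phi(s))\, \dot\phi(s')\,ds' .$$

`evolve()` discretizes $\phi$ at the midpoints of $n = 64$ segments (method
of lines). The friction integrals couple every rate to every other, so each
step solves a dense $n \times n$ mass-matrix system
$M(\phi)\,\dot\phi = b(\phi)$, with
$M_{ij} = h\,(1 - \max(s_i, s_j)) \cos(\phi_j - \phi_i)$; the stiff `lsoda`
integrator handles the time stepping adaptively. Torque-free ends are
imposed by ghost-node reflection, which makes the boundary curvature vanish
identically in the solver's own difference convention; the extrapolated
boundary curvature converges to zero as $O(h^2)$. The head is pinned by
construction, since positions are reconstructed by integrating the tangent
from $s = 0$ (`to_xy()`), which also preserves inextensibility exactly.

Runs are initialized with the leading eigenmode of the linearized operator
(dense eigendecomposition of $M_0^{-1} A$), scaled to a head angle of
`init_amplitude = 0.01` rad — the linearization fixes the mode shape but not
its amplitude, and 0.01 rad is small enough that the early evolution is
accurately exponential while large enough to keep integration times modest.
Integration stops when the head angle reaches 90°; subcritical runs return a
decay flag instead.

**Profile library.** `build_profile_library()` evolves 30 activity values,
log-spaced so that $L/L_c$ covers 1.05–9, and stores 64 snapshots per value
(first at $t = 0$, the rest geometrically spaced so the nonlinear stage is
well resolved). Interpolation between stored members is linear in time within a
member and linear in $\log\Gamma$ across members, **after phase alignment**:
a query time is mapped to the same fraction of each member's stopping time,
with the stopping time itself interpolated log-linearly in $\Gamma$. Phase
alignment matters because the growth rate varies strongly along the grid —
blending members at equal raw time mixes different buckling stages and
biases fits toward grid nodes. Contours are rebuilt from the blended angle
field, so interpolated shapes remain exactly inextensible. Midway between
grid nodes the interpolant deviates from a directly evolved contour by well
under 2% RMS of the contour length.

## Fitting contour tracks

An observed track is a time series of x–y polylines (µm). The residual
between an observation and a theoretical shape is the mean squared
Euclidean distance between arclength-corresponding points after resampling
both curves to 64 equally spaced points — the point-to-point rule after
arclength resampling is our reading of the integrated square distance (the
point-to-curve alternative is slower and changed nothing in trials). For
any candidate $(\Gamma, \tau)$ the optimal rigid rotation and translation
have a closed 2-D Procrustes solution, so they never enter the numerical
optimization. Both mirror images are tried, because the buckling direction
is chiral but arbitrary.

`fit_frame()` scans all library nodes for a seed and refines
$(\log\Gamma, \log\tau)$ by Nelder–Mead. `fit_global()` then fits one
parameter set $(\Gamma, t_0, t_{\text{offset}})$ plus a single rigid
transform to all frames simultaneously, mapping frame time $t_i$ to scaled
time $(t_i - t_{\text{offset}})/t_0$; per-frame results seed the joint fit,
which is restarted from three perturbed seeds. Physical parameters follow
from the species-median bending modulus:
$$f = \frac{\Gamma B}{L^3}, \qquad \eta = \frac{t_0 B}{L^4}.$$
Frames after secondary wall contact should be excluded upstream via the
track's validity mask. Straight frames are flagged uninformative (any
$\Gamma$ fits them at small amplitude). `bootstrap_global()` repeats the
fit on 20 random half-subsets of the frames (the published procedure fixes
the count, not the subset rule; we draw 50% of frames without replacement)
and reports interquartile ranges.

## Weighted logistic regression of outcomes

Each collision event $i,j$ (individual $i$, observation $j$) has length
$L_i$, pre-collision speed $v_{0,ij}$, and outcome $y_{ij} \in \{0, 1\}$.
The buckling probability is modelled as
$p = \mathrm{sig}((L - L_c)/\Delta L_c)$ with
$\mathrm{sig}(x) = (1 + e^{-x})^{-1}$; $L_c$ is the population median
critical length and $\Delta L_c$ the width of its distribution. Individuals
observed $N_i$ times get weight $1/N_i$ per event, so the weighted
log-likelihood
$$\log\mathcal{L} = \sum_{i,j} \frac{y_{ij}}{N_i} \log \mathrm{sig}(x_{ij})
  + \frac{1 - y_{ij}}{N_i} \log\left[1 - \mathrm{sig}(x_{ij})\right]$$
represents the population rather than the sampling.

`fit_logistic_length()` maximizes this by BFGS with the analytic gradient,
$\Delta L_c$ on the log scale for positivity, three quantile-based starts.
Standard errors come from the observed information matrix at the optimum
(the estimator behind published spreads is not specified; observed
information is the standard choice). Near-perfect separation is detected
when $\Delta L_c$ collapses below $10^{-3}\,\mathrm{median}(L)$; then Wald
errors are meaningless and the gap between outcome classes is reported as
an interval for $L_c$ instead.

`fit_logistic_velocity()` couples the threshold to the observed speed
through isotropic friction, $f = \eta v_0$:
$$L_c(v_0) = \left(\frac{\eta\,v_0}{30.5722\,B}\right)^{-1/3}
  = (\alpha v_0)^{-1/3},$$
and maximizes the same weighted likelihood over $(\alpha, \Delta L_c)$;
$\eta = 30.5722\,B\,\alpha$ is reported in nN s µm⁻². With all speeds
equal, $\alpha$ and $L_c$ are aliased (warned) and the model reduces
exactly to the length-only fit.

```{r logistic}
ev <- gen_events(population_spec(truth = list(Lc_um = 161, dLc_um = 35)),
                 n_events = 388, seed = 1)
fit_logistic_length(ev)
```

## Bending analysis

The micropipette force sensor converts deflection to force by Hooke's law
(spring constant 9.5 nN/µm in the emulated setup). For a filament spanning
two pillars a distance $\Delta x = 80$ µm apart and loaded mid-span,
standard beam theory gives
$$B = \frac{\Delta x^3}{48}\,\frac{\partial P}{\partial d}.$$
`fit_slope()` fits the force–deflection line with an intercept (absorbing
the contact-point offset; only the slope carries the modulus) and reports
$R^2$ and a loading/unloading hysteresis measure. `summarize_moduli()` uses
linear-interpolation quartiles and whiskers that reach the last measurement
within **one** interquartile distance of the box limit — the convention of
the emulated experiment's box plots, deliberately different from the common
1.5 IQR rule.

## Bead-chain simulation

An independent, particle-based route to the threshold: `run_bead_chain()`
integrates an overdamped Langevin equation (fixed-step Euler–Maruyama, C++)
for a chain of $N$ beads of diameter $\sigma$ spaced $\sigma/2$, with

- stiff harmonic bonds (stiffness 100, keeping stretch below 1%; the
  coarse-grained geometry fixes the rest length, not the stiffness),
- harmonic bending energy $\frac{\kappa_b}{2}\sum_j (\theta_j - \pi)^2$ on
  the turning angles,
- a constant active force $F_a$ per bead along the local tangent
  (central-difference tangent, one-sided at the ends),
- WCA repulsion from the two walls of a V-trap (opening angle 90°), and
- thermal noise of scale $kT$.

The continuum map is $B \approx \sigma\kappa_b/2$, $f \approx 2F_a/\sigma$;
each bead represents $\sigma/2$ of contour, so a chain of $N$ beads stands
for length $N\sigma/2$ (this consistent accounting matters: using the
bead-center span instead shifts the apparent threshold by tens of percent).
The per-length friction is $\eta = \mathrm{drag}/(\sigma/2)$. The timestep
is capped at $0.02\,\mathrm{drag}\,(\sigma/2)^2/\kappa_b$ and at a fifth of
the bond relaxation time; noise is applied as accumulated Brownian
increments every 0.02 time units, far below any physical time scale of the
chain. Trajectories are bit-reproducible given the seed (the noise comes
from R's RNG).

`threshold_scan()` collides chains of 12 lengths spanning $0.6$–$1.8\,L_c$
(8 replicates each; $L_c = 12\sigma$ by default, so the longest chains have
~43 beads) against the trap, classifies outcomes by sustained transverse
deviation of the chain from its head–tail chord exceeding $0.15\,L$, feeds
the outcomes to the same logistic regression used for experiments, and
converts the fitted median length to $\Gamma_c = \hat L_c^3 f / B$. The
observation horizon per run is 8 linear-growth times (floored near
threshold, where the growth rate vanishes and any finite window is a
choice); $kT = 10^{-3}$ keeps the persistence length three orders of
magnitude above the chain length while still seeding the instability.
The published simulations fix none of temperature, bond stiffness, or the
buckling criterion, so all are exposed as arguments; the 15% acceptance
band absorbs these choices. With the defaults the scan lands within about
10% of 30.5722.

## Synthetic data: what it does and does not emulate

The generators produce every input the pipeline consumes, with ground truth
embedded so all recovery tests are self-contained:

- `gen_events()` — individuals with one length each, observed
  $1 + \mathrm{Geom}$ times (mean 2; the emulated study reports repeated
  observations but no distribution), outcomes Bernoulli from the logistic
  model (length-only or velocity-coupled). Default lengths are uniform on
  30–600 µm — broad coverage around the threshold maximizes information for
  regression tests; a log-normal family is available for realism
  experiments. Speeds are uniform on 1–3 µm/s, the characteristic observed
  range.
- `gen_contour_track()` — Kirchhoff solver output sampled at frame times,
  rigidly transformed, with i.i.d. isotropic Gaussian point noise as a
  localization-error proxy (correlated segmentation noise is out of scope).
- `gen_bending_curve()` — linear force–deflection data with multiplicative
  force noise and Hooke-consistent pipette deflection.

Passing tests on these data show that the estimators recover the generating
mechanics under the model's own assumptions (isotropic friction, constant
force density, planar motion, logistic outcome model). They cannot show
that real filaments satisfy those assumptions, that segmentation noise is
uncorrelated, or that real populations have uniform length distributions.

## Numerical choices and limitations

- Problem sizes: solver tests use $n = 32$–64 segments (with a
  64-vs-128 convergence check), libraries of 7–8 members for fitting tests
  and 30 for production, logistic ensembles of 280–388 events matching the
  emulated study, and 96 collision simulations per threshold scan.
- Ties and degenerate inputs: zero-length polylines, constant deflections,
  single-outcome event tables, subcritical activities, and missing
  collisions all raise informative errors rather than propagating NaNs.
- The rotor frequency `measure_rotor_omega()` is measured from the
  late-time head-angle drift; near threshold the transient is long and the
  horizon (8 times the 90°-crossing time) may need to be raised.
- The library hull bounds fitted $\Gamma$: fits at the edge are flagged
  (`edge = TRUE`) and should be rerun with a wider library.
- Only planar, twist-free dynamics; no bulk hydrodynamics; no higher
  buckling branches; no collective effects.
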