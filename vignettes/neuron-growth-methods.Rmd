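---
title: "Phase-field neuron growth: model, numerics and morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field neuron growth: model, numerics and morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurongrowth)
```

## The model

`neurongrowth` simulates the early stages of neuron development in two
dimensions: lamellipodia formation from an initially circular cell
(stage 1), outgrowth of several neurites of similar length (stage 2),
differentiation of the longest neurite into the axon (stage 3), and
continued dendrite growth (stage 4). The state consists of four coupled
fields on a square lattice:

* the **phase field** $\phi \in [0,1]$, 1 inside the cell and 0 in the
  extracellular medium, with a diffuse interface;
* the **tubulin concentration** $c_{tub}$, normalized to the initial
  intracellular level, produced in the cell body and carried to the
  neurite tips by diffusion and active transport;
* a static random **orientation field** $\theta \in [0,1]$ whose
  gradient perturbs the interface;
* the **temperature** $T$ of a dendritic-solidification-style
  undercooling equation; the undercooling $\Delta T = T_{eq} - T$
  limits growth where latent heat has accumulated.

The phase field evolves as

$$\frac{\partial \phi}{\partial t} = M_\phi \Big[ \nabla\!\cdot\!\big(a(\Psi)^2 \nabla\phi\big)
  - \partial_x\!\big(a\,a_\Psi\, \partial_y \phi\big)
  + \partial_y\!\big(a\,a_\Psi\, \partial_x \phi\big)
  + \phi(1-\phi)\big(\phi - \tfrac12 + E + 6H\,|\nabla\theta|\big) \Big],$$

with the j-fold anisotropic gradient coefficient
$a(\Psi) = \bar a\,(1 + \delta \cos j(\Psi - \theta_0))$ of the
dendritic-solidification family ($\Psi$ is the interface normal angle,
set to 0 at degenerate gradients, where the convention is inert). The
tubulin balance is written for the conserved quantity $\phi\,c_{tub}$:

$$\frac{\partial (\phi c_{tub})}{\partial t} =
  \delta_t \nabla\!\cdot\!(\phi \nabla c_{tub})
  - \alpha_t \cdot \nabla(\phi c_{tub})
  - \beta_t\, \phi c_{tub}
  + \varepsilon_0 \frac{|\nabla\phi_0|^2}{\int |\nabla\phi_0|^2\, d\Omega},$$

where $\phi_0$ is the frozen initial cell: the production source lives
on the initial membrane and, being normalized by its own discrete
integral, injects exactly $\varepsilon_0$ units of tubulin per unit
time regardless of the interface shape. The driving force

$$E = \frac{\alpha}{\pi} \arctan\!\big(H_\varepsilon(\dot L)\, \gamma\, \Delta T\big),
\qquad \dot L = r_g\, c_{tub} - s_g,$$

couples growth to the tip extension rate $\dot L$ (tubulin assembly
minus disassembly) through a smoothed Heaviside gate
$H_\varepsilon(x) = (1+\tanh(x/\varepsilon))/2$; when assembly cannot
balance disassembly ($r\,c_{tub} < s$) the driving force is zero
exactly, inhibiting growth. $E$ is evaluated inside 6 x 6 *energy
activation zones* centered at detected neurite tips and is zero
elsewhere; during stage 1, before any tip exists, the whole interface
is driven (lamellipodia formation). Overlapping zones combine by
pointwise maximum.

The undercooling follows
$\partial T/\partial t = D_T \nabla^2 T + K\, \partial\phi/\partial t$
with $\Delta T = T_{eq} - T$. The growing front releases latent heat
($K$) which locally reduces $\Delta T$ and throttles $E$ - the
competition mechanism behind self-limited lamellipodia and neurite
selection.

### Staging

Stage transitions are schedule-driven (iteration counts), because the
model has no intrinsic trigger for them; the full-scale schedule is
500 / 10,500 / 28,500 / 35,000 iterations. In stage 2 all neurites
carry the global rates $(r_g, s_g)$ and grow at similar speeds. At the
start of stage 3 the geodesic length from the soma center to each tip
(shortest path within $\phi > 0$, diagonal steps weighted $\sqrt 2$) is
measured, the longest neurite is selected as the axon, its tip receives
the enhanced assembly rate $r_g^{tip}$ (so $r^{tip}_g c_{tub} > s_g$ at
the tip), and every other neurite receives rates with
$r\,c_{tub} < s$, making its zone force exactly zero. A turning angle
is sampled from the normal distribution of measured culture turning
angles (mean 41.673 deg, sd 32.007 deg), given a random sign (the
measurements are absolute angles), and an extracellular cue is placed
at a fixed distance from the tip in that direction; the activation zone
is shifted toward the cue so the axon curves accordingly. Stage 4
restores growth-permissive rates for all neurites and gives each tip a
cue.

Neurites of the same neuron are not allowed to merge: points whose
neighborhood contains two distinct arms of one neuron have their
$\phi$-increase suppressed, while contact between different neurons is
permitted.

## Numerics

### Isogeometric collocation

The strong form is collocated on tensor-product cubic B-splines
($C^2$), one collocation point per basis function at the Greville
abscissae $\hat u_i = (u_{i+1} + \cdots + u_{i+p})/p$ of an open
uniform knot vector with spacing 1, so the parametric and physical
lattices coincide and no geometric mapping is needed. Basis functions
and derivatives use the Cox-de Boor recursion. In value space every
derivative is one small dense product per direction
($G = D\,N^{-1}$ with $N$ the 1D Greville interpolation matrix), which
the whole integrator exploits. Verification: the collocation operators
reproduce quadratic polynomials to $10^{-9}$, and a manufactured
steady-diffusion solution converges at observed order $\ge 2$ over
three uniform refinements.

### Time integration

Implicit Euler with time step $\Delta t = 0.01$ and Newton-Raphson to
residual $\infty$-norm below $10^{-4}$. Design choices:

* **Anisotropy lagging.** The coefficients $a^2$ and $a\,a_\Psi$ are by
  default frozen at the previous time level for the whole step
  (first-order consistent, the same order as implicit Euler); the
  reaction term is differentiated analytically, so Newton converges
  quadratically - in practice 1-2 iterations per step. Re-lagging the
  anisotropy at every Newton iterate (available as
  `solver_settings(anisotropy_lag = "iterate")`) makes the iteration a
  fixed point whose contraction degrades with anisotropy strength; at
  $\delta = 0.15$ it stalls just above $10^{-4}$, which motivated the
  default.
* **Linear solves.** The Newton systems are solved matrix-free by
  BiCGSTAB with a tensor-product preconditioner
  $(I - \beta G_{xx}) \otimes (I - \beta G_{yy})$ whose inverse is two
  dense 1D products; for the nonpositive collocation spectra this
  preconditioned iteration converges for any $\beta$. No sparse
  factorization is ever formed.
* **Operator splitting.** $\phi$ is stepped first (Newton), then
  $c_{tub}$, then $T$ - sequential first-order splitting. The tubulin
  step is implicit in the local decay/time terms and explicit in the
  transport terms, which at the default coefficients sit a factor ~6
  below their stability limit; the bookkeeping variable
  $\max(\phi, 10^{-3})\,c_{tub}$ keeps the update well defined where
  the cell is absent while leaving the discrete balance exact wherever
  $\phi \ge 10^{-3}$, and concentrations below the phase cutoff
  $\phi < 0.005$ are pinned to zero (dividing spline-interpolation
  ringing by a near-zero $\phi$ would otherwise destabilize the
  explicit terms). With decay and advection off, the discrete total
  $\sum \phi c_{tub}$ grows at $\varepsilon_0$ per unit time to within
  1%.
* **Boundary conditions.** Boundary collocation rows are replaced by
  homogeneous Neumann (zero normal derivative) conditions - a closed
  extracellular medium that conserves tubulin. Corners carry the
  y-direction condition. A Dirichlet variant exists for manufactured
  verification problems.
* **Domain extension.** When a tip comes within 10 points of a
  boundary the knot lattice grows by 10 spans on the approached side
  (optionally all sides). Fields transfer through their spline
  interpolants - exact at surviving collocation points - and new
  points take extracellular values. The orientation noise is a
  deterministic hash of global position and seed, so a point keeps its
  $\theta$ when the domain grows and successive extensions commute
  with a single larger one.

### The orientation field

$\theta$ is i.i.d.-uniform-like noise keyed on position, fixed for the
whole run. The noise term $6H|\nabla\theta|$ must stay below 0.5
everywhere: beyond that the reaction term destabilizes the $\phi = 0$
state and nucleates spurious cells in the medium. With the collocation
gradient of unit-range noise peaking near $|\nabla\theta| \approx 6$,
this bounds $H < 0.012$; the default is $H = 0.004$.

## Parameter defaults and the reduced study conditions

The structural constants of the model are fixed: $\Delta t = 0.01$,
soma radius $r_0 = 20$, cubic splines with knot spacing 1, 6 x 6
activation zones, CPT significance 0.05 with $q \in 1..10$, and the
full-scale stage schedule above. The remaining coefficients have no
direct physical counterpart; they were calibrated once, as a set, to
reproduce the qualitative staging at reduced scale, and are documented
(with units and rationale) in `?neuron_params`. The calibration logic:

* interface width $2\sqrt2\,\bar a \approx 1.6$ cells ($\bar a = 0.55$)
  - thin enough for distinct neurites on a 150-cell lattice;
* mobility $M_\phi = 25$ gives tip speeds of ~1-3 cells per time unit;
* the tip Peclet number $v\,w/D_T$ must stay below ~1 or the growing
  tip overheats itself and stalls: with the speeds above this requires
  a thermal diffusivity well above the front scale, $D_T = 8$, with
  latent heat $K = 1$;
* tubulin transport ($\delta_t = 2$, radially-outward active transport
  of speed 2) keeps tip concentrations above the disassembly threshold
  $s_g / r_g = 0.1$ along growing neurites.

The reduced **staging** configuration (150 x 150 lattice, schedule
100 / 900 / 1500 / 2000) is the reference problem for the heavy tests:
under seed 1 it produces a lamellipodial disk with several distinct
neurites, a selected axon that extends by >10 lattice units during
stage 3 while every inhibited neurite's front stays frozen to within
the tip-localization tolerance, and resumed dendrite growth in
stage 4. A 100 x 100 **smoke** configuration covers end-to-end checks,
and **full_383** records the full-scale setup (383 x 383, 35,000
iterations), which is not exercised by the test suite. The model is
grid-dependent by construction - the orientation noise re-randomizes
with resolution - so all tests fix the grid and the seed.

New neurites register only when their tip protrudes above the local
rim level by a prominence margin (3 cells) once a neuron has growth
cones; this keeps shallow ripples of a broad lamellipodial front from
spawning spurious neurites. Tip detection itself finds plateau-aware
maxima of the within-mask geodesic distance, merges maxima within a
separation radius into one growth cone, and refines the tip to the
largest-radius point of the near-maximal band (the 8-connected path
metric is anisotropic by up to ~8%, which would otherwise bias tips
laterally on oblique arms); maxima below the exclusion radius
$1.1 r_0 + 4$ are never tips, so a bare circle reports none.

## Morphometrics

Traced neurites - ordered (x, y) polylines, e.g. manual tracings in
pixels - are segmented by a change point test: at each interior point
the mean direction of the $q$ steps before is compared with the $q$
steps after; the deviation statistic is the angle between the two
resultants. Significance is calibrated against a Monte-Carlo null of
straight paths with isotropic direction noise matched to the trace (a
robust MAD estimate from the step-direction increments), using the
$1-\alpha$ quantile of the *maximum* statistic over the trace, which
controls the per-trace false-positive rate at $\alpha$ (a
per-candidate threshold would not: a 60-step trace has ~50 correlated
candidates). Declared change points are window-local maxima at least
$q$ apart. The test is run for $q = 1..10$ and the lowest $q$ with the
most change points is selected. Per segment, the arc length and the
signed turning angle between successive segment chords
(counterclockwise positive) are reported; absolute angles are used for
cross-sample comparison. Summaries use mean, sd ($n-1$; a single
value reports 0 by convention) and linear-interpolation quartiles.
Two angle samples are compared with a two-sided Mann-Whitney test
(exact enumeration for small untied samples, tie-corrected normal
approximation otherwise) with the Hodges-Lehmann shift estimate and
its distribution-based confidence interval at the achievable level
nearest 95%.

Simulated neurites are traced as the within-mask shortest path from
the soma center to the tip, which follows the arm to within half its
width; no skeletonization step is involved.

### What the synthetic fixtures do and do not show

The star fields, planted-turn traces and reduced configurations
exercise exact recovery properties: arm counts, tip positions, turn
indices and angles are known by construction, independently of the
detectors. They emulate the geometry of traced neurites, not the
imaging process - no phase-contrast noise, no uneven illumination, no
tracing subjectivity. Passing them demonstrates that the detectors and
the statistics are correct on clean geometry at the stated noise
levels; performance on real micrograph tracings additionally depends
on tracing quality. Likewise the reduced simulations demonstrate the
staged competitive dynamics (tip formation, axon dominance, inhibited
fronts), not the full-scale morphologies, which require the 383 x 383
/ 35,000-iteration setting.

## Known limitations

* Stage-5 maturation, neuron-type-specific branching and
  chemoattractant cue dynamics are out of scope.
* Stage transitions are imposed by the schedule, not emergent.
* The collocation discretization is not exactly conservative; tubulin
  bookkeeping is accurate to ~1% over the tested horizons.
* Tip identity across time uses nearest-neighbor matching with a
  6-cell radius; rapidly branching tips can transiently swap
  identities.
* At reduced scale the soma-plus-lamellipodia disk is proportionally
  larger relative to neurite lengths than at full scale.

## Worked example

```{r example, eval = FALSE}
cfg <- reference_configs(seed = 1)$staging
sim <- run_simulation(cfg, progress = TRUE)
sim
sim$registry            # per-neurite rates, positions, geodesic lengths
image(sim$state$phi)    # final morphology

tr <- extract_trace(sim$state$phi,
                    neurongrowth:::.centers_lattice(sim$state, sim$grid)[1, ],
                    unlist(sim$registry[sim$registry$neurite_id == sim$axon,
                                        c("ix", "iy")]))
sq <- select_q(tr)      # CPT segmentation of the simulated axon
summarize_angles(sq$cps$abs_angles)
```
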