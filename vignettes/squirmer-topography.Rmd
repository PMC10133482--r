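---
title: "Squirmer hydrodynamics near structured walls: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Squirmer hydrodynamics near structured walls: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

squirmtopo simulates a spherical tangential squirmer — a rigid sphere of
radius $a = 1$ that self-propels through a prescribed tangential surface
slip — swimming in Stokes flow near a no-slip boundary that may be flat or
carry a periodic topography whose amplitude is an order of magnitude below
the swimmer size. This vignette records the model, the numerical method,
the tunable parameters with their defaults and rationale, and the known
limitations. It is the package's own account of choices that were
genuinely open; empirical statements below are the ones the test suite and
`scripts/acceptance.R` recompute.

## The model

**Squirmer.** The flow obeys the non-dimensional Stokes equations. On the
sphere surface the fluid velocity equals the rigid-body motion plus an
axisymmetric tangential slip
$$u_s(\Theta) = \sum_n B_n V_n(\cos\Theta), \qquad
V_n(x) = \frac{2\sqrt{1 - x^2}}{n(n+1)} P_n'(x),$$
where $\Theta$ is the polar angle from the orientation $\mathbf{n}$.
Modes beyond the second are set to zero, so the swimmer is characterised
by $B_1$ (free-space speed $|U| = \tfrac23 B_1$; we use $B_1 = 3/2$ for
unit speed) and the squirmer parameter $\beta = B_2/B_1$ ($\beta < 0$
pusher, $> 0$ puller, $= 0$ neutral). The slip evaluator internally
accepts a general mode list (used by the oracle tests), but the public
surface is the two-mode truncation. Production runs use $\beta = 7$, a
strong puller, because only strong pullers swim stably near a flat wall —
the phenomenon the wall studies build on.

**Topographies.** The wall surface is $z = h(x, y)$ about the mid-plane
$z = 0$, with $h$ one of: flat; a singly periodic sinusoid
$A\sin(kx)$; a doubly periodic sinusoid $A\sin(kx)\sin(ky)$; or doubly
periodic peaks $A(2\sin^2(kx)\sin^2(ky) - 1)$, all bounded by $\pm A$ and
with $k = 2\pi/\lambda$. For the peaks family the squared sinusoids halve
the spatial period, so the inter-peak wavelength is $\lambda/2$.

**Angles.** $\theta = \arcsin n_z$ is the pitch relative to the mid-plane
(negative = nose down); $\varphi = \mathrm{atan2}(n_x, n_y)$ is the
heading of the horizontal projection of $\mathbf{n}$ measured from the
$+y$ axis toward $+x$. The sign of $\varphi$ is a convention; the physics
is mirror-symmetric, so trajectories mirrored in $x$ are equivalent.

## The nearest-neighbour regularised Stokeslet method

The single-layer boundary integral
$$u_j(x) = -\frac{1}{8\pi}\int_{S \cup W} S^\epsilon_{ij}(x, y)\,
f_i(y)\, \mathrm{d}S_y$$
is discretised on two node sets per body: a *coarse* set carrying the
unknown traction $g[n]$ and a *fine* set carrying the quadrature, linked
by the nearest-neighbour matrix $\nu[q, n]$ (each fine node maps to its
nearest coarse node of the same body; ties break to the lowest index).
Aggregated kernel sums
$\sum_q S^\epsilon(x_m, x_q)\, \nu[q, n]\, \mathrm{d}A_q$ use the
*fine-node* areas; when the fine areas are uniform this reduces exactly to
the classic single-grid weight placement, and it is the only reading that
keeps the kernel rows and the force/torque balance rows dimensionally
consistent with each other. Collocating the boundary condition at the $N$
coarse nodes and appending the six discrete force/torque balance rows
(aggregated through the same $\nu$ and fine areas) gives a square dense
system of $3N + 6$ equations for the tractions and the rigid-body
velocities $(U, \Omega)$, solved directly by LU with partial pivoting
($N \lesssim 500$ at defaults). The continuum gauge freedom
$f \to f + \alpha m$ does not affect the solved dynamics: both discrete
gauge integrals vanish to rounding on our meshes by reflection symmetry.

The regularised Stokeslet is the Cortez blob kernel
$$S^\epsilon_{ij} = \frac{(r^2 + 2\epsilon^2)\delta_{ij} + r_i r_j}
{(r^2 + \epsilon^2)^{3/2}},$$
with the $-1/(8\pi)$ prefactor applied in the assembly, not the kernel.
Defaults $\epsilon = 10^{-3}$ and sphere refinements
$(n_s, N_s) = (4, 18)$ — i.e. 96 traction and 1944 quadrature nodes —
reproduce the free-space speed to better than 1%.

**Sphere mesh.** Each face of the circumscribing cube is split into
$n \times n$ cells; one node per cell centre is projected radially. The
node weight is the *exact* solid angle of its projected cell (closed-form
corner formula), so the weights sum to $4\pi$ to rounding. Cell-centre
placement guarantees the coarse and fine meshes share no node whenever the
refinement ratio has an even numerator (e.g. 4 vs 18): coincident
coarse/fine nodes would inject the finite but huge self-term
$2/\epsilon$ into the quadrature and destroy its accuracy — this drove
several discretisation defaults below.

**Half-space image kernel.** For a flat wall the package can avoid wall
unknowns entirely by swapping the kernel for a regularised Blakelet: the
image system (mirror Stokeslet, potential dipole, Stokeslet doublet) with
every inverse power of the image distance regularised by the same blob
width. On the wall plane the classical cancellation happens separately at
each power of the image distance, so this variant satisfies the no-slip
plane condition to rounding for *every* $\epsilon$ — a stronger property
than the published image systems, whose wall velocity vanishes only as
$\epsilon \to 0$ — while still converging to the classical Blake tensor as
$\epsilon \to 0$ and to the free-space kernel far from the wall. Both
limits are enforced in the test suite against independent oracles.

**Wall patch.** Topographies require an explicit wall: a truncated square
patch of side $L$ that re-centres under the squirmer at *every*
right-hand-side evaluation (keeping the truncation error
state-independent). An equally spaced cell-centred grid on the unit square
is stretched componentwise by $f(x) = \tfrac12\tan(\pi x/2)$ (halving the
central cell relative to the edge cell), dilated by $L$, lifted onto the
topography, and weighted by mapped cell area times the metric
$\sqrt{1 + |\nabla h|^2}$ — so flat-wall weights tile $L^2$ exactly. The
wall's nearest-neighbour assignment is computed once on the flat grid
template: for $A = 0$ it equals the 3-D assignment, for $A = 0.1$ it can
differ only at near-ties, and it keeps the right-hand side smooth in time
(no discrete reassignment as the patch slides along the topography).

## Parameters, defaults, and why

| parameter | default | units | rationale |
|---|---|---|---|
| $B_1$ | 3/2 | — | unit free-space speed |
| $\beta$ | 7 (wall studies) | — | strong puller: stable near-wall swimming |
| $\epsilon$ | $10^{-3}$ | radii | regularisation error is $O(\epsilon)$; speed changes < 0.5% from $10^{-2}$ to $10^{-3}$ |
| $(n_s, N_s)$ | (4, 18) | — | ~1% free-space speed error; grids provably disjoint |
| $L$ | 8 | radii | patch truncation; instantaneous solves change < ~1.5% when $L$ doubles |
| $(n_w, N_w)$ | (20, 80) | — | see below |
| start | $(0, 0, 1.2)$, $\theta_0 = -0.17\pi$ | | standard release used by all wall studies |
| `stop_clearance` | 0.05 | radii | above mesh/regularisation scales, below stable gaps (~0.15) |
| `rtol`, `atol` | $10^{-6}$, $10^{-8}$ | — | halving changes the flat-wall end point < $10^{-3}$ |
| integrator | Dormand–Prince 5(4) | | adaptive; orientation renormalised each accepted step |

**Wall resolution $(n_w, N_w) = (20, 80)$.** This was the one default we
had to choose by measurement. Coarser traction grids
($n_w = 16$ at $L = 8$) under-resolve the wall traction beneath the
squirmer so badly that the vertical velocity at gap $\approx 0.2$ is wrong
by $\sim 50\%$ and the flat-wall run plunges into the wall instead of
settling. Odd fine/coarse ratios (48/16, 80/16) make every coarse wall
node coincide with a fine node — the $2/\epsilon$ self-term problem above.
With $(20, 80)$ the discretised flat wall settles at $z^* = 1.1556$,
within 0.2% of the boundary-element reference 1.1578 and consistent with
the half-space-kernel result 1.1689, at ~0.3 s per mobility solve on one
core. Gap-sensitive *instantaneous* quantities still converge slowly
toward the half-space kernel (the test suite checks the convergence trend
and agreement at higher resolution), but the settled dynamics — the
quantity the production runs depend on — are accurate at the default.

**Stopping rules.** Runs halt at `max_time`; or when the
squirmer–wall clearance (global minimisation of centre-to-surface
distance: coarse grid beneath the centre, Nelder–Mead refinement,
tolerance $10^{-6}$) reaches `stop_clearance`, because below that the
physics would be dominated by unmodelled short-range surface interactions;
or when a monitor requests it — the flat-wall validation stops once
$|\mathrm{d}z/\mathrm{d}t| < 10^{-4}$ holds over a trailing unit time
window ("settled").

**Oscillation metrics.** The steady vertical oscillation amplitude is half
the peak-to-peak range of $z$ over the final window (the conservative
reading of "oscillation" vs the topography amplitude), and the wavelength
is the mean horizontal-arc-length spacing of consecutive $z$ maxima with
local quadratic peak refinement.

## Validation anchors

The suite pins the implementation to independently known values: the
free-space speed table (numerical vs the closed form
$|U| = \tfrac23 B_1$); Stokes drag $6\pi$ and rotation torque $8\pi$ from
the resistance solve; mobility/resistance reciprocity; the classical
identity that the surface-averaged slip equals $-U_{\text{free}}$; the
Blake-tensor and wall-no-slip limits of the image kernel; and the
flat-wall stable height against the published boundary-element value
1.1578. Topography phenomenology is checked at the regime level: small
wavelengths ($\lambda \lesssim 2$) perturb the flat-wall height by less
than the topography amplitude, large wavelengths produce larger
oscillations whose spatial period locks to the topography
($\lambda = 8$), trough-aligned swimming over the peaks family is nearly
flat, and hydrodynamic capture (heading relaxing toward a trough) occurs
only when the swimmer diameter is comparable to the wavelength.

## Problem sizes used by the tests

Symmetry and regression properties hold at any resolution, so those tests
run at reduced size ($n_s = 3$, $N_s = 8$, $n_w = 10$, $N_w = 32$,
$L = 6$, short horizons) — the properties checked there (bit-identical
reruns, $x \leftrightarrow y$ symmetry, $A = 0 \equiv$ flat,
heading-invariance) do not depend on accuracy. Quantitative acceptance
checks (speed table, stable height, steady oscillation amplitudes and
wavelength) run at the full defaults above, with trajectory horizons
chosen as the shortest that reach the statistically steady window: the
short-wavelength amplitude runs use $t = 12$--$16$ (steady by $t \approx
6$--$8$; analysed over the final half), the wavelength-locking run at
$\lambda = 8$ uses $t = 25$ so the final window spans several topography
periods, and the headline reproduction in `scripts/acceptance.R` keeps
$t = 25$ throughout.

## Limitations

- Hydrodynamics only: no steric, contact, electrostatic or Brownian
  effects; runs stop at the clearance threshold rather than model them.
- Spherical squirmers with two tangential modes; no prolate shapes, no
  swirl (rotlet-dipole) modes, no time-dependent slip.
- The wall is a truncated, re-centred patch, not a periodic (Ewald-type)
  representation; accuracy in the gap degrades if the squirmer approaches
  the surface much closer than the central wall spacing.
- The square patch breaks exact rotational invariance of the
  discretisation at the quadrature-error scale (~$10^{-4}$ over a few
  time units at reduced resolution); the half-space kernel does not.
- Reported stable heights carry the ~1% discretisation accuracy of the
  default meshes; fourth-decimal agreement with published values would
  require node placements those references do not document.
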