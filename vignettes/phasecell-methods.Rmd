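---
title: "Modeling single-cell migration on curved and porous substrates with phasecell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling single-cell migration on curved and porous substrates with phasecell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`phasecell` simulates a single motile cell in three dimensions with a
nonconserved phase field. The cell is an order parameter $\rho(\mathbf{x},t)$
whose $\rho = 0.5$ level set is the membrane; a vector field
$\vec p(\mathbf{x},t)$ represents the local strength and orientation of the
actin machinery. A substrate is described by two static diffuse fields: the
solid location $\Phi$ and a wider sensing shell $\Psi$ that a cell detects
shortly before contact, plus a spatial adhesivity map $\kappa(\mathbf{x})$.
All quantities are nondimensional; the intrinsic scales are 1 length unit =
1 µm and 1 time unit = 10 s (set by the actin diffusivity and the
depolymerization rate).

The cell field evolves as

$$
\partial_t\rho =
  D_\rho\nabla^2\rho
  \;-\; \alpha\,\vec p\cdot\nabla\rho
  \;-\; \kappa\nabla\Phi\cdot\nabla\rho
  \;+\; w_0\,\nabla\!\cdot\!(\kappa\nabla\Phi)\, 6\rho(1-\rho)
  \;-\; \lambda\rho\Phi^2
  \;+\; (1-\rho)\bigl(\rho-(1-\delta)\bigr)\rho ,
$$

with the interface set point
$\delta = \tfrac12 + \mu(V_0 - V) - \sigma|\vec p|^2$. The terms are, in
order: interface diffusion; advection of the membrane by actin; conformal
adhesion transport toward the substrate; a graded wetting force (the
Allen–Cahn variational derivative of the contact energy
$w_0\kappa\int\nabla\Phi\cdot\nabla g(\rho)\,dV$ with
$g(\rho)=\rho^2(3-2\rho)$), which makes the spread footprint respond to the
*magnitude* of the local adhesivity; exclusion of the cell from the solid;
and bistable boundary motion. The cubic is written with threshold
$1-\delta$ so that both bulk phases $\rho = 0,1$ are dynamically stable
while $\delta > \tfrac12$ advances the interface and $\delta < \tfrac12$
retracts it; volume control then acts in the stabilizing direction
($V > V_0$ lowers $\delta$ and retracts).

The polarity field evolves as

$$
\partial_t\vec p =
  D_p\nabla^2\vec p - \tau_1^{-1}\vec p
  - \gamma(\nabla\rho\cdot\vec p)\,\vec p
  - \Phi^2\vec p - \beta\,\vec S ,
$$

with the actin source

$$
\vec S = \Psi\left[(1-\theta)\hat P(\nabla\rho) + \theta\nabla\rho\right]
       + \varepsilon\,\chi\, e^{\chi\zeta c}\,\nabla\rho .
$$

$\hat P$ rotates the polymerization direction tangential to a nearby
substrate (the $\theta$-split between pushing into a surface and turning
parallel to it); $\chi = 1-\tanh^2 G(\rho-\tfrac12)$ localizes the second
term to the membrane; $c = \nabla\cdot(\nabla\rho/|\nabla\rho|)$ is the
level-set membrane curvature (negative on convex bulges); and
$\zeta = f_0 T\,(A-A_0)/A_0$ is the global membrane stretch relative to the
minimum area $A_0$ of a stationary free cell. The exponential factor is the
membrane-tension term: polymerization decays where the membrane is stretched
and locally convex, which is what lets the cell read substrate curvature.
Because $\nabla\rho$ points into the cell, the source enters with $-\beta$
so that generated polarity pushes the membrane outward.

## Reference state and initialization

Cells start as a binary 17 µm cube (or a sphere; both relax to the same
steady shape within a few percent) with unit polarity pointing down,
$\vec p = -\vec e_z$. The reference area $A_0$ comes from relaxing a cell
with no substrate and no actin generation to stationarity
(`free_cell_reference()`, residual below $10^{-6}$); the stretch
$\zeta$ is clamped at zero since $A_0$ is the minimum. The relaxation box
leaves at least 12 µm of clearance — diffuse tails couple measurably to the
mirror boundary in smaller boxes and the relaxation then never converges.

The weak volume control of the model ($\mu = 0.001$) deserves a note: a
stationary droplet balances curvature-driven shrinkage against the volume
term, which requires $\delta - \tfrac12 = \sqrt{2D_\rho}/R$, i.e. a steady
deficit $V_0 - V \approx \sqrt{2D_\rho}\,/(R\mu)$. For the 17 µm cell this
is about 2.7–3 % of $V_0$ — an intrinsic property of the parameter set, not
a numerical artifact; tests on volume conservation must budget for it.

## Numerical scheme

Explicit Euler with second-order central differences on a regular lattice
with zero-flux (mirror) boundaries; the conformal adhesion transport is
discretized upwind, because strong adhesion ($\kappa = 5$) compresses the
interface against a wall below lattice resolution and a centered transport
stencil then oscillates and diverges. Updates are restricted to an active
band — every voxel carrying any appreciable cell density (threshold
$10^{-8}$, comfortably containing the $\rho \ge 0.01$ region) dilated by a
1 µm buffer, rebuilt every 10 steps — which matches full-domain integration
to better than $10^{-6}$ in $\rho$ while skipping most of the box. The
constructor rejects `dt` above $0.2\,\mathrm{dx}^2/\max(D_\rho, D_p, 1)$.
The area $A$, stretch $\zeta$, indicator $\chi$ and curvature $c$ are
recomputed every step. The exponent $\chi\zeta c$ is clamped to $\pm 8$ as
a numerical guard; voxels with $|\nabla\rho| < 10^{-6}$ (bulk) carry zero
curvature.

Simulations in this package run at spacing 1 µm with $\mathrm{dt} = 0.04$
(half the stability guard; halving it again changes no scenario outcome).
At that resolution the interface spans about three voxels, and the membrane
indicator uses $G = 4$ so that $\chi$ covers the whole resolved interface;
the steep $G = 14$ indicator is appropriate for finer lattices
(spacing 0.5), where the same band is resolved by several voxels. This
choice is load-bearing: with a membrane band much thinner than the lattice
the tension term cannot act, and the model loses the sustained crawling
(~0.3 µm per time unit, i.e. ~2 µm/min — a physiologic speed) that all of
the migration phenomenology rests on.

Two coefficients of the model are reconstructions whose absolute scale the
source material does not fix, and each was calibrated once, against the
model's own stated behaviors, before any acceptance measurement:

* the wetting normalization $w_0$ (`adh_scale`): set so that a cell on a
  weakly adhesive surface ($\kappa = 1$) stays a rounded, weakly wetting
  droplet while $\kappa = 5$ produces strong spreading — the two regimes
  the adhesive-strip experiments distinguish;
* the membrane indicator width at spacing 1 ($G = 4$), as above.

## Substrates

All substrates are built as binary solid masks on a spacing-1 lattice and
relaxed into $\Phi$ and $\Psi$ by brief diffusion ($D_\Phi = 0.5$ for a
total time 0.15; $D_\Psi = 4$ for 0.25), integrated with a stable internal
substep — it is the total diffusion time that sets each interface width.
$\Psi$ is clipped from below by $\Phi$ so the sensing shell always covers
the solid.

* **Adhesive strips**: flat slab, $\kappa = 5$ on a centred strip, 1
  elsewhere.
* **Hemisphere array**: 12 µm bumps on a square lattice; the validation
  geometry for the tension term.
* **Particle-templated material (PTM)**: a layered random close packing of
  35 µm spheres (periodic drop-and-settle deposition with a sticky-particle
  rolling budget), voxelized and inverted. Spheres rest at centre distance
  $2r(1-s)$ with $s = 0.0543$, which makes the circular interconnect
  windows 0.325 sphere diameters wide; the rolling budget is fixed at 4,
  which lands the bulk union volume fraction at the random-close-packing
  value 0.64. The full-scale combination of window fraction and packing
  fraction cannot be produced by a strictly hard-sphere bed, so the
  generator satisfies the two quantitative anchors (window 0.325 D, union
  fraction 0.64) and treats settling quality as the free algorithmic knob.
* **Three-pore interconnect**: the isolated pore–window–pore motif. The
  desk-scale fixture uses 42 µm pores probed by a 7 µm-radius cell so that
  the window/cell diameter ratio — the number that controls interrogation —
  matches the full-scale study (~1.05); a smaller pocket would test size
  exclusion instead of curvature sensing.
* **Hyperboloid channel**: same maximum and minimum diameters as the
  interconnect motif but with far lower wall curvature at the throat; the
  control that separates aperture from curvature.
* **Bijel-templated material (BTM)**: Cahn–Hilliard coarsening
  ($u_t = \nabla^2(u^3 - u - \nabla^2 u)$, symmetric 50:50 quench,
  stabilized semi-implicit spectral update with a short small-step start)
  stopped when the first-moment structure-factor length reaches 30 µm,
  then thresholded at $u > 0$. The resulting mask is bicontinuous with
  saddle-dominated (non-positive Gaussian curvature) internal surfaces.

The spinodal stopping length is measured as
$L = 2\pi\sum S(k)/\sum k\,S(k)$, which returns the full (solid + void)
wavelength; single-phase pores are roughly $L/2$.

## Scenario protocol

Scenario runs record shape metrics every time unit: centroid and
displacement, co-area surface area, volume, inertia-tensor eigenvalues
$k_{11}\ge k_{22}\ge k_{33}$, shape energy, mean $p_z$, and a diffuse
contact-area proxy ($\int\chi\Psi^2 dV$ normalized by the mean membrane
thickness). Steady state is declared when centroid motion stays below
$10^{-3}$ µm per unit and $\max|\partial_t\rho|$ below $10^{-4}$ per unit
for ten consecutive units. Two seeding conventions matter: the hemisphere
cell starts 2 µm off the apex axis, because the discrete problem is
otherwise exactly mirror-symmetric and no lateral decision can occur (the
outcome is insensitive to the offset's size); and the pore-motif cell
starts with its leading edge a few µm above the window, since an initial
polarity kick carries a free cell only ~8 µm before decaying
($\tau_1 = 10$).

Desk-scale problem sizes were chosen to keep a full scenario within a few
minutes: grids up to $52\times52\times104$, run lengths 80–300 units, and
the spacing-0.5 discretization check run to t = 40 on the hemisphere pair.

## What the generators do and do not emulate

Synthetic substrates reproduce the geometric features that drive the
studied behavior — curvature landscapes, window/pore ratios, adhesion
patterning — not materials chemistry (no particle jamming or wetting
physics in the spinodal mask, no mechanical compliance anywhere). The cell
model contains no nucleus, focal adhesions, or lamellipodial substructure,
so absolute aspect ratios and contact areas underestimate real cells;
only orderings and relative dynamics are asserted by the tests. Passing the
suite therefore shows that the implemented dynamics reproduce the model's
qualitative substrate-response phenomenology at desk scale, not that the
model quantitatively predicts any particular cell type.

## Known limitations

* Explicit Euler only; the time step is diffusion-limited, and production
  resolutions below 0.5 µm would be slow.
* The literal rendering of some published terms is ambiguous (the cubic's
  sign convention, the adhesion operator, the curvature and stretch
  normalizations); this package fixes each by its stated physical contract
  and documents every such decision here.
* The weak volume control lets small cells drift several percent below
  their initial volume (see above).
* Metrics are voxel-based; meshes are used only for export and curvature
  maps (marching tetrahedra, watertight but not feature-adaptive).
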