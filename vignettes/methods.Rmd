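---
title: "Methods: the adaptive multigrid tumor-growth solver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adaptive multigrid tumor-growth solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`tumormg` simulates a growing tumor in a fibrotic (desmoplastic) tissue as
a thermodynamic mixture. Four solid constituents share the solid volume:
viable tumor cells $\phi_V$, dead tumor cells $\phi_D$, extracellular
matrix $\phi_E$, and healthy host cells $\phi_H = 1-\phi_V-\phi_D-\phi_E$.
The phase fields obey Cahn–Hilliard-type advection–diffusion equations:
the Fickian flux of phase $i$ is $M_i\nabla\mu$ with degenerate mobility
$M_i = \bar M\,\max(\phi_i,0)$, the chemical potentials are variational
derivatives of a ternary bulk free energy plus square-gradient interface
energies (coefficients $\varepsilon_T,\varepsilon_E$ for the tumor and ECM
interfaces and $\varepsilon_{TE}$ for their cross-adhesion), and an
optional ECM elastic energy with isotropic eigenstrains contributes
$\partial W/\partial\phi_E$ to $\mu_E$. All variables are dimensionless.

Around the phase fields sit:

* a Darcy flow problem: the solid pressure $p$ solves a variable-forced
  elliptic equation whose right-hand side is the net phase source, and the
  phase velocity is $u_\alpha = -k_\alpha(\nabla p - \gamma_T\varepsilon_T
  \mu_T\nabla\phi_T - \gamma_E\varepsilon_E\mu_E\nabla\phi_E)$; the ECM
  additionally drifts down its own potential gradient,
  $u_E = u_\alpha - \bar M\phi_E\nabla\mu_E$;
* quasi-steady reaction–diffusion species: oxygen and glucose (delivered
  by the vasculature, consumed predominantly by tumor cells), CO$_2$,
  lactate and the charged species (bicarbonate, H$^+$, Na$^+$) with a
  shared electro-diffusive drift and Cl$^-$ closed algebraically by
  electroneutrality, and the tumor growth/angiogenic factors;
* transient tissue species: matrix-degrading enzymes (diffusing, sourced
  by tumor cells), ECM-based myofibroblasts (advected by $u_E$ with an
  explicit growth-factor counter-flux, no self-diffusion), and blood and
  lymphatic vessel densities (advected, chemo-/haptotactic, diffusing,
  with far-field Dirichlet values 0.2).

Every spatially varying diffusivity or transfer coefficient is blended
across phases with the smoothstep $Q_3(x)=x^2(3-2x)$:
$\psi = \psi_E Q_3(\phi_E) + [1-Q_3(\phi_E)]\{\psi_T Q_3(\phi_T/\phi_C) +
\psi_H[1-Q_3(\phi_T/\phi_C)]\}$ with $\phi_C = 1-\phi_E$; the degenerate
case $\phi_C = 0$ falls back to the host coefficient. Sources use sharp
Heaviside gates with $H(0)=1$: mitosis requires $n \ge n_h = 0.3$ and is
upregulated by growth factors; necrosis activates below the viability
limits $n_{v,V}=0.21$, $g_{v,V}=0.1$; dead cells lyse at unit rate; ECM is
secreted by myofibroblasts (rate 5, gated by growth factors above 0.2 and
boosted up to a factor $1+2\cdot$(hypoxia depth) under hypoxia) and
degraded by enzymes (rate 5).

# Discretization and the solver

Space is discretized on a cell-centered, block-structured Cartesian
hierarchy: global levels $\kappa_{\min}..0$ each cover the domain with one
block, refinement levels $\kappa\ge 1$ consist of rectangular blocks,
spacing halves per level, and blocks align to even parent indices so
parent/child cells nest 8:1. Every block stores one ghost layer per face;
interior cells are indexed $1..N$, ghosts $0$ and $N{+}1$, and centers
obey $x_i = L + (i-\tfrac12)\eta$.

Time stepping is Crank–Nicolson on the phase fields with the fourth-order
equations split into second-order pairs $(\phi,\mu)$ solved
simultaneously. The surface-adhesion cross terms
$\varepsilon_{TE}^2\nabla^2\phi$, the upwinded advective terms, the source
terms and the elastic derivative are treated explicitly at the old time
level; species, sources and velocities enter a step at the old time
(operator splitting). The implicit system of a step is solved by the
adaptive FAS-FMG pass:

* **Relaxation.** Red–Black Gauss–Seidel (colored by the parity of the
  global index sum, so updates within a color are order-independent for
  7-point stencils). For the coupled block the three $\phi$'s are affine
  in the cell's $\mu$'s at frozen neighbors, leaving a 2×2 nonlinear
  system in $(\mu_T,\mu_E)$ solved by a damped Newton iteration (step cap
  5, tolerance $10^{-12}$, at most 25 iterations); on failure the cell is
  left unchanged for that sweep and counted. Face mobilities are frozen
  within a cell update (Picard), which preserves the fixed point. Cells
  within $d_\kappa$ of a block boundary receive $\nu_b$ extra sweeps,
  with $d_\kappa = 2^{\kappa-\kappa_{\min}}$ on global levels and 1/8 of
  the smallest block dimension on refined levels.
* **Transfers.** Restriction averages the 8 children; correction
  prolongation is trilinear (weights $\{27,9,3,1\}/64$); coarse–fine
  ghosts are filled by two tangential quadratic passes (weights
  $\{30,5,-3\}/32$, applied per tangential axis sequentially — the 3D
  ghost construction is our interpretation of the printed 2D stencil)
  followed by a quadratic normal pass through the intermediate point and
  two interior cells; edge and corner ghosts use the diagonal rule
  (nearest coarse center plus two fine diagonal cells, which lies exactly
  on the diagonal because blocks are even-aligned). Ghosts overlapping a
  same-level neighbor's interior are then overwritten by that data, and
  physical faces by the boundary conditions (Dirichlet ghosts
  $2v-\text{interior}$, Neumann mirrors). FMG solution interpolation is
  cubic Lagrangian (weights $\{-7,105,35,-5\}/128$), tensor-product per
  axis $x\to y\to z$, degrading gracefully to quadratic then injection
  where the 4-point stencil would leave the available data (block edges,
  physical boundaries).
* **FAS cycles.** The coarse level under a fine region is initialized by
  restriction, its right-hand side receives the tau correction
  $R(R_\kappa - L_\kappa\psi) + L_{\kappa-1}(R\psi)$ on the overlap and
  keeps its own RHS elsewhere; the correction $\bar\psi - \psi^0$ is
  prolonged and added on the overlap. The coarsest level is solved either
  by exactly $\nu_0$ sweeps (the `"nu0"` option, used when matching the
  published cycle verbatim) or, by default, by sweep batches until the
  coarsest-level tolerance is met — the printed algorithm allows "a direct
  solver or $\nu_0$ smoothing steps" there, and the near-exact variant
  avoids V-cycle stagnation on shallow hierarchies.
* **FMG and adaptivity.** Levels are visited coarse to fine; below the
  root a fixed $r_\kappa$ cycles are run, from the root upward cycles
  repeat until the level residual norm (scaled $l_2$ over level interior
  cells) meets $tol_\kappa = tol_{\min}\sigma^{\kappa_{\max}-\kappa}$,
  with the minimum tolerance $5\times10^{-4}$ assigned to the finest
  level. After a level $\kappa\ge0$ converges, cells are flagged by the
  undivided gradient test on $\phi_T$ (squared sum of undivided centered
  differences compared against $C_\kappa = 0.05$ as printed, not
  $C_\kappa^2$), buffered by 4 cells per direction (a 9×9×9 cube, clipped
  at external boundaries and at the level's patch union so new blocks
  nest), clustered by the signature algorithm (accept at efficiency
  $\ge0.9$ or size $\le 2\times10^3$ cells; split at the most central
  zero-signature gap, longest axis first with ties toward the lower index
  and $x\to y\to z$; else at the most central sign change of the
  signature's second difference; else accept at efficiency $\ge0.5$ or
  bisect; trim empty edge slices), and the new level is populated by
  cubic interpolation (current data) and bit-identical copy from
  overlapping old blocks (previous-time data), with de-refined regions
  averaged down.

Solver constants default to the published configuration: $\gamma=1$
(V-cycles), $\nu_1=\nu_2=2$, $\nu_0=4$, $\nu_b=2$, $r_\kappa=1$,
$\sigma=4$, $\theta=10^{-2}$, minimum tolerance $5\times10^{-4}$.

# Parameters

Constants printed with the model (mitosis/necrosis/lysis rates 1/3/1, ECM
secretion/degradation rates 5/5, hypoxia and viability thresholds 0.3 /
0.21 / 0.1, growth-factor gate 0.2, far-field vessel densities 0.2, seed
$\phi_V=0.65$ with uniform $\phi_E=0.35$) are hard defaults. Everything
that lives only in an unavailable supplement — bulk-energy constants,
interface coefficients, diffusivity/uptake triples, ion and vessel
kinetics, Lamé/eigenstrain values — ships as a documented placeholder in
`inst/extdata/reference_config.yaml`, tagged `placeholder`. The main
choices and their rationale:

* $A_3=A_5=0.35$ makes the uniform host state ($\phi_T=0$,
  $\phi_E=0.35$) a bulk equilibrium, so the far field is quiescent;
  $A_1=1$, $A_2=A_4=0.5$ give an order-one ternary well.
* $\varepsilon_T=\varepsilon_E=2$ (length units of the 40-unit domain)
  sets a diffuse interface a few units wide — wide enough to be resolved
  on every grid of the shipped convergence protocol, including the
  coarsest ($\eta=2.5$); an unresolved interface would measure
  representation error rather than the scheme's order.
  $\varepsilon_{TE}=0.5$ keeps cross-adhesion at half the self-adhesion
  strength.
* Oxygen and glucose diffusivity triples $(12,12,15)$ and $(8,8,10)$ with
  tumor uptake 5 and 2 give penetration depths below the seed radius, so
  the tumor center turns hypoxic and necroses within a unit of simulated
  time — the qualitative regime the model is meant to exhibit (hypoxia,
  dead-core formation, ECM remodeling). Vascular supply is normalized so
  the far-field vasculature delivers unit concentration
  ($n_C = B_{nE}\phi_E / (B_\infty \phi_{E,0})$), keeping healthy tissue
  normoxic independently of the domain boundary; supply must vanish where
  vessels vanish.
* The regional sprouting fraction (0.1–0.8) is mapped octant-wise over
  the domain, a deterministic stand-in for the unpublished map that still
  perturbs the symmetry of vessel growth.
* Elasticity defaults off ($\varepsilon_e=0$) because its constants are
  placeholders; the machinery (stress assembly, $\partial
  W/\partial\phi_E$, the displacement solve by damped pseudo-time
  relaxation on the root grid) is implemented and tested on its
  degenerate invariants.

Open items in the printed model were resolved as follows: $Q_3$ is the
clamped smoothstep; $\mu_H$ (appearing only in the boundary conditions) is
not evolved; the ECM drift mobility is $\bar M\phi_E$; the growth-factor
production terms are $\lambda\,\phi_V$ (secretion by viable cells, per the
model's description); CO$_2$ and lactate vascular supplies default to
zero (vessels clear waste).

# Fixtures and what the tests show

The package generates all of its inputs programmatically:

* `poisson_mms` (product-of-sines manufactured solution) validates the
  multigrid machinery: mesh-independent cycle counts and $O(\eta^2)$
  solution error after FMG.
* `heat_mms` validates one Crank–Nicolson step against a dense
  linear-algebra solve of the same system.
* `cahn_hilliard_scalar` (a smooth spherical blob under the double well
  obtained from the ternary energy with the ECM and dead phases inert,
  no-flux boundaries) checks conservation — the discrete scheme is in
  divergence form, so total mass drifts only at the level of the solver
  tolerance — and stability of the nonlinear relaxation.
* `tumor` is the published seeded configuration: a sharp-interfaced cube
  of viable cells ($\phi_V=0.65$, side 10) centered in $(0,40)^3$ with
  uniform ECM.

The adaptive FAS cycle is additionally checked against an independent
dense two-grid oracle (scalar loops on full arrays) on an
everything-refined two-level mesh, where the two must agree to roundoff;
the relaxation kernel is compared sweep-by-sweep with a scalar-loop
reference; transfer operators are checked for their polynomial exactness
degrees (1, 1, 2, 3) and linearity.

These fixtures exercise the numerics, not the biology: passing tests
demonstrate correct operators, conservation, convergence of the iteration
and of the discretization on manufactured problems, and stable,
physically plausible dynamics of the coupled model at desk scale. They do
not calibrate the placeholder parameters against data, and real-tissue
behavior is outside what the suite can certify.

# The convergence study

`convergence_study()` follows the published protocol at reduced scale:
runs at doubled root resolutions with the time step on the linear
refinement path $\theta = 0.032\,\eta$ (the step count is chosen so the
end time is hit exactly while staying closest to the path), composite
$\phi_T$ sampled onto each run's uniform grid at the finest spacing
(fine-block data where present, trilinear interpolation of the coarser
composite elsewhere), successive-grid $l_2$ errors after averaging the
finer run down, and the observed order $\log_2(e_{\text{coarse}} /
e_{\text{fine}})$. The shipped protocol uses roots $8^3/16^3/32^3$ with
one refinement level and end time 1.0 — sizes chosen so the full study
runs in a few minutes on one CPU.

At these deliberately coarse grids the measured order sits slightly above
the first-order band: the successive-grid error is a mixture of the
interface-profile representation error (converging near second order),
the non-smooth Heaviside-gate shells in the sources (converging below
first order), and the genuinely first-order time/advection/splitting
component, which is small at this short horizon (halving $\theta$ at a
fixed grid isolates it). At the full published scales — twice-refined
hierarchies with finest spacings four times smaller — the first-order
component dominates and the expected order is one. The study reports
whatever it measures; nothing is rescaled toward an expected value.

# Numerical details and degenerate inputs

* Mobilities are clamped at zero ($\bar M\max(\phi,0)$), so undershoots
  cannot produce negative diffusion; the dead phase starts with zero
  mobility and decouples until necrosis populates it.
* The ion drift denominator carries a $10^{-12}$ floor; with all charged
  concentrations zero the drift is zero and Cl$^-$ closes to zero.
* The initial chemical potentials are evaluated consistently from the
  initial phases (including ghost layers) before the first step;
  otherwise the first step's old-time fluxes would see stale ghosts and
  leak mass.
* Heavisides are sharp with $H(0)=1$; ties in the clustering ("most
  central") break toward the lower index; axes scan longest-first with
  ties $x\to y\to z$.
* Empty flag sets produce empty block lists; regridding to an empty level
  removes it after averaging its data down; a single-level hierarchy
  degenerates the cycle to plain relaxation.
* Checkpoints use R's native serialization (no HDF5 binding is required);
  round-trips are bit-identical and the model is deterministic, so
  restarted runs reproduce direct runs exactly.

# Known limitations

* 2D operation is not provided; all operators are implemented in their 3D
  forms and the test problems are small 3D grids.
* The supplementary parameterization of the original study is not
  recoverable; quantitative trajectories therefore depend on the
  documented placeholder defaults, and only structural/qualitative
  behavior is asserted.
* The pointwise relaxation of the original work is specified only in its
  supplement; our diagonal-block Newton is a faithful-but-unverifiable
  reconstruction.
* The displacement solve is a simple damped relaxation on the root grid,
  adequate for the disabled-by-default elasticity; a production elastic
  solve would reuse the multigrid machinery.
* No time-step adaptivity; advection is first-order upwind; W-cycles are
  plumbed ($\gamma=2$) but all shipped configurations use V-cycles.
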