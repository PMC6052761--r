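# tumormg

Three-dimensional simulation of multispecies desmoplastic tumor growth —
the ECM-rich, fibrotic microenvironment typical of pancreatic
adenocarcinoma — with a diffuse-interface mixture model solved by a fully
adaptive nonlinear full-multigrid (FMG) finite-difference algorithm.

The package is for computational/mathematical oncology researchers who
want a tested, desk-scale implementation of the coupled machinery:
block-structured adaptive mesh refinement, Full Approximation Scheme (FAS)
V-cycles with Red–Black Gauss–Seidel relaxation, and the stiff
Cahn–Hilliard-type tumor system itself.

## The model

Viable tumor cells, dead tumor cells and extracellular matrix are tracked
as volume fractions φ_V, φ_D, φ_E (healthy host cells close the mixture,
φ_H = 1 − φ_V − φ_D − φ_E; the total tumor fraction is φ_T = φ_V + φ_D).
Each phase obeys an advection–diffusion law of Cahn–Hilliard type,

    ∂φ_i/∂t + ∇·(φ_i u_α) = ∇·(M_i ∇μ) + S_i,      M_i = M̄ φ_i,

with chemical potentials derived from a ternary bulk free energy plus
square-gradient interface terms (and, optionally, an ECM elastic energy
with eigenstrains),

    μ_T = ∂F_b/∂φ_T − ε_T² ∇²φ_T − ε_TE² ∇²φ_E,
    μ_E = ∂F_b/∂φ_E + ∂W/∂φ_E − ε_E² ∇²φ_E − ε_TE² ∇²φ_T.

The cell–ECM phase moves with a Darcy velocity u_α driven by the solid
pressure p; oxygen, glucose, waste products, ions and tumorigenic factors
are quasi-steady reaction–diffusion species with phase-blended effective
coefficients; myofibroblasts and blood/lymphatic vessel densities are
transient species advected by the ECM velocity with chemo-/haptotactic
fluxes. Mitosis is gated by hypoxia, necrosis by oxygen/glucose viability
limits, ECM is secreted by myofibroblasts and degraded by matrix-degrading
enzymes.

Each Crank–Nicolson time step is solved by an adaptive FAS-FMG pass:
relaxation by Red–Black Gauss–Seidel (a small per-cell Newton for the
coupled nonlinear block), averaging restriction, trilinear prolongation of
corrections, quadratic coarse–fine ghost interpolation, cubic FMG
interpolation of solutions, and signature-based clustering of flagged
cells (undivided gradient test) into refined blocks.

## Worked example

```r
library(tumormg)

h <- build_hierarchy(list(L = c(0, 0, 0), R = c(40, 40, 40)),
                     root_cells = c(32, 32, 32), n_global = 3, kappa_max = 2)
print(h)
#> <tmg_hierarchy> levels -2..2, domain [0,40]^3, DOF 37376
#>   kappa -2  eta 5         blocks 1
#>   kappa -1  eta 2.5       blocks 1
#>   kappa +0  eta 1.25      blocks 1
#>   kappa +1  eta 0.625     blocks 0
#>   kappa +2  eta 0.3125    blocks 0
```

The three global levels (8³ + 16³ + 32³ cells) carry 37,376 degrees of
freedom; the two refinement levels start empty and are populated by the
flag/cluster/regrid machinery as the interface evolves.

```r
st <- initial_condition(cfg = solver_config(theta = 0.02),
                        root_cells = 16, n_global = 2, kappa_max = 1)
st <- run_simulation(st, end_time = 0.2)
tail(st$log, 1)
#>    step time   dof cycles_finest residual_finest
#> 10   10  0.2 26560             1     0.000121079
```

After the first step the interface region is flagged and clustered into
one refined block, raising the composite mesh to 26,560 DOF; the implicit
phase-field solve converges in one V-cycle per step (residual ≈ 1.2e-4,
below the 5e-4 finest-level tolerance). By t = 0.2 the oxygen minimum
inside the seeded tumor has dropped to ≈ 0.24 — below the necrosis
viability limit 0.21 only later in the run, when a dead core forms.

A grid-convergence study along the linear refinement path θ = 0.032 η:

```r
convergence_study(c(8, 16, 32), kappa_max = 1, end_time = 1.0)
```

returns the successive-grid l₂ errors of φ_T and the observed order
`log2(e_coarse/e_fine)`.

A thin command-line driver is installed with the package
(`inst/cli/tumormg`): subcommands `run`, `converge`, `meshinfo` and
`fixtures` over the same functions. Snapshots are written as ASCII VTK
image-data files per block, logs as CSV, mesh summaries as JSON; the full
parameter set with provenance tags ships in
`inst/extdata/reference_config.yaml`.

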