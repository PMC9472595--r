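# tubulemc

Kinetic Monte Carlo simulation and theory of self-limited helical tubule
assembly from triangular monomers.

Monomers with three inequivalent, shape-complementary edges — the kind
realised with DNA origami triangles — assemble into cylindrical tubules.
A tubule is a rolled triangular lattice named by its rollup indices
`(m, n)` (carbon-nanotube convention: `m` lattice sites around one helical
turn, `n` along the orthogonal direction); its circumference is
`|C| = l0 sqrt(m^2 + mn + n^2)` and its diameter `D = |C|/pi`.  Programming
the three preferred dihedral angles of a target `(m, n)` into the monomer
makes that tubule the stress-free ground state, but assembly remains
polymorphic: the product is a distribution over neighbouring geometries,
and that distribution is set kinetically — it is quenched when a growing,
curling sheet first closes on itself, not at the final tubule length.

The package implements, per monomer edge `j` and bound edge pair `i`,

    H = sum_j (k_S/2) (l_j - l0)^2
      + sum_i (B/2) (theta_i - theta0_i)^2
      - E_B * n_bound                              [units of kBT]

and provides:

* **Simulator** — grand-canonical kinetic Monte Carlo from a single monomer
  against a bath at chemical potential `mu` (`c0 = c_SS exp(mu)`), with
  vertex moves, single-monomer association/dissociation, and edge
  fusion/fission split into seam (crack-healing) and closure (rim-joining)
  channels; the closure-channel attempt rate `f_fusion` is the control
  parameter for closure kinetics.  `run_trajectory()`, `run_batch()`.
* **Analysis** — outcome classification (defect-free / defective / open),
  `(m, n)` assignment from mesh topology, length/diameter measures, and
  ensemble aggregation.  `classify_outcome()`, `aggregate_outcomes()`.
* **Equilibrium theory** — the per-monomer lattice free energy
  `g = 2 gamma a0/L - (3/2) E_B + sum_i (B/4)(theta_i - theta0_i)^2 - T s`,
  the resulting `(m, n)` distribution, the continuum width fluctuation
  `Delta D / D0 = sqrt(kBT D0 / (4 pi Btilde L))` with
  `Btilde = (sqrt(3)/2) B`, and absolute free energies by Einstein-solid
  thermodynamic integration.  `discrete_distribution()`,
  `continuum_width_fluctuation()`, `thermodynamic_integration()`.
* **Kinetic model** — the deterministic growth–closure competition: a disk
  grows at `k0_grow * 2 sqrt(pi N a0)/l0` and closes into geometry `(m,n)`
  at `k0_close * I(N) * exp(-N sum_i (B/4) dtheta_i^2)`, yielding closure
  sizes, per-geometry probabilities and phase maps over `B` and
  `log10(k0_close/k0_grow)`.  `solve_closure_table()`, `phase_map()`,
  `gillespie_closure()`.

See `vignettes/tubule-assembly-methods.Rmd` for the models, conventions,
numerical choices, and known limitations.

## Worked example

Assemble one structure with target `(8,0)` at `B = 20 kBT`, `E_B = 6 kBT`,
`mu = -3 kBT`, fast closure (`f_fusion = 1e-2`):

```r
library(tubulemc)
target <- tubule_indices(8, 0)
params <- energy_params(E_B = 6, B = 20, target = target)
cfg    <- simulation_config(f_fusion = 1e-2, seed = 15)
traj   <- run_trajectory(target, params, bath_conditions(), cfg)
traj
#> trajectory: N_final=444 after 5678 sweeps, closed at N=358,
#>             events i/d/f/x = 1562/1119/130/9
out <- classify_outcome(traj$sheet, traj$closed, traj$N_close, traj$finished)
out$category; format(out$mn)
#> "defect_free"  "(7,0)"
c(D = out$D, L = out$L, L_close = out$L_close)
#>       D        L  L_close
#>   2.228   27.471   22.153
```

This run nucleated from a single monomer, grew as a curved sheet
(1562 insertions against 1119 deletions — assembly is strongly
reversible), closed into a cylinder at 358 monomers, and finished as a
defect-free `(7,0)` tubule: one lattice step narrower than the programmed
target, a typical polymorphic outcome.  The equilibrium lattice
distribution at the closure size concentrates on the target,

```r
cand <- candidate_geometries(target, width = 0.25)
eq <- discrete_distribution(cand, N = out$N_close, B = 20, target = target)
head(eq[order(-eq$P), ], 3)
#>  m n        D            P
#>  8 0 2.546479 9.999704e-01
#>  9 0 2.864789 2.960074e-05
#>  7 0 2.228169 2.946830e-08
```

so observing `(7,0)` at all is a kinetic effect: off-target closures
happen at smaller sizes, where the bending penalty `N * (B/4) dtheta^2`
has not yet crushed the neighbours.  The kinetic model makes this
quantitative — `solve_closure_table()` propagates the growth–closure
competition and returns the closed-geometry split, the never-closed mass,
and the closure-size distribution.

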