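---
title: "Kinetic Monte Carlo assembly of helical tubules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic Monte Carlo assembly of helical tubules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubulemc)
```

## The physical problem

Triangular monomers with three inequivalent, shape-complementary edges can
assemble into helical tubules: cylindrical triangular lattices labelled by
rollup indices $(m, n)$ in the carbon-nanotube convention, where $m$ counts
lattice sites around one helical turn and $n$ along the orthogonal
direction.  Each edge type $i$ carries a preferred ("ideal") dihedral angle
$\theta^0_i$; choosing the triple equal to the ideal angles of a target
$(m,n)$ makes that tubule the stress-free ground state.  Because the ideal
angles of neighbouring geometries differ only slightly, assembly is
polymorphic: thermal fluctuations and kinetics distribute the product over a
family of $(m,n)$ around the target.

`tubulemc` implements the full stack for studying this polymorphism:

* a grand-canonical kinetic Monte Carlo (KMC) simulator of assembly from a
  single monomer (`run_trajectory()`, `run_batch()`);
* structure classification into defect-free / defective / open outcomes with
  $(m,n)$ assignment (`classify_outcome()`, `classify_geometry()`);
* equilibrium models: the discrete lattice distribution
  (`discrete_distribution()`), the continuum (Helfrich) width fluctuation
  (`continuum_width_fluctuation()`), and absolute free energies by
  Einstein-solid thermodynamic integration
  (`thermodynamic_integration()`);
* a deterministic growth–closure kinetic model with a stochastic oracle
  (`solve_closure_table()`, `gillespie_closure()`, `phase_map()`).

## Hamiltonian

For a triangulated sheet with vertex positions $x$, the energy (in units of
$k_BT$, lengths in units of the stress-free edge length $l_0$) is

$$
H \;=\; \sum_{\text{edges } j} \tfrac{k_S}{2}\,(l_j - l_0)^2
\;+\; \sum_{\text{bound } i} \tfrac{B}{2}\,(\theta_i - \theta^0_{t(i)})^2
\;-\; E_B\, n_{\text{bound}} ,
$$

with $k_S = 200\,k_BT/l_0^2$ (stiff edges, the thin-sheet regime), bending
modulus $B$, and binding energy $E_B > 0$ per bound edge pair.  A bound edge
is a single record (its stretching is counted once); the dihedral
$\theta$ is measured through the material, so a flat sheet sits at $\pi$.
The harmonic $1/2$ prefactors are the package's convention; the per-monomer
bending energy in the lattice models is then
$\sum_i (B/4)(\theta^{(m,n)}_i - \theta^0_i)^2$, each bound edge being
shared between two monomers.

A geometric note: for the exact equal-edge embedding of an $(m,0)$ tubule,
the circumferential (type-1) edges are slightly *reflex*
($\theta_1 > \pi$; 3.3247 rad for $(10,0)$) while the other two types are
convex (2.7783 rad).  Staggered vertex rings make ring-parallel edges
locally valley-like — the antiprism geometry — even though the surface
curves outward.  All angles approach $\pi$ as $m \to \infty$.

## Ideal embeddings

`ideal_embedding()` does not relax a generic mesh.  A defect-free tubule
with every edge exactly $l_0$ is fixed by a linear map from lattice
coordinates to cylinder coordinates ($\phi = Ai + Bj$, $z = Ci + Dj$, radius
$R$); the five unknowns satisfy two closure constraints and three
chord-length constraints, solved by a damped Newton iteration to a residual
below $10^{-13}$.  This makes all same-type dihedrals identical by
construction and avoids the soft flex modes an open triangulated band
exposes to a generic stretch-only relaxation.  Geometries with
$m^2 + mn + n^2 < 7$ have no equal-edge embedding and raise an error.

## Move set and detailed balance

Moves are drawn per attempt with weights

| move | weight | proposal |
|---|---|---|
| vertex displacement | $N_v$ | uniform cube, half-width `delta_v` (0.12 $l_0$) |
| monomer exchange | `p_exchange` $\times\, n_{\text{free}}$ (0.1) | apex uniform in a cube of half-width `wp` (0.5 $l_0$) about the ideal position |
| seam fusion/fission | `p_seam` $\times\, (n_{\text{free}} + n_{\text{bound}})$ (0.1) | pairs sharing a vertex; $\le 1$ vertex merge |
| closure fusion/fission | `f_fusion` $\times\, (n_{\text{free}} + n_{\text{bound}})$ ($10^{-3}$) | distant boundary pairs; 2 vertex merges |

and time advances by $1/W$ per attempt, so one sweep is one attempted
vertex move per vertex.  The stationary distribution is grand-canonical,
$\pi \propto e^{\mu N - H}$ with one factor $1/v_p$ per vertex, where
$v_p = (2\,\texttt{wp})^3 = 1\,l_0^3$ is the association proposal volume;
the standard-state normalisation $c_{SS} v_p$ is absorbed into $\mu$.  All
acceptances carry the exact reverse/forward attempt-probability ratios:
free-edge and removable-monomer counts and the total-weight ratio $W/W'$
for exchange; partner-degeneracy counts $1/d$, channel-count ratios, and a
reversible-jump volume factor $v_p/(8 r_c^3)$ per merged vertex for
fusion/fission (`r_c` = 0.3 $l_0$ is the capture half-width; fission draws
the splitting displacement from the matching cube).  Two deliberate
exceptions to microscopic reversibility are documented below.

**Seam versus closure channels.**  A monomer binding into a lattice notch
forms its second bond essentially at the binding timescale, whereas the
first contact of two distant rims of a curling sheet is a rare collective
event.  The move set encodes this by attempting *seam* channels (fusable
pairs that already share a vertex, and fissions that split at most one
vertex) at `p_seam` per channel, and *closure* channels (no shared
vertices; fission splitting two) at `f_fusion` per channel.  `f_fusion`
is therefore exactly the closure-rate control parameter: the rate at which
an open structure attempts to close (or a closed seam to reopen).  With a
single global fusion budget instead, growth seams outnumber the attempts
and every structure ends riddled with unhealable cracks, which contradicts
the observed prevalence of well-formed tubules and well-bonded open spirals.

**Irreversible locks.**  Fission is restricted to bound edges adjacent to a
boundary vertex; interior edges of a fully closed tube are locked.  The
final seam-closing fusion of a tubule therefore has no reverse move — the
physical statement that reopening a closed tubule requires breaking many
bonds at once.  Similarly a fission that would disconnect the structure is
rejected (single-structure constraint).  Detailed balance holds everywhere
else; the stationarity tests below quantify this.

**Validation.**  The suite checks stationarity on the enumerable
monomer–dimer micro-system without any free parameter: (i) with a flat
target ($\theta^0_i = \pi$) the three dimer topologies are exactly
symmetric, tested by $\chi^2$; (ii) shifting $\mu$ by $\Delta$ shifts the
dimer:monomer odds by exactly $e^\Delta$; (iii) the absolute occupancy
matches a direct configurational-integral oracle — a 3-D insertion integral
averaged over monomer configurations from an independent R implementation —
including the symmetry number 2 of the dimer (the ordered
(base, apex) parameterisation covers each physical two-monomer state
twice) and the $1/W$ time-weighting of sweep-based sampling.  Equipartition
on fixed sheets and incremental-versus-full energy agreement complete the
suite.

## Classification

A zero-width crack (two coincident *free* edges) is indistinguishable from
a bound edge in a plain (vertices, triangles) mesh, so the simulator
exports its explicit bound-pair table and all topology operations consume
it.  `classify_outcome()` labels a finished trajectory `open` when no
closure (first boundary-cycle split 1 → 2) occurred; `defective` when the
final structure has more than two boundary cycles (residual cracks), an
inconsistent triangle 2-colouring, an interior vertex without six incident
triangles (a disclination), or rims whose rollup vectors disagree; and
`defect_free` otherwise, with $(m,n)$ read off by summing lattice steps
around a rim and reducing under the hexagonal point group.  For a manifold
triangulated cylinder these checks force a single consistent $(m,n)$ at
every axial station, so no separate waist-loop scan is needed.  Measures:
$D = |C|/\pi$ and $L = N a_0 / (\pi D)$, with $L_{\text{close}}$ evaluated
at the closure size $N_{\text{close}}$.

## Equilibrium models

The per-monomer free energy of an $(m,n)$ tubule of length $L$ is

$$
g^{(m,n)}_L = \frac{2\gamma a_0}{L} - \tfrac32 E_B
  + \sum_i \tfrac{B}{4}\big(\theta^{(m,n)}_i - \theta^0_i\big)^2 - T s ,
$$

and with geometry-independent entropy the equilibrium distribution at size
$N$ is $P^{(m,n)} \propto g_{\text{mult}} \exp[-N \sum_i (B/4)
(\Delta\theta_i)^2]$, where $g_{\text{mult}} = 2$ for chiral classes (the
mirror pair) and 1 for achiral ones.  In the continuum limit the bending
energy density is $(\tilde B/2)(2/D - 2/D_0)^2$ with
$\tilde B = (\sqrt3/2) B$ (the standard triangulated-membrane mapping,
verified against the discrete energy per area to better than 10% for
$m \ge 10$), and equipartition on $E(D) = \pi D L \times$ density gives

$$
\frac{\Delta D}{D_0} = \sqrt{\frac{k_B T\, D_0}{4\pi \tilde B L}} .
$$

The prefactor follows from the quadratic expansion; a direct quadrature of
the full Boltzmann weight agrees to 2% when fluctuations are small.

## Thermodynamic integration

Absolute free energies of fixed-topology lattices are computed along a
pathway anchored at an Einstein solid (independent tethers of spring $k_t$
to the relaxed lattice, three anchor vertices additionally tethered at all
stages to pin rigid-body modes; the reference free energy is analytic in
the same $1/v_p$ measure as the simulator, so $g$ is directly comparable
with $\mu$).  The default `method = "bridge"` splits the pathway at the
harmonic expansion about the minimum: Einstein → coupled-harmonic is an
analytic determinant ratio (a finite-difference Hessian), and only the
small anharmonic remainder is estimated by Bennett's acceptance-ratio
bridge between exact Gaussian draws and Metropolis samples of the full
model, with block-bootstrap errors.  The classical single-path
Gauss–Legendre integration is kept as `method = "einstein"`; it needs the
tether matched to the mode spectrum and many nodes because off-target
lattices are prestressed and own soft modes that concentrate the integrand
near $\lambda = 1$, and even then it retains a bias of a few tenths of
$k_BT$ per ~100-monomer lattice.  The bridge was validated against an
independent Hessian log-determinant oracle.

Relaxation before integration matters: the ideal $(m,n)$ embedding is not
the energy minimum when scored with the target's angles (stretch and bend
trade off), and tethering to a shifted centre biases the integral.
`thermodynamic_integration()` therefore quenches (downhill-only moves with
a shrinking step) and polishes with L-BFGS before building the reference.

Two headline results: free-energy differences between $(9,0)$, $(10,0)$
and $(11,0)$ lattices at $B = 20$ equal the ideal-angle bending
differences within two standard errors (the residual ~10% is the real
relaxation plus curvature-dependent vibrational-entropy correction); and
since binding enters linearly, a single run yields the binding-energy
threshold where $g$ crosses $\mu$, after removing rim effects by a linear
extrapolation in inverse length.  With our standard-state convention
($v_p = 1\,l_0^3$) the threshold at $\mu = -3$ comes out near
$4.0\,k_BT$; its absolute value inherits an $O(1\,k_BT)$ systematic from
that convention, consistent with the dynamical observation that growth at
$\mu=-3$ requires $E_B \gtrsim 4$ thermodynamically and $E_B \approx 6$
kinetically (nucleation).

## Kinetic growth–closure model

Before closure the structure is modelled as a disk of $N$ monomers bent to
the target curvature.  It grows at
$k_{\text{grow}}(N) = k^0_{\text{grow}} \cdot 2\sqrt{\pi N a_0}/l_0$
(boundary-length proportional; growth stochasticity is ignored, $N$
advancing at intervals $1/k_{\text{grow}}$), and while at size $N$ it
closes into any compatible geometry at
$k^{(m,n)}(N) = k^0_{\text{close}} I^{(m,n)}(N) e^{-\Delta G^{(m,n)}(N)}$.
Compatibility requires the disk to span the circumference,
$2\sqrt{N a_0/\pi} \ge \pi D(m,n)$ (for the $(10,0)$ target the unlock
size is $N^* = 182$).  The barrier is the elastic cost of bending the
whole disk to the $(m,n)$ dihedral pattern,
$\Delta G = N \sum_i (B/4)(\Delta\theta_i)^2$: the *discrete* form is used
rather than its Helfrich limit because same-diameter chiral neighbours
(e.g. $(8,3)$ next to $(10,0)$) differ in their dihedral pattern but not
measurably in curvature, and the continuum barrier would spread the yield
over them; the discrete form also makes the closed-geometry split at fixed
$N$ coincide with the equilibrium lattice distribution at that size —
closure quenches a quasi-equilibrium ensemble.  The survival recursion
$P_{\text{open}}(N{+}1) = P_{\text{open}}(N)\,e^{-\tilde k(N)\Delta t_N}$
conserves probability to $10^{-12}$ by construction, is independent of the
starting size below the first unlock, matches a Gillespie simulation of
the same competition to Monte Carlo accuracy, and closed structures never
reopen.  The width fluctuation of the predicted distribution scales as
$B^{-1/2}$ (fitted slope $-0.51$ over $B \in [1.25, 12.5]$); at larger $B$
the distribution enters the discrete regime (fluctuations below the
diameter spacing $l_0/\pi$) where the suppression steepens — the same
continuum-validity boundary as for the equilibrium scaling.

The mapping from the simulator's `f_fusion` to the model's
$k^0_{\text{close}}/k^0_{\text{grow}}$ is measured
(`fit_kinetic_rates()`): $k^0_{\text{grow}}$ from a through-origin
regression of $dN/d\tau$ on the perimeter over the post-nucleation growth
phase, and $k^0_{\text{close}}$ by censored maximum likelihood on the
closure sizes (never-closed runs contribute their survival).  Closure
attempts scale linearly in `f_fusion`, so one fitted condition maps the
whole axis.

## Study conditions and problem sizes

The simulated conditions mirror the main-text parameter set: $\mu = -3$,
$c_{SS} = 10\,\mu M$ (bath concentration $\approx 500$ nM), $E_B = 6$,
$k_S = 200$, trajectories started from one monomer and stopped at a length
of three circumferences.  The test suite and the acceptance script run
scaled-down ensembles chosen for a single CPU: targets $(6,0)$ and
$(8,0)$, 40–250 trajectories per condition, TI lattices of 90–110
monomers, and $2\times10^4$ Gillespie trials.  These sizes resolve the
monotone trends (open fraction versus `f_fusion`, distribution narrowing
versus $B$, yield versus closure rate) within binomial error but not the
two-digit percentages that thousand-trajectory ensembles estimate.

## What passing tests do and do not show

The generator produces single-structure, dilute-regime assembly with
specific like-type binding and no excluded volume, matching the modelled
experimental system's regime but not, for example, monomer depletion
(canonical ensemble), inter-structure coalescence, or non-complementary
binding.  Known quantitative departures, measured and deliberate:

* **Closure lateness.**  Closure requires two rims within the capture
  distance, which with this proposal set happens well past the geometric
  unlock: measured $L_{\text{close}}/D_0 \approx 4$–7 rather than the
  $\approx 1.5$ characteristic of closure right at (or, with fluctuation
  assistance, slightly before) the unlock size.  The downstream comparison
  is unaffected in direction — the simulated width spread matches the
  equilibrium prediction evaluated at the measured $L_{\text{close}}$
  better than at $L_{\text{end}}$ — but the absolute closure length is
  high, and the corresponding check in the acceptance suite is expected to
  fail.
* **Rate scale.**  `f_fusion` is an abstract attempt frequency; its mapping
  onto physical closure-to-growth ratios is what `fit_kinetic_rates()`
  measures.  At the $(6,0)$ target the open fraction moves from ~10% at
  $f_{\text{fusion}} = 10^{-2}$ to ~95% at $10^{-4}$; trends across two
  decades are monotone and strong.
* **Defect prevalence.**  Multi-site independent closures with
  incompatible registry — the known crack mechanism — are more frequent
  here, so defect-free fractions at fast closure are ~0.1–0.25 at the
  scaled-down targets rather than ~0.9.  Consequently the kinetic model's
  absolute yields at mapped ratios run high (the closed-geometry split is
  narrower than the defective-rich simulation ensemble).

Numerical choices not mentioned above: dihedrals via `atan2` of oriented
normals (flat $= \pi$, range $(0, 2\pi)$); degenerate (collinear)
triangles raise an explicit error in energy evaluation and reject the
move inside the engine; Newton tolerance $10^{-13}$ for embeddings;
16-node Gauss–Legendre default for the Einstein path; quench of 800
sweeps with a geometrically shrinking step followed by L-BFGS; per-trial
seeds derived deterministically from the master seed; a PCG32 counter
generator inside the engine, seed logged in every output.
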