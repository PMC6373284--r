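---
title: "Methods: a hybrid multiscale model of vein-graft adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hybrid multiscale model of vein-graft adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(veinsim)
```

## The problem

After bypass surgery an implanted vein graft adapts to arterial
hemodynamics. Two processes dominate the outcome: *intimal hyperplasia* —
smooth-muscle cells (SMCs) proliferate and deposit extracellular matrix
(ECM) in the innermost layer, narrowing the lumen — and *wall remodeling*,
the inward or outward reorganisation of the wall. `veinsim` simulates a 2D
cross section of the graft as the coupling of three sub-models on separated
time scales:

* a **mechanical model** (seconds): steady lumen blood flow, wall shear
  stress, wall strain energy and growth-factor (GF) diffusion;
* a stochastic **tissue-plasticity** agent-based model (hours): SMC
  division, apoptosis and migration, and ECM production/degradation;
* a **tissue-remodeling** model (within each hourly cycle): the wall
  relaxes as a highly viscous incompressible medium carrying the mass
  sources and sinks of the cellular events, computed by an immersed-boundary
  (Peskin) method, with off-lattice multi-potential SMC motility.

A reduced zero-dimensional dynamical system with a single growth gain
`gamma` provides an independent cross-check: calibrated by a seeded genetic
algorithm, it should reproduce the hybrid model's lumen-area dynamics to
within a few percent.

## Geometry and the basic solution

The cross section has four sub-domains — lumen, tunica intima, tunica
media, external support tissue — bounded by three closed elastic membranes
(lumen wall, internal elastic lamina (IEL), external wall) discretised at
the grid spacing. The *basic solution* is the stationary healthy-vein state
at implantation: concentric circles with lumen/IEL/outer radii
0.24 / 0.28 / 0.30 mm, the wall occupied by 25% SMCs (discs of radius
`R_SMC` = 5 µm placed by rejection sampling with at most 10% radius
overlap) and 75% uniform ECM. Cell clocks are seeded at uniformly random
phases: the mitotic (12 h) and ECM (2 h) cycles desynchronise from the
first step, avoiding unphysical division bursts.

```{r}
sec <- build_basic_geometry(0.24, 0.28, 0.3, h = 0.01)
cells <- seed_cells(sec, 0.25, rng = 1)
plot_cross_section(sec, cells$agents, cells$ecm)
```

## Mechanical model

Blood flow is a steady, fully developed axial flow: the axial velocity
solves a Poisson problem on the lumen with no-slip walls imposed by volume
penalisation (penalty `eta` = 1e-8) on the Cartesian grid, and the pressure
gradient is rescaled so the discharge always equals `Q_target` — the
vascular system's constant-flow control. Wall shear stress `tau_wall` is
evaluated at every lumen-membrane point by a one-sided quadratic
extrapolation along the inward normal (samples at 1.5, 2.5 and 3.5 cells),
which skips the penalty-smeared wall layer; on a circular lumen it matches
the Poiseuille closed form `4 mu Q / (pi r^3)` to within 5% at `h = r/40`.
These fields are recomputed only when the lumen boundary has moved (in the
symmetric Hausdorff sense over membrane points) by strictly more than
`tol`, one SMC diameter — the strict inequality avoids recomputation
chatter when the displacement sits exactly at the threshold.

Wall stress uses the analytic Lamé thick-cylinder solution with
area-equivalent inner/outer radii, plane strain, and venous elastic
constants (`E` = 0.3 MPa, `nu` = 0.45, internal pressure 13.3 kPa against
2 kPa outside — an arterialised graft). The strain energy density of that
stress state is the field `sigma`; its wall integral is the mechanical
potential energy used by the inward/outward rule.

The growth factor obeys steady isotropic diffusion with a Dirichlet value
`F(tau_wall)` on the lumen boundary and zero flux at the outer boundary.
The literature leaves `F` unspecified; here

> `F(tau) = max(0, (tau_bar - tau) / tau_bar)`,

the clipped relative shear *deficit*: low shear activates GFs, and the
basic solution (`tau = tau_bar`) carries none, which is exactly the balance
the stochastic rules need. The dimensionless `G` then multiplies the
division gain directly. Only the steady profile feeds the hourly biology,
so the diffusion equation is solved directly as a sparse linear system
rather than time-marched; with zero-flux outer conditions the steady state
is uniform across the wall at the boundary value, and it satisfies the
discrete maximum principle. The diffusion coefficient `c` (default
0.1 mm²/h) therefore does not shape the steady profile; it is kept as a
configuration value because any transient or consumptive extension would be
sensitive to it.

## Tissue plasticity

Each hour every live agent is interrogated. The probability laws, all
scaled by the macrophage-activity envelope `A(t)` and clipped to [0, 1]:

| event | probability |
|---|---|
| intimal SMC division | `alpha1 A(t) (1 + alpha5 G)` |
| intimal SMC apoptosis | `alpha1 A(t)` |
| ECM production | `alpha2 A(t) (1 + alpha6 dsigma/sigma_bar)` (gain in media) |
| ECM degradation | `alpha2 A(t)` |
| medial SMC migration | `alpha7 A(t) (1 + alpha8 G)` |

with `A(t) = exp(-(t - T)/deltaT)`, `T = alpha3` the time of maximum
macrophage activity and `deltaT = alpha4` its relaxation time. The literal
exponential exceeds 1 before the peak; since `T` is defined as the *maximum*
of activity, `A` is clamped to at most 1 for `t < T` (the literal formula
is available behind `allow_pre_peak_growth` for sensitivity studies).
Division versus apoptosis is resolved as a mutually exclusive trichotomy
(divide / die / nothing) on a single uniform draw, which requires
`p_div + p_apo <= 1` — violated configurations error out at evaluation.
A daughter is placed one cell diameter from its parent in a uniformly
random direction that stays inside the parent's layer (20 retries, then
radially inward). Migration is drawn hourly by medial agents within one
cell diameter of the IEL and succeeds only where the local IEL segment
stress exceeds the membrane's porosity threshold. ECM events add or remove
one ECM element area (`pi R_ECM^2`) of density around the agent, spread
over the 3x3 wall neighbourhood with per-cell occupancy bounded in [0, 1]
(an element is not confined to one grid cell, and a single-cell update
against the occupancy bounds would be badly asymmetric at this grid); the
mass source of each event is the area actually exchanged, so a production
into saturated matrix or a degradation of empty matrix contributes nothing
to the mass balance.

The rate coefficients are not printed constants of the field; the package
defaults (`alpha1 = alpha2 = 0.05`, `T = 24 h`, `deltaT = 168 h`,
`alpha5 = 4.6`, `alpha6 = 1`, `alpha7 = 0.02`, `alpha8 = 1`) are chosen
once so that (i) the basic solution is stationary (division/apoptosis and
ECM production/degradation balance exactly in expectation), (ii) a 50%
shear drop produces intimal hyperplasia on a time scale of weeks with
inflammation subsiding over roughly a month — a realistic post-surgical
course — and (iii) the division gain equals the dynamical-system operating
point. Every run records its configuration, so the defaults are data, not
hidden constants.

By default SMC division/apoptosis runs in the intima only (medial
proliferation is implemented but disabled, matching the early-phase
behaviour of the system) and ECM turnover runs wherever SMCs sit; both are
per-layer masks in the configuration.

## Tissue remodeling

Every hourly cycle the wall relaxes for a period `delta_t` (one
dimensionless relaxation unit by default) as a highly viscous
incompressible flow on a MAC staggered grid. A first-order semi-implicit
projection scheme advances the medium: semi-Lagrangian (method of
characteristics) convection, implicit diffusion, explicit membrane forces,
then a pressure correction `Lap(Pi) = (rho/dt)(div V* - s)` with
homogeneous Neumann conditions, where `s` is the mass-source density
assembled from the cycle's events — each division deposits one SMC disc
area over `delta_t` in its cell, each apoptosis the negative, ECM events
one ECM element area. After correction the discrete divergence equals `s`
exactly. The constant-coefficient operators are solved by 1D
eigendecomposition (tensor-product) transforms, so a substep costs a few
dense matrix products; the heavy kernels are in C++.

Event mass deposits are shifted along their ray to the radial mid-band of
their layer before spreading: a source inside the regularised-delta support
of a membrane leaks part of its volume across the interface (the membrane
moves with the kernel-smoothed velocity), and the shift keeps the volume
bookkeeping of each layer exact to well under a percent.

Membrane forces are linear spring tensions against per-segment rest
lengths, spread to the grid through the 4-point cosine Peskin kernel; the
same kernel interpolates the velocity back to the Lagrangian points, so
spreading and interpolation are exactly adjoint and total force is
conserved to round-off. Membranes and agents advect with the medium;
agents additionally move with the active motility velocity.

Two deliberate choices need flagging:

* **Source balancing.** The computational box is sealed (no-slip), so a net
  source is incompatible with the projection. The compensating uniform sink
  is restricted to the *external-tissue* region — the far tissue acts as
  the volume reservoir — so the divergence identity and the wall's mass
  accounting (wall-area change equals net source area to within the kernel
  width) hold over the vessel itself. A box-wide mean subtraction would
  silently divert ~20% of every source into the external region.
* **Membrane plasticity.** At the end of each hourly cycle the rest lengths
  relax toward the current segment lengths (`rest_plasticity = 1` by
  default): membranes resist deformation *within* a relaxation but carry no
  elastic memory across cycles, i.e. the tissue remodels between biology
  steps. Without this, accumulated membrane tension would eventually stall
  growth entirely; with it, the basic solution remains an exact numerical
  fixed point (membranes start every cycle at rest).

`delta_t` is an unknown of the model: the larger it is, the more each
relaxation restores circularity (membrane elastic energy after the cycle
decreases monotonically in `delta_t`, which the tests check over three
values). The substep is `dt_ibm = delta_t/25` by default; the relaxation
flow is quasi-static Stokes, and halving the substep changes trajectories
well below the stochastic noise floor, so long-horizon presets use
`delta_t/10`.

### SMC motility

The active velocity of an SMC is the sum of four potentials,
`V = V_S + V_E + V_G + V_R`:

* `V_S`, cell–cell repulsion between same-layer cells: magnitude decaying
  linearly from `k_S` at contact to exactly zero at `2 n_s R_SMC`
  (`n_s = 2` by default); a Lennard-Jones-like alternative with equilibrium
  at one cell diameter sits behind `repulsion_kind = "lennard_jones"` but
  all results use the linear law. Coincident centres get a random direction
  at full magnitude (logged).
* `V_E`, matrix invasion: attraction toward ECM-occupied, cell-free grid
  cells within `2 n_e R_SMC` (`n_e = 3`), linear in distance and weighted
  by ECM density — the mechanical-homeostasis drive that lets SMCs fill
  matrix pockets.
* `V_G`, chemotaxis: `k_G grad(G)` at the agent position (inert whenever
  the steady GF field is uniform, which is the usual case here).
* `V_R`, random motility: uniform direction, magnitude uniform on
  `[0, R_SMC/delta_t]`, so the random displacement per relaxation period
  never exceeds one cell radius.

Active velocities are evaluated once per hourly cycle and held during the
substeps (they vary on the biology time scale, not the relaxation one).
After each cycle agents are clamped radially back between their layer's
membranes; migration events are the only sanctioned IEL crossings.

### Inward/outward adjustment

Because the lumen is filled with the same incompressible medium, wall
sources alone can only push the graft outward. Inward remodeling therefore
enters as a signed lumen-side term in the mass balance: each cycle the
analytic Lamé wall energy is evaluated for a trial inward perturbation
(lumen loses `dA`, wall thickens) and a trial outward one (lumen gains
`dA`), and the term takes the sign of whichever trial strictly lowers the
energy — a sink draining the lumen ring for inward, a source for outward,
zero on a tie (doing nothing is the energy-neutral choice). Under a
physiological transmural load the inward trial wins, which is precisely
the stenotic tendency of grafts under sustained pressure. The amplitude is
`adjust_gain` (default 0.5) times the magnitude of the cycle's net event
source area: the adjustment is the wall's response to the cellular
perturbation, so it scales with turnover and vanishes in a quiescent wall.

## The reduced dynamical system and its calibration

The zero-dimensional counterpart evolves the intimal area as

`dA_I/dt = turnover * gamma * A(t) * (dtau/tau_bar) * A_I`,

with the relative shear deficit recomputed at each step from Poiseuille
shear at the current lumen radius under constant flow (`tau ~ 1/r^3`,
starting from a 50% drop), the lumen losing the area the intima gains.
`turnover` is the basic-solution area-turnover rate
`alpha1 * smc_fraction / mitotic_cycle`, so `gamma` plays exactly the role
of the hybrid division gain `alpha5`. The same inflammation envelope
`A(t)` multiplies the growth term (with the constant envelope it reduces
to the plain deficit-driven form); without it the two models could not
agree over any horizon on which inflammation subsides. Integration is
explicit with hourly substeps and daily output.

Calibration minimises the L2 distance between the normalised daily
lumen-area trajectories of the DS and a target — normally the hybrid
ensemble mean, normalised on its initial value — by a seeded genetic
algorithm (population 40, 100 generations, tournament selection, blend
crossover, Gaussian mutation, elitism, early stop after 25 stagnant
generations). Lumen area is the primary calibration output; intimal-area
mode is available by flag. The reported figure of merit is the maximum
pointwise percent relative error of the calibrated fit. On self-generated
targets the GA recovers a known `gamma` to well under 2%, and two GA seeds
agree to the same tolerance. Against the hybrid ensemble the calibrated
gain lands near the division gain `alpha5`, with the residual error
concentrated in the first simulated week: the agent model's growth
compounds on the SMC count (which multiplies severalfold under the default
rates), whereas the reduced system compounds on intimal area (which grows
far less in relative terms), so the two trajectories differ slightly in
curvature no matter the gain.

## Problem sizes and what the tests show

The package's desk-scale study conditions are: grid step `h` = 0.01 mm
(about 68×68 cells, satisfying `h` below one SMC diameter), membranes
discretised at `h`, roughly 320 SMC agents at seeding. The stationarity
checks run 10 seeds for 240 h; the early-phase motility comparison runs
variants (random only / plus repulsion / plus invasion, `n_e = 3`) for
24 h across 10 seeds and scores intimal uniformity by the coefficient of
variation of nearest-neighbour distances; the cross-validation runs an
N = 5 ensemble over a 2-month horizon before GA calibration. The full
4-month, N = 10 configuration is available as the `cross_validation`
preset defaults.

The synthetic initial state emulates a healthy implanted vein: concentric
circular membranes, homogeneous ECM, spatially uniform SMC seeding.
It does not emulate non-circular geometries segmented from histology,
adventitia (removed at surgery), macrophage particle dynamics (only the
`A(t)` envelope), pulsatile flow, or 3D effects — so passing tests support
the internal consistency of the method and its cross-scale agreement, not
fidelity to any particular animal's histology, which remains a qualitative
comparison.

## Known limitations

* The thick-cylinder (Lamé) wall stress is an approximation that degrades
  as the wall departs from circularity; a finite-element hyperelastic wall
  is out of scope.
* The steady GF field with zero-flux outer boundary is uniform across the
  wall, so the radial decay of the growth stimulus — and with it
  chemotaxis — is inert unless the shear varies along the lumen boundary.
* Event probabilities treat agents independently within an hour;
  crowding feeds back only through motility and the packing of daughters.
* Membrane rest-length plasticity removes long-term elastic memory of the
  wall; slower partial plasticity is configurable but uncalibrated.
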