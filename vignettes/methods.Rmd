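---
title: "The three-dimensional cable equation: model, discretization and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The three-dimensional cable equation: model, discretization and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The standard cable equation reduces a neuron to a tree of line segments and
ignores the structure of the extracellular potential. `neurocable3d` solves
the volumetric generalization instead. The intra- and extracellular spaces
are treated as purely resistive volume conductors: free charges relax on a
nanosecond time scale, far below the microsecond channel dynamics, so both
potentials satisfy Laplace equations,

$$-\nabla\cdot(\sigma_{in}\nabla\Phi_{in}) = 0 \ \text{in}\ \Omega_{in},
\qquad -\nabla\cdot(\sigma_{out}\nabla\Phi_{out}) = 0 \ \text{in}\ \Omega_{out},$$

coupled across the membrane $\Gamma$ by continuity of the normal current,
which equals the total transmembrane current density of the membrane model:

$$-\sigma_{in}\nabla\Phi_{in}\cdot n = -\sigma_{out}\nabla\Phi_{out}\cdot n
= j_{all}(V_m), \qquad V_m = \Phi_{in}-\Phi_{out} \ \text{on}\ \Gamma .$$

$j_{all}$ collects, per membrane patch, the capacitive current
$c_m\,dV_m/dt$, Hodgkin–Huxley channel currents on active patches (soma,
nodes of Ranvier), leak only on passive dendrites, the capacitive term alone
on myelin (with its own, much smaller $c_{m,myelin}$), plus stimulus and
synaptic currents on their patches.

The membrane potential lives on a two-dimensional surface while the
potentials live in volumes, which makes a direct discretization awkward. The
package therefore works with the *extension* formulation: the extracellular
potential is continued harmonically into the cell as a third field
$\Phi_{out}^{IN}$ ($-\Delta\Phi_{out}^{IN}=0$ inside the cell,
$\Phi_{out}^{IN}=\Phi_{out}$ on $\Gamma$; the interior right-hand side is a
free choice and is taken to be zero), and $V_m$ becomes a volumetric unknown
satisfying $-\Delta V_m = 0$ inside the cell with the flux condition

$$-\sigma_{in}\nabla V_m\cdot n = j_{all}(V_m) + j_{eph}, \qquad
j_{eph} = \sigma_{in}\nabla\Phi_{out}^{IN}\cdot n .$$

$j_{eph}$ is the *ephaptic current*: the route by which the extracellular
field generated by every cell feeds back on every membrane. It can be
toggled off (`solver_config(ephaptic = FALSE)`) to quantify its effect.

Two structural consequences are built into the discretization and checked by
the test suite:

* **Global flux balance.** Integrating the intracellular Laplace equation
  over a cell gives $\oint_\Gamma j_{all}\,dS = 0$ at every instant: any
  influx is simultaneously balanced by an outflux elsewhere on the same
  cell.
* **No current monopole.** For a spherical cell the exterior potential
  expands in spherical harmonics as
  $\Phi_{out} = \sum_{l,m} b_{lm} r^{-(l+1)} Y_{lm}$ with
  $b_{lm} = R^{l+2}/((l+1)\sigma_{out}) \oint j_{all} Y_{lm}\, d\Omega$
  (obtained by matching $-\sigma_{out}\partial_r\Phi_{out} = j_{all}$ at
  $r=R$; we keep the conductivity and the sign that this physical matching
  produces). The monopole $b_{00}$ is proportional to the total flux and
  therefore vanishes: the extracellular potential of a cell decays at least
  like $r^{-2}$.

## Discretization

Space is discretized with a vertex-centered finite-volume (box) scheme on
tetrahedral meshes, because the model is derived from flux conservation and
the box scheme conserves fluxes discretely, control volume by control
volume. The dual grid is barycentric: each tetrahedron is subdivided by its
edge midpoints, face barycenters and barycenter; the corner piece at each
vertex (exactly a quarter of the tetrahedron volume) joins that vertex's
control volume, and each membrane triangle contributes exactly a third of
its area to each corner vertex. Unknowns are piecewise-linear nodal
coefficients; since their gradients are constant per element, the flux
integrals over the polygonal dual sub-faces are evaluated analytically
(gradient times pre-integrated sub-face normal). On simplices this box
stiffness coincides with the P1 finite-element stiffness, which the test
suite exploits as an independent assembly oracle.

Membrane vertices carry three unknowns ($\Phi_{out}$, $\Phi_{out}^{IN}$,
$V_m$); the membrane flux terms are weighted by the per-vertex,
per-patch dual areas, so vertices on patch borders receive the correct
area-weighted mix of dynamics.

Time stepping is backward Euler (first order, unconditionally stable; the
model's stiffness comes from the capacitive term), default
$\Delta t = 10\,\mu s$, which resolves the fast sodium activation gate
($\tau_m \gtrsim 40\,\mu s$ near the spike peak). Each step solves the
coupled nonlinear algebraic system with Newton's method. Two couplings of
the gating variables are available:

* `gating = "staggered"` (default): $n,m,h$ advance once per step by an
  implicit (backward-Euler) update at the previous potential; the per-step
  system is then affine in the three fields and Newton converges in a
  single iteration.
* `gating = "nested"`: the gating update is re-evaluated inside every
  Newton iteration at the current iterate, making the step fully implicit
  in all unknowns at the cost of extra iterations.

The staggered default keeps the per-step cost minimal; at
$\Delta t = 10\,\mu s$ the splitting error is far below the backward-Euler
error itself (both are first order, and the step-halving test confirms the
first-order constant).

### Linear solves

The Newton correction can be solved in two ways:

* `linear_solver = "direct"`: one sparse LU of the monolithic Jacobian.
  Simple and exact; the default at desk scales.
* `linear_solver = "segregated"`: a block Gauss–Seidel sweep over the three
  fields in the order $V_m \to \Phi_{out} \to \Phi_{out}^{IN}$, each block
  solved with a cached sparse Cholesky factorization (all three field
  blocks are symmetric positive definite). The only coupling outside the
  sweep is the ephaptic block; because the loop gain of the neglected
  coupling chain is of the order of the membrane admittance divided by the
  volume-conductor admittance ($\sim 10^{-2}$), the sweep contracts by
  roughly two orders of magnitude per iteration. This is the solver used on
  refined meshes, where a monolithic LU becomes memory-bound.

In both modes a `jacobian = "frozen"` chord variant reuses factorizations
across steps; convergence is always judged on the true nonlinear residual,
and a stalling chord iteration triggers refactorization automatically. The
residual is measured in the 1-norm, so a converged step bounds *every*
signed sum of residual entries — in particular the per-cell flux balance —
by `newton_abs_tol` (default $10^{-6}$ nA, i.e. a femtoampere).

The extracellular problem needs a far-field condition because the
computational domain must be bounded. The default grounds the outer
boundary ($\Phi_{out}=0$), consistent with the $r^{-2}$ far-field decay; a
zero-flux alternative with a one-point gauge pin is provided
(`boundary = "insulated"`), since the pure-Neumann problem is otherwise
singular.

### Units

All lengths are in micrometers, times in milliseconds, potentials in
millivolts. Membrane parameters use the conventional units
(mS/cm², uF/cm², uA/cm²) and conductivities mS/cm; internally everything is
converted once to a mV–ms–um–nA system (1 mS/cm = 0.1 uS/um,
1 uA/cm² = $10^{-5}$ nA/um²). Stimulus and synaptic amplitudes are total
currents in nA, divided by the area of their patch.

## Membrane model and its defaults

The voltage convention is the shifted one (rest = 0 mV). The classical
squid-axon parameter set is the default
($\bar g_{Na}=120$, $\bar g_K=36$, $g_L=0.3$ mS/cm²; $E_{Na}=115$,
$E_K=-12$, $E_L=10.6$ mV; $c_m=1$ uF/cm²; 6.3 °C rate functions without a
temperature correction), with the removable singularities of
$\alpha_n$ (at 10 mV) and $\alpha_m$ (at 25 mV) evaluated by their limits.
These are configuration defaults, not constants — every value can be
overridden per run.

Purely passive patches (dendrites) use the leak conductance with a separate
reversal `e_pas = 0`: a passive membrane should rest at the resting
potential, the role the passive-mechanism reversal plays in compartment
simulators. (Using the classical $E_L = 10.6$ mV there would make every
dendrite drift several millivolts above rest with a 3 ms time constant.)
Myelin carries only capacitive current with
$c_{m,myelin} = 0.04$ uF/cm² (a typical multi-lamellar sheath value;
configurable).

Synapses are latched threshold devices: when the area-weighted mean
membrane potential on the presynaptic patch exceeds the threshold (default
5 mV, the value used by the reported network simulation; the alternative
2 mV mentioned in passing in the model description is available through
`synapse_spec(threshold = )`), a predefined postsynaptic current pulse is
injected for the configured duration regardless of what the presynaptic
potential does afterwards. The pulse shape is rectangular by default — the
simplest realization of a "predefined strong postsynaptic pulse of a few
nA" — with an alpha-function option.

## Geometry builders and the synthetic domains

All domains are generated programmatically and deterministically (no
randomized meshing), so identical arguments give identical meshes:

* **Cylinder** (`build_cylinder_domain()`): a structured extrusion of a
  triangulated regular polygon disk; the intracellular cross-section is the
  inscribed $n$-gon, so its area carries the polygonal deficit
  $\tfrac{n}{2}r^2\sin(2\pi/n)$ vs $\pi r^2$ — a geometric model error that
  refinement does *not* remove (uniform refinement bisects chords of the
  same polygon). Markers sit on the axis at the stimulated end, midpoint
  and far end.
* **Sphere** (`build_sphere_domain()`): radially stacked icosphere layers
  for the cell and the extracellular shell, with an optional polar
  stimulus cap.
* **Network** (`build_network_domain()`): idealized multi-cell domains on a
  uniform Cartesian grid (hexahedra split into six mirror-consistent
  tetrahedra). Each cell is a straight dendrite–soma–axon rod with square
  cross-sections of equal-area side, myelinated axon with regularly spaced
  nodes of Ranvier, synapse patch pairs between consecutive cells and
  stimulus patches on selected dendrites. The square cross-section is a
  deliberate idealization: it keeps the multi-cell mesh conforming without
  a general mesh generator, while the curved-geometry physics is exercised
  by the cylinder and sphere builders. Default dimensions follow the
  idealized network description (soma ≈ 20 um, dendrites ≈ 10 um, axon ≈
  5 um, cells several hundred um apart).

Uniform (red) refinement splits every tetrahedron into eight through its
edge midpoints, preserving total volume exactly and multiplying the
tetrahedron count by eight.

## The 1D reference solver and the verification experiment

`solve_cable_1d()` implements the standard cable equation
$c_m \partial_t V = \tfrac{d\,\sigma_{in}}{4}\partial_x^2 V - j_{ion} + j_{stim}$
with the same membrane code, sealed ends, backward-Euler diffusion and
staggered implicit gating. Axial resistivity derives from the same
$\sigma_{in}$ as the 3D solver ($R_i = 1/\sigma_{in}$), keeping the two
models parameter-consistent. It plays the role a standard compartment
simulator plays as a reference for the volumetric model on long thin
cylinders, where the two should agree.

`cylinder_verification()` runs both models on the long test cylinder
(9.8 mm × 200 um by default) and reports the relative L2-in-time error

$$\frac{\lVert V_m^{1D} - V_m^{\mathrm{Level}\,x}\rVert_{L^2([0,T])}}
       {\lVert V_m^{\mathrm{Level}\,x}\rVert_{L^2([0,T])}}$$

summed over the three probes, at several uniform refinement levels. The
property that matters is *stabilization*: under refinement the error
sequence converges to a plateau set by the systematic model differences
(polygonal cross-section, finite cylinder, finite extracellular
resistance and its grounded truncation) rather than by the grid — the
signature that the discretization itself has converged. On this mesh
family the plateau is approached from below: on coarse grids the numerical
dispersion of the wavefront partially cancels the (opposite-signed)
extracellular-loading difference between the models, so the coarsest level
can sit slightly *closer* to the 1D reference than the converged 3D
solution does. The successive level-to-level increments still shrink, the
plateau magnitude sits at the same order as published comparisons of this
kind, and the two models' conduction velocities and spike shapes agree to
within about a percent. Driving successive levels to agreement within 1%
of each other would require the level-1 discretization contribution to
drop below $10^{-3}$ relative, i.e. base grids roughly an order of
magnitude finer than this package's single-CPU scale.

The stimulus is injected over a lateral band at one end whose axial extent
equals the 1D injection length and aligns with the base axial grid, so
every refinement level (and the 1D reference) carries the identical
injection geometry — with an end-cap injection instead, the stimulated-end
traces diverge between the models as the mesh refines, for reasons of
stimulus geometry rather than solver quality.

Problem sizes were chosen so the whole three-level experiment runs on one
desk-scale CPU: full 9.8 mm length, octagonal cross-section at base level,
300 um base axial spacing (about 0.5 M tetrahedra at level 2), a 200 um
grounded extracellular sleeve (a nearby ground plane also mirrors the 1D
model's assumption of negligible extracellular resistance), $\Delta t =
20\,\mu s$ and 8 ms of simulated time — enough for the spike to form at
the stimulated end, arrive at the far probe and repolarize.

With the printed intracellular conductivity $\sigma_{in} = 2$ mS/cm and the
classical squid membrane, the spike propagates at about 2.1–2.3 m/s, i.e.
it crosses the 9.8 mm cylinder in roughly 4.5–5 ms. We read the reported
propagation figure of "5 ms" for this cylinder as exactly that traversal
time — at these parameters a velocity of 5 m/s would require an axial
resistivity about five times lower than the printed value — and the
acceptance script therefore reports the measured traversal time in
milliseconds alongside the velocity.

`conduction_velocity()` measures speed from the first upward half-amplitude
crossings at two probes with linear interpolation between samples; the
measurement is validated on constructed shifted pulses, on internal
consistency between probe pairs, and on the classical $\sqrt{d}$ diameter
scaling.

## The multipole analyzer

`fit_multipole()` expands an arbitrary membrane flux field on the
triangulated sphere in real orthonormal spherical harmonics (own stable
recurrence for the normalized associated Legendre functions, cross-checked
in the tests against frozen independent reference values). Two fitting
modes serve two purposes:

* `"quadrature"` (default): plain triangle-midpoint quadrature of the
  coefficient integrals. Because the dual-grid membrane area of a vertex is
  exactly the third of its incident triangle areas, the fitted monopole is
  *exactly* proportional to the finite-volume flux balance of the solver —
  the discrete counterpart of the vanishing-monopole theorem, with no
  quadrature slack in between.
* `"least_squares"`: weighted normal equations on the same grid, which make
  fitting an exact left inverse of evaluating the truncated basis; this is
  the mode for orthogonality and round-trip (Parseval) checks and for
  clean single-harmonic inputs.

Default truncation is $l_{max} = 8$. The exterior potential is evaluated by
`evaluate_potential()` (only for $r > R$) and cross-checked in the tests
against an independent volumetric exterior solve on a wide shell.

## Scenario layer

`run_scenario()` executes YAML-configured experiments with schema
validation (unknown fields are reported with their full path), writes trace
CSVs, VTU field snapshots at a configurable cadence and a provenance JSON
sufficient to reproduce the run. Three presets mirror the package's
reference experiments: `cylinder_verification`, `sphere_multipole` and
`network_ephaptic`. The pipeline is deterministic: identical configurations
give bit-identical traces.

### The paired ephaptic experiment

`ephaptic_experiment()` reproduces, at reduced scale, the network
observation that the extracellular field can decide whether a cell fires.
The preset uses a two-cell geometry (a reduced stand-in for the four-cell
layout, chosen for tractable runtimes): cell 1 is driven to spike by a
continuous dendritic current; the target cell receives one short pulse
timed just before cell 1's spike (the reduced analog of pulsing the fourth
cell mid-simulation, when the network's field transient reaches it). The
pulse amplitude is *calibrated*: the target's firing threshold is bisected
once with the ephaptic current enabled and once with it disabled, and the
test amplitude is the midpoint of the gap. The two paired runs then use the
identical stimulation paradigm and differ only in the ephaptic term.

In the reduced geometry the ephaptic field at the target is of the order of
microvolts, so the threshold gap is relatively small (a few times
$10^{-5}$ in relative amplitude) — which is exactly the reported picture:
the effect is tiny, yet with stimulation near threshold at the right moment
it flips the outcome. The bisection tolerance (default relative
$2\times10^{-6}$) sits an order of magnitude below the measured gap; the
solver itself is deterministic, so the comparison is exact.

## Numerical choices, degenerate inputs, limitations

* Degenerate (zero-volume) tetrahedra are rejected at mesh construction
  with the offending index; membrane triangles must separate exactly one
  intracellular and one extracellular tetrahedron, and their stored
  orientation (intracellular to extracellular) is validated geometrically.
* Cells touching by a face are rejected — cells must be separated by
  extracellular volume, otherwise the membrane patches of the two cells
  would be ambiguous.
* Prism and hexahedron tetrahedralizations use index-based (Dompierre-style)
  and parity-mirrored (Kuhn) rules respectively, so shared faces always
  receive matching diagonals and every generated mesh is conforming.
* Ties in threshold detection: spike times use the *first* upward crossing;
  the synapse latch is edge-triggered and idempotent.
* The solver assumes constant, isotropic conductivities per subdomain
  (tensor conductivities would only change the per-element gradient
  products) and a fixed geometry over time.
* Mesh file I/O supports the ASCII forms of VTK unstructured XML and Gmsh
  MSH 4.1 with the package's label conventions; binary files are rejected
  with a clear message.
* What the synthetic geometries do not emulate: realistic branched
  morphologies, curved network cells (square cross-sections on the grid),
  ion-concentration dynamics, temperature corrections, and stochastic
  channels. Passing tests therefore certify the numerics and the model
  structure, not fidelity to any particular biological reconstruction.
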