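---
title: "Methods: coarse-grained DPD of asymmetric phospholipid structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained DPD of asymmetric phospholipid structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the model, the numerical choices, and the design
decisions behind `lipiddpd`, in the spirit of a methods section: what is
computed, under which assumptions, and what the desk-scale tests do and do
not demonstrate.

## The model and its assumptions

Each bead represents a cluster of heavy atoms or water molecules. All beads
share one mass, one interaction range r_c and one energy scale k_B T; these
define the reduced units (time unit tau = r_c sqrt(m / k_B T)). Two
phospholipid species are built from the same architecture — one linear head
chain of `n_hb` hydrophilic beads and two linear tail chains of `n_tb`
hydrophobic beads — so the five bead species are HB1, TB1, HB2, TB2 and
water.

Non-bonded beads interact through the standard soft DPD triplet:
conservative `a_ij w(r) r_hat` with `w(r) = 1 - r/r_c`, dissipative
`-gamma w^2 (r_hat . v) r_hat`, and random
`sigma w zeta dt^(-1/2) r_hat`. The dissipative and random forces form a
momentum-conserving thermostat; `sigma^2 = 2 gamma k_B T` is enforced at
parameter construction, so `gamma = 4.5` at `k_B T = 1` always implies
`sigma = 3` exactly. The noise `zeta_ij` is one zero-mean, unit-variance
Gaussian draw per interacting pair per step, shared symmetrically
(`zeta_ij = zeta_ji`) so the random force is pairwise antisymmetric. Draws
come from a counter-based generator keyed by (seed, step, sorted pair
indices), which makes the stream independent of the cell-list traversal
order and hence bit-reproducible.

The repulsion table treats the five species as mutually distinct:
`a_ii = 25`, `a_ij = 100`. In particular HB1–HB2 = 100. "Same type" could
plausibly group the two hydrophilic head species, but identical heads would
remove the driving force that sorts the two lipid species into distinct
leaflets; the distinct-species reading produces the asymmetric structures
the model exists to study, and the table is fully overridable through the
configuration.

Bonds are harmonic, `U = (k_s/2)(r - r_s)^2` with `k_s = 100`,
`r_s = 0.7 r_c`. Bending terms `U = k_theta (theta - theta0)^2` come in
three classes: consecutive triples inside one chain (`k_theta = 6.0`), the
last two head beads with the first bead of each tail chain (`k_theta = 3.0`,
one term per tail chain), and the two first tail beads with the last head
bead at the apex (`k_theta = 4.5`). All equilibrium angles default to
`theta0 = pi`: a straight chain is the only equilibrium geometry that is
unambiguous for all three classes, and the junction/split angles are exposed
as configuration keys (`theta0_junction`, `theta0_split`) for anyone wanting
a kinked architecture.

## Integration and numerical choices

- **Integrator.** Groot–Warren modified velocity-Verlet with
  `lambda = 0.5`: drift with the current force, predict velocities for the
  dissipative force, recompute forces, complete the velocity half-step.
  `dt = 0.01 tau`. In the `gamma = sigma = 0` limit this is plain
  velocity-Verlet; its energy error is a bounded oscillation of relative
  amplitude ~(omega dt)^2/8 (about 0.5% for a `k_s = 100` bond), while the
  *secular* drift over 10^4 steps is below 1e-5. The symplectic-limit test
  therefore compares windowed means at the start and end of the run, not the
  raw oscillation amplitude.
- **Cell list.** Cells of width >= r_c with a 13-neighbour half-shell sweep;
  boxes smaller than three cells per side fall back to an exact all-pairs
  loop (the half-shell enumeration would alias cells there). The suite
  checks the cell list against an independent all-pairs oracle to round-off.
- **Overlapping beads** (r = 0, possible under soft repulsion): the pair
  force keeps its contact magnitude and takes a uniformly random direction;
  occurrences are counted and reported.
- **Angle gradient.** The bending force is the exact analytic gradient of
  `k_theta (theta - theta0)^2`; `sin(theta)` in the denominator is clamped
  at 1e-8. For `theta0 = pi` the limit `(theta - pi)/sin(theta) -> -1` keeps
  the clamped expression accurate near collinearity.
- **Bead count.** `N = round(rho L^3)` at `rho = 3`; water fills whatever
  the lipids do not use.
- **Trace energies** are per-bead potential energies in k_B T (pair + bond +
  angle), the scale on which self-assembly stage energies are quoted.

## Initial conditions

Four modes: `random` (straight rods at random positions/orientations),
`lamella` (bilayer slab at the box midplane, type 1 below), `cylinder`
(bilayer tube along z, type 1 inner) and `sphere` (bilayer shell, type 1
inner). Velocities are Maxwell–Boltzmann at k_B T = 1, shifted to exactly
zero net momentum.

Pre-assembled modes place each lipid as a straight rod with the two tails
side by side (0.15 r_c lateral offset, so bonded beads never coincide).
When the box is too small for the full rod — which is the normal situation
for long tails in desk-scale boxes — the placement spacing is compressed
below `r_s`, down to a floor of 0.3 r_c; the soft potentials and harmonic
bonds relax the compression within a few hundred steps. Geometric
impossibilities (overfull leaflet areas, no feasible tube/shell radius)
raise errors that name the limiting area or radius. The tube/shell
mid-surface radius defaults to the point nearest L/4 inside the feasible
interval.

Structure selection runs each candidate initial condition with identical
physics and keeps the state with the lowest mean per-bead energy over the
final 10% of reports (ties at 1e-9 go to the lowest candidate index). The
10% window is a package choice — the selection criterion only needs a
late-time average that is insensitive to the transient. The box-size sweep
(default 25–35 r_c) works the same way over L at fixed density and lipid
count, with the water count tracking the volume.

## Observables

- **Density profiles** bin per-species counts into equal slabs; the profile
  is exactly normalized per frame (sum of density x slab volume = bead
  count).
- **Orientational order** uses the head-chain first-to-last bead vector
  (minimum image) as the chain direction — the head ordering is what
  distinguishes the two leaflet surfaces; a whole-lipid end-to-end option
  exists. Per chain `S = (3 cos^2 theta - 1)/2`; the histogram gets an
  unweighted least-squares Gaussian fit (mean, sd, amplitude) via `nls`,
  with NAs when the fit cannot converge.
- **Gyration tensors** are computed per chain after unwrapping the lipid
  across periodic boundaries by walking its bonds with minimum-image steps.
  Reported ensemble components are `sqrt(mean R2_g,aa)`; the scalar
  `<R_g> = sqrt(mean trace)`.
- **Shape factor** sorts the tensor eigenvalues `L1^2 <= L2^2 <= L3^2` and
  averages the per-chain
  `delta = 1 - 3 (L1^2 L2^2 + L2^2 L3^2 + L3^2 L1^2) / (sum)^2` (mean of
  per-chain delta, not a ratio of means; a zero-trace tensor contributes 0).
- **Stage segmentation** finds two change-points minimizing total
  within-stage variance by exact dynamic programming over report indices
  (O(n^2) with prefix sums). A flat trace degenerates to boundaries at 1/3
  and 2/3 with a flag; non-monotone stage means warn rather than fail.
  Boundaries are reported as the time of the first report of the new stage.
- **Local pressure** follows the Irving–Kirkwood-1 contour: each pairwise
  virial term `F_ij,a a_ij` is spread over the slabs crossed by the
  minimum-image segment in proportion to path length; the kinetic term goes
  to the bead's slab. Angle terms enter through their exact two-leg pairwise
  decomposition about the apex. Only conservative + bonded forces are
  recomputed from frames: the dissipative and random pair forces cancel in
  the mean by construction of the thermostat. The slab-volume-weighted mean
  of every component equals the whole-box virial to round-off (a
  partition-of-unity identity that the suite asserts at 1e-10), and the
  implementation is cross-checked against an independent all-pairs R oracle.
  Per-group decompositions assign half of each pair term to each bead's
  group. Slabs thinner than 0.1 r_c are refused outright.
- **Interface tension** integrates `p_N - (p_T1 + p_T2)/2`; binned along an
  in-plane axis it gives the laterally resolved total tension of a membrane
  whose normal is supplied by the caller. **Osmotic pressure** subtracts the
  bulk-window mean of the normal component, per group, so the bulk mean is
  zero by construction.

## Morphology classification

The labels membrane / tube / vesicle are assigned algorithmically (the
underlying phenomenology is usually judged by eye): build a periodic contact
graph over lipid beads (cutoff 1 r_c), take the largest connected component,
count the axes along which it connects to its own periodic image (detected
as inconsistent image offsets around graph cycles), and flood-fill the free
cells of a 0.5 r_c occupancy grid — dilated by one cell so the thin
bilayer reads as a solid wall — to find enclosed water compartments.
Membrane = spans two axes; tube = spans one and is hollow; vesicle = spans
none and is hollow; everything else (including aggregates under 10 lipids)
is `other`. All thresholds are arguments. The asymmetry index is the
fraction of type-1 head beads on the lower (membranes) or inner (hollow
structures) side.

A practical consequence of the 1 r_c contact cutoff: a *pre-assembled*
leaflet laid out sparsely (grid spacing above 1 r_c) is not yet a connected
aggregate and labels `other` until the dynamics densifies it. The
classifier fixtures in the tests therefore use packings dense enough to be
connected at construction, which is also the regime self-assembled
structures end up in.

The phase-diagram driver exploits the tail-length symmetry: only the
half-grid `N_TB2 >= N_TB1` is simulated and the other half is mirrored with
the lipid types swapped. Grid points run at one box size per point;
per-point box sweeps would multiply the cost elevenfold for a refinement
the selection step rarely changes.

## Problem sizes in the tests

The suite runs everything at desk scale, chosen so the full suite completes
in minutes: water boxes of L = 6–8 (650–1500 beads, 2000–5000 steps) for
thermostat/stress properties, and one L = 12 lamellar self-assembly run
(60+60 lipids, tails 4 and 9, 30 000 steps, ~2.5 min) for the
membrane-formation check. The production-scale configuration (600+600
chains, L = 25–35, 200 000 steps) is what `default_config()` encodes; the
suite verifies it builds a consistent system but does not integrate it.

## What the tests show — and what they do not

The synthetic inputs (placed bead geometries, constructed energy traces,
prescribed chain orientations) validate the estimators exactly: analytic
order-parameter limits, hand-computable gyration/shape values,
known change-points, partition-of-unity stress identities. The scaled
self-assembly run shows the model's qualitative phenomenology — leaflet
segregation, bilayer density structure, membrane spanning — but a fixed
12 r_c box pins the membrane area per lipid at 2.4 r_c^2, well above the
tension-free area (~1 r_c^2 in optimized production boxes). The measured
in-plane tension of such a membrane is genuinely positive (+6.7 in reduced
units, stable across frames and verified against the global virial), so
desk-scale runs should not be read as tension-free membranes; obtaining
near-zero tension requires relaxing the area constraint, which is exactly
what the production-scale box-size sweep is for.

## Known limitations

- NVT only: no barostat, so membrane tension is set by the box, not
  relaxed to a target.
- No electrostatics, shear flow or external fields; two lipid species and
  linear chains only.
- The dissipative/random contribution to the *instantaneous* stress is
  neglected (exact only in the mean).
- Trajectory storage is in-memory frames plus extended-XYZ text; very long
  production runs should write frames incrementally via the CLI.
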