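---
title: "Membrane-driven docking of membrane-associated protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-driven docking of membrane-associated protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memswarm)
```

## The modelling problem

Complexes between a membrane-embedded receptor and a soluble partner are
under-represented in structural databases, and most docking tools ignore the
one piece of information such systems always come with: the membrane.
Because the bilayer occludes the transmembrane belt of the receptor, the
biologically accessible interface must lie on the exposed face — cytosolic
or periplasmic/extracellular. `memswarm` implements an integrative protocol
that encodes the bilayer as a layer of coarse-grained phosphate beads and
uses it twice:

1. **During sampling** — candidate pose neighbourhoods ("swarms") below the
   upper bead leaflet are discarded before any optimization, typically
   removing most of the search space.
2. **During scoring** — in full membrane mode, any ligand atom within the
   overlap distance of a membrane bead adds a fixed, strongly unfavourable
   penalty of −999.0 to the pose score, so the optimizer steers poses out of
   the bilayer.

Docked poses are then relieved of interfacial steric clashes by a restrained
minimizer and re-scored with a weighted physics-based energy; quality is
assessed with the community-standard CAPRI metrics.

## The sampling engine

Pose optimization uses glowworm swarm optimization (GSO). Each agent
("glowworm") encodes a rigid-body ligand pose — a translation plus a
scalar-first unit quaternion — and carries a luciferin level updated each
iteration as

$$\ell' = (1-\rho)\,\ell + \gamma\,S(x),$$

with decay $\rho = 0.4$ and gain $\gamma = 0.6$; $S$ is the pose score
(higher is better) and luciferin is clamped at zero. A glowworm moves a step
toward a probabilistically chosen brighter neighbour inside its adaptive
vision range (probability proportional to the luciferin excess); agents with
no brighter neighbour stay put. The vision radius adapts toward holding
`max_neighbors = 5` neighbours at rate `beta = 0.08`. These update rules and
defaults are the documented mechanics of the published glowworm-swarm
algorithm; the primary literature for this protocol does not restate them,
so they are exposed as configuration (`gso_params()`, `swarm_config()`).

Two pose-space choices are package design decisions:

* **Metric.** The distance between poses combines the translational
  Euclidean distance with the relative rotation angle scaled by
  `rotation_scale = 5` Å/radian, so a 0.2-radian reorientation "costs" the
  same as a 1 Å shift. This single scale controls both neighbourhoods and
  movement caps.
* **Moves.** Translations move linearly by the step length (capped at the
  neighbour's position); rotations move by spherical interpolation with a
  *fixed* fraction (`gso_rot_step = 0.5`) per move. We initially scaled the
  slerp fraction by pose distance, matching the translational rule, but a
  fixed fraction — the behaviour of the reference swarm-docking code — mixes
  orientations far faster and measurably improves native-site recovery;
  both behaviours remain reachable through configuration.

A docking run (`run_docking()`) generates up to `n_swarms = 400` swarm
centres on an inflated support surface of the receptor (deterministic
Fibonacci directions, farthest-point thinning; every centre is at least
`swarm_distance` from every receptor atom), filters them against the
membrane plane, populates each surviving swarm with `n_glowworms = 200`
random poses, and runs `steps = 100` GSO iterations per swarm. The best-ever
pose of each glowworm is retained, poses are clustered per swarm by the
sequential BSAS rule at a 4 Å ligand-RMSD cutoff, and cluster
representatives are pooled and ranked.

**Final pose polishing.** The leading pooled representatives (default
`polish_top = 20`) are additionally optimized by derivative-free
(Nelder–Mead) local search over the six rigid-body degrees of freedom,
restarted until the score stops improving; for the top half, a small fixed
set of basin-hopping kicks (±4 Å lateral translations, ±40° azimuthal and
one 26° tilt rotation, each followed by re-convergence, kept only on
improvement) lets a pose escape an adjacent, sub-optimal contact shell.
This stage goes beyond the plain generate–cluster–rank pipeline of the
original protocol: GSO is excellent at localizing scoring basins but — being
purely neighbour-following — poor at converging within them. The polish is
deterministic and applied uniformly to every run and mode.

## The membrane model

A coarse-grained snapshot (MARTINI-style bead naming) is reduced to its
phosphate head-group beads (`extract_phosphate_beads()`; defaults accept
residue `MMB` and atom names `PO4`/`P`/`BJ`, configurable because bead
labels vary across force-field dialects). Leaflets are detected by the
largest gap in the sorted bead z-values — a deterministic 1-D two-cluster
split, accepted only when the gap exceeds 10 Å (about half a bilayer) — and
the leaflet with the greater mean z is "upper". Beads closer than 2.5 Å
(strict) to any receptor heavy atom are removed, mirroring the overlap rule
used when an atomistic receptor is re-inserted into a simulated bilayer.
Lower-leaflet targets are handled by rotating the whole system 180° about
the x-axis (`flip_about_x()`) rather than by duplicated logic.

Three membrane definitions are supported, named by the statistic of the
upper-leaflet z-coordinates that defines the filtering plane: `beads_max`
(the full bead membrane; swarm filtering at the maximum z), `average` and
`minimum`. Since max ≥ mean ≥ min, surviving swarm counts are ordered
`beads_max ≤ average ≤ minimum ≤ blind` on any input — the package's
qualitative analogue of the published swarm-count trend across membrane
definitions. Whether the original implementation filters swarms against
individual bead positions or a single plane is not documented; we filter
against the plane and keep the explicit beads for the scoring penalty.

Run modes: `blind` ignores the membrane entirely; `filtered` uses it only to
discard swarms; `membrane` additionally enables the scoring penalty.

## Scoring

The docking score is a distance-binned pairwise statistical potential over
heavy atoms, summed over intermolecular pairs within the interaction cutoff;
higher is better. The potential table is pluggable
(`read_potential_table()`): a published atom-typed statistical potential can
be dropped in, and the package ships a reduced contact potential over
poly-alanine heavy-atom types (N, CA, C, O, CB, plus a thiol-like hot-spot
type SG used by the synthetic fixtures) with five bins
(0–2.5–3.5–5–7–10 Å). Its shape encodes three facts about protein
interfaces: overlap below the 2.5 Å clash threshold is strongly repulsive
(−100 per pair, so burial never pays), packing contacts in the 3.5–5 Å shell
are the most rewarded, and hot-spot (SG–SG) pairings dominate registration
the way interface hot spots do in real complexes.

The reserved `MEMBRANE_BEAD` type carries the fixed −999.0 value. In
membrane mode every ligand-atom–bead pair within `penalty_cutoff`
contributes that penalty. `score_pose()` defaults the cutoff to the table's
interaction cutoff; `swarm_config()` narrows it to 5 Å — about one
coarse-grained bead diameter — reading "overlapping with a bead" literally.
With the 10 Å interaction cutoff a pose merely *near* the membrane would be
annihilated, which contradicts the intent of penalizing *penetration*.
Whether the original applies the penalty per pair, per bin or once per model
is undocumented; per contacting pair is the simplest reading and is isolated
behind the table so alternatives are testable.

## Refinement and re-scoring

Rigid-body docking leaves interfacial clashes. `refine_pose()` removes them
with a restrained Cartesian minimization: interface atoms (within 10 Å of
the partner) move under a soft-core intermolecular repulsion — quadratic
below a relief target of 2.8 Å, safely above the 2.5 Å clash threshold —
while every mobile atom is harmonically tethered to its input position
(backbone weight 1.0, side-chain 0.2 kcal mol⁻¹ Å⁻²; repulsion constant 10).
L-BFGS-B with an analytic gradient converges in a few passes of pair-list
rebuilding and is fully deterministic. We considered the alternative of
ligand-rigid-body plus side-chain-torsion degrees of freedom, but with
poly-alanine fixtures clashes involve backbone atoms, and rigid-body relief
of a deep clash necessarily drags the whole interface — violating the
≤ 0.25 Å backbone-drift contract that per-atom restrained relief satisfies
easily. The observable contract (clashes removed, backbone held, weighted
re-scoring) is what the original coarse-grained refinement protocol is
measured by, and is preserved.

Refined models are re-scored with

$$\mathrm{score} = 1.0\,E_{\mathrm{vdw}} + 0.2\,E_{\mathrm{elec}} +
0.1\,E_{\mathrm{AIR}} + 1.0\,E_{\mathrm{desolv}},$$

where $E_{\mathrm{vdw}}$ is a 12-6 Lennard-Jones sum (geometric-mean
combining, 8.5 Å cutoff), $E_{\mathrm{elec}}$ a Coulomb sum with constant
332.0636 kcal Å mol⁻¹ e⁻² and a constant dielectric of 10 (the
constant-dielectric setting used for coarse-grained refinement), and
$E_{\mathrm{desolv}}$ an empirical per-atom solvation parameter times the
accessible surface buried on binding (Shrake–Rupley, 92 golden-spiral
points, 1.4 Å probe). No interface restraints are used in this protocol, so
$E_{\mathrm{AIR}} = 0$ identically. The nonbonded and solvation parameters
ship as a small documented table for the fixture atom types; they are
plausible reduced values, not a published force field. Lower scores are
better; ranking is ascending with stable ties.

## Evaluation

CAPRI metrics are computed against a reference complex sharing residue
numbering: Fnat (fraction of reference residue–residue contacts, 5 Å
heavy-atom cutoff, reproduced by the model), i-RMSD (backbone N/CA/C/O of
reference-defined interface residues — any heavy atom within 10 Å of the
partner — after least-squares superposition) and l-RMSD (ligand backbone
after superposing on the receptor backbone). The 5 and 10 Å cutoffs are the
CAPRI community values; the evaluation literature for this protocol cites
the criteria without printing them. Superposition uses the SVD-based Kabsch
algorithm; tests cross-check it against an independent quaternion-method
oracle and against `bio3d::fit.xyz`.

Quality classes are evaluated in precedence order exactly as printed in the
protocol's source: High (Fnat ≥ 0.5 and i-RMSD ≤ 1 or l-RMSD ≤ 1), Medium
(Fnat ≥ 0.3 and 1 < i-RMSD ≤ 2 or 1 < l-RMSD ≤ 5), Acceptable (Fnat ≥ 0.1
and 2 < i-RMSD ≤ 4 or 5 < l-RMSD ≤ 10), else Incorrect. The literal
intervals leave gaps — e.g. Fnat 0.2 with both RMSDs below 1 Å matches no
positive clause — and such models fall through to Incorrect here. That is a
documented package choice, not a claim about the original criteria's
intent. A steric clash is any intermolecular heavy-atom pair strictly below
2.5 Å. The success rate over a benchmark is the percentage of cases with at
least one Acceptable-or-better model in the top N.

## Synthetic fixtures and what they do (and do not) show

Everything is testable offline through seeded generators:

* `make_toy_complex()` builds a four-helix poly-alanine transmembrane
  bundle (ideal helical geometry, 0.12 Å coordinate jitter per seed) and a
  two-helix hairpin ligand. Three thiol-like SG pseudo-cysteines on the
  receptor crown and a complementary triad on the ligand belly form an
  asymmetric, non-centrosymmetric constellation, so no rotation about the
  membrane normal maps the hot-spot pattern onto itself: the native
  registration is uniquely optimal. The native pose itself is defined as
  the strongest attractor of the shipped potential reachable from the
  extracellular side (the hairpin is dropped onto the crown at four
  azimuths, each placement locally converged, best kept) — making the
  fixture's "truth" a genuine optimum of the score landscape rather than an
  arbitrary construction. Leaflet planes sit 7 Å below the crown with a
  28 Å bilayer, so only the top face is docking-accessible, as for a
  receptor whose extracellular face barely protrudes.
* `make_planar_membrane()` lays square phosphate-bead grids (default 8 Å
  spacing, 80 Å patch → 100 beads per leaflet) at the leaflet planes with
  1 Å Gaussian z-jitter, a modest roughness for an equilibrated phosphate
  layer.
* `make_cg_snapshot()` emulates a coarse-grained frame: five-bead lipids
  (NC3/PO4/GL1/C1A/C2A) on both leaflets plus backbone-bead placeholders at
  the receptor CA positions, feeding the full extract → detect → prune
  chain.
* `make_decoys()` produces rigid perturbations whose i-RMSD is calibrated
  into a requested band (the translation is rescaled against the measured
  i-RMSD), and a clashed variant that pushes the ligand toward the receptor
  core in 0.05 Å steps until at least the requested number of clashes
  exists — so clash depths stay shallow, as in real rigid-body docking
  output.

Passing tests on these fixtures demonstrate the mechanics of the protocol —
filtering, penalized optimization, clash relief within the drift bound,
metric arithmetic — under controlled conditions. They do not demonstrate
performance on real membrane complexes: poly-alanine toys have no sequence
diversity, no side-chain flexibility beyond CB/SG, a flat membrane, and a
score landscape that is (by construction) honest about its native. Success
rates on real benchmarks require the real statistical potential table and
experimental structures.

## Problem sizes and numerical choices

The shipped test and acceptance workloads are scaled to a desktop: toy
receptors of 120 residues (plus hot-spot caps), ligands of 20 residues,
clash-relief suites of 50 decoys over 5 seeded toys, and re-docking over 10
seeded toys at 25 swarms × 60 glowworms × 60 steps with top-10 polishing.
Determinism: every stochastic stage derives its RNG stream from a single
seed (per-swarm seeds are `seed · 1000 + swarm`); minimizers are
derivative-free or quasi-Newton with fixed starts, so whole runs reproduce
bit-for-bit. Degenerate inputs are handled explicitly: a single bead forms
its own upper leaflet, an empty post-filter swarm set is an error naming the
cause, `steps = 0` ranks the initial poses, and refinement of a clash-free
model is a no-op that still reports its energies.

## Known limitations

Flexible-backbone docking (normal-mode ligand flexibility) is deliberately
out of scope — the membrane-embedded receptor and its beads are one rigid
entity. The shipped potential is a reduced fixture-oriented table, not the
published statistical potential; protein–lipid energetics, curved or
deformable membranes, and symmetry-aware chain mapping for homo-oligomeric
evaluation are not implemented.
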