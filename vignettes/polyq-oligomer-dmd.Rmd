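---
title: "Coarse-grained DMD of polyQ exon-1 oligomerization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained DMD of polyQ exon-1 oligomerization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyqdmd)
```

## The problem

Huntington's disease is driven by expansion of the polyglutamine (polyQ)
tract in the first exon of huntingtin (HTT). Expanded exon-1 fragments
(clinically, beyond ~36 repeats) self-assemble through cross-β structure: β
sheets whose paired strands belong to *different* protein chains, the
operational signature of an aggregate precursor. `polyqdmd` provides a
desk-scale computational pipeline for studying that process: an event-driven
discrete molecular dynamics (DMD) engine for coarse-grained exon-1-like
constructs, temperature replica exchange for sampling, and the analysis
stack that turns trajectories into per-residue β-probability profiles,
mean smallest-distance and cross-β contact maps, aggregate-precursor calls,
single-linkage conformational clusters, and ΔΔG point-mutation scans.

Constructs are assembled from named segments in the order
N17 → polyQ(n) → P11 → R17 → P10 → R12 (n + 67 residues); `n = 23`
stands for the wild-type-like protein and `n = 74` for the expanded mutant.
This segment order is the unique one under which the classic interface
residues fall in their expected regions with continuous cross-chain
numbering (Q37/Q38 in chain-1 polyQ; L64/P65 in chain-1 R17; Q175 in
chain-2 polyQ; P191/P192 in chain-2 P11; L194 in chain-2 R17 for the
23Q + 74Q dimer) — an executable test in the suite. The true R17/R12
sequences are not included; the package ships clearly-flagged synthetic
placeholder sequences (N17 is the canonical huntingtin N-terminal 17-mer)
and accepts FASTA overrides. Every analysis depends only on segment classes
plus P/Q identity, so the placeholders do not affect the pipeline's
behaviour; only ΔΔG values at non-polyQ/non-proline positions see the
placeholder amino-acid identities.

## The coarse-grained model

DMD moves beads ballistically between instantaneous events at the
boundaries of piecewise-constant pair potentials. All quantities are in
reduced units: lengths in nm, k~B~ = 1, bead masses 1; the temperature
window 0.5–0.72 is the standard production range for this class of
simulation (1000 time units correspond to roughly 50 ps at full scale).

Each residue carries a backbone CA bead and one side-chain bead (none for
glycine). Geometry is maintained by infinite square wells:

| interaction | window (nm) | role |
|---|---|---|
| CA(i)–CA(i+1) | 0.345–0.415 | virtual backbone bond |
| CA(i)–SC(i) | 0.20–0.32 | side-chain attachment |
| CA(i)–CA(i+2) | 0.62–0.72 | virtual angle (extended) |
| CA(i)–CA(i+3) | 0.98–1.11 | virtual dihedral (trans) |

The 1–3 and 1–4 windows were chosen by explicitly sampling random four-bead
chains and measuring which window combinations pin the virtual dihedral:
with these values the accessible dihedral range concentrates near the
trans/extended region while helical geometry (dihedral ≈ 50°) is
excluded. Without the 1–4 constraint a two-bead chain makes tight turns
freely and collapses into globules that never satisfy an extended-dihedral
criterion — the all-atom sterics that forbid such turns have to be put back
in by hand at this resolution.

Non-bonded interactions are square wells by bead-kind and side-chain class
(Q, P, hydrophobic, other; glycine has no side chain):

* a backbone–backbone well (0.38 core, well to 0.56 nm, depth 0.33) acting
  as the hydrogen-bond surrogate. It acts **between chains only**: this is
  the package's minimal-model stance — intermolecular β pairing is the
  phenomenon being modelled, and an isotropic *intra*-chain backbone
  attraction (the only kind a two-bead model can express) produces compact
  non-β globules instead of strands. Intra-chain backbone contacts beyond
  the pseudo-bonds are purely repulsive.
* side-chain class-pair wells (0.35 core, full-depth shell to 0.45 nm,
  half-depth shell to 0.62 nm) with depths ordered so Q–Q (0.55) dominates,
  hydrophobic–hydrophobic is intermediate (0.40), and anything involving
  proline is nearly inert (0.06). PolyQ tracts therefore drive aggregation
  and polyproline stretches resist it.

The absolute energy scale is set so that the simulated temperature window
brackets the dimer pairing/melting transition. A zipped two-chain β ribbon
gains roughly one Q–Q well plus one backbone well per paired residue, so
pairing stability grows with polyQ length the way duplex stability grows
with strand length: at the cold end of the window a 23Q–23Q pairing is
marginal while a 74Q–74Q pairing survives. This is what makes the
qualitative aggregation ordering (74Q ≥ 23Q in polyQ β probability and in
cross-β contact mass) an equilibrium property of the model rather than an
accident of initial conditions. These parameters are declared design
choices of the stand-in force field, not fits: the all-atom implicit-solvent
force field used for such systems at atomistic resolution has no transferable coarse-grained
parameterization, and its quantitative β probabilities and cluster sizes
are explicitly *not* reproduction targets here.

## The engine

Events (hard-core bounces, well captures/escapes/bounces, bond reflections)
are kept in a binary heap with lazy invalidation via per-bead event
counters; pair predictions are restricted to beads in neighbouring cells of
a linked-cell grid (cell edge at least the largest interaction radius) and
cell crossings are themselves events. An Andersen-style thermostat resamples
single-bead velocities from the Maxwell–Boltzmann distribution as a Poisson
process (ghost
collisions are the standard thermostat choice for DMD). Between thermostat events
total energy is conserved to round-off and the suite asserts a relative
drift below 1e-9; with a fixed seed trajectories reproduce bit for bit.

Two numerical choices deserve note. First, shell boundaries are
right-continuous: a pair exactly at a boundary counts as outside it, and the
per-pair shell index is explicit bookkeeping rather than being re-derived
from distances, so the tracked potential energy is exact by construction.
Second, at every pair-event resolution the separation is snapped exactly
onto the boundary radius. Without the snap, a grazing bounce can leave a
pair marginally outside its bookkept shell with an outward perigee — no
return event exists and the pair would silently escape its bond; the snap
(order 1e-16 nm) removes the failure mode entirely.

Correctness is established against a brute-force reference engine written
independently in R: no heap, no cells, candidate events recomputed by
rescanning after every event. The two implementations mirror each other's
arithmetic operation for operation, so on systems small enough that the
production engine resolves every pair they agree on tens of thousands of
consecutive events to the last bit — the strongest equivalence a
floating-point comparison can make. Thermostatted runs are validated
statistically instead: equipartition of kinetic energy and the analytic
Boltzmann occupancy of an isolated pair in a square well.

Initial conformations are completely stretched zig-zag chains on parallel
axes 0.55 nm apart with
seed-controlled offsets, in a cubic periodic box auto-sized to hold the
stretched chains; minimal-image distances are used throughout, coordinates
are kept unwrapped internally (and, by default, on output — whole-system
RMSD clustering needs continuous coordinates, and with the auto-sized box
nothing ever wraps in practice; `write_trajectory(wrap = TRUE)` is
available).

## Replica exchange

`run_remd()` advances one replica per ladder temperature (default: 20
linearly spaced temperatures from 0.5 to 0.72) and attempts adjacent-pair
temperature swaps every 1000 time units (both defaults follow the
production protocol; desk-scale runs shrink them). Swaps alternate even/odd
parity and accept with probability min(1, exp[(1/T_i − 1/T_j)(E_i − E_j)])
on the replica potential energies, rescaling velocities by sqrt(T_new/T_old)
on acceptance. The suite checks the machinery against a two-level toy system
whose occupancies and per-state swap rates have closed forms. Burn-in is
flagged by a running-mean-of-energy criterion with a discard-first-half
fallback; flagged frames are kept but excluded from downstream summaries.

## Analyses

**β assignment.** Atomistic secondary-structure tools need backbone atoms a
two-bead model does not have, so β is assigned geometrically: a residue is β
when its virtual CA dihedral is extended (|dihedral| ≥ 135°; ideal strands
sit near 180°, helices near 50°) *and* it has a cross-strand partner
(another residue ≥ 3 positions away in sequence or on another chain with
CA–CA ≤ 0.55 nm), in runs of ≥ 3 consecutive such residues. All three
thresholds are configuration constants (`beta_params()`). Profiles carry
binomial error bars Δp = z·sqrt(p(1−p)/N) with z = 1.96; at N = 4000
frames the bound is 0.015.

**Maps.** The mean smallest-distance map averages, over frames, the minimum
bead–bead distance per residue pair. The cross-β map counts bead pairs
closer than 0.4 nm (strictly) between residues that are both β-labelled and
on different chains, averaged over *all* frames — frames without qualifying
contacts contribute zero; intra-chain entries are zero by construction.
Region-block summaries reduce either map over (chain, segment) blocks.

**Precursors.** An aggregate precursor is a frame with a β sheet involving
both proteins: connected patches (sequence-adjacent on both sides) of
inter-chain β pairing with at least 3 residues on each side, reported as
region pairs.

**Clustering.** Pairwise CA-RMSD of whole multi-chain frames after
least-squares superposition (SVD solution), then single linkage at 4 Å:
clusters are connected components of the d < cutoff graph (strict
inequality; chaining is intended). Clusters are ordered by size with ties
to the smallest member frame, and each cluster's central structure is its
medoid (smallest mean distance to co-members). The distance metric is a
package choice (the conventional one for conformational clustering), and
low-temperature trajectories are clustered by default.

**ΔΔG scanning.** The ΔG surrogate of a structure is its total contact
energy under the force field. A mutation swaps the side-chain class
(glycine removes the bead); side chains of residues whose CA lies within
0.8 nm of the site are re-packed by simulated annealing (geometric cooling,
Gaussian displacement proposals, hard constraints enforced by rejection),
backbone fixed. Each of the 250 default iterations re-anneals *both* the
wild type and the mutant with fresh seeds and takes the paired difference;
ΔΔG = mean(ΔG_mut − ΔG_WT) ± sd. Positive values destabilize — identity
substitutions are exactly zero, removing a purely attractive side chain can
only destabilize (an exact property when the repack shell isolates the
mutated side chain), and the scan mean tightens as 1/sqrt(iterations).
Proline substitutions are flagged `"proline-omitted"` and skipped by
default: the rigid ring makes the surrogate unreliable, and they are
excluded from rankings. Absolute ΔΔG magnitudes of the all-atom design
suite are not reproduction targets; sign conventions, the identity zero,
the proline flag, and interface-residue sensitivity are.

## Synthetic fixtures

`make_planted_trajectory()` builds trajectories with known truth so every
analysis stage is testable without engine runs: chosen residue ranges are
placed as ideal antiparallel strand pairs (0.36 nm/residue rise, planar
zig-zag, inter-strand CA–CA distance set per pairing, never exactly 0.4 nm
so the contact rule is unambiguous), present in a Bernoulli fraction of
frames; all other residues follow a compact helix-like curl whose dihedrals
deterministically fail the extended window, so false β (and hence false
precursor pairs) cannot arise at the fixture's default noise level
(Gaussian, 0.005 nm). Strand-edge residues whose dihedral quadruple
straddles the coil are marked `NA` in the truth record and excluded from
recovery scoring; the planted cross-β mass per "on" frame is exactly
`length − 4` aligned single contacts. These fixtures exercise the analysis
definitions, not the physics: they are geometric constructions that ignore
the force field's hard constraints (their contact energies are infinite),
so passing recovery tests says the *analyses* are correct, not that the
engine produces such structures.

`make_cluster_fixture()` produces bundles whose intra/inter RMSDs are
verified against the requested spread/separation, and
`make_two_level_toy()` supplies the analytic replica-exchange oracle.

## Problem sizes and what the tests show

The test suite and the acceptance script use desk-scale sizes chosen to
exercise every code path while staying comfortably within a single CPU:
20-bead systems for the engine equivalence runs (≥ 10^4 events), a
two-bead pair over 20000 time units for the Boltzmann occupancy, 200-frame
planted fixtures, 200-structure clustering sets, and 23Q/74Q dimers under
3-replica exchange for 500 time units with swaps every 50 (25 analysed
frames at the lowest temperature) for the qualitative ordering. The full protocol (20 replicas, 4×10^6 time units,
N = 4000 frames) is what the defaults in `run_config()` encode; runs of
that size are left to the user's budget. The qualitative 74Q-vs-23Q
ordering is a stochastic check on a reduced system; it expresses the
expected direction (essentially no aggregation for 23Q–23Q, robust
cross-β for 74Q–74Q) but does not reproduce, and is not intended to
reproduce, all-atom probabilities or cluster sizes.

## Known limitations

* The force field is a declared stand-in: two beads per residue, four
  side-chain classes, no electrostatics, no directional hydrogen bonds.
  Intra-chain β (monomeric hairpins) is suppressed by the intermolecular-only
  backbone attraction, which is a deliberate bias toward the oligomerization
  question.
* The β criterion is geometric and CG-specific; its thresholds are
  conventions, and comparisons with atomistic secondary-structure
  assignments are qualitative at best.
* The ternary "residue 38 / residue 270" numbering ambiguity inherited from
  the literature is documented (`?build_system`) and deliberately not
  resolved; `global_index()` always uses continuous numbering.
* ΔΔG magnitudes depend on the placeholder sequences outside polyQ/P
  segments and on the CG energy scale; only signs and orderings are
  meaningful.
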