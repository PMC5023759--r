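---
title: "Modeling GPCR homodimer interfaces with dimerscan: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling GPCR homodimer interfaces with dimerscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modeling problem

Class-A G protein-coupled receptors (GPCRs) form homodimers whose contact
interface — which transmembrane (TM) helices of each protomer touch — is
rarely observable directly. A practical computational strategy is population
based: enumerate every dimer arrangement compatible with membrane
integration, refine each locally, score the resulting population with
several independent interface-quality parameters, and ask which TM-pair
interface class dominates the best-scored dimers under consensus. dimerscan
implements that protocol end to end, together with a synthetic generator of
idealized seven-TM bundles so that every stage can be exercised and
validated against planted ground truth without any experimental structure.

## Pose enumeration

Membrane compatibility restricts a dimer to four degrees of freedom: each
protomer may rotate about its own membrane normal (+z), and the protomers
may shift relative to each other in the membrane plane (plus a small
z-register shift). `enumerate_dimer_poses()` builds the exhaustive grid
alpha_i = 360 i / steps_a, beta_j = 360 j / steps_b, rotates copy A by
alpha_i and copy B by beta_j, and slides B along +x until the minimum
heavy-atom distance equals `d_contact`. The placement shift has a closed
form (the maximum over atom pairs of the shift putting that pair exactly at
`d_contact`), so placement is exact, not iterative. The default 12 x 12
grid (30-degree steps per protomer) gives 144 starting dimers; only the
total is anchored in the protocol, the 12 x 12 factorization is this
package's convention and is configurable. `d_contact` defaults to 4.0 A —
a typical closest heavy-atom approach across packed protein interfaces;
the criterion at placement is a convention of this artifact.

## Rigid-body refinement

Each starting pose seeds `n_outputs` independent Metropolis chains
(default 10, giving 1440 refined dimers from the default grid) over the
membrane-compatible degrees of freedom of protomer B: rotation about its
own z-axis, in-plane translation, and a z-shift bounded at +/-2 A.
The chain minimizes the surrogate cross-protomer interaction energy and
reports its best-visited transform. Proposal scales are sigma = 1.0 A
in-plane, 0.25 A in z, 5 degrees in rotation; the temperature is 1 energy
unit, so an uphill move of +1 is accepted with probability exp(-1) ~ 0.37;
chains run 200 steps by default. These are local-sampling conventions: the
role of the stage is to relax each enumerated interface into its nearest
energy basin, not to perform global docking.

Because in-plane translation of B changes the inter-protomer axis (which is
gauge-equivalent to co-rotating both protomers), the sampler explores the
full membrane-compatible configuration space around each start.

## The surrogate interaction energy

All scoring is self-contained and deterministic. The pair potential is a
6-12 Lennard-Jones term (per-element radii: C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 A; well depths 0.02-0.25 kcal/mol; arithmetic-mean contact radii,
geometric-mean depths) plus Coulomb with the distance-dependent dielectric
eps(r) = 4r and a 10 A cutoff over cell lists. Partial charges are coarse
by design: backbone N +0.2, carbonyl O -0.2, carboxylate oxygens -0.5,
guanidinium nitrogens +0.33, planted decoration sites +/- their configured
magnitude. Two numerical safeguards matter:

* the repulsive Lennard-Jones term of a clashing pair is capped (default
  +100) and any pair closer than 0.5 A raises a clash flag;
* the Coulomb distance is floored at the pair contact distance, so a pair
  of opposite charges cannot lower the energy without bound by
  interpenetrating — without this floor the Monte Carlo chains collapse
  pseudo-atoms onto each other and report unphysical energies.

Hydrogen bonds use heavy-atom geometric criteria (the synthetic structures
carry no hydrogens): donor-acceptor distance <= 3.5 A, alignment angle
(donor antecedent - donor - acceptor) >= 120 degrees, energy
-eps cos^2(180 - theta) ramp(d) with the ramp falling linearly from 1 at
2.9 A to 0 at 3.5 A and eps = 2 kcal/mol.

## The four scoring parameters

For every refined dimer the package computes:

1. **Interface score** — the cross-protomer pair energy alone.
2. **Interface area** — SASA(A) + SASA(B) − SASA(AB), from a native
   Shrake-Rupley implementation (probe 1.4 A, 92 deterministic
   golden-spiral points per atom, neighbour-culled).
3. **Binding-energy surrogate** — E(AB) − E(A) − E(B). With rigid
   protomers the intramolecular terms cancel exactly, so this equals the
   cross-protomer pair energy plus the cross-protomer hydrogen-bond energy,
   and is computed that way.
4. **Hydrogen-bond energy** — the sum over detected cross-protomer bonds.

A numerical subtlety affects classification: per-atom SASA from a fixed
quadrature orientation carries a few A^2 of orientation noise, which is
harmless for totals but can flip per-helix burial sums at interface-class
boundaries. The population scorer therefore evaluates each chain's burial
in its own template frame, where the isolated-protomer reference cancels
exactly for every non-interface atom.

Interface classes label each protomer by its dominant adjacent-TM pair
(12, 23, 34, 45, 56, 67, 71 — the seven sequential pairs), the pair
maximizing the summed buried area of its two helices, ties toward the lower
TM index; the dimer label is the lexicographically sorted pair of pair
labels, giving exactly 28 classes plus "none" for contact-free poses.
Collapsing an interface dominated by non-adjacent helices onto the
best-covering adjacent pair is a deliberate convention of this package and
is flagged in reports.

## Consensus ranking

Parameters are first normalized per population onto [0, 1], oriented so 1
is better (lowest energy -> 1; largest area -> 1; a constant parameter maps
to 0.5). Two consensus methods then rank the classes:

* **Value averaging** — per parameter, the top-100 dimers by that
  normalized parameter are taken and each class scores the mean over its
  members in that subset (0 when absent); the combined consensus applies
  the same rule to the unweighted mean of the four normalized parameters.
  "Average scores of the 100 best scored dimers with respect to each
  interface" is ambiguous between this reading and per-class top members;
  the alternative reading is available via `per_class_top = TRUE`.
* **Frequency** — per parameter, each class's share of the top-100; the
  combined score is the mean of the four shares, ties broken by the value
  consensus, then label order.

The unweighted combination and the top-100 cutoff are the protocol's
conventions; `top_n` is configurable for smaller populations.

## The synthetic generator

`build_ideal_tm_bundle()` produces an idealized class-A GPCR-like monomer:
seven helix axes on a 12 A circle at uniform azimuths, alternating
up/down orientation (N-terminus extracellular), +/-10 degree alternating
tilts, ideal alpha-helix geometry (rise 1.5 A/residue, twist 100
degrees/residue, CA radius 2.3 A), 26 residues per helix, short loops and
tails, poly-alanine backbone+CB everywhere except designated functional
residues. Helix phases are chosen so the orthosteric-pocket positions
(3.32, 6.48, 6.55) face the bundle axis. Generic numbers are attached via
the annotation config (each default helix spans x.30-x.55), never inferred
from coordinates.

Functional residues carry minimal pseudo-side-chain interaction sites:
carboxylate-like oxygen pairs (3.32, 3.49, 6.30), a guanidinium-like
nitrogen triplet (3.50), and single polar atoms (5.42 OH, 6.34 OG1, 6.48
NE1, 6.55 NE2, plus an N-terminal tyrosine hydroxyl). Because the idealized
helix layout places TM3 and TM6 too far apart for physically short
side-chain arms, the Arg 3.50 and Glu 6.30 termini are placed
schematically along the line joining their CB atoms with a planted minimum
N-O gap (`lock_gap`, default 3.5 A, the salt-bridge convention): the
inactive-state ionic lock is formed by construction, which is exactly what
the trajectory diagnostics need as ground truth. The arms are schematic,
not rotamers.

`plant_interface_patch()` decorates the outward faces of a chosen helix
pair (default TM4/TM5) with hydrogen-bond donor pseudo-atoms (+q) on the
first helix and acceptors (−q) on the second (default 8 + 8 sites,
|q| = 1.0 — each complementary pair is a salt-bridge-like ionized contact).
Both faces point along the pair's shared outward bisector, and the sites of
each face form an idealized lattice: a vertical ladder (3 A spacing,
centred at the membrane midplane) on a common contact plane normal to the
face direction, attached to the most outward-facing residues by schematic
arms of varying length. Under the two-fold symmetry of the in-register
dimer the two faces' lattices coincide site-for-site, so the symmetric
double-contact dimer — TM4 of each protomer against TM5 of the other — is
by far the deepest arrangement. This planted interface is the known truth
that recovery tests ask the whole pipeline to find.

### What recovery shows — and a structural property of frequency consensus

Across seeded end-to-end runs the **value consensus recovers the planted
`45_45` class as its top class**, robustly. The **frequency consensus
places `45_45` in its top three but ranks the asymmetric neighbour
`34_45` first**, and analysis shows this is structural, not accidental.
On a 12 x 12 rotational grid each protomer side of an interface class
covers a 51.4-degree azimuthal sector, about 1.7 grid columns, so a
symmetric class XX draws from about 1.7 x 1.7 ~ 3 grid cells (about 30 of
the 1440 refined dimers), while an asymmetric class XY is the canonical
merge of the (X, Y) and (Y, X) orientations and draws from about twice as
many. Because refinement is local (each population stays attached to its
starting interface, so that each enumerated interface contributes a fixed
number of refined dimers), these capacities are fixed; a class with twice the members in the
well-scored region wins a membership count even when every one of its
members scores worse than every member of the planted class. The value
method, which averages scores instead of counting members, is immune to
this capacity bias — which is precisely why the two consensus methods are
worth running side by side, and why a frequency-based consensus tends to
crown asymmetric interface classes. Deepening the planted signal (within
physically sensible decoration strengths) does not change the outcome,
because membership counts, not score magnitudes, decide the frequency
ranking.

`simulate_trajectory()` emulates an equilibrated production trajectory as
reference coordinates plus i.i.d. per-atom Gaussian jitter plus planted
event displacements applied cumulatively from their frame onward. It
reproduces known-truth displacements and noise amplitudes — not physical
dynamics, correlations, or solvent.

### What passing tests do and do not show

The synthetic bundles exercise every code path with controlled truth:
exact helix geometry, a formed ionic lock, a plantable interface, known
event frames and occupancies. They do not emulate loop flexibility,
rotamer packing, membrane or solvent, sequence variation, or the rugged
energy landscape of a real receptor; recovery of the planted interface
demonstrates that the population/consensus machinery is sound, not that
the surrogate energy would rank real GPCR interfaces correctly.

## Trajectory diagnostics

`ionic_lock_series()` reports the per-frame minimum distance between the
Arg 3.50 guanidinium nitrogens and Glu 6.30 carboxylate oxygens, with the
fraction of frames below 4.5 A (salt-bridge convention) as the
lock-formed summary. `hbond_persistence()` applies the heavy-atom H-bond
criteria per frame and reports occupancy. `water_bridges()` counts waters
whose oxygen touches both partners within 3.5 A. `rmsd_series()` reports
Kabsch-superposed RMSD to frame 0 (the package's reference-frame
convention) with a stability verdict at 4 A, the usual complex-stability
criterion.

## Binding-site geometry

The default orthosteric site is the CA centroid of 3.32/6.48/6.55; site
distances come in two modes: `direct` (Euclidean) and
`extracellular_path`, a two-segment path through a waypoint on the dimer
z-axis 5 A above the structure — a stated surrogate for a route around the
extracellular surface, always at least the direct distance. Distances
between sites of a real receptor dimer depend on the underlying structural
model and are not reproduced by the synthetic bundles; the operations are
validated on planted geometry instead.

## Problem sizes and determinism

The validation suite runs the full production-scale population: a 12 x 12
grid, 10 replicates per pose, 200 Monte Carlo steps per chain (1440 scored
dimers per run) and five seeded end-to-end recovery runs. Every stochastic
stage takes an explicit seed and is bit-reproducible; all randomness flows
through R's RNG so a fixed seed fixes the entire pipeline output,
including the C++ Monte Carlo (which consumes pre-drawn R variates).

## Known limitations

* The surrogate energy is intentionally coarse (no solvation, no
  polarization, schematic charges); its absolute values are not comparable
  to physical binding free energies.
* Interfaces dominated by non-adjacent helices are folded into the
  adjacent-pair alphabet.
* PDB support is deliberately narrow: single-character chains, no
  alternate locations or insertion codes, occupancy column repurposed for
  partial charges, multi-model files as trajectories.
* The value-averaging consensus gives absent classes a score of 0 within a
  top-N subset, which rewards classes with many strong members; with very
  small populations (`top_n` close to the population size) both methods
  lose discrimination.
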