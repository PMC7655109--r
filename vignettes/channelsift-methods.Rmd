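---
title: "Methods: interaction fingerprints, Markov uncertainty, and pore geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction fingerprints, Markov uncertainty, and pore geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(channelsift)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, what the synthetic generator does and does not
emulate, and the places where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The analysis problem

Pentameric ligand-gated ion channels (pLGICs) such as the serotonin 5-HT3A
receptor bind small-molecule agonists and competitive antagonists
(setrons) in five equivalent pockets at subunit interfaces. Three linked
questions recur in structural studies of such systems: *which* chemical
contacts a bound ligand maintains over a simulation and how confidently
their frequencies are known; *how* the binding loops and the
loop-stabilizing salt bridge behave per frame; and *whether* the
transmembrane pore is wide enough to conduct a hydrated ion. `channelsift`
implements exactly this analysis layer, decoupled from any particular MD
engine: inputs are multi-model PDB trajectories plus two declarative
annotation files (ligand chemistry, residue roles).

## The nine-class fingerprint

For residue $r$, frame $t$, and subunit $s$, the bit vector
$b_{r,t,s} \in \{0,1\}^9$ covers apolar contact, face-to-face and
edge-to-face aromatic stacking, hydrogen bonds with the protein as donor or
acceptor, electrostatics with the protein positive or negative, and
water-mediated hydrogen-bond bridges of order 1 and 2. Both side-chain and
backbone heavy atoms of the residue are considered; hydrogens never enter
distance tests.

Distance gates (all inclusive, configurable via `fingerprint_config()`):
4.5 Å for carbon–carbon apolar contacts, 4.0 Å for aromatic and
electrostatic contacts, 3.5 Å donor–acceptor for hydrogen bonds. The
hydrogen-bond geometry is deliberately two-mode: simulation frames carry
explicit hydrogens, so a donor–H–acceptor angle criterion (≥ 120°, best H)
applies; experimental models usually do not, so with no hydrogen within
1.25 Å of the donor the distance alone decides. The face/edge split of an
aromatic contact at a 45° inter-normal angle is a conventional choice, not
a literature-asserted constant, and is exposed in the config for the same
reason.

Chemistry the classifier assumes rather than perceives: the ligand's
rings, donors, acceptors, charged groups and nonpolar carbons come from an
explicit `ligand_spec()` annotation (mirroring what a force field encodes);
protein charged groups are Arg (NE/NH1/NH2), Lys (NZ) and explicitly
protonated His (HIP/HSP) positive, Asp (OD1/OD2) and Glu (OE1/OE2)
negative, termini excluded — force-field protonation at pH 7. Tryptophan
contributes the pyrrole and benzene rings of its indole independently;
either ring can set an aromatic bit.

Water bridges are enumerated as hydrogen-bonded paths
ligand–(water)$_k$–residue with $k \le 2$, each link evaluated by the same
hydrogen-bond test with waters acting as both donor and acceptor. Paths
never revisit a water; identical paths are deduplicated; a residue–frame
pair may set order 1 and order 2 simultaneously through distinct paths.
Order-3 chains are never reported.

Two consequences worth knowing. First, an aromatic stack at ≤ 4 Å is
always also an apolar contact (ring atoms are carbons); planted aromatic
scenes therefore carry both bits, and the synthetic ground truth accounts
for it. Second, the default residue roster for a trajectory sweep is "any
residue with a heavy atom within the largest cutoff + 2 Å of the ligand";
an order-2 water bridge can reach farther (up to three hydrogen-bond links,
about 10 Å), so analyses centered on long bridges should pass an explicit
`residues` table. This default follows the build contract and is kept.

Residues are pooled across subunits by label (`TRP156` in pocket A and
pocket E are one row), because probabilities average over all five binding
sites; when several same-numbered copies are in reach, each subunit uses
the copy nearest its own ligand.

## Markov uncertainty on occupancy probabilities

The occupancy probability of a bit is its plain mean over frames and
subunits. Frames are autocorrelated, so a binomial error would be
overconfident; instead each bit's series is modelled as a two-state Markov
chain. Transition counts are pooled across the five subunit series (treated
as replicates; no transition spans a series boundary), each row of the
transition matrix gets an independent conjugate posterior
$p_{01} \sim \mathrm{Beta}(n_{01}+\alpha,\, n_{00}+\alpha)$,
$p_{10} \sim \mathrm{Beta}(n_{10}+\alpha,\, n_{11}+\alpha)$ with symmetric
prior mass $\alpha = 1$ per cell (the conventional uniform Dirichlet
choice; the level, draw count and prior are defaults, not claims about any
original analysis), and the stationary probability
$\pi_1 = p_{01}/(p_{01}+p_{10})$ is summarized over 10 000 posterior draws
by its mean and equal-tailed 95 % credible interval. Draws with
$p_{01}+p_{10}=0$ are impossible under a positive prior but guarded by
rejection since $\pi_1$ is undefined there. Everything is
seed-deterministic, and the local RNG is restored so calls do not disturb
the session seed.

Probabilities are binned for reporting with lower-exclusive bounds:
`very_stable` > 0.75, `stable` > 0.50, `occasional` > 0.25, `rare`
otherwise.

## Conformational descriptors

All RMSD descriptors follow the align-then-measure discipline: a Kabsch
superposition (equal weights, SVD with the reflection branch corrected to a
proper rotation) is fitted on the role map's alignment selection only —
for receptor work, the Cα atoms of the extracellular-domain helices and
sheets, supplied as a configuration input because no universal residue set
exists — and the RMSD is evaluated on the measured set without re-fitting.
The loop descriptor uses exactly the Cα + carbonyl C + backbone N atoms of
the loop range (18 atoms for the default 200–205 range) and a four-Cα
dihedral (defaults 208/199/198/203) whose sign follows the IUPAC torsion
convention; large values mean the loop points away from the binding site.
The gate descriptor is the minimum distance over listed polar side-chain
atoms of the pair (defaults Arg65 NE/NH1/NH2 vs Asp202 OD1/OD2) with an
inclusive 4 Å engagement threshold. Boundary inclusivity (≤ everywhere) is
a package decision made for deterministic behavior at exact cutoffs.

Pocket hydration counts distinct water oxygens within 3 Å of any ligand
atom, per ligand copy. Displacement maps match residues by chain and
number, report unmatched residues as absent (never zero), and smooth, when
asked, with a natural cubic spline over sequential residue index within
each chain only — never across chain breaks, and per chain rather than over
the pentamer, a choice left open by the source material.

## Pore profiling

The pore radius at axial coordinate $z$ is the largest
$\min_i(\lVert c-x_i \rVert - r_i)$ over in-plane centers $c$, with Bondi
van der Waals radii by default (swappable). Instead of Monte Carlo
annealing, the in-plane optimization is a three-start polar pattern search
(16 directions, step shrinking geometrically from 1 Å to 10⁻⁸ Å) with the
center warm-started from the neighboring plane and capped at 10 Å; sweeps
proceed outward from the midpoint in both directions. On convex pore
cross-sections this finds the same optimum as stochastic search, and it
makes runs bit-identical and rigid-transform invariant to ~10⁻⁸ Å, which
the test suite verifies at 10⁻⁶. Planes with no atom in reach are capped
and flagged unbounded rather than erroring. The default axis is the
dominant principal component of the Cα cloud — the C5 symmetry axis for an
elongated pentamer — with the sign fixed by the third axial moment so the
choice is rotation-covariant; it is user-overridable and should be
overridden for non-channel geometries.

## The synthetic world

`build_pocket_scene()` emits a miniature pocket: a rigid model ligand
(aromatic ring, protonated amine with explicit hydrogens, carbonyl
acceptor, carboxylate, aliphatic carbon), one ideal-geometry residue stub
per planted interaction placed in a well-separated direction sector at the
exact requested distance/angle, explicit-hydrogen waters at ideal geometry
for bridge plants, and far-field glycine/water decoys (≥ 7 Å from the
ligand; decoy waters ≥ 4.2 Å from every polar atom so they cannot join a
hydrogen-bond network). The expected bitset is derived from the planted
parameters by the stated threshold rules — plus carbon–carbon and
donor–H–acceptor geometry read off the emitted coordinates where physics
couples bits — never by running the classifier; a scene whose geometry
would contradict its declared truth (for example, an electrostatic plant
close enough to hydrogen-bond) raises an error instead of emitting
coordinates.

`build_pocket_trajectory()` toggles each scheduled plant between its
engaged geometry and a pose translated 50 Å outward, following an
independent simulated two-state chain per plant. The build contract
sketched a disengaged *ligand* pose; toggling the ligand would couple every
scheduled bit, so the residue (plus its bridge waters) moves instead —
same contract, independent bits. Scenes emulate geometry and two-state
kinetics only: no force-field energetics, no membrane or solvent box, no
correlated side-chain motion, and rigid plants. A green test therefore
establishes the correctness of classification, counting and estimation on
controlled geometry — not the realism of any simulation.

`build_pore_structure()` stacks rings of carbon pseudo-atoms whose centers
sit at `radius_fn(z) + vdw` from the axis, so the accessible radius is
`radius_fn(z)` up to a discreteness correction; the exact on-axis
accessible radius computed from the emitted coordinates is returned as the
analytic reference. When rings with very different radii sit close along
the axis (steps, tight waists), a narrow ring legitimately bounds spheres
at neighboring planes; the generator surfaces the resulting gap between
nominal and realizable radius as a warning with its magnitude.

## Numerical choices and degenerate inputs

Collinear points make dihedrals and superpositions undefined and raise
errors; rings must have ≥ 5 members and non-collinear geometry. Minimum
distances break ties to the lowest index pair. Altlocs collapse to the
highest-occupancy conformer, ties to letter 'A'. Atom clashes below 0.5 Å
abort bond inference with the offending pairs listed. Strict PDB parsing
errors on malformed lines and on models with inconsistent atom counts;
lenient mode skips malformed lines with a warning. PDB output rounds
coordinates to 3 decimals, the format's precision, which bounds round-trip
error at 5·10⁻⁴ Å.

## Known limitations

Periodic-boundary images are not reconstructed: trajectories must contain
whole molecules. Binary trajectory formats are out of scope (the
multi-model PDB dialect is the contract; adapters can wrap it). Ligand
protonation is annotated, not perceived. Halogen bonds and a distinct
cation-π bit are not part of the nine-class scheme. The pore axis is
straight; curved permeation pathways are not modelled. Gate-pair residues
are matched within one chain; inter-subunit gate pairs would need an
extended role map.
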