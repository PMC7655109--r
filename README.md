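# channelsift

Structure/trajectory analysis for ligand-bound pentameric ligand-gated ion
channels (pLGICs), written for receptor–antagonist systems such as the
setron-bound serotonin 5-HT3A receptor: per-residue structural interaction
fingerprints with Bayesian uncertainty, channel-specific conformational
descriptors, and maximal-sphere pore-radius profiles — plus a synthetic-data
generator that makes every stage verifiable against analytic ground truth
without access to production MD trajectories.

## What it computes

**Structural interaction fingerprints (SIFt).** For each receptor residue
and each trajectory frame, a 9-bit vector records which interaction classes
the residue forms with the bound ligand:

| bit | class | criterion (defaults) |
|---|---|---|
| 1 | `APOLAR` | any ligand carbon within 4.5 Å of a residue carbon |
| 2 | `AROM_FTF` | ring–ring contact ≤ 4.0 Å, inter-normal angle ≤ 45° |
| 3 | `AROM_ETF` | ring–ring contact ≤ 4.0 Å, inter-normal angle > 45° |
| 4 | `HB_PROT_DONOR` | H-bond, protein donates (≤ 3.5 Å, D–H–A ≥ 120°) |
| 5 | `HB_PROT_ACCEPTOR` | H-bond, protein accepts |
| 6 | `ELEC_PROT_POS` | Arg/Lys/His⁺ group within 4.0 Å of a ligand anion |
| 7 | `ELEC_PROT_NEG` | Asp/Glu group within 4.0 Å of a ligand cation |
| 8 | `WATER1` | ligand –HB– water –HB– residue bridge |
| 9 | `WATER2` | ligand –HB– water –HB– water –HB– residue bridge |

Interaction probabilities are averaged across frames and across the five
binding sites of the pentamer. Uncertainty comes from a two-state Markov
model of each bit's time series: transition counts pooled over subunits,
Beta (two-state Dirichlet) posteriors on each transition row with symmetric
add-one priors, and an equal-tailed credible interval on the stationary
probability π₁ = p01 / (p01 + p10).

**Conformational descriptors.** Ligand-pose RMSD per subunit after Kabsch
superposition on an alignment selection (no re-fit on the measured atoms);
binding-loop ("Loop C") RMSD over the Cα/C/N backbone of residues 200–205
and the orientation dihedral over the Cα atoms of residues 208/199/198/203;
minimum polar-atom distance of the Arg65–Asp202 gate pair with a 4 Å
engagement threshold; water-oxygen counts within 3 Å of the ligand; and
per-residue Cα displacement maps between structures, optionally
spline-smoothed along the chain.

**Pore profile.** The largest-sphere radius along the channel axis,
r(z) = max over in-plane centers of min over atoms (|c − x| − r_vdw), as in
HOLE, but re-implemented with a deterministic multi-start pattern search so
repeated runs are bit-identical. Per-frame profiles reduce to per-z mean ±
sd across equidistant simulation frames (e.g. a 12.5 ns stride → 8 frames
of a 100 ns run).

## Worked example

Build a labelled synthetic pocket (a serine donating a hydrogen bond, plus
a one-water bridge), drive the donor on and off with a two-state Markov
chain whose stationary occupancy is 0.25, then fingerprint the trajectory
and recover the planted parameters:

```r
library(channelsift)

scene <- build_pocket_scene(pocket_scene_spec(
  planted = list(
    list(type = "HB_PROT_DONOR", distance = 2.8, angle = 165),
    list(type = "WATER1")
  ),
  n_decoy_residues = 3L, n_waters = 5L, seed = 42
))
scene$truth[, c("label", "chain", "HB_PROT_DONOR", "WATER1")]
#>   label chain HB_PROT_DONOR WATER1
#> 1 SER10     A          TRUE  FALSE
#> 2 SER11     B         FALSE   TRUE
#> 3 GLY51     A         FALSE  FALSE
#> ...

sch <- occupancy_schedule(scene$truth$label[1:2], p01 = c(0.1, 0.3),
                          p10 = c(0.3, 0.3), n_frames = 200, seed = 43)
bt <- build_pocket_trajectory(scene, sch)
fp <- fingerprint_trajectory(
  bt$trajectory, scene$ligand,
  residues = data.frame(chain = scene$truth$chain[1:2],
                        resno = scene$truth$resno[1:2])
)
fp
#> <fingerprint_matrix> 2 residues x 9 bits x 200 frames x 1 subunit(s)

p <- occupancy_probability(fp, "SER10", "HB_PROT_DONOR")
c(p, stability_class(p))
#> "0.245" "rare"
markov_error(bit_series(fp, "SER10", "HB_PROT_DONOR"), seed = 1)
#> <markov_estimate> stationary 0.2491 [0.1492, 0.3728] (95% CI),
#>   counts n00=135 n01=16 n10=16 n11=32
```

The planted chain had p01 = 0.1, p10 = 0.3, i.e. a true stationary
probability of 0.25: the measured occupancy is 0.245 and the 95 % credible
interval [0.149, 0.373] covers the truth.

A synthetic channel with a 2 Å waist (emulating the hydrophobic 9' gate,
which real setron-bound structures constrict below the 2.76 Å hydrated
Na⁺ radius):

```r
pore <- build_pore_structure(function(z) 2.0 + 3.5 * (abs(z) / 15)^2,
                             lining_density = 2, z_range = c(-15, 15))
pore_profile(pore$structure, axis = c(0, 0, 1), anchor = c(0, 0, 0),
             z_range = c(-12, 12),
             roles = residue_role_map(pore_marker_residues = c("9'" = 31L)))
#> <pore_profile> 49 samples, z in [-12.0, 12.0];
#>   minimum radius 2.00 A at z = 0.0 (9')
```

Real inputs enter the same machinery as multi-model PDB trajectories
(`read_structure()`), a JSON ligand-chemistry annotation
(`read_ligand_spec()`), and a JSON residue role map (`read_role_map()`);
`run_fingerprint()` / `run_descriptors()` / `run_pore()` orchestrate whole
runs from a JSON config and write CSV tables plus a reproducibility
manifest. A thin CLI lives at `inst/cli/channelsift.R`.

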