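---
title: "Rigidity- and mode-based flexibility analysis of multidomain proteins"
author: "domainflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigidity- and mode-based flexibility analysis of multidomain proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainflex)
```

## The problem and the model

Large multidomain proteins — the motivating case is protein disulfide
isomerase (PDI), a four-domain folding catalyst whose two redox-active sites
must engage substrates of very different shapes — move on timescales that
put an exhaustive molecular-dynamics treatment out of reach.  `domainflex`
implements the alternative: a *flexibility analysis* that answers "what
motions does the structure's constraint topology permit?" rather than "what
motion occurs in a thermal bath?".  The pipeline has four stages.

1. **Constraint network.**  The all-atom structure is deconstructed into a
   bars-and-bodies network: covalent bonds (rotatable single bonds as 5-bar
   joints, non-rotatable peptide/resonant bonds merging their atoms into one
   body), hydrogen bonds kept when their energy is at most `E_cut` (default
   −2 kcal/mol), and 2-bar hydrophobic tethers between apolar carbon/sulfur
   pairs within the van der Waals sum + 0.25 Å.
2. **Rigid-cluster decomposition.**  A (6,6) body-bar pebble game partitions
   the network into maximal rigid clusters and counts floppy modes.  The
   game realises the (6,6)-sparsity matroid, which for generic body-bar
   frameworks is exactly the rigidity matroid (Tay's theorem); the test
   suite checks this equivalence against a dense constraint-Jacobian
   null-space oracle on random frameworks.
3. **Elastic modes.**  A Cα anisotropic network model (uniform springs,
   10 Å cutoff, unmass-weighted) supplies low-frequency directions of easy
   motion.  Modes 1–6 are the trivial rigid-body motions; m7 is the softest
   internal motion — for PDI-like architectures, the hinge that closes the
   two active sites toward each other.
4. **Geometric simulation (mode following).**  The structure is displaced
   repeatedly along one fixed mode (default 0.01 Å RMS Cα motion per step,
   2000–5000 steps, structure recorded every 100 steps) and after every step
   relaxed back onto the constraints: every rigid cluster's "ghost" template
   (cluster atoms plus their covalently bonded first shell) is refit
   rigidly, atoms move to the averaged fitted positions, and nonbonded pairs
   closer than the van der Waals sum − 0.5 Å are pushed apart.  The result
   is a stereochemically acceptable trajectory of the *possible* motion
   along that mode, not a thermal ensemble.  The production protocol runs
   both directions of the five softest nontrivial modes: 10 trajectories of
   20–50 structures each, optionally replicated over five perturbed starting
   conditions for error bars.

## The motion measures

* **`dcc`** — the Cα–Cα distance between two configured functional residues
  (for yPDI, the active-site cysteines 61 and 406), the principal
  open/closed indicator.
* **`sheet_frame` / `tilt` / `twist`** — each domain's orientation is the
  plane of its core β-sheet: four Cα atoms ("alternating central residues"
  of two adjacent antiparallel strands, in perimeter order) form a
  quadrilateral whose diagonal cross product gives the unit normal and
  whose centroid gives the center.  For a domain pair, *tilt* is
  `acos(n1·n2)` in [0°, 180°]; *twist* is the signed dihedral between the
  planes spanned by (n1, r12) and (n2, r12), with r12 the center-to-center
  vector and the sign by the right-hand rule about r12, in (−180°, 180°].
* **`pseudodihedral_profile`** — with pseudo-bonds `q_i = r_{i+1} − r_i`
  along the Cα trace, `ξ_i` is the angle between the projections of
  `q_{i−1}` and `q_{i+1}` onto the plane normal to `q_i`.  The first
  pseudo-bond is *not* negated, so ξ equals 180° minus the conventional Cα
  virtual torsion: cos ξ ≈ 1 for an extended chain and ≈ −0.7 for an
  α-helix.  (The conventional torsion would give ≈ +0.64 for helices and is
  therefore the wrong convention for reproducing those signatures.)  ξ is
  undefined at the first and the last two residues.  The per-residue
  flexibility measure is the RMS deviation of cos ξ_i across all conformers,
  pooled over modes m7–m10.
* **`domain_rmsd`** — Cα RMSD of each domain to its starting structure
  after optimal (Kabsch) superposition, so rigid domain motion contributes
  zero and the value isolates internal distortion.
* **`sheet_angle_stats`** — mean ± SD of angles at configured residue
  triples; their constancy (SD of 2–3° in flexibility runs) verifies that
  the core sheets ride through the motion as rigid units.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `e_cut` | −2 | kcal/mol | hydrogen-bond retention threshold; more negative → fewer constraints, more flexibility |
| ANM `cutoff` | 10 | Å | Cα spring range |
| `n_steps` | 5000 | steps | length of each mode-following run (production range 2000–5000) |
| `save_every` | 100 | steps | recording interval (so 50 saved conformers + start) |
| `step_size` | 0.01 | Å | RMS Cα bias per step; 5000 steps ≈ tens of Å of cumulative domain motion |
| `clash_tol` | 0.5 | Å | subtracted from vdW sums for pairs ≥ 4 bonds apart |
| `template_tol` | 0.1 | Å | rigid-template convergence tolerance |
| `n_starts` | 5 | — | perturbed starting conditions (RMS amplitude 0.2 Å) |

The hydrogen-bond energy is the simplified Mayo form
`E = 8 [5 (2.8/R)^12 − 6 (2.8/R)^10] cos²θ` (R the donor–acceptor distance,
θ the donor–H–acceptor angle, hydrogens placed ideally from heavy atoms when
absent).  Only the −2 kcal/mol threshold is anchored by the protocol this
package reimplements; the functional form, the hydrophobic-tether radii and
the clash/template tolerances are declared engineering defaults, configurable
and reported in every run manifest.

## Design choices made where the design was open

* **Step-size normalisation.**  "Å of Cα displacement per step" is realised
  by scaling the all-atom extension of the mode to unit RMS over Cα sites.
  Normalising the 3N vector to unit Euclidean norm instead would make the
  per-atom step shrink like 1/√N and a 5000-step run could never produce
  the tens-of-Å excursions in the active-site distance that the method is
  known to generate.
* **Mode sign.**  m7's sign is chosen so that "+" motion decreases the
  configured active-site distance (closing); other modes take the
  largest-magnitude-component-positive convention.  Along a trajectory,
  sheet normals keep temporal sign continuity (flip when the dot product
  with the previous frame is negative).
* **Twist symmetry.**  The twist construction is symmetric under exchanging
  the two *frames*: swapping them also reverses r12 and the two sign flips
  cancel, exactly as a conventional torsion is invariant under chain
  reversal.  The antisymmetry one intuitively expects holds when the two
  *normals* are exchanged about the fixed interplane axis, and that is the
  property the test suite asserts.  Reported twists are therefore tied to
  the configured domain-pair order (a–b, b–b′, …).
* **Rigidity model granularity.**  Bodies are heavy atoms merged across
  non-rotatable bonds (peptide C–N, carbonyl, carboxylate/amide, aromatic
  rings, guanidinium).  Bar multiplicities: rotatable covalent 5, locked 6
  (within-body), hydrogen bond 5, hydrophobic tether 2.  Terminal
  single-bonded heavy atoms contribute a spurious spin degree of freedom to
  the floppy count, a known and documented coarseness of the atoms-as-bodies
  model.
* **Relaxation scheme.**  Ghost templates overlap by one covalent shell, so
  bond lengths and angles at cluster boundaries are maintained by the
  averaging step without explicit bond constraints; torsions between
  clusters stay free, which is precisely the motion the method wants to
  allow.  Relaxation converges when the worst template deviation is below
  `template_tol` and no clash exceeds half of it; non-convergence after 200
  iterations truncates the trajectory and is recorded in the run manifest
  rather than silently ignored.
* **Degenerate geometries.**  A strictly planar Cα arrangement makes the
  pairwise-spring ANM singular (every out-of-plane displacement is
  zero-energy to first order), so `compute_modes()` rejects inputs with
  more than six near-zero eigenvalues instead of mislabelling them; the
  sheet generator applies a ±0.4 Å β-pleat, which both mimics real sheets
  and keeps fixtures non-degenerate.  The measurement quadrilateral uses
  alternating residues, which share a pleat sign, so the ground-truth
  normal stays exact.
* **Zero-mode tolerance.**  Trivial modes are those with eigenvalue below
  10⁻⁶ times the 7th-smallest; disconnection is diagnosed first against
  10⁻⁹ times the largest eigenvalue.

## What the synthetic fixtures emulate — and what they do not

`make_helix()` and `make_peptide_chain()` produce ideal helical/extended
geometry (the latter with exact ideal internal coordinates via the NeRF
construction, giving textbook i→i+4 hydrogen bonds for α-helical torsions).
`make_sheet()` produces planar antiparallel Cα sheets with a recorded
ground-truth normal.  `make_hinge_toy()` joins two rigid sheet domains by a
4-residue diagonal linker and applies a prescribed hinge schedule as an
exact rigid-body motion, so tilt/twist/d_cc series are known in closed form;
the toy's ANM m7 overlaps the prescribed hinge field by > 0.9.  The linker
runs diagonally between the chain ends because a collinear linker would
leave an exactly free torsion of one domain about the linker line — a real
property of distance-spring networks, not a bug, but not the motion the toy
is meant to prescribe.  The toy also ships cross-strand Cα constraints
(stand-ins for interstrand hydrogen bonds, which the minimal N/C/O backbone
reconstruction cannot realise geometrically) so the pebble game resolves
each domain as one rigid cluster.

Green tests on these fixtures establish that the machinery — network
construction, rigidity counting, mode computation, constraint-preserving
mode following, and every measure — is internally consistent and recovers
known ground truth.  They do *not* establish biological realism: fixtures
have no side chains, no realistic packing, and hydrogen-bond geometry only
where built by torsions.  Results on a real protein depend on the supplied
structure and on a user-supplied domain configuration: the β-sheet
quadrilaterals must be chosen by the stated rule (alternating central
residues of the two central antiparallel strands of each domain's sheet,
perimeter order), because such selections are inherently
structure-specific.

## Known limitations

* The rigidity model is coarser than a full bond-bending network analysis;
  cluster boundaries on a real protein will not match a reference
  implementation atom-for-atom (deliberately out of scope).
* Mode following explores one fixed direction per run; it reports the
  *reach* of easy motion, not free-energy differences, and trajectories
  that stall against steric contacts are flagged (`asymptote`) rather than
  escaped by randomisation.
* The measures layer ingests any multi-model PDB, but chain breaks and
  missing Cα atoms in configured residues are errors by design, not
  repaired.
* Whole-protein validation against the published yPDI numbers (starting
  d_cc of 27 Å, m7 excursions between 15 and 80 Å, sheet-angle SDs ≤ 3°)
  requires the 2B5E coordinate file, which cannot be redistributed inside
  the package; `inst/extdata/config-ypdi.json` carries the corresponding
  configuration skeleton so the run is one `run_pipeline()` call once the
  file is supplied.

## A compact worked run

```{r toy, eval = FALSE}
toy <- make_hinge_toy()                      # two rigid domains + hinge
res <- run_pipeline(
  toy$structure, toy$config,
  sim_config  = simulation_config(n_starts = 1),
  extra_hbonds = toy$extra_constraints)
res$summary[res$summary$mode == "m7",
            c("mode", "direction", "dcc_start", "dcc_min", "dcc_max")]
```

Every number the package reports — including the summary above and the
acceptance quantities in `scripts/acceptance.R` — is computed at run time by
this pipeline; nothing is looked up.
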