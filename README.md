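# domainflex

Rigidity- and elastic-mode-based flexibility analysis of multidomain
proteins in R.

Large multidomain proteins — the motivating system is protein disulfide
isomerase (PDI), whose four thioredoxin-fold domains (**a**–**b**–**b′**–**x**–**a′**–**c**)
must rearrange to engage substrates of very different sizes — move too
slowly and over too large a scale for routine all-atom molecular dynamics.
`domainflex` implements the fast constraint-based alternative: decompose
the structure into a rigidity network, find its soft elastic modes, and
generate stereochemically valid conformer trajectories by following those
modes while re-enforcing the constraints after every step.  A measures
layer quantifies the resulting inter- and intradomain motion.

## Method in brief

* **Constraint network**: covalent bonds (rotatable single bonds as 5-bar
  joints; peptide/resonant bonds lock their atoms into one body), Mayo-type
  hydrogen bonds kept at energy ≤ *E*<sub>cut</sub> (default −2 kcal/mol),
  hydrophobic tethers (2 bars) between close apolar pairs.
* **Rigid clusters**: (6,6) body-bar pebble game; floppy-mode counts are
  test-verified against a dense constraint-Jacobian null-space oracle.
* **Elastic modes**: Cα anisotropic network model (uniform springs, 10 Å
  cutoff); modes m1–m6 are trivial, m7 is the softest internal motion.
* **Mode following** (geometric simulation): 2000–5000 biased steps of
  0.01 Å RMS Cα displacement along a fixed mode, each followed by iterative
  rigid-template refitting and steric projection; structures recorded every
  100 steps; one trajectory per direction for modes m7–m11 (10 total),
  optionally over 5 perturbed starts.
* **Measures**: active-site Cα distance *d*<sub>cc</sub>; per-domain-pair
  β-sheet plane **tilt** θ = acos(n̂₁·n̂₂) and signed dihedral **twist** δ
  about the interplane axis; per-residue pseudodihedral flexibility (RMS of
  cos ξ across conformers, where cos ξ ≈ 1 for extended chain and ≈ −0.7
  for α-helix); Kabsch-superposed per-domain Cα-RMSD; sheet-angle
  statistics.

## Worked example

The bundled synthetic generator builds a two-domain "book hinge" toy —
two rigid β-sheet domains joined by a 4-residue linker — whose softest
elastic mode is the hinge that closes the two marker sites:

```r
library(domainflex)

toy <- make_hinge_toy()
res <- run_pipeline(toy$structure, toy$config,
                    sim_config   = simulation_config(n_starts = 1, seed = 1),
                    extra_hbonds = toy$extra_constraints)

res$summary[res$summary$mode %in% c("m7", "m8"),
            c("mode", "direction", "n_conformers",
              "dcc_start", "dcc_min", "dcc_max")]
#>  mode direction n_conformers dcc_start  dcc_min  dcc_max
#>    m7         1           51      25.6 10.53569 25.60000
#>    m7        -1           51      25.6 15.04195 26.21770
#>    m8         1           51      25.6 25.60000 30.10356
#>    m8        -1           51      25.6 25.60000 28.94314
```

Reading the table: each trajectory records 51 structures (step 0 plus every
100th of 5000 steps).  Along the softest mode m7 the inter-site distance
*d*<sub>cc</sub> closes from 25.6 Å down to 10.5 Å — the hinge motion — while
m8 explores opening instead; this is the toy analogue of the active-site
closure analysis for a real multidomain protein.  The constraint network and
rigidity decomposition behind the run:

```r
res$network
#> ConstraintNetwork: 136 atoms, 69 bodies; bars: 165 covalent (67 locked),
#>   20 hbond (E_cut = -2), 0 hydrophobic
res$decomposition
#> RigidClusterDecomposition: 11 clusters over 69 bodies; largest 57 atoms;
#>   floppy modes 16 (internal 10)
```

The pseudodihedral convention check on an ideal α-helix fixture:

```r
mean(cos_xi(make_helix(12)), na.rm = TRUE)
#> [1] -0.6422
```

For a real protein, supply a PDB file plus a JSON configuration naming
domain intervals, the four β-sheet quadrilateral residues per domain
(alternating central residues of the two central antiparallel strands, in
perimeter order), sheet-angle triples and the active-site pair;
`inst/extdata/config-ypdi.json` is a skeleton for yeast PDI (2B5E, active
sites Cys61/Cys406).  Then:

```r
res <- run_pipeline("2b5e.pdb", "config.json", out_dir = "run1")
```

which writes one multi-model PDB and one measures CSV per trajectory, the
pooled flexibility profile, a per-mode summary and a JSON run manifest.
A command-line front end is available via
`Rscript -e 'domainflex::domainflex_cli()' simulate --pdb ... --config ...`.

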