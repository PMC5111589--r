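{
  "_comment": [
    "Domain configuration for yeast protein disulfide isomerase (PDB 2B5E,",
    "full-length author numbering). Residue intervals are approximate domain",
    "assignments for the a-b-b'-x-a'-c architecture; the active-site",
    "cysteines are Cys61 (domain a) and Cys406 (domain a').",
    "sheet_quad entries must be supplied by the user before tilt/twist",
    "analysis: pick four C-alpha atoms as alternating central residues of",
    "the two adjacent antiparallel strands (strands beta2 and beta4 of each",
    "thioredoxin fold), listed in perimeter order p1,p2 (along strand 1)",
    "then p3,p4 (back along strand 2). The same applies to angle_triples",
    "used for the sheet-geometry statistics."
  ],
  "domains": [
    {"name": "a",  "intervals": [[1, 120]],   "active_site": [61, 64]},
    {"name": "b",  "intervals": [[121, 231]]},
    {"name": "bp", "intervals": [[232, 350]]},
    {"name": "x",  "intervals": [[351, 367]]},
    {"name": "ap", "intervals": [[368, 485]], "active_site": [406, 409]},
    {"name": "c",  "intervals": [[486, 522]]}
  ],
  "dcc_residues": [61, 406]
}
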