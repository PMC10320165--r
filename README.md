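# tcrpmhc

Scaffolding for T cell receptor (TCR) – peptide–MHC (pMHC) complex structure
prediction, with the deep-learning folding engine abstracted behind a
pluggable predictor interface. The package implements, in testable desk-scale
form, everything a TCR–pMHC modeling server does *around* the neural network:

- **pMHC template curation and selection** — resolution (≤ 3.5 Å) and
  release-date filtering, Class II peptide trimming to the 9-mer binding core
  plus one flank per terminus (≤ 11-mers), an at-most-two cap on identical
  pMHC sequences, BLOSUM62 similarity ranking (MHC score first, then peptide
  score with a flat −100 gap penalty so peptide alignments are ungapped), and
  peptide+MHC chain merging with a residue-index shift at the chain break.
- **TCR template search** — single-sequence (never MSA-profile) global
  alignment against a chain database, ranked by percent identity.
- **Confidence scoring** from predictor outputs (per-residue pLDDT and the
  N×N predicted-aligned-error matrix): pTM, ipTM, the TCR–pMHC *group* ipTM
  restricted to the docking interface, per-CDR3 mean pLDDT, and the ranking
  score

  &nbsp;&nbsp;&nbsp;&nbsp;model confidence = 0.2 · pTM + 0.8 · ipTM,

  classified against the operating points ≥ 0.85 (likely accurate) and
  ≤ 0.49 (likely inaccurate).
- **Docking assessment** — Fnat, interface RMSD (I-RMSD), ligand RMSD
  (L-RMSD), DockQ = mean(Fnat, 1/(1+(I-RMSD/1.5)²), 1/(1+(L-RMSD/8.5)²)),
  CAPRI accuracy tiers for protein–protein and protein–peptide interfaces
  (to flag displaced peptides), and unbound-TCR CDR loop RMSD after
  framework superposition.
- **Benchmark assembly** — date / resolution / modified-peptide filters and
  greedy redundancy removal at ≥ 95% single-chain or ≥ 92% V-domain
  sequence identity within an MHC class, plus ROC AUC (Medium/High vs
  Incorrect) and Pearson confidence-vs-DockQ statistics.
- **An end-to-end pipeline** — V-domain extraction, VDJdb-style gene+CDR3
  sequence assembly, feature bundling, a deterministic mock predictor, model
  ranking and postprocessing (chain renaming, renumbering hook, alignment of
  all models to the top-ranked one by the pMHC chains).
- **Synthetic fixtures** — idealized toy complexes with analytically known
  metric values, controlled PAE profiles, toy gene tables and template
  libraries; every generator is a pure function of its seed.

## Worked example

```r
library(tcrpmhc)

# a VDJdb-style query: germline genes plus CDR3s, against a toy gene table
tab   <- make_toy_gene_table(1)
query <- preprocess_query(list(
  va = "TRAV-T1", ja = "TRAJ-T1", cdr3a = "CAGQLNAGNMLTF",
  vb = "TRBV-T1", jb = "TRBJ-T1", cdr3b = "CASAPLVGAPEAKNIQYF",
  peptide = "SPRWYFYYL", mhc_genes = "MHC-T1", mhc_class = "I"),
  table = tab)

result <- run_job(query, mock_predictor(), n_models = 3, seed = 7)
result
#> JobResult: 3 model(s), predictor 'mock'
#>   rank 1  model_1  confidence 0.881
#>   rank 2  model_2  confidence 0.715
#>   rank 3  model_3  confidence 0.561
```

Models are ranked by model confidence; `model_1` (0.881 ≥ 0.85) would be
flagged likely accurate, the others indeterminate. `write_job_result(result,
"outdir")` emits ranked PDB files, a `confidence.tsv` report and a
`manifest.json`; reruns with the same seed are byte-identical.

Assessing a model against a native structure:

```r
toy <- make_toy_complex(fixture_spec(seed = 3,
         perturbation = list(type = "ligand_shift", shift = 2)))
assess_docking(toy$native, toy$model, toy$receptor_chains, toy$ligand_chains)
#> DockingAssessment: Acceptable (Fnat 0.159, I-RMSD 0.98 A, L-RMSD 2.00 A, DockQ 0.603)
```

The 2 Å uniform shift of the TCR reads back exactly as L-RMSD = 2.0, and the
tier follows the configured CAPRI table.

A command-line wrapper with subcommands `run`, `score`, `assess`,
`build-templates` and `fixtures` ships at
`system.file("cli", "tcrmodel.R", package = "tcrpmhc")`.

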