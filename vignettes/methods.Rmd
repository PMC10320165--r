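---
title: "Methods: template curation, confidence scoring and docking assessment for TCR-pMHC modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template curation, confidence scoring and docking assessment for TCR-pMHC modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrpmhc)
```

## Scope and design

Accurate structure prediction of T cell receptor (TCR) recognition of
peptide–MHC (pMHC) targets rests on a deep-learning folding engine, but the
engine is only one stage of a working modeling pipeline. Everything around
it — how pMHC templates are curated and chosen, how sequences are reduced to
variable domains, how the predictor's error estimates are turned into
ranking and accept/reject decisions, and how finished models are judged
against experimental structures — is ordinary, deterministic computation
that deserves unit-level testing. This package implements exactly that
scaffolding, with the folding engine abstracted behind a predictor
interface: any function `(features, n_models, seed) -> predictions`
satisfies the contract, and the shipped reference implementation is a
deterministic mock so that every downstream stage can be exercised at desk
scale. The mock is a first-class simulation component, not a stand-in one
hopes to replace: its purpose is controlled inputs with known structure.

The package follows base-R conventions with light S3 classes
(`StructureModel`, `TemplateLibrary`, `PredictionOutput`,
`ConfidenceSummary`, `DockingAssessment`, `JobResult`), in the style of
structural-bioinformatics packages such as bio3d, which also supplies the
PDB/mmCIF parsing underneath the I/O layer.

## The atomic model and superposition

A `StructureModel` is an ordered atom table (chain, author residue number,
residue name, atom name, coordinates) plus optional resolution, release
date and source identifier. Author numbering is preserved verbatim —
template curation and model renumbering both need it — while per-chain
sequential order is recovered on demand. Water is skipped at parse time;
non-water heteroatom residues (selenomethionine in particular) are kept and
map to `M`/`X` in extracted sequences. When alternate conformers are
present only the highest-occupancy one is retained, ties resolved by file
order, so a file parses to exactly one deterministic model.

Rigid-body superposition is the closed-form least-squares (Kabsch)
solution: SVD of the 3×3 cross-covariance of the centered point sets with a
reflection correction forcing a proper rotation (det = +1). At least three
non-collinear pairs are required; degenerate sets raise an error rather
than returning an arbitrary member of the solution family. The test suite
cross-checks the optimum against two independent routes — Horn's quaternion
eigenvalue closed form, and a brute-force random-restart search over Euler
angles — the former to 1e-6 Å, the latter to 1e-3 Å.

Backbone RMSD throughout the package means the N, CA, C, O atom set, the
DockQ convention.

## Template curation and selection

The pMHC template library applies, in order: a resolution cutoff
(default 3.5 Å, inclusive), an optional release-date cutoff (used to build
leakage-free benchmarks), Class II peptide trimming, a redundancy cap, and
chain merging.

**Class II trimming.** Class II binding grooves are open at both ends, so
template peptides are reduced to their 9-mer binding core plus one flanking
residue on each side where a flank exists — at most 11 residues, never
fabricating sequence. The core position is an annotation on the input
(in production it comes from an external core predictor; here it is a
pluggable `peptide -> core_start` function or an explicit offset, and the
library builder defaults to the centered window when unannotated). The
trimming operation is pure string arithmetic and is also applied to query
peptides longer than 11 residues at preprocessing time.

**Redundancy cap.** Peptides adopt heterogeneous conformations, so identical
(peptide, MHC) sequence pairs are retained up to twice. The two
best-resolution copies are kept, ties broken by source identifier — the
curation source states only "up to two", so the best-resolution criterion
is this package's choice, made once for determinism.

**Similarity ranking.** Candidate templates are first restricted to the
query's MHC class and to peptides of exactly the query peptide length, then
ordered by MHC similarity score (descending), peptide similarity score
(descending), and source id (ascending). Scores are BLOSUM62 global
alignment scores. Peptide scoring uses a flat gap penalty of −100, which
makes any gap strictly worse than an all-mismatch ungapped alignment for
peptide-length sequences; equal-length peptide scores therefore reduce to a
position-wise matrix sum, and the test suite verifies this against a direct
sum oracle on 1,000 seeded pairs. MHC scoring uses the matrix's standard
affine companions (open −11, extend −1); the −100 penalty is specified only
for peptides. The BLOSUM62 values are loaded from Biostrings' shipped copy
of the published matrix rather than re-embedded — Biostrings is already a
hard dependency and duplicating data invites drift.

Two points the curation rules leave open were decided once: Class II
template selection length-matches on the *trimmed* peptides (after
truncation both query and templates are ≤ 11-mers, so matching remains
meaningful and the Class I code path is reused unchanged), and the TCR
template search runs against a caller-supplied chain-sequence table rather
than a bundled PDB snapshot (the package ships no external data). The TCR
search deliberately aligns the single query sequence — never an MSA
profile — and ranks by identity computed as matches over the full global
alignment length, gap columns included in the denominator.

**Chain merging.** The folding engine consumes a pMHC template as one
chain; the chain break is encoded as a residue-index shift (default 200,
the ColabFold convention; a configurable minimum of 32 keeps the break
unmistakable for a loop deletion). The merge places MHC first by default
(configurable), inserts the offset at every chain boundary — including the
Class II α/β boundary, where a physical chain break equally exists — and
touches no coordinates; a recorded segment table makes the split an exact
inverse.

**Focused databases.** The genetic-search stage of the engine is pointed at
small FASTA databases assembled by unioning hit sets from searches seeded
with representative TCR and MHC sequences, deduplicated by record id (first
occurrence kept). Running the homology searches themselves is out of scope;
hit sets are inputs.

## Confidence scores

All scores derive from the predictor's N×N predicted aligned error matrix
(PAE; entry *(i, j)* is the expected positional error of residue *j* when
the model is aligned on residue *i*) and per-residue pLDDT.

The predicted TM-score estimator is

$$\mathrm{pTM} = \max_i \; \frac{1}{|J_i|}\sum_{j \in J_i}
  \frac{1}{1 + (\mathrm{PAE}_{ij}/d_0(N))^2},\qquad
  d_0(N) = \max\{1.24\,(N-15)^{1/3} - 1.8,\; 1\},$$

with $N$ the number of residues participating in scored pairs. The
constants are the published TM-score normalisation; the upstream estimator
the scores mirror does not restate them, so they are pinned here and
documented. Restricting the scored pair set $J_i$ yields the interface
variants: ipTM admits only pairs whose chains differ, and the TCR–pMHC
group ipTM only pairs whose partner assignment (TCR vs pMHC) differs —
equivalent to relabeling the complex into two super-chains and recomputing
ipTM, which is how the score isolates the docking interface from the
peptide–MHC and TCRα–TCRβ interfaces that default ipTM mixes in. For the
restricted variants $N$ counts the residues participating in scored pairs,
mirroring the upstream multimer implementation. One version-specific
ambiguity (whether upstream masks pairs beyond the same-chain exclusion) is
resolved by pinning the definition above; the oracle tests enforce exactly
it.

The ranking score is the fixed combination
$\mathrm{confidence} = 0.2\,\mathrm{pTM} + 0.8\,\mathrm{ipTM}$, and models
classify against two inclusive operating points: ≥ 0.85 likely accurate,
≤ 0.49 likely inaccurate, between them indeterminate. Both bounds are
stored in a `ConfidenceCutoffs` object and are user-adjustable; the
defaults are the published values, printed with inclusive comparisons, and
the boundary semantics are tested by bisection. Per-CDR3 mean pLDDT is
reported so users can inspect loop-level reliability separately from global
scores — CDR3 conformation is the hardest part of the problem and a global
confidence can hide a poor loop.

## Docking assessment

Model accuracy against a native structure uses the standard docking
metrics: Fnat (fraction of native cross-interface residue contacts, heavy
atoms within 5 Å, reproduced by the model), I-RMSD (backbone RMSD over
native interface residues — any heavy atom within 10 Å of the partner —
after superposition on those same atoms), and L-RMSD (ligand backbone RMSD
after superposition on the receptor backbone). Both cutoffs are the DockQ
conventions and are configurable. DockQ itself is the published formula
$\tfrac13[\mathrm{Fnat} + (1+(\mathrm{iRMSD}/1.5)^2)^{-1} +
(1+(\mathrm{LRMSD}/8.5)^2)^{-1}]$.

CAPRI accuracy tiers (High / Medium / Acceptable / Incorrect) are evaluated
from threshold tables shipped as a versioned JSON config rather than
hard-coded, because the method delegates to the CAPRI literature without
restating the tables. Complex-level assessment takes the pMHC as receptor
and the TCR as ligand; peptide–MHC assessment takes the MHC as receptor and
the peptide as ligand and classifies with the stricter protein–peptide
tiers, whose Incorrect class is the operational flag for partially or fully
displaced peptides.

Unbound-TCR accuracy is per-loop: one superposition on the pooled framework
backbone of both chains, then per-CDR backbone RMSD with no re-fitting.
Loop and framework definitions are caller-supplied position tables (the
shipped fixtures carry their own); overlapping loop/framework definitions
are rejected.

**Benchmark assembly.** Candidate cases pass four filters: released after
the cutoff date, resolution ≤ 3.25 Å, no chemically modified peptide, and
no redundancy — against the pre-cutoff reference set and, greedily in
source-id order, against already-accepted cases. Two same-class complexes
are redundant when either single-chain V identity reaches 0.95 or the
concatenated α+β V-domain identity reaches 0.92. Concatenation (rather than
per-chain averaging) is this package's reading of "V domain sequence
identity", chosen and documented once; the greedy source-id order makes the
kept set reproducible where the criteria leave tie order unstated.
Discrimination statistics follow the published framing: rank-based ROC AUC
for Medium-or-High versus Incorrect (Acceptable excluded, ties one half)
and Pearson correlation of confidence against DockQ.

## Pipeline and postprocessing

Query preprocessing reduces full-length TCR chains to variable domains. The
contract prefers an external immunoglobulin numbering tool when supplied;
the internal fallback anchors on the conserved CDR3 cysteine and the
F/W-G-X-G motif that closes the J segment, keeping ten residues past the
anchor — enough for the J tail, excluding any constant-region sequence.
Gene mode assembles a V domain from a germline V gene (everything before
its conserved Cys), a user CDR3 (in full, anchor-checked: starts with C,
ends with F/W), and a J gene (everything after the F/W of its motif),
which makes repertoire-database records (genes + CDR3) modelable without
hand-built sequences. Class II query peptides longer than 11 residues are
trimmed around a core supplied by a pluggable predictor contract or an
explicit offset; Class I peptides pass through untouched.

`run_job` bundles features (ranked pMHC templates, per-chain TCR templates,
focused databases), invokes the predictor, scores and ranks the models, and
postprocesses: chains are renamed from the predictor-contract letters
(MHC A/B, peptide C, TCR α D, TCR β E — a configurable map, since the
target naming scheme is conventional rather than specified), an optional
renumbering contract is applied per model with failures degrading to
warnings, and models 2..n are rigidly superposed onto the top-ranked model
by the pMHC backbone (whole-TCR backbone in unbound mode). Alignment is
rigid, so intra-model geometry is bitwise-preserved up to rotation;
the manifest records seeds, template ids and parameters, and serialized
output contains no timestamps, making reruns byte-identical.

The mock predictor builds an idealized complex from the query sequences,
adds seeded per-model coordinate noise, and fabricates pLDDT and
block-structured PAE whose inter-chain level grows with model index — so
ranking, classification and alignment all have non-trivial, fully
deterministic work to do.

## Synthetic fixtures and what they show

`make_toy_complex` constructs an idealized four-chain complex: an MHC
proxy of two α-helices (1.5 Å rise, 100° twist, 2.3 Å radius) flanking a
9-mer peptide strand, with two TCR mini-domains docked above the peptide
within contact range. Defaults are a 40-residue MHC proxy, 9-mer peptide
and 16-residue TCR domains. Perturbation families have closed-form
expected metrics: `none` and `rigid` give Fnat 1 and all RMSDs 0; a
uniform ligand shift of *d* gives L-RMSD exactly *d* (and Fnat 0 once the
interface is fully broken); a loop shift of *d* gives that loop's CDR RMSD
exactly *d* and 0 elsewhere. The central integration test checks these
annotations against the assessment module to 1e-6 across seeded specs.

These fixtures emulate chain topology, interface contacts and numbering —
not real TCR–pMHC geometry, sequence statistics, peptide register or
energetics. Passing tests therefore demonstrate that the bookkeeping and
mathematics are right (metrics, rankings, filters, round trips), not that
models of real complexes will be accurate; accuracy claims require the real
folding engine and experimental structures, both outside this package's
scope by design.

## Numerical choices and problem sizes

- Tolerances: pTM-family oracle agreement 1e-12 (pure arithmetic);
  docking-metric oracle agreement 1e-6 (one superposition involved);
  rotation-search comparison 1e-3 (stochastic search).
- Tie-breaks are lexicographic everywhere a ranking could tie (template
  source ids, model names, benchmark order), so every ordering is
  reproducible.
- Degenerate inputs fail loudly: empty structures, chains longer than the
  PDB format allows, fewer than three or collinear superposition pairs,
  zero-contact natives (Fnat undefined), single-class label sets (AUC
  undefined), empty CDR3 loop ranges.
- Test problem sizes: oracle sweeps use 50 PAE matrices of 10–40 residues
  and 100 toy complexes of 49 residues (24-residue MHC proxy, 10-residue
  TCR domains); monotonicity uses 1,000 single-entry PAE bumps and a 20³
  DockQ grid. These sizes exercise every code path with the naive O(n²)
  oracles while keeping the default suite fast.
- The d0 clamp: for fewer than 27 scored residues the TM normalisation
  falls below 1 and is clamped to 1, so small-interface scores remain
  bounded and the "all entries equal d0 gives 0.5" identity holds at every
  size.

## Known limitations

- The Aho renumbering and Class II core prediction contracts ship without
  external-tool adapters; the internal V-domain fallback is anchor-based
  and will reject sequences whose CDR3 anchors are noncanonical.
- The relaxation hook is a no-op by design.
- Template featurization stops at merged single-chain structures plus
  ranked metadata; engine-specific tensor encoding belongs to the predictor
  behind the interface.
- Nucleic acids, small molecules and MHC-like presenters (CD1/MR1) are out
  of scope.
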