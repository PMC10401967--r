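---
title: "Geometric criteria for the active kinase conformation and assessment of predicted models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric criteria for the active kinase conformation and assessment of predicted models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinactive)
```

## The problem

A typical protein kinase domain is only catalytically competent in a
narrow conformational state: the ATP site, the magnesium-chelating DFG
aspartate, the beta3-lysine/C-helix-glutamate pair and the substrate
groove formed by the activation loop must all be arranged simultaneously.
Crystal structures and predicted models alike sample many inactive
states, so an automatic, geometric definition of "active" is needed both
to curate experimental structures and to select predicted models.

`kinactive` implements a five-criterion definition of the active state of
a kinase chain, measures the supporting observables, ranks predicted
models by the per-residue confidence (pLDDT) of the activation loop, and
computes activation-loop backbone RMSD between a model and a reference
after superposing the C-terminal domains. A synthetic-fixture generator
produces kinase-like coordinate sets with exactly prescribed geometry so
that every computation is testable offline.

## The five criteria

For an annotated chain, `classify()` renders `active = "true"` iff all of
the following hold (any unevaluable criterion gives `"unevaluable"`,
never `"false"`):

1. **DFGin spatial state.** The DFG-Phe ring tip (Cζ, or a documented
   surrogate atom for non-Phe residues at this position) lies within
   11 Å of the Glu4 Cα (the residue four after the C-helix Glu) and at
   least 11 Å from the beta3-Lys Cα. The reverse pattern is `DFGout`;
   anything else `DFGinter`.
2. **BLAminus dihedral state.** The residue before the DFG motif, the
   DFG-Asp and the DFG-Phe occupy the Ramachandran regions B (beta),
   L (left-handed) and A (alpha) respectively, and the Phe χ1 rotamer is
   gauche-minus (≈ −60°).
3. **Salt bridge.** The minimum Lys-Nζ to Glu-Oε1/Oε2 distance is
   < 3.6 Å. Skipped for the WNK kinases (no beta3 Lys) and MAP3K12/13
   (Asp in place of the C-helix Glu); the skip list is a packaged,
   user-extensible registry (`family_exceptions.tsv`).
4. **ActLoopNT.** The sixth activation-loop residue (DFGxxX) forms a
   backbone hydrogen bond with the residue immediately preceding the HRD
   motif: the minimum of the N–O and O–N distances is < 3.6 Å. This is
   the beta6/beta9 bridge that extends the loop away from the ATP site.
5. **ActLoopCT.** The Cα of the ninth residue from the activation-loop
   end (XxxxxxAPE) contacts the HRD-Arg backbone carbonyl oxygen:
   < 6 Å for Ser/Thr kinase families, < 8 Å for TYR kinases (tyrosine
   kinases hold the P+1 loop further from the catalytic loop). Skipped
   for HASPIN, TP53RK and PKDCC, which lack an APE motif.

All "in" comparisons are strict (`<`); a value exactly at a cutoff is
"out". The spatial rule uses inclusive bounds at 11 Å, and the doubly
degenerate point (both distances exactly 11 Å) is deterministically
`DFGinter`. The three regulatory-spine distances (HRD-His/DFG-Phe,
DFG-Phe/Glu4, Glu4/HPN7 minimum side-chain heavy-atom distances, intact
when all < 5 Å) are measured and reported but never gate the verdict:
nearly all structures passing the five criteria have an intact spine
anyway, and the exceptions trace to C-helix distortions that do not
touch the ATP or substrate sites.

```{r}
fx <- make_kinase_fixture()        # synthetic active-geometry article
classify(fx$chain, fx$annotation)
```

## Anchor annotation

Every criterion is phrased in terms of anchor residues (beta3 Lys,
C-helix Glu, HPN His, HRD, DFG, APE) and offsets from them. Offsets are
counted in residues of the protein sequence, never in author numbers, so
insertion codes and numbering idiosyncrasies cannot corrupt the derived
positions (DFG6 = DFG-Asp + 5, APE9 = APE-Glu − 8, Glu4 = C-helix
Glu + 4, HPN7 = HPN-His + 6, XHRD = HRD-His − 1). When author numbering
jumps inside a walk — residues missing from the coordinates — the derived
position is treated as unresolvable and the dependent criterion becomes
unevaluable; disorder is never scored as inactive.

Anchors come from an explicit JSON/TSV config
(`read_annotation_config()`), optionally completed by a degenerate
ordered pattern search (`annotate_by_anchor_search()`: H[RK]D / [HYLF]RD,
D[FLYWMV]G, [ASP]PE, HRD before DFG before APE, with the DFG→APE span
constrained to 15–45 residues). Ambiguity is an error, not a guess.
Anchor residue types are validated against expected motifs with a
warning, not an error, since variants are real (AKT1 has YRD for HRD).

The activation-loop span runs from the DFG-Asp through the APE-Glu
*inclusive* (a config switch can exclude the endpoints); kinases without
an APE motif must state the loop end explicitly.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `dfg_anchor_cutoff` | 11.0 | Å | DFGin/DFGout two-anchor rule |
| `saltbridge_cutoff` | 3.6 | Å | Lys-Nζ/Glu-Oε contact |
| `actloop_nt_cutoff` | 3.6 | Å | DFG6/XHRD backbone H-bond |
| `actloop_ct_cutoff_nontyr` | 6.0 | Å | APE9-Cα/HRD-Arg-O, Ser/Thr kinases |
| `actloop_ct_cutoff_tyr` | 8.0 | Å | same contact, TYR kinases |
| `spine_cutoff` | 5.0 | Å | intact regulatory spine (reported only) |

The packaged `default_cutoffs.json` mirrors these numbers exactly and a
user JSON can override any subset. Ramachandran regions are a
rectangular partition of the (φ, ψ) torus chosen to capture the beta,
alpha and left-handed basins while remaining total and overridable
(`region_config.json`): B is φ ∈ [−180, 0) with ψ ≥ 50 or ψ < −120; A is
φ ∈ [−180, 0) with ψ ∈ [−120, 50); L is φ ∈ [0, 180] with
ψ ∈ [−50, 100); everything else is E. Conformations outside {A, B, L}
can never be BLAminus, which is what the active verdict needs; users
replicating a specific published labelling scheme for inactive-state
sublabels should substitute that scheme's boundaries. χ1 wells use the
standard staggered edges (−120/0/120, half-open).

## Model assessment

Per-residue pLDDT is read from the Cα B-factor of model files (model
files write one value per residue; chains must be flagged `is_model` —
experimental B-factors are refused). Models are ranked by the *minimum*
pLDDT over the activation loop, descending, with mean pLDDT and model id
as tie-breaks; optionally only models passing the active criteria are
ranked.

Accuracy against a reference structure is the backbone RMSD (N, Cα, C,
O) over the activation loop after superposing the C-terminal domains —
the loop itself never participates in the fit, so loop errors are not
absorbed. Residue correspondence comes from a global sequence alignment
(≥ 90% identity required; below that an explicit map must be supplied).
The superposition set is a deterministic, sequence-driven stand-in for a
structure-based C-terminal-domain alignment: aligned Cα atoms from the
residue after the APE-Glu to the chain end, plus the catalytic-loop
block from ten residues before the HRD-His through XHRD, with
activation-loop residues always excluded and an explicit residue-list
override available. Loop pairs require complete four-atom backbones on
both sides; the retained count is reported so benchmarks can insist on
complete loops. Superposition is a standard SVD Kabsch fit with
determinant correction (reflections excluded); the test suite checks it
against an independent quaternion eigenvalue oracle at 1e-9 Å.

```{r}
e <- make_model_ensemble(n_models = 6, plddt_rmsd_coupling = 1, seed = 7)
scores <- do.call(rbind, lapply(e$models, function(m) {
  ch <- select_chain(m, "A")
  score_model(ch, e$reference$annotation, model_id = attr(m, "model_id"))
}))
rank_models(scores)[, c("model_id", "min_plddt_al", "active")]
```

## Curation rules

Ortholog hit filtering keeps hits strictly above 50% identity and 90%
query coverage with strictly below 10% alignment gaps. Redundancy
reduction is a CD-HIT-style greedy pass, longest sequence first, where a
sequence founds a new cluster unless it exceeds 90% identity to an
existing representative; identity is defined as matches over alignment
columns (gaps included) of a global alignment, which is deterministic and
reproducible, unlike word-based estimates — so the guaranteed
postcondition (no representative pair above the threshold), not exact
cluster membership, is the contract. Template selection sorts active
candidates by ordered activation-loop residue count, then resolution,
then entry/chain id, and takes up to two per kinase from *distinct* PDB
entries, with the prediction target's own entry excluded. MSA truncation
keeps the query plus the first `depth − 1` rows, covering both the
30-sequence default regime and the very shallow 1–5-sequence regime used
to force template-driven modelling.

## The synthetic-fixture generator

`make_kinase_fixture()` defines the test conditions for everything
above. It builds a 90-residue chain carrying all anchor motifs from
prescribed φ/ψ/ω torsions (standard internal-to-Cartesian construction
with ideal bond lengths N–Cα 1.458, Cα–C 1.525, C–N 1.329, C=O 1.231 Å),
then rigidly places three segments — the C-helix block, the
activation-loop start (XDFG through DFG6) and the loop end plus
C-terminal tail — so the requested salt-bridge, ActLoopNT, ActLoopCT and
DFG-anchor distances hold exactly, and finally adds only the pseudo
side-chain atoms the criteria read (Nζ, Oε1/Oε2, CB/CG for χ1, Cζ on the
two anchor spheres, one spine atom per spine residue). All placement
directions are taken from local backbone frames, so the construction is
equivariant under rigid motions and the generator/measurer agreement is
exact to 1e-6 Å (cross-validated in the test suite). Geometrically
impossible target combinations (triangle-inequality violations for the
ring-tip placement) raise a construction error naming the conflicting
pair.

The default targets describe a typical active structure: salt bridge
3.0 Å, ActLoopNT 2.9 Å, ActLoopCT 3.5 Å, ring tip 12 Å from the Lys Cα
and 9 Å from the Glu4 Cα, spine distances 4.0 Å, XDFG torsions in the
B/L/A basins, χ1 = −60°, pLDDT 90. These values sit in the centres of
the distributions observed for substrate-bound structures; out-regime
test conditions draw from the complementary side of each cutoff.

`perturb_loop()` adds seeded isotropic Gaussian noise to the activation
loop only, and `make_model_ensemble()` turns that into a model set whose
loop pLDDT decreases with the *realised* loop error plus noise scaled by
`1 − coupling`: at coupling 1, pLDDT ranking provably recovers the
lowest-RMSD model, which is the recoverable form of the empirical
confidence–accuracy relationship the ranking relies on.

What the fixtures deliberately do not emulate: real side-chain
stereochemistry, packing, or the conformational heterogeneity of real
activation loops. Passing tests therefore demonstrate the correctness of
the measurements, labels, ranking and RMSD machinery — not that the
cutoffs themselves generalise, which is an empirical claim about real
structures that requires the published reference entries (see the
benchmark tests, which accept locally supplied coordinate files).

## Numerical choices and degenerate inputs

* Angles are wrapped to (−180, 180]; all region and rotamer intervals
  are half-open, so every point gets exactly one label (the partition is
  property-tested on a grid).
* Torsions follow the standard IUPAC convention (cis = 0, right-handed
  positive); a proper torsion is invariant under atom-order reversal and
  negates under mirror reflection, and the tests pin both.
* Alternate locations: reads retain all alt-locs; per-chain reduction
  keeps the highest occupancy, ties broken alphabetically.
* Multi-model files: model 1 only, with a warning. Hydrogens are ignored
  throughout; all criteria use heavy atoms.
* Missing atoms are values (`NULL`/`NA`), and flow into "unevaluable"
  states rather than errors or "out" calls; Gly at a spine position
  makes the spine unevaluable; a missing χ1 makes the dihedral label
  unevaluable.
* Kabsch requires ≥ 3 non-collinear points; collinear inputs and
  bonded-triple-collinear torsions are errors.
* Problem sizes in the test suite and acceptance script (200 regime
  fixtures, 100 point clouds, 100 rigid transforms, 50 ranking trials,
  ensembles of 8–20 models on 90-residue chains) were chosen as the
  smallest sets that exercise every regime of every criterion with
  stable statistics.

## Known limitations

* The Ramachandran rectangles are a deliberately simple partition; they
  agree with the B/L/A basin assignments the active verdict needs but
  may disagree with finer published region taxonomies on boundary cases.
* ATP presence is reported from chain-associated ligand codes only; no
  geometric active-site test is attempted.
* The sequence-driven C-terminal-domain superposition approximates a
  structure-based alignment; small RMSD differences against numbers
  derived from structure aligners can trace to the superposition set.
* No profile-HMM alignment or automatic family assignment: families,
  gene labels and (for pattern-search-resistant sequences) anchors are
  inputs.
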