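---
title: "Quantifying the variability of protein-protein interfaces"
author: "ppiface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the variability of protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiface)
```

## The question

An edge in a protein-protein interaction network says that two proteins
bind; it does not say *how*. When the same pair of proteins has been
crystallized repeatedly, the deposited biological assemblies let us ask
whether the two proteins always touch through the same residues, or whether
the "same" interaction is realized through alternative interfaces.
`ppiface` implements this analysis end to end: it annotates interfaces in
biological assemblies, measures pairwise interface similarity, organises
all observations into a redundancy hierarchy, and estimates how interface
similarity is distributed once over-represented sequences and families have
been down-weighted. A generator of synthetic assemblies with planted ground
truth makes every stage testable without any structure download.

## Interface annotation

Hetero-dimers are pairs of interacting chains mapped to two *different*
protein accessions (external interactions). Entries are restricted to X-ray
structures with resolution better than 2.5 Å; chains interact when at least
one inter-chain atom pair lies within 6 Å.

A residue pair (Rx, Ry) belongs to the interface when

1. its minimal inter-atomic distance *d* is below 6 Å, **or**
2. all of the following hold: both residues lose accessible surface area
   upon binding (dASA > 0, computed as ASA of the chain alone minus ASA in
   the dimer), Rx has no partner within 6 Å, and Ry is the dASA-positive
   partner residue closest to Rx.

Rule 2 admits contacts that fall slightly above the distance cutoff but
clearly bury surface. With a 1.4 Å probe, two carbon atoms stop occluding
each other beyond about 6.2 Å, so rule 2 operates in the narrow 6.0-6.2 Å
band — the analysis scripts report exactly this range on synthetic data.
The rule is stated asymmetrically; because an interface is a symmetric
object we evaluate it in both orientations and take the union (a
one-directional mode exists for sensitivity analysis). Accessible surface
areas come from a rolling-probe (Shrake-Rupley) engine implemented in
compiled code, with deterministic golden-spiral quadrature points.

Dimers with fewer than five interacting residues on either side are
discarded. Each dimer also receives an *interface copy number*: the number
of dimers in its assembly with exactly the same unordered pair of SEQRES
sequences.

Key parameters (all in `annotation_config()` / `run_config()`):

| parameter | default | meaning |
|---|---|---|
| `distance_cutoff` | 6 Å | contact rule; 4 Å is the common strict variant |
| `use_dasa` | TRUE | enable rule 2 |
| `dasa_min` | 0.1 Å² | positivity floor absorbing quadrature discretisation |
| `probe_radius` | 1.4 Å | water probe |
| `n_points` | 960 | quadrature points per atom (doubling moves per-residue ASA by < 2%) |
| `max_resolution` | 2.5 Å | entry filter, strict inequality |
| `min_face_size` | 5 | residues per face |

## Similarity measures

All comparisons first reduce the two dimers to *common residues*: identical
sequences give the identity map on positions resolved in both structures;
otherwise a global (Needleman-Wunsch, BLOSUM62, affine gaps) alignment of
the SEQRES sequences defines the map. Comparisons whose mapped fraction
falls below the coverage floor (default 0.3) are skipped and logged.

**Face Position Similarity (fps).** A face is the set of residues on one
side of an interface. For faces F and F' (after reduction),
fps = |F ∩ F'| / sqrt(|F| · |F'|) ∈ [0, 1]. The two sides of a comparison
give two values; we report both and combine them by the arithmetic mean
(the combiner is a package choice — any other can be applied to the
per-side columns downstream).

**L_rms.** The larger chains ("receptors") are superposed on the backbone
atoms (N, CA, C, O; CA-only fallback for incomplete backbones) of their
common residues; the resulting transform is applied to the smaller chains
("ligands") and their backbone RMSD is the L_rms. It reflects alternative
binding positions *and* conformational change anywhere in the ligand.
Receptor roles are assigned by combined chain length over both dimers, with
accession-order tie-breaks, so the measure is symmetric.

**I_rms.** Backbone RMSD over the interface region common to both dimers
(union of the two annotations' faces mapped through the correspondence),
superposed jointly across both chains.

Superpositions use a Kabsch (SVD) solver constrained to proper rotations;
the test suite cross-checks it against an independent quaternion
(eigenvalue) oracle to 10⁻⁶ Å.

When accessions and families leave the chain pairing ambiguous (both chains
of both dimers from one family), the orientation with the higher combined
fps is used, with accession-ordered tie-breaks.

## The redundancy hierarchy and the three distributions

Hetero-dimers are grouped by unordered key at three levels: identical
SEQRES pair (**SameSeq**), identical accession pair (**SameProt**),
identical family pair (**Interolog**). The hierarchy is a strict nesting;
every averaging step below is unweighted, so a family with thousands of
depositions counts exactly as much as one with two.

* **D-SameSeq** — per eligible SameSeq group (≥ 2 members), the histogram of
  all pairwise similarities of its members; averaged SameSeq → SameProt →
  Interolog → overall.
* **D-SameProt** — per SameProt group, every unordered pair of distinct
  SameSeq children contributes the histogram of its *cross*-child
  comparisons (within-child pairs are already covered by D-SameSeq);
  averaged upward identically.
* **D-Interolog** — per Interolog group, every unordered pair of distinct
  SameProt children; for each, every combination of one SameSeq child from
  each side contributes its cross histogram. Children are subsampled to at
  most 50 protein pairs per family and 50 sequence pairs per protein pair
  with a seeded RNG recorded in the run configuration.

Comparisons between interface copies within one assembly are included and
flagged `intra_assembly` (a switch excludes them); copy-number effects are
part of the biology the distributions should capture.

Histograms use half-open bins — fps in ten 0.1 bins with a closed top,
Å-valued measures in 1 Å bins from 0 to 9 with an open top bin — expressing
the conventional reporting thresholds (< 1 Å, > 2 Å, > 9 Å). Per-bin
standard errors come from a seeded bootstrap that resamples top-level
(Interolog) groups with replacement; with fewer than two top-level groups
the SE is reported as absent.

## Homomer best-match filtering

A protein bound twice by the same homo-oligomer contributes two genuinely
different interfaces. To quantify how much diversity this explains, the
filter works per comparison X/Y vs X'/Y': it collects all interfaces of X'
with homomer partners of Y' and of Y' with homomer partners of X'
(including X'/Y' itself), where "homomer partner" means chains of identical
sequence (`sequence` mode) or identical family (`structural` mode)
connected through the interaction graph, transitively closed so an n-ring
counts as one oligomer. The comparison survives only when it is the best
match among the alternatives — in both directions, so the retained set is
symmetric. Ties retain (discarding them would delete exact-equivalent
matches); "best" means maximal fps or minimal RMSD, applied per measure.
When the two compared dimers share an assembly, one side's perfect
self-match is among the alternatives, so intra-assembly cross-mode
comparisons are filtered out — exactly the diversity the filter is supposed
to attribute to the homomer context. Structural mode is computed only for
D-Interolog and only for interactions joining two different families; at
the other levels it would compare different protein pairs.

## The synthetic world generator

`world_spec()` / `generate_world()` produce valid PDB files, a mapping
table and a truth table. Chains are idealized α-helices (CA rise 1.5 Å,
twist 100°, backbone + CB), so a residue's "side" is its helical phase;
binding modes designate disjoint axial windows on the receptor-side chain
and well-separated phase bands on the partner, which makes faces of
different modes essentially disjoint (fps < 0.2 between modes, fps = 1
within a mode). The generator plants:

* family pairs with up to two (default) alternative binding modes mixed at
  0.8/0.2;
* protein pairs within each family (35% sequence divergence, preserved
  backbone) and point-mutant sequence pairs (3% substitutions);
* interface copy numbers drawn from a decreasing distribution over 1-6,
  as repeated copies of the docked pair;
* with probability `homomer_rate` (default 0.2), the double-binding
  topology: two identical copies of the partner bound at two adjacent
  sites, in contact with each other;
* one hexameric ring of two same-family proteins alternating around a
  central third protein — the structural-homomer scenario — determined
  twice with the ring rotated by 60°.

For homomer-free worlds the expected fraction of cross-mode comparisons is
`1 - sum(mixture²)` (0.32 at 0.8/0.2) at every hierarchy level, because
modes are drawn independently per interface; this closed form is the
recovery target of the calibration tests. The generator does *not* emulate
real data in several respects: no side chains beyond CB, no conformational
flexibility, no disorder, no crystal contacts, no indels between homologs,
and docking geometry without energetics. Passing tests therefore
demonstrate correctness of the measures, grouping, averaging and filtering
machinery under known truth — not robustness to experimental noise.

## Numerical and design choices

* ASA: element van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 Å,
  default 1.70 with a warning), probe 1.4 Å, 960 spiral points; dASA floor
  0.1 Å² against discretisation noise.
* Degenerate superpositions (< 3 points, collinear sets) raise errors
  rather than returning unstable answers.
* Undefined similarities (empty face after reduction, coverage below the
  floor, < 3 common residues for RMSD measures) are skipped and logged;
  groups whose comparisons were all skipped contribute no distribution.
* Cumulative masses are whole-bin sums; thresholds must be bin edges (no
  interpolation).
* Replicate-level calibration checks use 99% bootstrap-t intervals
  (Student-t quantile at G-1 degrees of freedom times the bootstrap SE over
  top-level groups): with 40 simultaneous replicate checks, per-replicate
  99% intervals keep the family-wise false-alarm rate near 5% while still
  detecting bias an order of magnitude smaller than the planted effect.
* Problem sizes: the analysis scripts use one default world (50 assemblies,
  ~130 hetero-dimers, ~1,000 comparisons); calibration uses 40 replicate
  worlds of 10 family pairs each. These sizes give stable estimates for
  every quantity reported while keeping each script in the minutes range.

## Limitations

* The chain-to-protein mapping is an input; the package does not query
  sequence databases. The identity fallback (`map_by_identity()`) requires
  90% chain coverage and ≥ 30 residues, mirroring common mapping practice,
  but is no substitute for curated mappings.
* Family assignment of multi-domain chains is delegated to the mapping
  table; a chain has exactly one family label.
* Only standard amino acids participate; ligands, waters and nucleic acids
  are ignored, so ligand-mediated interface changes are visible only
  through the protein geometry.
* Real-data headline percentages depend on the structure corpus and its
  mappings; this package reproduces the *machinery* and validates it on
  synthetic truth.
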