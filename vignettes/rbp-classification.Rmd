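---
title: "Classifying modular phage receptor-binding proteins by serogroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying modular phage receptor-binding proteins by serogroup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpmosaic)
```

## The model

Phage receptor-binding proteins (RBPs) are treated as two-module mosaics:
an N-terminal anchor domain that fastens the protein to the phage
particle, and a C-terminal receptor-binding domain (RBD) that recognizes
a host surface receptor, typically the O-antigen of the *E. coli*
lipopolysaccharide. The package's working assumptions are:

* **anchors evolve vertically** — they are conserved within a phage genus
  because they must dock onto that genus's tail architecture;
* **RBDs move horizontally** — they are exchanged between phages, even
  across genera, because a swapped RBD switches host specificity without
  disturbing particle assembly;
* **an RBD lineage implies a receptor** — RBPs whose RBDs descend from a
  common transfer event (a *subtype*) bind the same receptor, so the host
  serogroups observed across a subtype vote on its specificity.

From these assumptions the pipeline derives everything else: a pair of
RBDs with amino-acid identity at or above `hit_min_identity` (30%)
covering at least `hit_min_coverage` (60%) of either RBD is evidence of a
transfer relationship; subtypes are the connected components of these
hits (single linkage, because transfer chains are transitive); and a
subtype is serogroup-specific when either an experimentally confirmed
member vouches for it or at least `consensus_fraction` (90%) of its at
least `consensus_min_known` (2) known host-serogroup votes agree.

The 30/60 thresholds are deliberately permissive: distant RBD homologs
retain specificity down to roughly 30% identity, while unrelated domains
align far below it (the test suite's null experiment with random 300-mers
never produces a passing pair). The consensus rule is categorical, not
probabilistic — a subtype either earns a serogroup or is rejected as
`inconsistent` (votes split) or `insufficient_data` (fewer than two known
votes), mirroring how a curator would treat the evidence.

## Pipeline stages and their parameters

`run_rbp_pipeline()` chains the stages; each is exported on its own.

**Metadata filters.** Prophage records carry an activity score in [0, 1];
scores above `prophage_active_score` (0.8) count as active, scores in
[`prophage_ambiguous_floor`, `prophage_active_score`] = [0.5, 0.8] are
kept only on request (`allow_ambiguous`) and flagged. Phages isolated on
rough laboratory strains (the `rough_strain_blocklist`: 58, AG1, B, BL21,
C, C600, DH1, DH5α, MG1655, W3110, W945) are discarded — a rough strain
displays no O-antigen, so such an isolate says nothing about serogroup
specificity.

**Delineation.** Curated boundaries always win (`curated_anchor_end` or a
boundary table; a record flagged `split_rbp`, where anchor and RBD are
separate proteins, gets `anchor_end = 0`). Otherwise, genera with at
least three members get a data-driven breakpoint: every member's
positions are scored by the fraction of same-genus partners identical at
that position in a global pairwise alignment, the profile is smoothed
with a running mean of `breakpoint_window` (20 aa), and the anchor ends
at the last smoothed value ≥ `breakpoint_t_high` (0.7) before the profile
first drops below `breakpoint_t_low` (0.4). The thresholds encode the
contrast the model assumes: within-genus anchors at ~95% identity sit
well above 0.7, while RBDs of different families fall to background. When
no clean drop exists (e.g. all members identical, or fewer than three),
the tentative `default_anchor_cutoff` of 150 aa applies; sequences of
160 aa or less are rejected rather than given an RBD shorter than 10 aa.

**Alignment.** Protein alignments use BLOSUM62 with affine gap penalties
11 (open) and 1 (extend) — the familiar protein-BLAST parameterization.
Identity is counted over *all* alignment columns, gaps included in the
denominator; this conservative convention is stated so tests can be
exact. Hit detection uses local alignment; identity matrices for
phylogenies use global alignment of the selected region. Because the
optimal local alignment is symmetric in its inputs, the hit criterion
takes coverage on *either* RBD, making the hit an undirected edge
predicate by construction.

**Redundancy.** Two rules, both with the same keep-priority (higher
prophage score, then stronger evidence group A > B > ... > F, then longer
sequence, then smaller id): within a serogroup, records at or above
`redundancy_identity` (80%) full-length identity to an already-kept
record are collapsed greedily; within a (subtype, genus) cell a single
representative survives. Removed records donate their host-serogroup
votes to their representative (`double_serogroups`), so deduplication
never silences evidence — only sequences.

**Validation and accounting.** `assign_serogroups()` applies the
experimental-first, consensus-second rule. Two conflicting
experimentally-confirmed members are a data contradiction and raise an
error rather than being auto-resolved; the package applies this rule to
RBP-level evidence and, when none exists, to phage-level evidence as
well. A tie for the modal serogroup is `inconsistent` (a tie can never
reach 90% with at least two voters). The consensus denominator counts
only known votes: unknown hosts neither support nor veto, they simply
fail to contribute toward the minimum of two. `genus_filter()` keeps
genera with at least `genus_min_specific_rbps` (2) assigned RBPs, and
`build_ledger()` places every record in exactly one terminal category
(final / omitted by the genus filter / inconsistent / insufficient),
raising an error if the categories fail to telescope. The published
per-group tallies behind the ledger arithmetic ship as
`study_group_counts()` / `study_prophage_counts()`.

**Phylogenies.** Distances are `1 - identity/100` from global-alignment
identity matrices — for small, strongly diverged sets this tracks an
MSA-based matrix closely without committing to a protein MSA heuristic.
Neighbor-joining is implemented in-package so that negative branch
lengths (possible on non-additive input) are clamped to zero with the
deficit moved to the sister branch, preserving path lengths; joins are
tie-broken by the lexicographically smallest member labels, so the tree
is invariant to taxon order. The clustering claim is quantified by
`label_concordance()`: the fraction of taxa whose nearest neighbor shares
their label (singleton labels excluded, ties broken lexicographically).
Nearest-neighbor agreement was chosen over tree-clade purity because it
is deterministic and needs no clade-extraction convention.

**Motif scan.** For records with nucleotide sequences, two windows are
cut: ±`flank_halfwidth` (150 nt) around the last anchor nucleotide
(position `3 * anchor_end`), and `downstream_len` (120 nt) after the stop
codon. Windows are aligned with a center-star procedure (center = window
with the best summed pairwise score; "once a gap, always a gap" merging)
under nucleotide-BLAST scoring (match 2, mismatch −3, gap open 5, extend
2 — the stiff gap extension keeps alignments of diverged flanks from
drifting). Conservation is the mean pairwise identity per column,
computed over **cross-genus pairs** when genus labels are available:
within-genus flank identity reflects shared ancestry of the gene region,
not motif conservation, and the biological claim being tested is
conservation *across* genera. Columns with fewer than 50% non-gap rows
are ignored (sparse insertion columns carry no signal). Conserved
windows are the maximal scoring segments of the profile against the
midpoint of (`motif_min_identity`, `motif_col_floor`) = (55%, 40%),
which tolerates isolated low columns inside a real motif while keeping
background negative; a segment must contain a smoothed core (window
`motif_window` = 10 columns) reaching `motif_min_identity`, span at least
`motif_min_len` (15) dense columns, be supported by `motif_min_members`
(4) sequences non-gap over ≥ 80% of the span, and reach mean pairwise
identity ≥ `motif_min_identity`. Defaults bracket motif lengths of
20–95 nt at 55–85% identity. Significance is a permutation test:
`motif_n_perm` (999) equally long column windows drawn from the same
alignment outside the hit, `p = (1 + #null ≥ obs) / (N + 1)`, exactly
reproducible for a fixed seed. Each hit reports per-member coordinates
and a consensus span (the median of member spans, robust to individually
misaligned rows).

## What the synthetic generator emulates

`simulate_rbp_dataset()` realizes every structure the pipeline assumes,
with ground truth: genera with ancestral anchors (planted boundary drawn
from 150–210 aa; ~5% pairwise within-genus divergence), serogroup-linked
RBD families dealt cyclically across genera so each family recurs in
several genera (the transfer structure), per-record RBD divergence drawn
uniformly up to 40% substitutions, near-duplicate pairs above the 80%
redundancy threshold, decoy families whose member labels alternate so no
label reaches 90%, records with unknown hosts, and two DNA motifs — one
codon-aligned block ending exactly at the anchor/RBD boundary (45 nt,
per-site mutation rate 0.12, i.e. ~78% pairwise identity) and one in the
noncoding flank after the stop codon (20 nt at rate 0.08). Sizes default
to 5 genera × 3 records + 2 duplicates + 3 decoys + 2 unknowns = 22
records; this keeps the seeded multi-replicate test suites (50–100
replicates) fast while exercising every code path, and the generator
scales up by configuration.

Nucleotide sequences are built by lineage-consistent back-translation:
each ancestral sequence receives one random synonymous codon per residue,
and descendants inherit the ancestral codon wherever the residue is
unmutated, drawing a fresh synonymous codon only at substituted sites. DNA
identity therefore tracks shared ancestry (within-genus anchors ~97% nt,
unrelated regions ~30%), which a fixed codon table would not give (it
makes all coding DNA ~40–55% identical). Motifs are planted by
overwriting the nucleotide window, and the amino-acid sequence is then
re-derived by translating the CDS, so the nt/aa consistency invariant is
exact; in-frame stop codons created by motif mutations are reverted to
the ancestral codon. One consequence is that the last ~15 anchor residues
are motif-derived and shared across genera — negligible against ≥ 150-aa
genus-specific anchors, but it softens the conservation profile just
before the boundary, which is why data-driven boundaries land a few
residues early (mean absolute error ~12 aa in the recovery report).

What the generator does **not** emulate: insertions/deletions (substitution
only — alignment gap handling is exercised by the alignment tests, not
the generator), rate heterogeneity along sequences, codon-usage bias,
genome context (synteny, multiple genes), branched multi-RBP architectures
beyond the `rbp_index` bookkeeping, and real serogroup label noise
(mislabels). Passing recovery tests therefore demonstrate correctness of
the machinery under the model's own assumptions, not robustness to every
artifact of real curation.

## Numerical choices and degenerate inputs

* Identity ties in the hit criterion are impossible to half-pass: the
  edge is `identity ≥ 30 AND (coverage_q ≥ 60 OR coverage_s ≥ 60)`.
* The 90% consensus boundary is inclusive (9 of 10 votes assigns).
* Subtype ids are the lexicographically smallest member id; all
  partitions, trees and center choices are tie-broken lexicographically,
  making every result invariant to input order.
* RBDs shorter than 10 aa are excluded from the hit search with a
  warning; prophages without scores are dropped with a warning; records
  without nucleotide sequences are skipped by the motif scan.
* Every stochastic operation (generator, permutation test) takes an
  explicit seed and restores the caller's RNG state.

## Known limitations

* The breakpoint delineation assumes at least three genus members and a
  genuine anchor/RBD conservation contrast; genera of hybrid or uniformly
  similar proteins fall back to the 150-aa default.
* Center-star alignment is a heuristic MSA; individual rows can slip in
  low-identity regions, which is why hit locations are reported as median
  consensus spans and conservation uses cross-genus pairs.
* The boundary motif abuts the RBD start, which is itself conserved
  across genera within a family (that is what transfer means), so the
  detected boundary window can merge with the RBD-start conservation
  block on some datasets; the downstream noncoding motif has no such
  neighbor and localizes cleanly.
* Serogroup labels are opaque case-sensitive strings ("O157", "4s/O22",
  "K1" all live in one namespace); no attempt is made to normalize or
  relate them.
* No E-value model, composition adjustment or database-search heuristics:
  comparisons are exhaustive optimal alignments, appropriate for curated
  collections of tens to hundreds of RBPs, not genome-scale search.
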