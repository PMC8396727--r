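---
title: "Evolution-guided topology annotation for CPA/AT-like transporters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution-guided topology annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpatopo)
```

## The problem

CPA/AT-like transporters (cation/proton antiporters, anion transporters
and relatives) are built from two inverted internal repeat units. Each
repeat contributes a *scaffold* subdomain (dimerisation and packing) and a
*core* subdomain (substrate path), and the middle helix of each core is
non-canonical: a **broken helix** that crosses the membrane with a
mid-bilayer discontinuity, or a **reentrant helix** that enters and exits
on the same side. These are precisely the elements that per-sequence
topology predictors miss most often — frequently in a *systematic* way, so
that every member of a family lacks one or both non-canonical helices in
its prediction. Annotating these families correctly therefore requires
combining per-sequence predictions with evolutionary context, comparison
to solved structures, and the positive-inside (KR-bias) rule.

`cpatopo` implements that integrated procedure as reusable, tested
components, and pairs it with a synthetic-family generator so every stage
can be checked against a known ground truth.

## The topology model

A `topology` is an ordered, contiguous, 1-based inclusive segmentation of
a chain into inside/outside loops, TM helices, broken helices, reentrant
helices and an optional N-terminal signal peptide, serialisable to a
per-residue string over `{i, o, M, B, R, S}`. Two structural rules are
enforced at parse time:

* **Side alternation.** TM and broken helices (and signal peptides) flip
  the loop side; reentrant helices return to their entry side. A TM helix
  flanked twice by the same side is an inconsistency and is rejected with
  the offending segment named.
* **Run lengths.** Helix runs below 5 residues are rejected; TM runs below
  12 residues draw a warning. Five residues is also the granularity of the
  helix-alignment rule (below), which keeps the two thresholds coherent.

A chain is summarised by its label, e.g. `10H-2RH-Nout`: canonical count,
non-canonical count and kind, and the side of the N-terminus. We use the
plain-text orientation forms `Nin`/`Nout` as the canonical serialisation;
the subscripted variants found in print (`N_in_`) are accepted on input.
Broken helices are modelled as *one* segment with an internal break
position rather than two half-helices, because family labels count each
broken helix as a single unit (two per transporter, one per repeat).
Total helix count is `n + m`; membrane crossings are `#TM + #broken`
(reentrant helices do not cross) — the two differ by exactly the number of
reentrant helices, an invariant the tests exercise on random topologies.
Signal peptides are parsed and participate in side alternation but are
never counted as helices.

## Sequence preprocessing

Family sets are filtered with the two standard rules: sequences covering
less than 75% of the annotated domain are removed as fragments (coverage
exactly 75% is kept, matching the strict printed inequality), and of any
pair above 90% identity the later sequence in scan order is dropped.
Identity is defined as identical aligned positions over the shorter
ungapped length; for unaligned pairs a global alignment with unit scores
(match = 1, everything else 0, free gaps) supplies the aligned positions
via `Biostrings::pairwiseAlignment`. The exact identity definition inside
blastclust/cd-hit is tool-internal; we document ours and use it
consistently, and we do not reproduce cd-hit's word-length speed
heuristic, which does not change results. Greedy clustering scans
sequences in descending length order (ties by id, the cd-hit convention),
making it deterministic; `Meff` is the cluster count at 62% identity.

## Evolution-guided consensus and subfamily splitting

Per-sequence topologies are projected onto the seed MSA (topology
characters at residue columns, `-` at gap columns; degapping the
projection recovers the input exactly) and rows are reordered to the
left-to-right leaf order of the phylogenetic tree. The tree is always
*consumed*, never inferred — phylogeny construction is out of scope, and a
clearly-labelled UPGMA-on-identity builder is provided for fixtures only.

Subfamily detection walks the tree from the root and accepts each maximal
clade in which at least `min_clade_fraction = 0.75` of the members share
one topology label and which has at least `min_group_size = 3` members.
Members with minority labels inside an accepted clade, and rows in no
qualifying clade, are flagged as deviants (putative prediction errors).
No numeric rule for "systematic topology variation" exists in the
literature for this procedure, so both thresholds are exposed as
parameters; 0.75 tolerates a realistic per-row error rate without
splitting every family, and 3 prevents two-member "subfamilies" that
could not be told from correlated errors. Without a tree, the function
falls back to grouping by label equality and warns — a deliberately
degraded mode.

The consensus ("initial") topology of a group is the per-column majority
over the member rows, with ties resolved toward the representative row
(the member with fewest gaps, ties by id — a deterministic stand-in for
the externally-chosen representative a production run would use). The
majority string is degapped on the representative, smoothed — interior
runs shorter than 5 residues merge into the longer flanking run, terminal
tails are never merged away — and side-repaired by N-terminal propagation
toward the majority orientation of the group. If smoothing leaves two
helix runs adjacent the function fails loudly with the column ranges
rather than guessing.

## Template comparison and the final topology

Pairwise query–template alignments are inputs (gapped string pairs with an
E-value); profile–profile search itself is not reimplemented. A template
membrane helix is *aligned* when at least five residues of both helices
are aligned. Otherwise its class is the dominating query composition over
the template-helix columns — gap, inside loop, outside loop or signal
peptide — with ties broken in that order (most to least common class, so
the rarest wins last). The broken/reentrant type of a family follows the
structural hit with the lowest E-value; an exact tie defers to KR-bias
arbitration.

Template helices classified as loops mark missing helices: a helix of the
template's kind is inserted at the mapped span, clipped to the enclosing
loop, with a 5-residue minimum (the insertion length is not specified by
the procedure we follow; the template span clipped to the loop is the
natural choice and the minimum matches the parser's floor). After every
insertion the loop sides are re-propagated from the N-terminus, because
inserting a crossing helix flips all downstream sides; orientation is
always anchored at the N-terminus. The inference is idempotent: once
inserted, the helices align and a second pass changes nothing.

Scaffold/core tags and repeat membership transfer across the aligned helix
map; unaligned query helices inherit from their nearest aligned neighbour
and are flagged as extrapolated. When the query's N-terminal helices map
to the template's C repeat the transfer emits a repeat-shuffle flag. The
transfer refuses to run when fewer than half the template helices align —
below that, the helix map is too sparse to trust.

## KR-bias model selection

For every membrane helix we count K and R from `inside_helix_depth = 10`
residues inside the helix to `after_helix_extent = 25` residues into the
following loop (truncated at the next helix); the N-terminal tail
contributes a symmetric window, and reentrant helices contribute a single
window on their entry/exit side. Overlapping windows never double-count a
position. The statistic is the plain difference inside − outside,
summarised per family by the mean; a ratio form was rejected because it is
undefined when the outside count is zero. Model selection evaluates every
MSA row under both candidate models on the representative's coordinates
(rows more than 50% gapped inside the window regions are skipped) and
takes the model with the higher mean; verdicts within `tolerance = 0.5`
of each other are reported as ambiguous rather than forced.

One structural fact matters for testing: the inside and outside window
*position sets* are only equal in size when the chain has an odd number of
crossings (tails on opposite sides). The zero-signal null test therefore
uses an odd-crossing blueprint, where the null expectation of the count
difference is exactly zero by symmetry.

## Core-helix features

The non-canonical helix of each repeat's core is sliced from the family
MSA on the representative's coordinates (gap-only columns retained).
Motifs are position frequency matrices with a uniform pseudocount
(default 0.5/20 per cell) and per-column information content
`log2(20) − H` in bits. Insertion free energy uses the packaged
position-independent biological hydrophobicity scale (per-residue
apparent ΔG of translocon-mediated insertion, kcal/mol); the full
position-dependent polynomial with length scanning is deliberately not
reproduced, because the pipeline uses ΔG only comparatively
(broken vs reentrant vs TM distributions), and for comparisons the
additive form preserves the ordering. The tests therefore pin properties
(poly-Leu inserts favourably; any single polar substitution raises the
score; additivity) rather than absolute values.

## Networks and visual reports

Hits are deduplicated to one record per unordered pair (lowest E-value
wins, as for reciprocal search directions) and built into an undirected
graph: edges below `E = 0.1`, thick below `E = 0.001`, weight
`log10(E)` stored raw (negative for significant hits; consumers may
negate for layout). The declared-node list is an explicit input so that
families with no significant hit remain visible as isolates. Dotplots
store one point per aligned residue pair coloured by `floor(log10 E)`;
distance maps store raw CA–CA Euclidean distances and clamp to 4–10 Å
only at rendering time. The phrase "distance between the mutual
distances" admits two readings, so both modes exist: cross-chain aligned
distances, and the absolute difference of intra-chain distance matrices;
neither is privileged.

## The synthetic generator

The generator is the package's ground truth, not a convenience: its
defaults define the study conditions under which the pipeline is
validated.

* **Blueprint.** A label such as `10H-2RH-Nout` expands to an N-tail (20
  residues), 21-residue TM helices (25 for broken, 16 for reentrant)
  separated by 15-residue loops, and a C-tail; helices split evenly
  between the repeats (odd counts give the N repeat an extra scaffold
  helix), the non-canonical helix is the middle of each repeat's
  three-helix core, and the repeat annotation is derived accordingly.
* **Composition.** TM helices draw from a hydrophobic distribution; loops
  from a polar/charged distribution with a 3% + 3% K/R baseline; inside
  loops receive a Poisson number of extra K/R with mean
  `positive_inside_strength` (default 2, a realistic cytoplasmic
  enrichment); reentrant cores draw a less hydrophobic mix whose middle
  third is G/P-substituted at `core_gly_pro_enrichment` (default 0.3).
* **Evolution.** Sequences diverge along a random coalescent tree
  (`ape::rcoal`, depth rescaled to `tree_depth = 0.4` mean root-to-tip);
  substitutions stay within residue class — hydrophobic, polar, K/R,
  D/E — so the topology and charge architecture decays slowly and
  controllably. Keeping K/R separate from D/E is deliberate: mixing them
  would erode the positive-inside signal with divergence. Indels are
  confined to loops with geometric lengths (mean 2); insertions become
  new alignment columns, so the emitted MSA is exact by construction.
  Substitutions are tree-structured; indels are applied per tip, a
  simplification that does not affect any statistic the pipeline
  measures.
* **Prediction errors.** Per row: each non-canonical helix is missed
  (replaced by loop, sides re-propagated) with `p_miss_noncanonical`;
  with `p_merge` two adjacent helices merge across their loop; with
  `p_flip_orientation` all sides flip. `p_miss = 1` reproduces the
  family-wide blindness to reentrant helices that motivates the template
  step.

What the generator does *not* emulate: realistic substitution matrices,
rate heterogeneity, alignment uncertainty (the true alignment is given),
signal-peptide cleavage, or structure coordinates beyond toy helical
bundles. Passing tests therefore demonstrate the pipeline's correctness
under its stated assumptions, not predictor-level accuracy on real
proteomes.

## Validation experiment sizes

The seeded experiments behind the tests and the acceptance script use:
20-row families of ~350–500 columns; 100 trials for consensus recovery at
30% per-column corruption; 100 trials for KR model selection at strength
2 (alternating broken- and reentrant-generated families); 50 seeds of
noise-free two-clade mixtures for the splitting adjusted Rand index; 200
random instances per brute-force oracle comparison. These sizes give
stable rates (recovery ≥ 95%, selection ≥ 90%, ARI = 1) while keeping a
full run in the tens of seconds on one CPU.

## Known limitations

* Chains mixing broken and reentrant helices are rejected by the label
  algebra (no known family mixes them); a future fold-type would need an
  extended label.
* Partial-template transfer (a template aligning only repeat-wise, not
  full length) interacts with orientation correction in ways the
  procedure leaves unspecified; the transfer quality gate (≥ 50% of
  template helices aligned) refuses the ambiguous cases rather than
  resolving them.
* The greedy clustering reproduces the *scheme* of blastclust/cd-hit, not
  their exact scores; Meff values are comparable within this package, not
  interchangeable with other tools'.
* `mmCIF` coordinate files are not read; PDB-format ATOM records only,
  first model, first alternate location.
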