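---
title: "Methods: post-transcriptional architecture analyses in dinoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-transcriptional architecture analyses in dinoarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dinoarch` analyses the post-transcriptional layer of gene regulation in
dinoflagellate genomes: introner-bearing introns, mRNA editing,
differential exon usage, duplicate-gene expression concordance, spliced
leaders, and multi-coding-unit gene models. This vignette documents the
models behind each component, the tunable parameters with their defaults,
the numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations. All coordinates are 0-based half-open
internally; GFF3, pileup TSV and residue-space report columns are 1-based
only at the I/O boundary, so the convention is converted in exactly one
place.

## Introner-element scanning

Introner elements are young introns propagated by a transposon-like
mechanism; their hallmark is a short terminal **inverted repeat** together
with a small **direct repeat** near both intron ends. `scan_introner()`
works on the intron in transcription orientation and restricts the search
to the first and last `window` bases (default 30; windows are clipped, and
may overlap, for introns shorter than `2 * window` — the least surprising
reading of "near each end" when no minimum length is defined). An intron
is IE-positive iff

1. some substring of the 5′ window with length in `[8, 20]` has its
   reverse complement in the 3′ window, **and**
2. some substring of the 5′ window with length in `[3, 5]` occurs verbatim
   in the 3′ window.

Repeats are not required to be anchored at the exact termini, and no
ordering constraint between the two repeat kinds is imposed; the longest
qualifying repeat of each kind is reported with deterministic tie-breaks
(leftmost 5′ start, then leftmost 3′ start). Only the boolean IE flag
enters summary statistics, because short direct repeats are ubiquitous by
chance (two random 30-mers nearly always share a 3-mer); the discriminating
signal is the inverted repeat. The scanner is validated against an
exhaustive substring-pair enumeration on hundreds of random introns.

Splice motifs are tabulated as the first two intron bases (donor:
GT/GC/GA/other) and the acceptor junction motif AG|G — the intron ends
with AG *and* the downstream exon starts with G. The junction reading was
chosen over "last three intron bases" because canonical acceptors already
end in AG, which would make an intron-internal AGG reading almost
degenerate with the G content of position −3.

## mRNA editing

Editing candidates are genomic positions where RNA base composition
diverges from the DNA composition. `call_edit_sites()` applies, per
condition, five criteria with strict inequalities: divergence score
> 1.15; DNA coverage > 10; RNA coverage > 5 in *every* replicate; exactly
one supported alternative base per replicate (support = count ≥ 2 and
fraction ≥ 5%); and the same alternative base supported in all replicates.
Filter boundaries are sharp and tested (coverage 10 vs 11 and 5 vs 6 flip
eligibility and nothing else changes).

The divergence score is this package's own statistic: with pseudocount 1
added to each of the four base counts, let `p̂_r` be the composition of
RNA replicate *r* and `p̂_DNA` the DNA composition; then

```
score = (1/R) * Σ_r  log2 [ L(ñ_r | p̂_r) / L(ñ_r | p̂_DNA) ]
```

where `L` is the multinomial likelihood of the pseudocounted counts `ñ_r`.
Because `p̂_r` is the maximiser of the first likelihood, the score is
non-negative, and it is exactly zero when every replicate's pseudocounted
composition equals the DNA composition. It is deterministic,
dependency-free and monotone in compositional divergence. It is **not**
numerically identical to any external variant caller's score; the 1.15
operating point is retained as a default threshold, not as a claim of
equivalence. In practice the gap is wide: a site with 30% editing at
coverage 10 against an unedited DNA pileup at coverage 20 scores ≈ 7.8,
while an unedited site with the same coverages scores ≈ 0.6.

Edit types are reported on the host gene's strand (both bases complemented
for minus-strand genes), giving the standard 12-type taxonomy. Sites
outside any gene are reported on "+" with an `intergenic` flag; sites
inside overlapping genes are reported once per gene with an `ambiguous`
flag. Differential editing between two conditions is a two-sided Fisher
exact test on the pooled (alt, ref) × (condition) table, BH-adjusted
across sites, declared differential only when q ≤ 0.05 *and* the editing
fraction differs by ≥ 0.1 — the effect gate prevents large-coverage sites
with negligible fraction changes from being flagged.

## Expression: FPKM, superclusters, exon usage

FPKM is computed exactly as `count / (libsize/1e6) / (exonlen/1e3)` with
library size the column sum and exon length the summed exon widths of the
gene model; the output carries its inputs as provenance attributes so the
matrix can be re-derived bit-identically. Superclusters are
complete-linkage hierarchical clusters of per-gene mean-centered
log2(FPKM + 1) profiles, cut to exactly *k* = 8 groups; labels are
renumbered by first appearance so the assignment is invariant to
sample-column order. Any post-hoc merging of similar clusters is a
reporting decision left to the analyst; only the *k*-cut is computed.

No established method is prescribed for exon-level usage in this setting,
so the test is deliberately simple and exactly checkable: usage of an exon
in a replicate is its count divided by the gene total in that replicate;
usages are arcsine-square-root transformed (variance stabilisation for
proportions) and compared between conditions by a two-sided Welch
*t*-test, BH-corrected, with a ≥ 0.1 mean-usage-difference gate.
Replicates with a zero gene total are dropped; exons with fewer than two
usable replicates per condition are flagged untestable rather than given a
p-value; genes with a single exon are skipped. With three replicates per
condition the Welch test is slightly conservative (null p ≤ 0.05 rate
≈ 0.035 in the packaged calibration runs) — acceptable for a screen whose
hits are gated on effect size as well. Note that usage is compositional:
planting a usage shift in one exon necessarily shifts its sibling exons in
the opposite direction, and those compensatory changes are genuine
differential usage, not false positives.

## Duplicate genes and concordance

Duplication modes follow common synteny-tool practice using gene *ranks*
(position of a gene among the genes of its scaffold ordered by start): for
each duplicated gene the nearest same-cluster paralog on the same scaffold
decides the mode — rank distance 1 is tandem, 2 to `proximal_max_gap`
(default 10, configurable) is proximal, anything farther or on another
scaffold is dispersed; clusters of size one are singletons. For
overlapping gene models the rank order falls back to gene-id order, an
explicitly arbitrary but deterministic choice.

Concordance over a homologous set considers its DEG copies (label ≠ "·"):
the pattern key is the sorted direction string ("++", "+−", ...), and the
concordance fraction is the majority direction's share among DEG copies —
a tie gives 0.5 and can never reach the 0.8 threshold, so no tie-break is
needed. The "at least 80% concordant" statistic is computed over sets with
≥ 3 DEG copies with an inclusive ≥ 0.8 comparison, and an empty
restriction returns an explicit empty result rather than zero. DEG
direction labels are an *input* (their upstream thresholds are recorded in
the label file header); this package does not fit expression models.

## Spliced leaders and coding units

Trans-splicing attaches the 3′ end of the conserved 22-nt leader to the
transcript start, so assembled transcripts carry an SL *suffix* as a
prefix. `detect_sl()` aligns, ungapped, the longest SL suffix of length
≥ `min_match` (default 10) against the transcript 5′ end, IUPAC-aware on
the leader side, tolerating ≤ `max_mm` mismatches. Gapped alignment was
rejected: assembled transcripts are typically fragmented, and indel
tolerance would mostly admit chance matches. The leader sequence itself is
a configurable default taken from the literature.

Multi-CU gene models encode several near-identical full-length protein
copies separated by spacers. `segment_coding_units()` (1) collects exact
k-mer (k = 8) self-matches, (2) votes the dominant period p ≥ 50 residues
from the match offsets, (3) marks residues covered by matches at period p,
filters isolated matches (< 3 consecutive), and snaps run edges to the
periodic grid — a boundary residue class kept only if covered more than
twice, since a single chance pairing (two spacers sharing an end residue)
covers a class exactly twice — then (4) re-joins fragments split by
mutation holes (gap classes still covered by the other copies, unlike
spacer gaps), (5) builds a majority-rule consensus and accepts runs with
≥ 95% identity to it as complete units. Flanking fragments of ≥ 50% of the
consensus length matching a consensus prefix or suffix become N-/C-
terminal partial units; residues between accepted units are spacers, and
leading/trailing residues are reported separately as candidate leader
regions. If no period is found, or fewer than two units pass the gate, the
protein is one unit. The seed-chaining design assumes the high (> 95%)
unit identity typical of these gene models; copies diverged much beyond
that (e.g. 90% each to a common ancestor, ~81% pairwise) are deliberately
*not* segmented — they fall back to a single unit, which the identity gate
reports honestly.

`map_cu_to_exons()` converts residue intervals to CDS nucleotide
coordinates (×3, terminal stop excluded; a length mismatch is a frame
error) and intersects them with the model's CDS segments in transcription
order. `scan_motifs()` reports exact FVGA/FVAP hit positions, Ser+Ala and
Arg+Lys fractions, and mean Kyte–Doolittle hydropathy — reported, never
thresholded, since "moderately hydrophobic" is not a cutoff.

## The synthetic-data generator

`generate_dataset()` plants every feature class with ground truth. Its
defaults are the package's study conditions: six conditions (20/26/30 °C ×
exponential/stationary phase) × 3 replicates; background GC 59.7% and a
GT 24.7 / GC 51.5 / GA 23.8 donor mix with a 79.7% AG|G acceptor rate
(typical of a GC-rich dinoflagellate genome); fixed DNA/RNA coverages 20
and 10 (fixed rather than Poisson by default so filter-boundary tests are
exact; Poisson available by flag); editing fraction 0.4 on a random
half of the conditions per site; a 4.95% spliced-leader rate; CU gene
layouts of 4 + partial, 3, 2 and 1 units with unit length 100–150 aa and
Ser/Ala-rich spacers of 20–25 aa carrying exactly one FVGA; and a family
spec covering tandem, proximal and dispersed duplicates of 2–5 copies with
mixed DEG directions. A single master seed drives per-stage sub-streams
(fixed offsets), so outputs are byte-identical across reruns and
independent of stage order.

The generator guarantees unambiguous truth, verifying each constraint
before writing: planted inverted repeats are the only qualifying ones in
their introns and IE-negative introns scan negative (backgrounds are
redrawn otherwise); flanking blocker bases prevent chance repeat
extension; the leader's detection suffix never occurs in any transcript
body; spacers within a CU gene have pairwise-distinct boundary residues
(shared ones would make the unit/spacer boundary genuinely off-by-one
ambiguous); planted family placements are re-checked with the mode
classifier; supercluster prototypes are planted as counts proportional to
exon length so copies of a prototype have identical FPKM regardless of
gene length. Deliberate simplifications: no sequencing-error or read-level
simulation (pileups are generated directly, so mapping artefacts,
strand bias and duplicate reads are out of scope); DEG labels are planted
directly rather than simulated through a count model; gene and exon count
tables carry independent planted structures. Passing tests therefore
demonstrate correctness of the implemented procedures under their stated
assumptions, not robustness to alignment or library-preparation artefacts
in real data.

## Problem sizes and numerical choices

The packaged test and acceptance runs use desk-scale datasets chosen to
make every property exact: ~60–150 genes across 3–4 scaffolds, ~200
introns for recovery checks, 10,000 null and 500 planted editing sites,
~500 exons × 5 seeds for usage calibration, 50 protein constructions for
CU recovery, and full pipeline runs on the 64-gene demo configuration.
Fisher p-values are checked against an independent hypergeometric
log-binomial-coefficient sum at 1e−12 over an exhaustive small-margin grid
plus randomised larger tables; the editing score against a direct
log-likelihood evaluation at 1e−9. Ties in hierarchical clustering and in
repeat search are broken deterministically (first occurrence / leftmost),
and all tabulated outputs are written in canonical sort order so that
pipeline reruns are byte-identical.

## Known limitations

- The editing score is a surrogate statistic; thresholds tuned for an
  external caller's score scale do not transfer exactly.
- CU segmentation requires near-identical units and distinguishable
  spacers; identical spacers (or unit-terminal residues shared with spacer
  boundaries) shift boundaries by one, within the documented ±1 tolerance.
- The DEU test treats exons independently; within-gene usage fractions
  are compositionally coupled, so sibling exons of a truly shifted exon
  are expected to change in compensation.
- Rank-based duplication modes depend on gene-model completeness;
  unannotated intervening genes compress rank gaps.
- The generator does not emulate fragmentary transcript assembly, so
  spliced-leader recovery rates on real assemblies will be lower bounds.
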