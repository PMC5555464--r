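---
title: "Annotating transcript structure: promoters, first exons, splice events and their coding consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating transcript structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceform)
```

## The problem

Genes of the vertebrate *auts2* family span hundreds of kilobases and emit
many mRNA isoforms from multiple promoters. The raw observations are mapped
transcript 5′ ends (5′-RACE products, RNA-seq transcript models, RefSeq
annotations) and alternative transcript structures. Turning those into a
coherent locus annotation requires a handful of recurring decisions, each
with a simple operational rule. `spliceform` implements those rules as pure
functions over explicit data structures, so every decision is reproducible
and testable.

All coordinates in the package are 1-based and fully closed, the convention
of GFF3, IRanges and printed genomic intervals; a degenerate interval with
`start == end` covers one base. Minus-strand input is mirrored onto a
plus-strand working copy at load time so every downstream rule is written
once; `original_coords()` maps report positions back.

## Putative TSSs and promoter clusters

A mapped 5′ end is classified against the annotated exon/intron structure:

* at an annotated transcript start, or anywhere within a first exon —
  accepted (`annotated_start`); scattered starts around one promoter are
  expected, not noise;
* inside an intron or outside annotation — accepted (`intronic`); a
  transcript whose first nucleotide is annotated in an intron is evidence of
  a novel first exon;
* inside an internal exon — accepted, **unless** the 5′ end coincides exactly
  with an ATG trinucleotide, in which case it is rejected as a truncated-cDNA
  suspect. Reverse transcription that stalls at a translation start produces
  exactly this signature, so such candidates cannot be distinguished from
  artefacts; internal starts *not* on an ATG are kept, since genuine
  exon-internal promoters exist.

Accepted TSSs are clustered by single-linkage along the chromosome. The key
parameter, `separation_threshold` (default **500 nt**), encodes the
convention that TSS clusters driven by distinct promoters are separated by
more than 500 bp; a gap of exactly 500 merges (the rule is strict `>`).
Clustering is order-invariant, partitions its input, and its cluster count is
monotone non-increasing in the threshold — all property-tested.

Cluster *shape* is `sharp` when the TSS scatter (cluster width) is at most
`sharp_width_max` (default **62 nt**, the reported average range of TSS
scatter) and `broad` otherwise; sharp initiation is the signature of TATA-box
promoters, broad initiation of CpG-type promoters. The TATA scan looks for
the TATAWAWR consensus on the sense strand with the motif start in a
`[-40, -20]` window relative to the cluster's 5′-most member (the
representative); window and consensus are parameters because the underlying
literature fixes neither. Windows truncated by the contig edge are scanned as
far as they reach. A cluster is flagged *exonic* (a candidate exon-internal
promoter) when its representative lies strictly inside an internal or coding
exon **and** is more than the separation threshold from every annotated
start; nearer clusters are absorbed into that start's promoter. Where two
PAPs may overlap, the package reports both clusters and does not attempt to
adjudicate the overlap.

## First-exon taxonomy

Each alternative transcript's first exon is compared with the reference:

* **canonical** — starts within `first_exon_tolerance` (default 62 nt, the
  same TSS-scatter figure) of the reference start;
* **mutually_exclusive_first** — lies wholly inside a reference intron, with
  zero overlap of any reference exon (one shared base reclassifies it as an
  extension; this is the operative distinction between the two classes), and
  its donor joins a downstream reference acceptor, which becomes the anchor;
* **five_prime_extension** — starts in a reference intron and shares its 3′
  boundary with reference exon *N* (labelled "*N*L");
* **intron_retaining_first** — runs uninterrupted through one or more
  complete reference introns into the next exon; `retained_nt` counts the
  intronic nucleotides included.

A first exon that overlaps nothing and splices to no reference acceptor is
reported `unresolvable` with a warning rather than forced into a class;
structurally incomplete transcripts (e.g. when a 3′ end could not be
determined) are left incomplete rather than inferred.

## Splice-event diffing

`diff_transcripts()` compares intron chains over the transcripts' shared
region. First-exon differences are the first-exon classifier's business, so
for non-canonical first exons the comparison starts at the acceptor where the
alternative transcript first joins the reference. Differences between the
remaining introns are grouped into overlap components and each component is
typed:

* one alternative intron bridging complete reference exons with matching
  flanks → **skipped_exon**, one event per contiguous run, all ordinals
  recorded (`delta_nt` = −(skipped exonic length));
* a junction shift into the exon (excluding sequence) → **alt_donor** /
  **alt_acceptor** with negative `delta_nt`; a 3-nt acceptor shift is flagged
  NAGNAG-mediated when the tandem hexamer is present;
* a donor shift into the intron confined to the 5′-UTR →
  **cryptic_donor_utr** (it lengthens the UTR without touching the coding
  region; coding-region shifts of the same geometry are typed as retention);
* intronic sequence kept in the mature mRNA → **intron_retention**, whether
  a whole intron, several consecutive introns (one event; any subsumed
  reference exons are recorded, and `delta_nt` counts only the intronic
  nucleotides, since subsumed exons are present in both transcripts), or a
  partial run at either intron edge;
* a reference internal exon replaced by a disjoint novel exon between the
  same flanking junctions → **mutually_exclusive_pair**.

The invariant behind the whole engine: the sum of event `delta_nt` equals the
spliced-length difference over the compared region. Every diff asserts it and
stores the outcome in the `"conserved"` attribute; anything the vocabulary
cannot express degrades to a warning, never a silent misclassification.

NAGNAG detection itself is positional: the six intron-terminal nucleotides
ending at a given acceptor must match NAGNAG, offering two AGs 3 nt apart.
Nomenclature is fixed package-wide: the **proximal** AG is the acceptor
producing the longer mRNA (the hexamer's upstream AG), the **distal** AG the
shorter one.

Mutually exclusive pairs across a transcript *set* are found by a stricter
rule than pairwise diffing: two internal exons with disjoint intervals,
identical flanking junction partners, carried by disjoint transcript sets,
each present at least once.

## Coding consequences

Events outside the reference CDS are `silent_utr` (verified: the protein is
bit-identical). For CDS events with `delta` divisible by 3, `|delta|/3`
residues are deleted; when the excision is not codon-aligned the chimeric
junction codon is translated and a substitution is emitted only if the
residue actually changes — a synonymous chimera stays a plain deletion. The
substituted position is compared against the reference codon contributing
the majority (two of three bases) of the chimeric codon, which is how such
junction substitutions are conventionally described (the −6 nt construct
deletes Gly and Lys and substitutes Tyr→Asp, not the other way round). The
deleted run is placed leftmost when repeat context makes it ambiguous.

`delta % 3 ≠ 0` produces `frameshift_ptc`: the first downstream in-frame
stop becomes the premature termination codon, reported in spliced transcript
coordinates. The NMD flag uses the standard 50-nt rule — the PTC (first base
of the stop codon) more than `nmd_distance` (default **50 nt**) upstream of
the last exon–exon junction — and is advisory and configurable; no full NMD
model is attempted. In-frame retentions without a stop are reported as
`inframe_insertion`, a vocabulary extension for completeness; mutually
exclusive exon swaps are summarised as `exon_substitution` by whole-protein
prefix/suffix alignment.

ORFs come from the CDS annotation when present; otherwise translation runs
from the first AUG to the first in-frame stop (no Kozak scoring), matching
how ORFs are read off cloned cDNAs. No AUG, or no in-frame stop, is a
recorded non-coding call, not an error.

N-terminal truncation bookkeeping is by longest common suffix:
`shared_suffix`, `unique_n = len(alt) − shared`, `missing_n = len(ref) −
shared`, so `len(alt) = len(ref) − missing_n + unique_n` holds by
construction (and is asserted on all inputs). Pairs with no common suffix
are flagged `unrelated` rather than dropped. Published isoform pairs do not
always close this identity exactly — cases where an unannotated junction
effect or a donor extension changes the start codon can shift the count by a
couple of residues — which is precisely why the package recomputes the
arithmetic instead of trusting printed deltas.

## The synthetic-locus generator

`generate_locus()` realises a `locus_spec()`: a reference backbone whose CDS
is stop-free sense codons (ATG…stop), random introns forced to GT…AG, and
one alternative transcript per planted feature, with truth records for the
first-exon class, the event (kind, ordinals, signed delta, NAGNAG flag) and
the consequence category. Constructs are engineered at the codon level:
exon boundaries sit on codon boundaries by default, so planted excisions are
codon-aligned; the −6 nt substitution construct shifts one exon's phase and
plants the codons GGT·AAA·TAT across the junction so that the excision
leaves the chimeric codon GAT (Gly/Lys deleted, Tyr→Asp); excluded donor
blocks begin GT and excluded acceptor blocks end AG so every alternative
junction is a plausible splice site; retained intronic heads/tails carry an
in-frame planted stop so retention isoforms always truncate. Lookalikes that
would create unplanted features — exon-initial NAG codons (phantom NAGNAGs),
upstream AUGs in UTRs and novel first exons, TATA motifs in promoterless
cluster windows — are scrubbed. The generator back-checks its own output
(GT/AG at every junction of every isoform, reference protein length,
premature stops in retention isoforms) before returning, and identical seeds
give byte-identical FASTA/GFF3/JSON.

Planted TSS tags are placed exactly as specified so cluster widths are
deterministic; a jitter option exists for property tests. Defaults emulate a
mid-size vertebrate gene: exons 90–180 nt, introns 550–900 nt, 150/120 nt
UTRs; `preset_auts2a_like()` scales this to 19 exons with five novel
mutually exclusive first exons, six 5′-extension exons, NAGNAG acceptors at
exons 3/8/15, a −21 nt donor at exon 9, and 38-nt and 745-nt retentions
(the larger spanning two introns and subsuming the exon between them).

What the generator does **not** emulate: realistic base composition or CpG
islands, expression levels, sequencing noise, truncated-cDNA artefacts, or
alternative polyadenylation. Passing the round-trip suites therefore shows
the *rules* are implemented correctly and consistently, not that the rules
themselves are complete for every real locus.

## Numerical and design choices

* Strict `>` threshold gap rule; ties merge. Cluster representative = 5′-most
  member. Leftmost TATA hit reported.
* Canonical-first tolerance, sharp/broad cutoff and the exonic-TSS distance
  all reuse the same two literature figures (62 nt scatter, 500 nt
  separation) rather than introducing new constants; all are arguments with
  those defaults, nothing is hard-coded.
* Degenerate inputs: empty evidence → empty cluster list; single-position
  cluster → width 0, sharp; transcripts with no overlap → empty diff plus a
  warning; identical transcripts → empty diff.
* Test and acceptance problem sizes: hand-built loci of 3–8 exons for unit
  oracles; 100 random 14-exon specs (one feature per disjoint two-exon
  block, so any draw is valid) for the round-trip suite; exhaustive
  enumeration for the 4096 NAGNAG hexamers and 65536 TATA 8-mers. The full
  suite runs in well under a minute on one CPU.

## Limitations

3′-end variation is deliberately out of scope (transcripts are compared over
their shared region); no splice-site strength scoring; no CpG-island or
promoter sequence model beyond the TATA scan; assembly gaps are not modelled
— each locus is assumed to live in a single consistent coordinate frame; the
NMD flag is a convention, not a prediction of decay.
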