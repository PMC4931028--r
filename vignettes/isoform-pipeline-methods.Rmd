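---
title: "Methods: long-read isoform reconstruction and APA detection"
author: "isopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read isoform reconstruction and APA detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures behind `isopipe`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not establish about real
data.

## Coordinate model

All internal coordinates are 0-based half-open (`[start, end)`), on a
single convention across every module; 1-based inclusive coordinates exist
only at the GFF3/GTF boundary (BED is already half-open). A cleavage
position is the 0-based coordinate of the last transcribed nucleotide.
This removes the main source of off-by-one drift in multi-module genomic
code.

## Reference-guided error correction

Long cDNA reads carry a per-nucleotide error around 2–3%, dominated by
short indels. Because the downstream analysis is entirely junction- and
end-driven, correction only needs to repair the read *against its own
alignment*: mismatched bases are replaced by the reference base, inserted
bases removed, deleted reference bases re-inserted; soft-clipped sequence
(adapter remnants, poly(A) tails) is never touched.

The subtlety is at splice junctions: an indel near a junction may be the
*cause* of a misplaced junction, and correcting it against a wrong
alignment would lock the error in. The pipeline therefore runs two
align/correct iterations: in the first, edits whose reference footprint is
within `junction_mask_width` (default 10 nt) of a block boundary adjacent
to an intron gap are left uncorrected; after realignment the second
iteration corrects everything. The mask width is a tunable with no
canonical value — 10 nt comfortably covers the anchor length within which
spliced aligners misplace junctions, while leaving the bulk of the read
correctable. Reads are realigned after every round, and correction output
depends only on (alignment, genome), which makes repeated application with
the same alignment idempotent.

The error profile estimator uses aligned reference nucleotides of primary
alignments as the shared denominator (the natural choice given that
deletions consume reference but not read bases); insertions count inserted
bases, deletions count deleted reference bases, so the three rates add up
to the reported total.

## Splice-junction filter

The junction filter replaces a trained splice-site classifier with a
transparent model: per-position log-odds matrices over a donor window of 3
exonic + 6 intronic nt and an acceptor window of 14 intronic + 3 exonic
nt, estimated from all distinct annotated introns with +1 pseudocounts
against the training windows' own base composition. Junctions must carry
one of the canonical terminal pairs GT–AG, GC–AG, AT–AC, and score at or
above the 5th percentile of training-junction scores — so ≥ 95% of
annotated junctions pass *by construction*, for any annotation. Rejection
is read-level and all-or-nothing: one failing junction discards the whole
alignment, which matches read-based accounting of the filtering cascade.
Deduplicating shared introns before training prevents highly expressed
gene structures from dominating the matrices.

The cascade order is junction filter → strand assignment → multi-mapper
separation, and the report carries the count at every stage. Narrative
descriptions of such cascades sometimes order stranding before junction
filtering; the counts for both stages are reported so either reading can
be reconstructed.

## Strand assignment

Libraries primed with oligo-dT carry the transcript's 3′ end, so a
trailing soft clip that is ≥ 80% A over ≥ 5 nt assigns the `+` genomic
strand (leading poly(T) ⇒ `-`). The thresholds are deliberately permissive
for long reads, whose clips contain primer remnants; the strict rule (clip
consists entirely of the homopolymer) is available via `min_purity = 1`
and is appropriate for EST evidence. A contradiction between tail-derived
strand and an upstream platform strand call makes the read unassignable —
the conservative choice, since both signals are individually fallible.
Unassignable reads and multi-mappers are excluded from isoform assembly
but retained in the report so that reads are conserved across terminal
bins.

## Isoform collapsing

Within a single-linkage overlap cluster, isoform identity is the intron
chain. Three merge rules apply, to transitive closure: identical chains
merge; a chain that is a proper 3′-terminal suffix of another merges into
it (long-read 5′ truncation); and differences confined to the downstream
boundary of the 3′-most exon never separate isoforms, because 3′-end
scatter is polyadenylation, not splicing. "3′-terminal" is strand-aware
(rightmost introns on `+`, leftmost on `-`).

Unspliced reads are a design decision the merge rules do not settle: they
are absorbed into a spliced isoform only when they lie in its 3′-terminal
exon region (downstream of its last intron, overlapping the terminal
exon) — the APA-compatible case — and otherwise form one intronless
isoform per cluster. Ties (several equally supported candidates) resolve
to the isoform with the lexicographically smallest chain, which keeps the
partition independent of read input order; a property test permutes input
order and asserts identical partitions, and a brute-force closure oracle
checks the whole procedure on random clusters.

One structural consequence of the suffix rule is worth knowing: retention
of a gene's *5′-most* intron produces a variant chain that is a 3′ suffix
of the base chain and is therefore folded back into the base isoform.
That is inherent to truncation-tolerant collapsing, not an implementation
artifact; the simulator consequently plants intron-retention events on the
3′-most intron.

The representative transcript takes the supporting read with the most
exons (ties: longer aligned span, then read id), extends its first exon to
the 5′-most supported coordinate and sets its 3′ end to the 3′-most
supported cleavage site. Gene association requires ≥ 1 nt of *exonic*
overlap on the same strand (default) so that intronic novel transcripts
are not absorbed by their host gene — `mode = "genic"` restores plain
span overlap for comparison. Isoforms spanning two or more genes are
flagged and excluded from splice-event analysis; isoforms overlapping
none are novel-gene candidates. A full-length isoform is one whose
5′-most exon starts within the annotated first exon of its gene
(strand-aware).

## Splice graphs and AS events

Per locus, exon intervals become nodes, observed consecutive exon pairs
become edges, and each isoform is a path. Events:

* **intron retention** — an intron of one path lies entirely within an
  exon of another;
* **exon skipping** — an exon of one path is absent from another path that
  carries a bridging intron fully spanning it (mere absence is not enough:
  terminal truncations must not count as skipping);
* **alternative 5′/3′ splice site** — two introns of different paths share
  one junction and differ at the other, *and* the flanking exons on the
  differing side overlap. The exon-overlap condition is essential: without
  it every exon-skipping bridge would also emit one alternative-donor and
  one alternative-acceptor event.

Naming is transcript-oriented (the donor is the 5′ side), so the same
geometry is alt-5′ on `+` and alt-3′ on `-`. Events are deduplicated by
(type, defining coordinates), i.e. an event shared by several isoform
pairs counts once — event totals are coordinate-level counts. An
exhaustive pairwise-path oracle validates the graph implementation on
random graphs of ≤ 5 isoforms.

## Poly(A) clustering and APA

Candidate cleavage sites are tail-supported read ends. Per gene, the
greedy procedure computes each candidate's depth as the number of read
ends within `window` nt (default 5, read as |p − s| ≤ 5; the narrower
total-width-5 reading is one parameter away), repeatedly accepts the
deepest candidate (ties toward the smaller coordinate) provided its depth
is ≥ 2 and it is not within 15 nt of an accepted site, and removes it
from the candidate list. The 15-nt spacing absorbs microheterogeneity —
small biological and alignment scatter around one true site. A brute-force
transcription of this loop serves as the oracle for an exhaustive
small-case sweep. One consequence of the leftward tie-break worth noting:
when all read ends of a site fall inside one window, every candidate ties
at maximal depth and the representative settles on the smallest observed
end, i.e. a nucleotide or two left of the mode under symmetric jitter.

Classification against the coding region uses the START/STOP pair that
minimizes total UTR length when a transcript carries several annotated
codons (per gene by default; a per-site mode exists because the
minimization could equally be read per site). Genes without annotated
codons are `unclassified`. Internal priming is flagged when the 10 nt
immediately downstream of the cleavage site contain ≥ 7 genomic A's; a
window truncated by the chromosome end scales the threshold
proportionally. A gene with ≥ 2 accepted clusters shows APA; its
preferred site must hold a *strict* majority (> 50%) of the gene's
clustered poly(A) reads. The nucleotide-composition profile and the
positional motif counter orient every window to the transcript strand, so
signals such as AATAAA appear at their true upstream offset regardless of
gene orientation.

## Novel genes and lncRNA

Clusters whose isoforms associate with no annotated gene are novel loci,
represented by their longest read. The lncRNA rule is: spliced transcript
length ≥ 350 nt and no ORF > 100 amino acids (ORFs scanned ATG→stop on
the transcript's own three forward frames — reads are already stranded by
their tails; length excludes the stop codon, and an ATG without an
in-frame stop does not count). A stricter published variant of the same
idea — no ORF > 200 nt, without the length gate — is available as
`variant = "orf200"`; the amino-acid rule is the default because it is the
more specific statement of the two. Whether the 350-nt gate applies to
spliced or genomic length is ambiguous; spliced length is used, being the
molecule's actual length. Fused-annotation evidence (one assembly bridging
≥ 2 genes) and entangled-annotation evidence (one gene overlapped by ≥ 2
disjoint assemblies) are reported separately.

## Synthetic data: what it emulates, and what it does not

The generator plants, per gene: 3–6 exons of 120–300 nt, introns of
80–400 nt with the full extended consensus `CAG|GTAAGT …
TTCTTTTTTTTCAG|GTT` at every junction, a CDS anchored by planted ATG/TAA
codons with 60/160-nt UTRs, 1–3 poly(A) sites 50 nt apart in the 3′ UTR
(the 3′-most carrying 60% of reads), AATAAA planted 25 nt upstream of 80%
of sites, and a ±2-nt cleavage jitter to exercise microheterogeneity. One
AS event per selected gene (3 IR, 2 ES, 1 alt-5′, 1 alt-3′ by default)
creates an alternative isoform withheld from the annotation. Reads carry
the error model at mismatch 0.64%, insertion 1.07%, deletion 0.63% with
geometric indel lengths of means 1.23/1.16 — the per-event rate is the
base rate divided by the mean length, so base-level rates are preserved.
Tails are 15–40 nt. Every read's source isoform, chosen site, injected
errors and tail length are recorded, and the true alignment of every read
is emitted, so downstream stages are testable without an aligner.

Deliberate simplifications: junction consensus is fixed (real splice
sites vary, so a threshold calibrated at the 5th percentile would drop up
to 5% of genuine junctions on real data); background sequence is i.i.d.
uniform (no repeats, so multi-mapping is exercised only via the optional
gene-duplication switch); error injection avoids block edges by 1 nt so
the truth alignment keeps the planted block structure; no chimeras, no
quality scores, no expression-level variation beyond per-isoform read
counts. Passing the closure tests therefore demonstrates the *logic* of
the pipeline — coordinate bookkeeping, merge rules, greedy clustering,
classification — at realistic error rates, not robustness to repeat-rich
genomes or degenerate splice sites.

## Problem sizes and numerical choices

The test suite and the acceptance script run 20-gene genomes (~50 kb,
~150–220 reads of ~1 kb), sizes chosen so a complete run including two
minimap2 iterations takes seconds on a laptop while every rate estimate
stays within tight sampling error of its generating value (at 150–200 kb
of aligned sequence, the binomial standard error of a 1% rate is ~0.025
percentage points). All randomness flows from a single mandatory seed;
the analysis path itself is deterministic, and stage outputs are cached
so interrupted runs resume. PWM scoring treats `N` as a zero-contribution
base; profile columns renormalize over non-N bases; sites closer than the
flank to a chromosome edge are skipped and counted rather than silently
truncated.

## Known limitations

No abundance estimation beyond supporting-read counts; no
percent-spliced-in; no mutually-exclusive-exon or alternative-first/last
exon classes; no EM rescue of multi-mappers; no reference-free
correction. The aligner adapter shells out to an external program — the
pipeline's own contribution starts at the SAM it returns.
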