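---
title: "Methods: desk-scale de novo transcriptome assembly and annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale de novo transcriptome assembly and annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`isotigr` reconstructs and annotates a transcript catalogue from short
paired-end RNA-seq reads without a reference genome, the situation typical of
non-model insects such as tephritid fruit flies. The workflow is the classic
short-read one: filter reads on a 5' quality window, build de Bruijn graphs at
several odd word sizes k, render unbranched paths as contigs, enumerate paths
through bubbles as isotigs (putative splice forms) grouped into isogroups
(putative genes), keep the k = 31 assembly and admit isotigs from other k only
when they carry a protein homologue not seen before, then annotate: best
homologues by translated local alignment, assembly completeness against the
nearest homologue, per-base read-mapping coverage, EC-group enzyme prediction
confirmed by catalytic-site motifs, collapsing of redundant isotigs into
putative genes, and translated scans for insecticide target-site genes.

Every stage is exercised on synthetic data with recorded ground truth, so the
pipeline's claims are tested end to end without downloads.

## Read filtering

A read is kept only if at least 25 of its first 35 bases have Phred quality
strictly above 30, and it contains no uncalled base (`N`) and no configured
adapter as an exact substring. The comparison with 30 is strict and the count
threshold inclusive; reads shorter than the 35-base window are rejected
because the rule is undefined for them. Input qualities are Phred+33 by
default with a configurable offset for legacy data. Pairs where both mates
survive stay paired; lone survivors are kept as single reads, mirroring the
paired/short channels of de Bruijn assemblers. Whole reads are filtered, never
trimmed.

## Assembly

Graphs store *oriented* k-mers: every k-mer of the reads and of their reverse
complements. Odd k guarantees no k-mer is its own reverse complement, so each
contig is discovered once per strand and deduplicated by its canonical
(lexicographically smaller) form. Edges are observed (k+1)-mers — adjacencies
actually supported by a read — rather than all possible overlaps, which keeps
spurious joins out of error-free simulations. Contigs are maximal unbranched
paths after pruning k-mers below `min_count` (default 1, matching reported
contigs near raw-graph length). Isogroups are connected components of the
contig graph; isotigs are source-to-sink paths, enumerated depth-first with a
configurable cap of 16 per isogroup and ranked by length-weighted mean k-mer
coverage. Bounded enumeration replaces transitive-reduction machinery; a
two-branch bubble yields exactly two isotigs in one isogroup. Tip clipping
and bubble popping are deliberately absent: the test conditions use
error-free reads, and heuristic error correction would only obscure the
properties under test.

## Homology and the multi-k merge

Translated alignment is exact local dynamic programming (Smith–Waterman,
affine gaps) over all six reading frames, with BLOSUM62, gap open 11 and
extend 1. A shared-peptide-word prefilter limits which frame/subject pairs
are aligned: a subject becomes a candidate when it shares at least two
distinct 5-residue words with the frame translation (one word suffices for
frames shorter than 40 residues). This is the same tradeoff as BLAST's
two-hit heuristic: a >60-residue alignment at 60% identity or better shares
two 5-mers with its subject except with negligible probability (expected
shared words ≈ 5-25), while chance single-word candidates — which dominate
runtime against databases of hundreds of proteins — are skipped. Alignments
near the detection floor (~35% identity) can be missed by the prefilter;
lower `word_size` for such searches. E-values use the ungapped
Karlin–Altschul statistic E = K·m·n·exp(−λS) with λ = 0.318, K = 0.13 and the
database residue count as size factor — an approximation applied to gapped
scores, chosen so the conventional 1e−5 cutoff behaves comparably to heuristic
search tools. An isotig's homologue is the subject with the smallest E-value
among alignments strictly longer than 60 residues with E < 1e−5; ties break
by higher score, then lexicographic subject id.

The merge rule keeps the base k = 31 isotig set in full and admits an isotig
from another k only when its homologue is new — absent from the base set and
from sets merged earlier. Non-base k are processed in ascending distance from
31, ties toward the smaller k; the order is declared and configurable because
per-k "additional homologue" counts depend on it.

Known-mRNA validation passes a pair when the best local nucleotide alignment
(either strand) has identity above 95% and covers more than 80% of the isotig
length. Sequences with internal poly-N runs are split and checked for
consistency: all segments must hit one protein with subject coordinates in
segment order (reversed for minus-strand frames). Target-site gene scans
align six query frames against six reference frames and report per-HSP
identities, flagging those above 90% and keeping the best sub-threshold
identity visible.

## Coverage and completeness

Mapping is exact-seeded and gapless: each read is anchored by 21-mer lookups
at its ends, scored by full-length mismatch count, and discarded below 95%
identity. Each read gets exactly one placement — best identity, ties broken by
(isotig id, position, forward strand) — so total depth equals total mapped
bases. Completeness of an isotig is the aligned fraction of its nearest
homologue (aligned subject span over subject length, capped at 1); the
alternative convention, isotig length in codons over subject length, is
exposed as an option since the denominator units are a genuine ambiguity.
Records binned by completeness into ten 10-point bins (left-closed,
right-open, 1.0 in the top bin) report counts and median coverage; on
lognormal-expression simulations the median coverage rises monotonically with
completeness, reproducing the expected relationship between expression and
assembly contiguity.

## Enzyme prediction and gene collapsing

An isotig is assigned to the EC group of its closest enzyme (smallest
E-value under the same homology thresholds). When top hits disagree on EC and
their E-values are within a factor of 10 of each other — the declared
criterion for "no clear ranking" — catalytic-site motifs arbitrate: if exactly
one competing EC group has a motif matching some frame translation, it wins
and the prediction is motif-confirmed; otherwise the minimum-E choice stands,
flagged unresolved with competitors listed. The bundled motif library holds
the literature motifs `FxxGxRxCxG` (P450), `SxAI`/`TxAI` (GST), `GxSxG`
(carboxylesterase), `SEDCL` (acetylcholinesterase) and the flexible-gap GST
signature `PxLxD-x(7,10)-SxAIxxYLxxK`. Motif grammar: uppercase letters are
fixed residues, `x` any single residue, `x(m,n)` a bounded gap, `-` cosmetic;
wildcards and gaps never match a stop, so matches cannot cross stop codons.
Matching reports every admissible start position, overlapping matches
included.

Redundancy is resolved in two steps. Within each (EC group, shared nearest
homologue) set, only the highest-coverage isotig survives, ties by longer
isotig then id. Isotigs sharing a nearest homologue then collapse into one
putative gene; within a gene, alignments overlapping reciprocally by at least
20% count as isoform candidates of one transcript unit, while mutually
non-overlapping alignments are fragments (one gene, several units). The 20%
reciprocal threshold turns the binary notion of "non-overlapping" into a rule
robust to few-residue accidental overlaps. Family labels (Cyp clades, GST
classes, esterase classes) come from a user-supplied annotation of the
reference enzymes, not from phylogenetics.

## The synthetic-data generator

Transcripts are 5' UTR + CDS + 3' UTR; the CDS is a start codon, exon-sized
blocks of sense codons (no internal stops) and a stop codon, with an in-frame
stop planted just upstream of the start so the recorded CDS is exactly the
longest ORF. With configurable probability a gene emits a second isoform
skipping one internal block — frame-preserving, and the source of the bubble
structures the isotig builder must resolve; blocks are at least 60 bp, so
isoforms always share a run longer than the largest k (41). Expression is
lognormal (meanlog 0, sdlog 1.2 by default), reproducing the skewed abundance
of real transcriptomes. Reads are 90-base pairs from fragments of mean 200 bp
(sd 15), drawn per transcript proportional to expression × length, with
position-dependent Phred scores decaying from 39 at the 5' end to 25 at the
3' end (sd 3, clamped to [2, 41]) — high enough that the window filter passes
typical reads and fails degraded ones. Substitution errors and uncalled bases
are injected per base at configured rates; adapter events shorten the
fragment below the read length so the read runs into a configurable adapter.
A "tiled" mode lays fragments at a regular stride with both transcript ends
covered: exact-reconstruction experiments are impossible when ends are never
sequenced, as happens under multinomial sampling. Protein databases are
longest-ORF translations with random substitutions to a controlled identity;
reference genes for target-site scans are nucleotide copies diverged the same
way. Every generator derives its randomness from the configuration seed, and
identical configurations produce byte-identical FASTA/FASTQ.

The generator does not model real Illumina error spectra, GC bias, indels,
intron retention, or any particular species' gene catalogue; green tests
demonstrate algorithmic correctness under controlled conditions, not
performance on real libraries.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale versions of the study conditions:
10,000 reads for the filter-oracle equivalence; 200 transcripts (300–600 bp
CDS) at ~30x tiled coverage for exact reconstruction; a 500-gene
lognormal-expression simulation at ~20x for the completeness/coverage
relationship; 1,000 random length multisets for N50; 200 random peptide pairs
(length ≤ 50) for the alignment oracle; 100,000 random residues per motif for
the matcher/regex equivalence. The default pipeline sweeps k over odd 21–41
anchored at 31, with every stage threshold (25/35/Q30, >60 aa, E < 1e−5,
95%/80%, 90%) visible and overridable in `pipeline_config()`. Degenerate
inputs are defined rather than accidental: empty read sets give empty graphs,
empty sequence sets give all-zero statistics, reads shorter than the window
fail filtering, sequences shorter than a codon translate to empty frames with
a message.

## Known limitations

The assembler performs no scaffolding, no coverage-cutoff estimation and no
error correction, so it is not a replacement for production assemblers on
noisy data; path enumeration caps at 16 isotigs per isogroup and reports
truncation. E-values are approximations, comparable across runs of this
package but not numerically equal to any other tool's. Mapping is gapless and
single-placement, adequate for depth accounting but not for variant-aware
analyses. Translated-scan identities are per-HSP, not aggregated across HSPs.
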