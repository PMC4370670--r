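---
title: "Methods: APA gating of intronic miRNA host-gene feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APA gating of intronic miRNA host-gene feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

An intronic miRNA is co-transcribed with its host gene. If the host's 3′UTR
contains a seed-match site for one of the miRNA's mature arms, the locus is a
self-repressing unit: we call such arms host-targeting (HT), all other
hosted arms non-host-targeting (NT). Alternative polyadenylation (APA)
modulates this loop: a 3′UTR with several cleavage/poly(A) sites can be
transcribed as a short isoform that lacks the binding site or a long isoform
that retains it. The package quantifies every in-silico step of that
argument: seed-site detection, cleavage-site discovery, poly(A)-signal
positional bias, differential UTR-isoform usage between two conditions, and
enrichment of APA-machinery genes among HT-miRNA targets.

## Coordinates, alphabets, conventions

* Internal coordinates are 0-based half-open; GFF3 I/O converts from/to
  1-based inclusive; BED output stays 0-based. Human-facing tables report
  1-based positions.
* UTR and mature sequences are RNA (T→U on load); the genome stays DNA.
* "Longest annotated transcript" means maximal genomic span (not summed exon
  length), ties broken by lexicographically smallest transcript id — a
  deterministic reading of an otherwise ambiguous phrase.
* Cleavage positions are boundaries: on "+" the 0-based index after the last
  templated base, on "−" the index just 5′-genomic of it. With this
  convention a site's UTR offset equals the retained isoform length on both
  strands, and a site at the annotated transcript end is inside the
  transcript.
* When several genes contain a miRNA locus we prefer a same-strand host,
  then intronic over exonic containment, then the smallest containing
  intron, then the smallest gene id; alternates are reported.

## Seed matching

A 7mer-m8 site is a UTR 7-mer equal to the reverse complement of mature
nucleotides 2–8 (1-based); a 7mer-A1 site is the reverse complement of
nucleotides 2–7 followed by an adenine on the UTR. All occurrences are
reported, overlaps and duplicates included; a position satisfying both
definitions (possible only when nucleotides 2–8 are all U) is reported once
as 7mer-m8. No 6mer/8mer classes and no context scoring are implemented:
the two 7-nt rules are the entire definition. An arm is HT iff it has ≥1
match in its host's 3′UTR; a host without an annotated 3′UTR yields an NT
call with a warning rather than an error. Genes hosting both HT and NT arms
belong to the HT host-gene set in cohort comparisons ("HT host gene" reads
as "gene hosting ≥1 HT arm").

## Cleavage-site discovery

EST-style evidence requires a terminal soft-clip A-run of more than 10
nucleotides (≥11, with no non-A contamination inside the run — a literal,
configurable reading). The run must be untemplated: if the genomic A-run at
the cleavage is at least as long as the clip run, the read is discarded as
templated. The internal-priming filter then inspects the 20 genomic
nucleotides downstream of the cleavage in sense orientation and rejects the
site when they contain ≥12 adenines or an A-run of ≥6. These two window
parameters follow common poly(A)-site-calling practice; the upstream
protocol this filter stands in for is not specified precisely in the source
material, so both are exposed as arguments. RNA-Seq evidence generalizes a
colorspace two-untemplated-zeros rule to base space: a position is supported
when ≥2 reads each carry ≥2 untemplated terminal adenines and at least two
supporting reads differ in aligned length.

Evidence positions are clustered per gene by single linkage with a 40-nt
link distance. The representative is the member with maximal support, ties
resolved to the most proximal member (closest to the CDS). Clustering is
idempotent and conserves total support. Only sites within the gene's
longest annotated transcript are kept.

## Differential 3′UTR usage

With K sites at UTR offsets s₁ < … < s_K, poly(A) region k spans
(s₍ₖ₋₁₎, s_k], region 1 anchored at the UTR start. A read belongs to the
region containing its 3′-most aligned base; spans are right-closed, so a
read ending exactly at a site counts toward the isoform that ends there.
Region counts are tested with a two-sided minimum-likelihood binomial test
of x = study count out of n = study + control against
p0 = lib_study/(lib_study + lib_control); this library-size parameterization
is our choice where the source is silent (per-gene normalization is the
alternative). BH correction is applied across all tested regions in one
genome-wide family at α = 0.05 — the family actually tested — rather than
per gene. Genes need ≥20 total reads (configurable; no published value
exists) and both a significant up- and a significant downregulated region
to be called; the call is *longer* when the median index of upregulated
regions exceeds the median of downregulated ones and *shorter* otherwise,
with exact median ties called shorter (the literal "otherwise") and
flagged `tie = TRUE`. Medians of even sets are midpoint medians and may be
fractional.

Two properties bound what the caller can do: swapping conditions (counts
and library sizes) flips every non-tied call, and scaling all counts and
both library sizes by a common factor preserves the direction of every
significant region — though it can promote borderline genes into the called
set, since statistical power grows with depth.

## Statistics

The two-sided binomial and Fisher tests use the minimum-likelihood
("small-p") convention of standard statistical software; these and BH
adjustment are delegated to R's stats primitives behind the package API.
The Mann–Whitney U test enumerates all C(n₁+n₂, n₁) group labelings when
n₁+n₂ ≤ 14 and reports min(1, 2·min(P(U ≤ u), P(U ≥ u))) — well-defined
under ties, where the permutation distribution need not be symmetric —
and otherwise uses the normal approximation with midrank tie correction
and continuity correction. The exact/approximate boundary is an argument.

For the APA-machinery enrichment the default BH family is the set of genes
in one comparison (11 genes for the packaged fixture); a joint family
across two comparisons is obtained by row-binding counts into one call.
The packaged fixture records only the HT (n = 203 arms) and NT (n = 601)
cohorts; the intergenic cohort size is unpublished, so that comparison is
not testable from the fixture and no denominator is invented. The exact
family behind the published q-values cannot be reconstructed, so tests
assert family-robust facts only: CPSF2 attains the minimum p and is the
only gene with q < 0.05 in the 11-test family.

## The simulator: what it emulates, what it does not

`generate_cohort()` builds one synthetic chromosome of alternating-strand
two-exon genes (intronic miRNAs in the single intron), plants exact
7mer-m8 sites for HT arms, rejection-samples NT arms to zero matches
against the final UTR, plants canonical signals (uniformly in HT hosts, in
the distal 20% elsewhere under `distal_biased`), and places evenly spaced
cleavage sites whose downstream windows are overwritten with an A-poor
sequence so genuine sites pass the priming filter; decoy loci get an
A-rich window that must fail it. Region counts are multinomial with a
distal-heavy baseline; a planted *shorter* shift moves an `effect_size`
fraction of distal mass proximally (and conversely). Defaults mirror the
study conditions at desk scale: a 2:1 control:study library ratio
(scaled down from ~100M vs ~50M reads), effect size 0.3, 500 reads/gene,
5 tail reads/site, 2–4 sites per UTR ≥ ~150 nt apart. Everything is
byte-deterministic under `rng_seed`.

The simulator does **not** emulate real genomes: no sequence composition
bias, no overdispersion (the binomial test assumes at most Poisson-like
noise and there is one library per condition; an overdispersion hook would
be the first extension for replicated designs), no sequencing errors beyond
untemplated tails, no multi-isoform annotation, no antisense hosts. Passing
recovery tests therefore demonstrates correctness of the algorithms under
their own assumptions, not performance on biological data.

`zfr_like_fixture()` deterministically reconstructs the geometry of the
worked biological example — a minus-strand 20-exon host with a 1409-nt UTR,
its miRNA in intron 11 (4722 nt long, 684 nt from the upstream exon), a
seed match at UTR position 1301, signals at positions 135/314 (AUUAAA) and
738 (AAUAAA), and three cleavage sites all upstream of the match, so only
the longest isoform is repressible. It is synthetic sequence built to that
geometry, not the real gene.

## Problem sizes and scale

Tests and the acceptance script run at desk scale: enumeration-oracle
sweeps up to total size 12, 1,000 random UTR/mature scanning pairs, 200-gene
shift-recovery and null-calibration cohorts, a 25-gene site-recovery cohort
with 25 priming decoys, and a 600-gene signal-position cohort yielding
~10,000 scanned hits per side. Genome-wide cohort statistics (hundreds of
HT/NT arms, kilobase median UTR contrasts, thousands of called genes)
require the original RefSeq, miRBase, EST, external poly(A)-site and
deposited RNA-Seq inputs; the pipeline accepts such inputs through the same
loaders, but nothing in this repository reproduces those numbers and the
desk-scale outputs always carry their own cohort sizes in the provenance
headers so the two cannot be conflated.

## Known limitations

* The EST internal-priming parameters are field-standard stand-ins, not the
  original protocol's.
* "Preceded by a canonical signal" is implemented as any motif wholly 5′ of
  the seed match (abutting counts); a stricter coupling of the signal to an
  upstream cleavage site would be a reasonable alternative reading.
* Multi-UTR annotation is reduced to the longest transcript's 3′UTR.
* Read-to-gene assignment for cleavage evidence uses the longest-transcript
  span; overlapping genes on the same strand would need disambiguation
  rules the simulator never exercises.
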