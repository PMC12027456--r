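---
title: "Methods: locus-centric PAV genotyping, haplotype typing and editing design"
author: "locuspav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-centric PAV genotyping, haplotype typing and editing design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locuspav)
```

## The problem

Whole genes can be present in some accessions of a species and absent in
others (presence/absence variation, PAV). The rice heading-date regulator
*Ghd7* is a canonical case: a compound structural variant of roughly 60 kb —
a gene-spanning deletion interleaved with inversions and substituted blocks —
removes the gene entirely in a substantial fraction of cultivars, and within
gene-carrying accessions a spectrum of SNPs, small indels, premature stops
and splice-site mutations further modulates function. Characterising such a
locus requires several coordinated analyses: comparing the few available
high-quality assemblies against the reference to delineate the variant
structure; genotyping the deletion in thousands of short-read datasets where
assembly is impossible; validating calls with a cheap PCR assay; typing the
gene-region haplotypes of the non-deleted accessions; interpreting their
variants mechanistically; and, for a chosen causal variant, designing the
prime-editing reagents that would correct it. `locuspav` implements this
workflow as a set of composable stages over a single shared coordinate frame,
the `gene_locus` (a reference segment, its single-transcript gene model, and
an `origin_offset` mapping segment positions onto the source chromosome).

## Dot-plot structural-variant inference

Assemblies are compared to the reference segment by exact k-mer anchoring:
all maximal runs of consecutive shared k-mers (forward and
reverse-complement) are merged into anchors, the dot-plot's dots and lines.
At locus scale (~10^5 bp) exact anchors are a faithful stand-in for a
seed-and-extend aligner: any homologous block longer than k that is free of
differences contributes an anchor, and the blocks that matter here (conserved
flanks, inverted or substituted segments of hundreds of bp to tens of kb) are
orders of magnitude longer than k.

Parameters:

* `k = 16` (minimum 8). At 16 the expected number of chance k-mer hits
  between two random 120 kb sequences is a few; at the default it is the
  anchor-length filter that removes them.
* `max_occ = 8`: k-mers occurring more often than this in either sequence are
  skipped, a simple repeat mask.
* `min_len = k + 8`: anchors must contain at least 9 consecutive shared
  k-mers. A chance exact match of 24 bp between unrelated 120 kb sequences
  has expectation ~5·10^-5, so spurious anchors — which could otherwise split
  the deletion gap — are effectively excluded, while real homologous blocks
  are unaffected.

Anchor chaining is a weighted longest-increasing-subsequence over forward
anchors (weight = anchor length, ties toward the smaller reference
coordinate). The deletion span is the maximal reference interval containing
the gene that no anchor covers while chained anchors flank it on both sides;
because the last shared k-mer on each side ends at the breakpoint, the
recovered boundaries are exact up to k−1 bp. Inverted-anchor chains are
reported as inversion segments; a gap that is at least `min_sub = 50` bp on
*both* the reference and the accession side (and not explained by an
inversion) is typed as a substitution. The gene is called present when
forward anchors cover at least `min_gene_cov = 0.9` of its span.

## Depth-interval PAV calling

For short-read cohorts the stage uses three diagnostic windows of
`interval_len = 400` bp: `a` in the conserved flank upstream of the deletion
span (ending `margin = 500` bp before it), `c` symmetric downstream, and `b`
inside the gene, centred on the junction between the intron and the second
exon. The statistic is the flank-normalised depth ratio

r = depth_b / ((depth_a + depth_c) / 2),

which is ~0 for a homozygous deletion, ~0.5 for a heterozygous one and ~1
for an intact gene, independent of library size (the ratio is invariant to
scaling all depths). Calls: absent if r < `tau_abs` = 0.15, present if
r > `tau_pres` = 0.65, ambiguous otherwise; a mean flank depth of 0 makes r
undefined (ambiguous, flagged), below `min_flank_depth = 5` flags low
confidence. The mean of a and c, rather than their minimum or maximum, is
used for robustness to one-sided mismapping.

The present threshold deserves a note. Under Poisson counting noise the
heterozygous ratio is distributed symmetrically *around* 0.5 (standard
deviation ≈ 0.011 at 20x over 400 bp windows), so a cutoff at 0.5 would send
half of all heterozygous carriers to "present" by chance. 0.65 sits more
than ten of those standard deviations above the heterozygous band and more
than twenty below the present band around 1, so all three classes separate
cleanly; the choice follows from the sampling distribution, not from tuning.

## The PCR deletion assay

Two primer pairs complement the depth calls: G1 amplifies inside the gene
(product only when the gene is present), G2 anchors in the conserved flanks
on either side of the deletion span (its binding sites are ~60 kb apart on
the intact allele, far beyond amplifiable range, but collapse to under
`max_product = 3000` bp on the deleted allele, a typical Taq limit). Primer
constraints: length 18-27 nt (20 by default), GC 40-60%, Wallace-rule
Tm = 2(A+T) + 4(G+C) between 55 and 65 C with pair ΔTm ≤ 3, and locus-wide
uniqueness of the primer and its reverse complement. The Wallace rule is
deliberately transparent and trivially swappable for a nearest-neighbour
model; at these lengths it only gates candidate windows.

The in-silico PCR engine reports every amplicon where the forward primer
matches one strand and the reverse primer matches the other within
`max_product`; with `max_mismatch > 0` internal mismatches are tolerated but
the 3'-terminal 3 bases of each primer must match exactly, since 3'
mismatches abolish extension. The band-pattern interpreter follows the
assay's truth table: G1-only = gene present, G2-only = gene deleted,
neither or both = uninterpretable.

## Haplotype typing

Gene-region genotypes (biallelic SNPs plus single-indel columns) are read
from VCF. Because the analysis is haplotype-based and unphased data cannot
resolve heterozygous vectors, every sample with a heterozygous or missing
call is excluded, as is the whole-gene-deletion class (labelled H0, which
has no allele vector); each exclusion is logged with a reason, with
h0_deletion taking precedence over het over missing when several apply.
Identical allele vectors collapse into haplotypes labelled H1, H2, ... by
descending carrier count, ties broken by first-seen sample order — so the
partition is invariant to sample order and the labels are reproducible.
Frequencies are tabulated per subpopulation (proportions summing to 1 within
each subpopulation; carriers without metadata are kept under "unassigned").
The haplotype tree is classic neighbor-joining (`ape::nj`) on Hamming
distances between allele vectors; negative branch lengths, a known NJ
artefact, are clamped to 0 with a message.

## Variant effects and cryptic splicing

Annotation against the single-transcript model follows a fixed decision
order: splice site (the 2 bp at each intron edge) > coding > intronic >
intergenic. Coding substitutions are typed by codon comparison (synonymous /
nonsynonymous / premature stop); coding indels by length difference mod 3.
All splice logic operates on the coding-strand view, so minus-strand genes
are handled by the same code path. Positions in exons but outside the CDS
fall through to intergenic; the generated models carry no UTRs so the case
does not arise internally.

The cryptic-splice predictor models the consequence of disabling a canonical
acceptor: the spliceosome's fallback is taken to be the *nearest downstream
AG*, scanned into the exon (up to `max_scan = 200` bp; nothing found means
the outcome is reported as unresolved exon skipping rather than guessed).
Nearest-downstream-AG is the minimal mechanistic model consistent with an
observed shortened product; upstream (intronic) cryptic acceptors would
lengthen the transcript and are not scanned by default. The report carries
the signed cDNA length change, the frameshift verdict (delta mod 3), the
truncated protein from re-splicing and re-translating, and the annotated
domains lost — a domain is lost when translation stops before the domain's
last residue. On the package's synthetic *Ghd7*-like demonstration locus
(`synthetic_ghd7_locus()`, a fully synthetic stand-in whose acceptor variant
maps to the reported chromosome coordinate), mutating the acceptor adenine
to cytosine yields a 34 bp cDNA deletion, a frameshift, and premature
termination inside the CCT-like domain — the mechanism this predictor
exists to explain.

## pegRNA / PE3 design

For a single-base correction the designer enumerates SpCas9 NGG protospacers
on both strands (nick between protospacer positions 17 and 18, the standard
Cas9n H840A geometry), keeps those whose nick lies 5' of the edit on their
own strand with the edit reachable by the RT template, and picks the
smallest nick-to-edit distance (ties toward the smaller coordinate). The 3'
extension is written 5'→3' as RT template then PBS:

* PBS = reverse complement of the `pbs_len = 12` nicked-strand bases ending
  at the nick. The default is the length recovered by suffix analysis of the
  reported reagents for this locus.
* RT template = reverse complement of the *edited* strand from the nick, the
  smallest length ≥ `rt_min = 10` covering the edit plus ≥ 3 downstream
  bases, capped at `rt_max = 16`.

The PE3 second-nick guide is sought on the opposite strand with nick-to-nick
distance in `pe3_window = c(40, 90)` bp (closest to the midpoint); designs
without one are emitted with a warning rather than refused. `validate_design`
re-derives every invariant from the sequence; in reagent mode (spacer +
extension only) it infers the PBS length as the longest extension suffix
(≥ 8 nt, screening out chance dinucleotide matches) whose reverse complement
is a protospacer suffix ending exactly at the 17/18 nick.

## The synthetic-data generator

The generator is the package's study-condition definition, not a test
convenience. Defaults: a 120 kb reference segment carrying a two-exon gene
(700 + 452 bp exons, 500 bp intron — the architecture of *Ghd7* with the CDS
covering the whole transcript) at its centre; a 60 kb deletion span centred
on the gene; a cohort of 200 accessions with 15% homozygous deletion
carriers, each also receiving 1-3 nested inversion/substitution blocks
(0.5-2 kb) in the flanks, kept ≥ 3 kb from the deletion edges; non-carriers
receive 30 flank SNPs. Depth is Poisson at 20 reads/base over present
sequence, 2% of that (off-target mapping) over deleted spans, and half over
the span for heterozygous carriers. The SNP matrix draws 46 SNPs and one
indel inside the gene span from 8 founder haplotypes with skewed founder
frequencies; 6% of samples receive heterozygous calls and a disjoint 4.5%
missing calls (every founder keeps at least one clean carrier, so the
founder count is recoverable by construction). Where the source cohort's
sequencing depth was unstated, 20x was adopted as typical of modern
resequencing panels.

Every artifact is deterministic under the master seed, and per-accession
draws come from sub-streams keyed by a stable hash of the accession id, so
enlarging a cohort never perturbs existing accessions.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: read-level artefacts (mapping bias, GC bias,
duplicated reads), population structure beyond a configurable
founder-subpopulation confusion, linkage to anything outside the locus,
segmental duplications that would defeat the uniqueness assumptions of both
the anchor mask and the primer design, and genuine splice-site usage beyond
the AG-scanning model.

## Problem sizes and numerical choices

The test-suite and the reproduction script run: 20 seeded depth cohorts of
200 accessions (4,000 calls) for the PAV precision/recall check; 50
compound-SV accessions for deletion-boundary recovery at ≤ k−1 = 15 bp; 200
assemblies for PCR concordance; the default 200-sample SNP matrix (21
planted exclusions, 8 founders) for haplotype typing; an exhaustive
substitution scan (every position × 3 alternates) of a ≤ 1 kb toy gene
against a brute-force re-splice-and-translate oracle; and 100 random
design/validate round-trips for the pegRNA stage. These sizes keep the full
suite under two minutes while leaving each check statistically trivial to
interpret (the planted truth is recovered exactly or the test fails).

Remaining numerical conventions: all internal intervals are 1-based
inclusive (GFF/VCF convention; BED output is 0-based half-open); lowercase
input is uppercased and N is allowed everywhere except primers and spacers;
translation stops at (and includes) the first stop codon, reports `X` for
codons containing non-ACGT characters, and flags trailing partial codons;
NJ branch lengths below zero are clamped to zero.

## Limitations

The dot-plot stage reports segment structure, not base-level identity, and
does not attempt whole-genome comparison. The depth caller assumes a single
deletion span per locus and does not segment novel CNVs. Primer design
screens neither dimers nor hairpins. Haplotype typing neither imputes nor
phases. The splice predictor knows nothing of branch points, polypyrimidine
tracts or splice-strength scoring. pegRNA design optimises distance
geometry only — no editing-efficiency or off-target model.
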