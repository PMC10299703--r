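---
title: "Proteoform inference from splice isoforms, epitope maps, and spectral counts"
author: "ProteoformTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteoform inference from splice isoforms, epitope maps, and spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoformTools)
```

# The inference problem

A gene with several promoters and alternative 5' exons over a shared 3'
coding region can encode a family of protein isoforms that are identical
over a long C-terminal stretch and differ only in N-terminal extent. Two
features make the protein-level evidence for such a gene ambiguous:

1. **Nesting.** When a transcript's first AUG corresponds to an internal
   methionine of a longer isoform, the shorter isoform's entire sequence
   is a suffix of the longer one. Every peptide of the nested isoform is
   then shared; only the longer isoform can have unique N-terminal
   peptides.
2. **Group-wise antibody detection.** An antibody raised against an
   antigenic region detects every isoform containing that region, so a
   band's antibody pattern constrains a *set* of candidates, not a single
   isoform.

ProteoformTools formalizes the deduction practitioners perform by hand:
enumerate what the transcripts can encode, work out which probes and
peptides discriminate which isoforms, and quantify band evidence with
spectral counts.

# Catalog model

## ORF choice

Translation is assumed to initiate at AUG only. For each stop codon in
each reading frame, the 5'-most in-frame AUG with no intervening stop
defines one maximal ORF; the coding ORF of a transcript is the longest
such ORF, with ties broken by the 5'-most start. This joint rule
("first methionine" within an ORF, "largest ORF" among ORFs) is
deterministic and reproduces the conventional annotation for transcripts
whose 5'UTRs carry incidental short ORFs. Codons containing N are never
treated as start or stop codons and translate to X — an ambiguous base
can hide a signal but never invent one.

A minimum ORF length (default 30 codons) is applied when building a
catalog, suppressing spurious micro-ORFs; the enumerator itself reports
all ORFs so that its contract is exactly the rule above.

## Coordinates

Genomic exon intervals are held as `GRanges` (1-based, closed), the native
Bioconductor convention used by the GFF3 reader/writer (rtracklayer), so
no coordinate conversion exists anywhere in the package. Transcript and
protein positions are 1-based inclusive; an antigenic region printed as
"residues 25 to 171" has 147 residues.

## Nesting and N-terminal classes

Isoform B is *nested* in A when B's full sequence equals a suffix of A
starting at an internal methionine (recorded as the 1-based Met position
in A). N-terminal classes are the connected components of the nesting
relation. This is deliberately stricter than "shares a C-terminal
region": two isoforms whose own 5' exons encode disjoint N-termini fall
in different classes even though they share the common 3' coding region.
For an isoform nested in several parents, the longest parent is reported
(nesting is transitive, so positions in intermediate parents follow by
offset arithmetic, and all pairs remain available via `nestingPairs()`).

Isoform naming is deterministic — decreasing length, then transcript
input order — with an alias table available because historical isoform
names are conventions, not derivable quantities.

# Allele comparison

`compareAlleles()` aligns the alternative protein globally to the
reference (match +1, mismatch −1, gap opening 5, gap extension 1,
Biostrings `pairwiseAlignment`) and classifies columns into
substitutions, deletions and insertions, merging gap runs into single
events. The gap penalties are deliberately stiff relative to mismatches
so that isolated single-residue indels stay contiguous instead of
splitting into gap–mismatch mosaics; they are configurable. Positions are
reference-frame and 1-based; an insertion is reported at the position of
the next reference residue. Swapping the inputs swaps insertions with
deletions and reverses substitution residue order.

`detectOrfExtension()` addresses a subtler variant effect: a single-base
insertion in a 5'UTR can bring an upstream AUG in frame with the coding
ORF, extending the protein N-terminally. The two coding ORFs are compared
by a *global–local* alignment (reference global, variant local): the
reference must be consumed entirely and the alignment must reach the
variant's C-terminus (the stop-anchored 3' end), while the variant's
N-terminal overhang — the extension — is unpenalized. A plain global
alignment fails here precisely when the extension itself starts with
methionine: the aligner pairs the two initial Ms and the leading gap
disappears. "Novel" extension residues are counted operationally as those
matching no other catalog isoform at the C-terminally aligned position;
this reproduces the extension-vs-novel-domain distinction structurally
without claiming knowledge of how any particular published count was
derived.

# Digestion and peptide classes

Trypsin cleaves C-terminal to K/R and chymotrypsin (high-specificity
rule) C-terminal to F/W/Y, in both cases not before proline; cleavage
after L/M can be enabled for low-specificity chymotrypsin. Peptides carry
0..`maxMissed` missed cleavages (default 2, the common search-engine
setting); the 0-missed set partitions the protein. Downstream
quantification uses an observable-length window of 6–40 residues as a
simple LC-MS/MS detectability proxy — real detectability depends on
hydrophobicity, charge and ionization, none of which are modelled.
Peptides containing X are excluded from classification since an ambiguous
residue cannot support attribution. A peptide is `unique`,
`class_specific`, or `shared` according to its carrier set; by the
nesting argument above, a peptide unique to a nested isoform cannot
exist, and the classifier will never emit one.

# Spectral-count quantification

## Relative abundance

Within a sample, r(peptide) = spectral count / highest spectral count of
any peptide sequence in that sample, pooling modification states of the
same sequence; r is scale free (multiplying all counts by a constant
changes nothing) and lies in (0, 1] with the most-observed sequence at 1.
Per-residue coverage takes the *maximum* r over covering peptides rather
than a sum: the maximum preserves the 0–1 scale and is insensitive to how
finely a region happens to be chopped by cleavage sites. A contamination
guard (`flagContamination()`, default off, threshold 0.1) flags
low-abundance peptides that may be carry-over from previous runs.

## Phosphosite occupancy

Occupancy is phospho counts over all counts covering the site, as a
percentage rounded to the nearest integer (halves up, so the estimate is
deterministic; 1 of 9 counts prints 11%). Zero coverage is an error, not
0%. With counts from binomial sampling at true occupancy θ the estimator
is unbiased, which the test suite verifies at θ = 0.10 and 0.65 over
1000 replicates of depth 50.

## Truncation boundaries

A truncated proteoform shows no coverage before its first residue. The
boundary estimator fits a two-level step to c(pos): level 0 before b,
level μ from b on, where μ is the mean coverage of the covered
(non-zero) region, choosing b to minimize the sum of squared errors (tie:
smallest b, so a fully covered protein yields b = 1, a full-length call).
μ is deliberately a fixed plateau rather than a b-dependent suffix mean:
with a suffix-dependent mean, any prefix whose coverage falls below half
the running mean is trimmed, and on sparse profiles the boundary drifts
far to the right. The estimator is exact on noiseless steps and, at the
simulation conditions below, lands within ±15 residues of a planted
boundary in ≥90% of runs. Its residual failure mode is one-sided: when no
N-terminal peptide of the truncated form is observed, b̂ moves toward
the first observed peptide, never leftward. Digests without missed
cleavages leave structural coverage gaps (peptides outside the length
window) that aggravate this; the 2-missed default gives quasi-continuous
coverage.

## Band assignment

Candidates for a band are isoforms carrying the epitope of *every*
detecting antibody. Non-detection excludes nothing — a probe may simply
lack sensitivity for a low-abundance form — and is instead a score
penalty (default 0.25 per non-detecting probe whose epitope the candidate
carries). A candidate explains the apparent mass either full-length
(relative error ≤ `massTolFrac`, default 0.15) or as an N-terminal
truncation whose start comes from the boundary estimator when counts are
available, otherwise solved from the mass; the 15% default is wide enough
to accept ordinary gel anomalies yet flags bands running far above their
theoretical weight, which are reported as `modified_unexplained` rather
than silently dropped or forced. Scores combine mass closeness and the
fraction of the band's spectral counts carried by the candidate form;
ties rank alphabetically. When several nested isoforms share the
truncated suffix, their candidates are equivalent by construction and the
ranking shows them tied — the method reports that ambiguity instead of
resolving it, since no peptide evidence can.

# The synthetic locus

`makeGene()` builds a genome whose alternative first exons splice onto a
shared coding chain, with every downstream quantity known by
construction: two transcripts differing only in 5'UTR (collapsing), first
exons splicing in downstream of internal AUGs at residues 170 and 346 of
the 1087-residue full-length protein (nesting), a second N-terminal class
with its own coding first exon (910 residues, plus a 40-residue extended
variant), and a transcript whose 5'UTR is primed — an upstream AUG
followed by an in-frame stop — so that `mutateAllele()` can plant a
single adenosine insertion that joins that AUG in frame with the coding
ORF, extending it by 67 residues by default. Non-coding filler is drawn
from the {A, C} alphabet: such sequence cannot contain AUG or a stop
codon, even across splice junctions, so translation starts exactly where
the design places them. These dimensions (isoform lengths near 1087, 918,
910, and 742 residues; nested starts at 170 and 346; a truncation planted
at residue 477) were chosen once to be realistic for a large multi-start
kinase locus.

Planted allele events default to 6 substitutions and 1 single-codon
deletion at well-separated (≥10 residues) positions with unequal
neighbours, so alignment recovery is unambiguous. Counts are simulated by
digesting each mixture component, distributing the expected depth
(default 100 spectra per band, within the range of real per-band totals)
by mixture weight and uniformly across each component's observable
peptides — detectability is uniform inside the length window and zero
outside, the simplest model sufficient for recovery testing — then
drawing Poisson counts and splitting phosphosite-covering counts
binomially at the configured occupancy. One seeded generator per dataset,
with fixed per-component sub-seed offsets, makes every output
byte-reproducible.

What the generator does *not* emulate: gel migration anomalies
(covalently modified forms running high), peptide-specific detectability,
chimeric or mis-identified spectra, and FDR structure in the
identifications. Passing recovery tests on this generator therefore shows
the inference logic is sound under idealized sampling, not that real
bands will be equally clean.

# Problem sizes and determinism in the test suite

The suite exercises: ORF-enumerator equivalence with a naive brute-force
oracle on 1000 random sequences up to 1 kb; digestion partition checks on
1000 random proteins; 100 seeded boundary-recovery simulations at depth
100 with a 2-missed tryptic digest; 1000-replicate occupancy calibration
at n = 50; and one full simulate-write-read-analyze round trip through
the FASTA/GFF3/TSV interfaces. All randomness is seeded, so every test is
deterministic.

# Known limitations

* Epitope matching is exact substring identity — appropriate when
  antigens are cloned from the coding sequence itself, but allele-specific
  substitutions inside an antigenic region will break a match; matrices
  are computed per allele catalog and such differences surface as matrix
  differences, which the caller must interpret.
* The boundary estimator assumes a single truncation per band; mixtures
  of two truncated forms in one band yield an intermediate call.
* Band mass constraints use theoretical average masses; post-translational
  mass shifts are flagged, not modelled.
* Non-AUG initiation, splice-site prediction, motif/disorder annotation
  and raw spectrum processing are out of scope; the pipeline consumes
  transcript structures and validated peptide identifications.
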