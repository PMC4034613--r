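---
title: "Sorting allopolyploid transcriptome reads into subgenomes"
author: "HomoeoSort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting allopolyploid transcriptome reads into subgenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HomoeoSort)
```

## The problem

An allopolyploid carries two divergent parental genomes — two homoeologous
copies of most genes — in one nucleus. When its short transcriptome reads are
mapped to a single reference, reads from the two homoeologues pile up on the
same target, so polymorphic positions largely reflect homoeologue divergence
rather than heterozygosity: apparent heterozygosity is several-fold that of
the diploid relatives, population-structure input is contaminated, and a
phylogeny built from such genotypes places the polyploid on a meaningless
averaged branch.

The way out is that the two diploid progenitor species still exist and can be
sequenced. Any site where the two progenitor genomes differ — a
*diploid-distinguishing polymorphism* (DDP) — lets a read that covers it be
attributed to one subgenome. HomoeoSort implements this sorting and the
analyses around it: read quality processing, a scored aligner, SNP calling
and genotype-matrix handling, species-group consensus assembly, the
preferential-mapping classifier, subgenome SNP recall, electronic chromosome
painting, and phylogenomic dataset preparation.

## The procedure

### Read processing

Reads are demultiplexed by an exact match of their leading bases against the
library barcodes (the barcode is removed on assignment). Quality processing
trims bases from the read extremes while the terminal base quality is below
30, then discards reads shorter than 50 nt; both thresholds are inclusive
("minimum quality 30", "minimum length 50") and exposed as parameters.
Trimming is applied to both extremes by default; a `3prime` mode is available
because some trimmers only clip the degraded 3' end. Trimming is idempotent
and never alters interior bases.

### Alignment with best/second-best semantics

The internal aligner is seeded and ungapped: candidate placements are found
by exact 20-mer seeds (non-overlapping across the read, plus one flush with
the 3' end) on both strands, and every candidate is scored end-to-end. The
scoring is *match 0, mismatch −6, ambiguous column −1*, so a perfect
alignment has score AS = 0 and "AS = 0 and XS = 0" literally means "matches
two places with no mismatch". XS is the score of the best alternative
placement, when one was found. Non-overlapping 20-mer seeding guarantees that
any placement with at most ⌊L/20⌋ − 1 mismatches is found (pigeonhole); at
the divergences this package targets (a few percent) that is ample, and the
oracle tests compare the aligner against an exhaustive scan on constructions
where every relevant alternative is seed-detectable.

Mapping quality is a declared, deterministic stand-in for an external
aligner's model: `mapq = 42` with no alternative placement, `0` on a tied
best score, else `min(42, 5 × (AS − XS))`. The constant 5 is chosen so that a
single distinguishing mismatch (score gap 6 → mapq 30) survives the standard
`mapq ≥ 20` filter while ties fail it; the filter also removes tied records
explicitly ("no preferential mapping").

### SNP calling and genotype matrices

Calling is a pileup rule set, not a likelihood model, matching the filters it
reproduces: per column, alleles supported by ≥ 2 reads are considered; a site
is emitted iff at least one non-reference allele passes and total coverage is
≥ 5; the genotype is homozygous when the top allele holds ≥ 80% of called
bases, else heterozygous in the top two alleles (ties prefer the reference
base, then alphabetical order). Merging samples takes the site union;
a sample without a call is homozygous-reference where it has ≥ 5× coverage
and missing otherwise — this distinction is what the per-sample coverage
vectors are kept for. Matrices export to VCF 4.2, HapMap, Structure
(two rows per individual, −9 missing) and, via the supermatrix builder, to
FASTA/PHYLIP with IUPAC ambiguity codes for heterozygotes.

The per-sample summary reports RPKM (reads on gene × 10⁹ / (mapped reads ×
gene length)), "represented genes" (RPKM > 0), the covered fraction of the
reference, and the percentage of heterozygous positions. The heterozygosity
denominator is the sample's processed SNP calls (not all covered positions);
this is a documented choice where the convention is ambiguous.

### Consensus transcriptomes

A species-group consensus is the majority base per reference-gene column
among all covering reads, N where coverage is below the masking depth, and
the *reference* base on majority ties — the consensus feeds the aligner, so
it must stay unambiguous. The masking depth defaults to 1 (only zero
coverage becomes N); the sorting pipeline raises it to 3 so that an isolated
sequencing error can never fix a wrong base into the reference the
classifier trusts. Gene-level quality statistics implement the downstream
selection rule: pass iff length ≥ 1000 bp and N fraction ≤ 10% (both
inclusive; a strict flag is provided because "no more than 10%" could be
read either way), and *full-length* iff the consensus has no N at all.

### Subgenome classification

The two progenitor consensus sets are joined into one reference, aligned on
gene ids. For each polyploid read, candidate (gene, offset, strand)
placements are seeded in either set, and the read is scored against *both*
consensus sequences over the same columns. Columns where the read or either
consensus carries an N are excluded from both scores. This paired-column
masking is a deliberate design decision: consensus sequences have N at
low-coverage positions, and under naive per-side scoring an asymmetric N (or
a read error at a position masked on one side only) hands one progenitor a
strict score advantage carrying no homoeologue information. With masking,
a score difference can only arise from actual base differences between the
progenitor consensus sequences — that is, from DDPs — which yields the
guarantee the tests enforce: a read overlapping zero DDPs is never given a
progenitor label.

The label rules are then exactly the preferential-mapping conditions: no
placement → `UNMAPPED`; a strictly better best score on one side → that
progenitor's label; equal best scores with zero mismatches on both sides →
`SHARED` (a perfect match to both, kept); equal best scores with mismatches →
`AMBIGUOUS` (discarded: it cannot be attributed). Multi-mapping *within* one
progenitor still yields that progenitor's label — the discard rule targets
cross-progenitor ties only.

`SHARED` reads contribute to both subgenome consensus assemblies (they
support either haplotype and prevent double-N regions) but are excluded from
the subgenome SNP-recall samples by default — they carry no distinguishing
alleles, and counting them twice would double-weight shared variation. Both
behaviors sit behind `includeShared` flags. The `mapq ≥ 20` filter applies on
the back-mapping to the reference, not on the classification pass, mirroring
the two distinct mapping stages of the workflow.

### Electronic chromosome painting

Subgenome-tagged SNP positions are binned along chromosomes (half-open bins;
a SNP at position `binSize` falls in the second bin) into one track per
subgenome, exportable as bedGraph and plottable as opposing colored bars. The
single-homoeologue scan slides a window of 5 bins and flags it iff the window
holds at least `minInformative = 10` SNPs *and* one subgenome's count is
exactly zero; overlapping flagged windows merge into candidate intervals. The
informativeness guard is what keeps gene-poor (pericentromere-like) stretches
from being flagged: windows empty on both sides are silent. The default bin
size is 100 kb at genome scale; the synthetic analyses in this package use
2.5–5 kb bins on 50–100 kb chromosomes, which keeps the expected per-window
SNP count in the same regime (tens of SNPs). The scan detects presence versus
absence only; it cannot distinguish a 3:1 dosage from 2:2.

### Phylogenomic preparation

OTU construction splits every allopolyploid accession into one OTU per
subgenome (e.g. the D1 homoeologue of T1 accession 1288 becomes `D1T1_1288`);
in species-tree mode OTUs are species-level groups, one per subgenome for
polyploid species (`T2-D3`). For the shipped 24-accession *Glycine* panel
plus the *G. max* outgroup this yields 36 supermatrix OTUs and 11 ingroup
species-tree groups; the outgroup stays its own row, since the 11-group count
conventionally excludes it. The supermatrix encodes heterozygotes as IUPAC
ambiguity codes by default (information-preserving; a major-allele flag
exists) and missing data as N, with columns ordered by (chromosome,
position).

Gene selection for gene-tree work requires the consensus quality criteria in
*every* accession plus membership in the retained duplicate-pair list from
the recent whole-genome duplication. The outgroup screen then removes
alignments contaminated by deep paralogues. The acceptance condition is "the
outgroup is sister to all ingroup sequences in a clock-rooted tree": we build
a UPGMA tree from pairwise-deletion p-distances and pass iff the outgroup is
still a singleton at the final, deepest join. A neighbor-joining tree rooted
*on* the outgroup cannot express this criterion — rooting an unrooted tree at
a pendant tip always leaves the rest as one clade — whereas under clock
rooting a pair of anciently diverged paralogues pulls the root inside the
ingroup and fails the screen, which is exactly the observed signature
("two large clades with long branches"). The screen is one-sided by design
and is property-tested to pass ≥ 95% of clean orthologue simulations and fail
≥ 95% of simulations with two deep paralogues.

Tree calibration multiplies all branch lengths by `rootAge / root height`
(default 5 Myr, the annual–perennial split in the target system), after
checking the input is rooted and ultrametric within a relative tolerance of
1e-6. Minimum divergence between two tip sets — e.g. a subgenome's alleles
versus its progenitor's — is the smallest MRCA height over cross pairs,
computed by one post-order traversal and verified against an all-pairs scan.
The Evanno ΔK statistic is the replicate-wise absolute second difference of
the clustering log-probability, averaged, divided by the standard deviation
of L(K); it requires ≥ 3 consecutive K values with equal replicate counts
≥ 2, and reports NA where the replicate variance is zero.

## The synthetic triad generator

Every downstream stage is tested against simulations with full truth labels,
so the generator's defaults are the study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| genome | 5 chromosomes × 100 kb, 200 genes × 1.5 kb | desk-scale; ~60% genic so painting has realistic gaps |
| `progenitorDivergence` | 0.02 /site | the observed bracket of homoeologous divergence (~1.5–2.4% heterozygous positions in unseparated polyploids) sets d ≈ 2% at transcribed sites |
| `referenceDivergence` | 0.03 /site | the mapping reference is a congeneric species (~5 My diverged), not a progenitor; without it nearly every polyploid call would be heterozygous and diploids would have no SNPs at all |
| `withinSpeciesPolymorphism` | 0 | the taxa are cleistogamous selfers, near-homozygous; the parameter exists to study robustness to residual polymorphism |
| `paleoDupFraction`, `paleoDivergence` | 0.10, 0.30 /site | a retained-duplicate fraction from the older whole-genome duplication, divergent enough to confound the outgroup screen when sampled in place of the orthologue |
| `postMergerRate` | 1e-4 /site | polyploid origins are young (hundreds of kyr) relative to progenitor divergence (~1 My) |
| `readLength`, `errorRate` | 100 nt, 0.001 /base | single-end 88/100 nt platforms; Q40-scale error |

DDP sites are drawn per transcribed site with probability d and each mutates
exactly one progenitor away from the common ancestor, so the DDP catalog is
*exactly* the set of differences between the founding haplotypes — the
invariant the truth-consistency tests check. Mutations are i.i.d.
substitutions, uniform over the three alternatives; there are no indels,
matching the ungapped aligner and SNP-only analysis. Genes are single-exon
with whole-gene CDS (lengths forced to multiples of 3). Reads are exact
substrings of transcripts, uniform over genes and offsets, with equal
subgenome (or haplotype) sampling; qualities are constant Q40 with an
optional degraded-3'-end model to exercise trimming. Loss blocks delete
whole genes overlapping the interval from one subgenome.

What the generator does *not* emulate — expression-level variation, splicing
and isoforms, library biases, coalescent gene-tree discordance, indels,
structural variation — bounds what the passing tests show: they validate the
logic and its thresholds under the stated model of divergence, not
performance on real RNA-seq. In particular, uniform coverage makes the ≥ 5×
depth filter easier to satisfy than in real transcriptomes, and the absence
of isoforms flatters the consensus N statistics.

## Problem sizes and observed behavior

The end-to-end acceptance analysis uses the default triad (200 genes ×
1.5 kb, d = 0.02, error 0.001), 2 × 10⁵ polyploid reads and 10⁵ reads per
diploid accession (~33× diploid, ~66× polyploid coverage), sizes chosen so
the whole analysis runs in about a minute on one CPU while keeping every
depth filter comfortably engaged. The false-positive control for the
painting scan uses 100 independent 2 × 50 kb triads. On these simulations the
classifier labels ~87% of reads — matching the analytic DDP-coverage
expectation 1 − (1 − d)^L = 86.7% for L = 100 — with ≥ 99.9% of labels
matching the truth subgenome and no zero-DDP read labeled; unseparated
polyploid heterozygosity (~40% of calls) collapses to ~0% in the separated
subgenome samples, reproducing the qualitative signature that motivates the
whole workflow.

## Degenerate inputs and numerical conventions

Coordinates are 0-based half-open internally; VCF, HapMap and SAM output are
1-based per their standards, and minus-strand lifting complements alleles.
Zero requested reads give an empty, valid FASTQ. Zero progenitor divergence
gives an empty DDP catalog and (correctly) no PROG labels. An empty barcode
map leaves all reads unassigned. Deterministic tie order everywhere:
alignment candidates by (target, position, strand); consensus and genotype
ties prefer the reference base; gene ids break classification ties. All
randomness flows from explicit integer seeds, and identical seeds give
bit-identical outputs.

## Known limitations

The aligner is ungapped and single-end by design; reads spanning real indels
would be lost or mis-scored. The mapq model is a stand-in, not a
reconstruction of any external aligner's. Classification is rule-based, not
probabilistic: it abstains (SHARED/AMBIGUOUS) rather than weighing evidence,
so the labeled fraction is bounded by DDP coverage. The painting scan flags
only total absence of one homoeologue. The screen, calibration and ΔK
utilities prepare and post-process phylogenomic data; tree *inference* itself
is out of scope.
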