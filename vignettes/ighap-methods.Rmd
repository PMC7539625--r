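---
title: "Methods: haplotype-resolved IGH assembly and genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-resolved IGH assembly and genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models each
stage implements, the parameters that matter, the design decisions taken
where the problem was genuinely open, and what the synthetic studies do and
do not demonstrate about real capture data.

## The custom locus reference

The pipeline maps everything against a *custom* locus reference: a base
locus sequence with known SV insertion sequences spliced in at their
positions. This makes population SV alleles part of the mapping target, so
reads from an SV-carrying haplotype align contiguously instead of
soft-clipping at a breakpoint, and each embedded body can be genotyped as
a biallelic site (present vs absent).

Coordinates are 0-based and half-open everywhere inside the package;
1-based coordinates appear only in VCF output. Gene annotations that
would straddle an insertion point are rejected at build time: embedded SVs
sit between genes, and a split annotation has no defined meaning. Gene
features are stored stranded, but extraction returns plus-strand locus
coordinates and reverse-complements at the boundary, keeping all alignment
code strand-agnostic. A liftover table maps intervals between base and
custom coordinates; a custom-coordinate interval intersecting an embedded
body has no image and is reported unmappable (comparisons against call
sets made on the base assembly route through this, and unmappable records
are excluded rather than counted as false positives).

## Alignment

No installed R package exposes an in-process long-read aligner, so the
package carries its own anchored affine-gap aligner (C++): unique k-mers
(k = 17, query stride 10) seed a colinear chain (longest chain with
strictly increasing query and reference positions), and inter-anchor
segments are resolved by a full affine-gap DP (Gotoh; match +1, mismatch
-2, gap open -4, gap extend -1, all configurable). One-sided segments
become pure insertion/deletion runs, which is what makes a 25 kb
one-haplotype deletion appear as a single deletion operation rather than a
split alignment. Two guards matter in practice:

* **Chain-segment filtering.** A single stray k-mer hit elsewhere in the
  locus can extend the optimal colinear chain by one anchor and fabricate
  a mega-gap. Chains are split at gaps > 2 kb and segments with fewer than
  3 anchors spanning < 150 bp of the query are discarded. Only unique
  k-mers seed chains; ambiguous (repeat) regions are left to the DP fill.
* **Leftmost-gap canonicalization.** Equivalent gap placements inside
  repeats are score-ties. Every alignment gets a left-shift pass so that
  all reads represent the same event identically; without it, consensus
  votes for a tandem-repeat length change scatter across repeat offsets
  and the event is lost. Variant records are additionally left-normalized
  (VCF convention) at calling time, and the simulator normalizes its truth
  the same way, so coordinates are comparable.

The DP tie-break order (diagonal > deletion > insertion) is fixed, making
alignments deterministic. Scores are validated against an independent
plain-R quadratic DP in the test suite.

## Read filtering and phasing

Molecules with fewer than 2 subread passes are dropped (`min_passes = 2`):
a consensus read needs at least two observations of the molecule.
Heterozygous SNV candidates require pileup depth >= `min_depth` (10) and a
second-most-common base frequency within
[`min_alt_fraction`, `max_alt_fraction`] = [0.25, 0.75]. These are
conventional CCS-grade thresholds; candidate detection is deliberately
permissive because assembly, not the pileup, makes the final call.

Read assignment is greedy agreement phasing: connected components of
candidate sites (linked by reads covering two or more) are phased left to
right from the leftmost site, then read assignment (majority match against
the current haplotype allele strings; ties unassigned) and per-site phase
(majority vote of assigned reads) are iterated to a fixed point, at most
10 rounds. Phasing uses substitutions only — indel heterozygosity does not
define blocks.

**SV-aware rescue.** A read lying wholly inside a large deletion carried
by one haplotype covers no het site (the simulator, like biology, does not
put SNVs on a haplotype that has no sequence there), yet its existence is
only compatible with the intact haplotype. After the fixed point, reads
wholly inside a >= 1 kb deletion seen in >= 2 assigned reads of one
haplotype are assigned to the other. Without this the intact haplotype's
interior is unassemblable across every hemizygous span. This is also how
the package resolves the homozygous-vs-hemizygous ambiguity: phasing keeps
the merged class, and SV evidence downstream (junction reads, depth)
separates the two.

Haplotype blocks are the connected components of het sites joined by
assigned reads; the block interval runs from the first to the last site
extended to the assigned reads' boundaries (trimmed at midpoints where
neighbours would overlap), and the read-covered gaps between het blocks
become homozygous-or-hemizygous blocks. Phase orientation is only defined
within a block: all evaluation respects label symmetry (switch errors are
counted per block as adjacent-pair flips, which is invariant under global
relabeling), and an optional trio-genotype table relabels blocks to
parental origin by majority vote over block SNVs.

## Assembly

Assembly is reference-guided: reads are already aligned, so layout is a
coordinate sort chained on overlap, and consensus is per-reference-column
majority with insertions voted as whole sequences at their (canonicalized)
junction. The layout-overlap threshold defaults to 1 bp — chains break
only at true coverage gaps — because any two reads covering the same
column already agree on placement through the reference. `min_identity`
(0.9) is applied as a read-versus-reference guard before layout rather
than recomputing pairwise read overlaps, which the shared reference
anchoring makes redundant. The per-column quality is the phred of column
disagreement, capped at 60 (a consensus QV needs a testable definition;
agreement-based phred is the natural one for majority consensus), and a
contig's `mean_qv` is the column average; contigs with `mean_qv` < 20 are
filtered. Heterozygous-block bins take only reads whose het sites belong
to that block — phase orientation does not transfer across blocks, so
positional overlap is not membership.

Regions covered by reads but by no contig are retried with the
recruitment pool (all unfiltered reads, including single-pass molecules);
the covered universe includes the pool so that a region seen only by
filtered-out molecules is still recovered. Contigs of the same haplotype
label (or unphased) sharing a terminal overlap >= 1,000 bp with mismatch
rate <= 0.002 and <= 20 gap bases are merged to a fixed point, the overlap
sequence taken from the higher-QV contig; these defaults bracket the
curated duplication-region examples the merge rule is modeled on (a
7.7 kb overlap with 5 mismatches and ~10 gap bases). Within one bin, a
minority read cluster (>= 2 reads) sharing a >= 50 bp deletion signature
against the bin consensus is set aside and assembled separately — the
somatic-deletion situation — rather than averaged into the germline
contig.

## Variant calling

Mismatch columns become SNVs; insertion/deletion runs separated by fewer
than 10 matched columns are merged into one sequence-resolved event before
classification. Length classes: 1 bp events are reported as indels with a
separate `special` size class (they are tallied apart because 1-2 bp
events are the dominant consensus error mode); 2-49 bp events are indels;
>= 50 bp events are SVs (the boundary is configurable). Genotypes combine
the two haplotypes per block: phased `a|b` inside heterozygous blocks,
`1/1` from unphased (homozygous-block) contigs, and haploid `1` where the
other haplotype has no contig — unless the CCS pileup is saturated
(alt fraction >= 0.8) and no large deletion explains hemizygosity, in
which case the site is upgraded to `1/1` (the missing contig is a coverage
seam, not a missing haplotype).

Each SNV carries the annotation set (detecting contig, overlapping
embedded SV, CCS support, gene feature, segment region, block). The
`ccs_support` annotation is true when the alt base is seen in >= 2 reads
making up >= 10% of the pileup. Separately, the PASS filter requires
pileup depth >= `min_depth`, alt count >= 3 and alt fraction >=
`min_alt_fraction`: at ~15x, two coincident read errors at a thin
consensus column can form a haplotype-bin majority, and demanding
genotype-consistent pileup corroboration removes exactly that failure mode
while leaving 40x calling untouched. Assembly-derived calls get no further
statistical filtering.

A single-haplotype deletion >= 10 kb whose right edge lies within 5 kb of
the J-proximal end (the end of the last J gene) is flagged as a putative
V(D)J/somatic event; gene-loss calls inside it are reported as
`vdj_suspect` instead of germline deletions. Position is the
discriminating feature: an equally large deletion in the middle of the V
region is never flagged.

## Embedded SV genotyping

Evidence priority is contig > junction > depth > SNV corroboration, with
thresholds exposed in the configuration (span fraction 0.8 of the body;
depth ratios 0.2x / 0.6x against 2 kb flanks; >= 2 junction reads). A
haplotype is *present* when a contig aligns across >= 80% of the body,
*absent* when a contig or >= 2 reads span the deletion junction with a gap
covering >= 80% of the body. When contigs are silent the depth channel
decides, but **absence always requires junction evidence**: a true
deletion leaves junction-spanning reads, pure capture dropout does not, so
degrading coverage moves a call toward no-call instead of flipping
present to absent. For unphased (hemizygous-candidate) regions the total
depth ratio separates present/present from present/absent. Unresolvable
combinations are no-calls with the evidence retained. Non-biallelic
(structurally complex) regions are excluded from automatic genotyping and
routed to a curation report.

## Allele inference

Matching is on the exon (coding) sequence, which is the granularity of
germline allele databases; an extended flank comparison is out of scope
for naming. Assignment is exact full-length string equality; anything else
is novel, reported with the nearest database allele by edit distance
(lexicographically first on ties, flagged) and a substitution/indel diff
list from the affine alignment. Database sequences with ambiguity codes
are rejected at load: exact matching must be unambiguous. Read support is
the number of CCS reads containing the exact assembled sequence (or its
reverse complement) as a substring — deliberately conservative under
sequencing error; an approximate mode (<= k mismatches) exists behind an
argument. Genes inside called deletions are `deleted`, genes in contig
gaps `not_assembled`, genes inside a flagged V(D)J interval
`vdj_suspect`. Per-gene records are kept as-is; a non-redundant rollup
collapses identical alleles shared by duplicated genes.

## Hardy-Weinberg exact test

The exact conditional test enumerates heterozygote counts given the
allele counts (log-factorial recurrence). The p-value sums tables at least
as extreme *in heterozygote count*, measured as distance from the
conditional expectation `n_A n_B / (2n - 1)`. This ordering keeps the
balanced table at p = 1 exactly and converges to the chi-square tail for
large samples; the common probability-ordering alternative is asymmetric
around the mode for heterozygote excess. Note that near the mode any
full-ordering exact test exceeds the continuous chi-square tail by up to
the probability atom at the mode (~0.03 at n = 1000); agreement with the
chi-square approximation is therefore a statement about balanced and
clearly-deviating tables, not about every neighbouring count. A
chi-square method is available as an option. Monomorphic sites return
p = 1 by convention.

## The synthetic-data generator

The generator defines the study conditions; it is the stand-in for
orthogonal truth (finished clones, trio data) that real studies validate
against.

* **Locus**: random sequence with V/D/J gene segments (V: LP1 55 bp,
  intron 85 bp, exon 296 bp, RS 39 bp; D: 25 bp exon with flanking RS;
  J: 50 bp exon plus RS), a 59-mer tandem repeat, and embedded SV bodies —
  the first of which contains gene segments of its own, so that absence of
  the body deletes genes. The default study locus is 600 kb with 25 kb and
  10 kb embedded SVs.
* **Diploid truth**: 200 heterozygous + 100 homozygous SNVs, 20 indels
  (2-49 bp), three SV classes (deletion of an embedded body, a novel
  deletion, a tandem-repeat copy-number expansion), novel alleles made by
  1-3 exonic substitutions, alternate database alleles, and a V(D)J-like
  deletion on one haplotype running from 10 kb proximal of the D region to
  the end of the J region. Variant footprints never overlap; random small
  variants avoid exons (+/- 20 bp) so allele truth stays defined by the
  allele specification; heterozygous indel/SV breakpoints get a linked
  heterozygous SNV within 2 kb on each side, reflecting that divergent
  haplotypes carry linked SNVs — an isolated het indel is unphaseable by
  SNV-based read-backed phasing by construction, not by defect. Truth
  variants are left-normalized with the same routine the caller uses.
* **Reads**: per-haplotype depth (the "40x" study = 20x per haplotype,
  40x total), lengths Normal(6457, 1200) truncated at 500 bp (the mean
  matches reported capture CCS read lengths), uniform starts, random
  strand, subread-pass counts 2 + Poisson(6) with an optional single-pass
  fraction, constant per-read quality encoding the error rate. The error
  model plants substitutions and 1-2 bp indels, the indels biased into
  homopolymer runs (>= 3 identical bases) with configurable probability —
  the dominant CCS error mode. The noisy study uses mismatch 0.006 + indel
  0.004 (~1% per base) with bias 0.6. Coverage dropout intervals
  (capture-bias stand-in) thin reads by a keep probability; they are
  user-configured, not fitted.
* **Multiplexing**: total yield held fixed; at plex level p each sample
  draws total/p bases from the pooled replicates in a seed-reproducible
  order. The multiplex study uses a 40 kb locus, 8 replicates and total
  yield 620x, so per-sample coverage spans ~310x (2-plex) down to ~15.5x
  (40-plex); multiplexed call sets are compared at position level against
  the top-coverage 2-plex run, which is how downsampling series are
  conventionally scored.

What passing these studies does **not** show: the generator's locus is
random sequence, so it has none of the segmental-duplication homology that
makes real IGH assembly hard (the merge-curation path is exercised only on
constructed fixtures); capture bias is a step function rather than a
probe-affinity profile; CCS errors are independent per base; and there are
no chimeras, barcode hopping or PCR duplicates. Results on synthetic data
bound what the algorithms can do under their own assumptions, not what a
wet-lab capture will deliver.

## Problem sizes and runtime choices

The bundled studies are sized for a single CPU: the main diploid study is
one 600 kb locus at 40x (a full pipeline run takes tens of seconds), the
noisy replication uses ten read seeds over the same locus, and the
multiplex sweep runs six plex levels over ten seeds on the 40 kb locus.
These sizes are the package's own choices for a reproducible desk-scale
demonstration; every count and threshold above is a configuration value,
so larger studies are a matter of patience, not code.

## Known limitations

* The aligner assumes mostly-unique sequence; inside long perfect repeats
  it relies on the DP fill and leftmost canonicalization, and it does not
  handle inversions or translocations.
* Reference-guided consensus cannot assemble sequence absent from the
  custom reference beyond insertion sizes that fit between anchors;
  entirely novel multi-kilobase insertions would need de novo assembly.
* Haploid genotypes in hemizygous regions are only as good as the
  deletion evidence; a hemizygous region with no junction coverage
  degrades to a no-call rather than a confident haploid call.
* The exact substring rule for allele read support undercounts with
  sequencing errors (by design; the approximate mode trades specificity
  for that).
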