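# ighap

Haplotype-resolved assembly, variant detection and germline allele
inference for targeted long-read sequencing of the immunoglobulin heavy
chain (IGH) locus.

## The problem

IGH is one of the most polymorphic and structurally complex regions of the
human genome: more than a hundred highly homologous V, D and J gene
segments, large structural variants (SVs) segregating in the population,
and allele databases that are still far from complete. Short reads and
arrays systematically miscall the locus, so characterizing a sample means
assembling both haplotypes from high-accuracy (CCS-grade) long reads and
reading variants and gene alleles directly off the assemblies.

`ighap` is a desk-scale, end-to-end R implementation of that workflow, for
immunogenomics researchers who want the whole pipeline — reference
construction through allele tables — scriptable, testable, and runnable on
a laptop. Every stage is driven by tibbles and composes with the pipe.

## What the pipeline does

1. **Custom locus reference** (`build_reference()`): known SV insertion
   sequences are spliced into a base locus at their positions, so that
   population SV alleles are part of the mapping target. Gene/feature
   annotations shift with the splice, each SV body is registered as a
   biallelic region (alternate allele = absence of the body), and a
   liftover map connects base and custom coordinates.
2. **Read-backed phasing** (`phase_reads()`): heterozygous SNV candidates
   are detected from the read pileup (depth >= 10, minor-base fraction in
   [0.25, 0.75]), reads are partitioned into haplotypes by a greedy
   agreement rule iterated to a fixed point, and haplotype blocks are the
   connected components of het sites linked by assigned reads; the gaps
   between them are homozygous-or-hemizygous blocks.
3. **Haplotype assembly** (`assemble_haplotypes()`): each (block,
   haplotype) read bin is laid out on reference coordinates and collapsed
   by per-column majority consensus with an agreement-derived quality
   (contigs with mean QV < 20 are dropped). Uncovered regions are retried
   with the unfiltered read pool; high-identity terminal overlaps between
   contigs are merged.
4. **Variant detection** (`call_variants()`): mismatch columns of the
   contig-to-reference alignments become SNVs (annotated with detecting
   contig, overlapping embedded SV, CCS pileup support, gene feature
   class, V/D/J region and block); gap runs become sequence-resolved
   indels (2-49 bp) and SVs (>= 50 bp), left-normalized, with phased
   genotypes. A one-haplotype deletion >= 10 kb abutting the J-proximal
   end is flagged as a putative V(D)J artifact.
5. **Embedded SV genotyping** (`genotype_svs()`): per haplotype, a contig
   spanning the body means present, a contig (or reads) spanning the
   deletion junction means absent, with a read-depth channel as fallback;
   conflicts become no-calls.
6. **Allele inference** (`call_alleles()`): exon sequences are projected
   out of the contigs, matched exactly against a `gene*allele` database,
   novel sequences get a nearest-allele diff list, and supporting CCS
   reads are counted by exact substring match.

A synthetic-data module (`sim_locus()`, `sim_diploid()`, `sim_reads()`,
`sim_multiplex()`) generates the locus, diploid truth sets and CCS-grade
reads with a homopolymer-biased error model, and an evaluation module
implements call-set concordance, trio Mendelian checks, phase switch
errors, assembly concordance, exact Hardy-Weinberg tests, accessibility
partitioning, imputation signal-to-noise and multiplex downsampling
sweeps.

## Worked example

```r
library(ighap)
library(dplyr)

locus <- sim_locus(locus_len = 120000, n_v = 8, n_d = 3, n_j = 2,
                   sv_lens = c(8000, 4000), seed = 11)
truth <- sim_diploid(locus, n_snv_het = 40, n_snv_hom = 20, n_indel = 6,
                     novel_del_len = 800, seed = 12)
reads <- sim_reads(truth, coverage = 20, seed = 13)   # 20x per haplotype
run   <- run_pipeline(locus$ref, reads, locus$db)
run
#> <ig_run>
#> <ig_phase> 632 aligned reads, 40 phased het SNVs, 3 blocks (2 heterozygous)
#> <ig_assembly> 5 contigs, 202340 assembled bases; 0 uncovered intervals
#>   calls: 60 SNVs, 6 indels, 4 SVs; 2 embedded SVs genotyped
```

632 reads phase into 3 blocks; the assembly recovers both haplotypes with
no uncovered intervals. The embedded SVs genotype from junction evidence:

```r
run$sv_genotypes %>% select(sv_id, genotype, junction_reads)
#>   sv_id genotype        junction_reads
#> 1 sv1   present/absent              17
#> 2 sv2   present/present              0
```

`sv1` is absent on one haplotype (17 reads span its deletion junction);
`sv2` is present on both. Allele calls beyond plain database hits:

```r
run$alleles %>% filter(status != "known") %>%
  select(gene, hap, status, nearest, n_diffs, support)
#>    gene      hap status      nearest n_diffs support
#>  1 IGHV1-1     2 novel       01            2      13
#>  2 IGHV1-2     2 novel       01            1      16
#>  3 IGHV9-1     1 deleted     <NA>         NA      NA
#>  ...
#>  7 IGHD1-1     1 vdj_suspect <NA>         NA      NA
```

Three novel alleles (1-3 exonic substitutions from their nearest database
allele, each supported by 13-16 reads containing the exact sequence), the
two genes living inside the deleted SV body reported as `deleted`, and the
D/J-region genes on the haplotype carrying the V(D)J-like somatic deletion
flagged `vdj_suspect` rather than called as germline losses. Comparing the
SNV calls to the simulator truth:

```r
glance(compare_snv_callsets(snv_call_table(run$calls),
                            truth_snv_table(truth, locus$ref)))
#>      tp    fp    fn genotype_discordant excluded_unmappable recall precision
#> 1    60     0     0                   0                   0      1         1
```

All 60 planted SNVs are recovered with correct genotypes and no false
positives.

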