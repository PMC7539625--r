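# Serialization at the package boundary: FASTA/FASTQ through Biostrings,
# plus plain-text SAM/VCF/BED/TSV writers for the pipeline's own tables
# (1-based coordinates only in VCF; everything else stays 0-based
# half-open, BED-style).

ref_seq_name <- "igh_custom"

#' Write / read a locus reference directory
#'
#' Serializes an `ig_reference` as a FASTA plus BED-style annotation
#' tables and the tab-delimited liftover map
#' (`custom_start  custom_end  base_start  base_end`).
#'
#' @param ref An `ig_reference`.
#' @param dir Output directory.
#' @return The directory (writer) or an `ig_reference` (reader).
#' @export
write_locus_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- Biostrings::DNAStringSet(ref$seq)
  names(x) <- ref_seq_name
  Biostrings::writeXStringSet(x, file.path(dir, "reference.fasta"))
  readr::write_tsv(ref$genes, file.path(dir, "genes.bed"))
  readr::write_tsv(ref$features, file.path(dir, "features.bed"))
  readr::write_tsv(ref$svs, file.path(dir, "sv_regions.bed"))
  readr::write_tsv(ref$liftover, file.path(dir, "liftover.tsv"))
  readr::write_tsv(ref$repeats, file.path(dir, "repeats.tsv"))
  writeLines(as.character(ref$base_len), file.path(dir, "base_len.txt"))
  invisible(dir)
}

#' @rdname write_locus_reference
#' @export
read_locus_reference <- function(dir) {
  seq <- as.character(Biostrings::readDNAStringSet(file.path(dir, "reference.fasta"))[[1]])
  structure(list(
    seq = seq,
    genes = readr::read_tsv(file.path(dir, "genes.bed"), show_col_types = FALSE),
    features = readr::read_tsv(file.path(dir, "features.bed"), show_col_types = FALSE),
    svs = readr::read_tsv(file.path(dir, "sv_regions.bed"), show_col_types = FALSE),
    liftover = readr::read_tsv(file.path(dir, "liftover.tsv"), show_col_types = FALSE),
    base_len = as.integer(readLines(file.path(dir, "base_len.txt"))[1]),
    repeats = readr::read_tsv(file.path(dir, "repeats.tsv"), show_col_types = FALSE)),
    class = "ig_reference")
}

#' Write / read simulated reads as FASTQ
#'
#' Pass counts and truth labels travel in the header comment
#' (`np:i:<passes> hp:i:<hap> hs:i:<start> he:i:<end> sm:Z:<sample>`).
#'
#' @param reads Read tibble.
#' @param path FASTQ path.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- sprintf("%s np:i:%d hp:i:%d hs:i:%d he:i:%d st:Z:%s sm:Z:%s",
                      reads$read_id, reads$n_passes, reads$truth_hap,
                      reads$truth_start, reads$truth_end, reads$truth_strand,
                      reads$sample)
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_fastq_reads <- function(path) {
  # the comment-field metadata is parsed from the names; the container's
  # own metadata-column note is irrelevant here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  nm <- names(x)
  field <- function(tag, type) {
    v <- stringr::str_match(nm, paste0(tag, ":[iZ]:([^ ]+)"))[, 2]
    if (type == "i") as.integer(v) else v
  }
  tibble(read_id = sub(" .*$", "", nm),
         seq = suppressWarnings(as.character(x)),
         qual = as.character(Biostrings::quality(x)),
         n_passes = field("np", "i"), truth_hap = field("hp", "i"),
         truth_start = field("hs", "i"), truth_end = field("he", "i"),
         truth_strand = field("st", "Z"), sample = field("sm", "Z"))
}

#' Write / read a diploid truth set
#'
#' SNVs go to a VCF (phased genotypes); indels and SVs to a BED with
#' explicit ref/alt sequence columns; allele truth and embedded-SV
#' genotypes to tab-delimited tables.
#'
#' @param truth An `ig_truth`.
#' @param dir Output directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snv <- filter(truth$variants, .data$type == "SNV")
  con <- file(file.path(dir, "truth_snv.vcf"), "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Planted variant origin\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##contig=<ID=", ref_seq_name, ">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTRUTH"), con)
  gt <- ifelse(snv$hap == 0L, "1/1", ifelse(snv$hap == 1L, "1|0", "0|1"))
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tORIGIN=%s\tGT\t%s",
                     ref_seq_name, snv$start + 1L, snv$ref, snv$alt,
                     snv$origin, gt), con)
  close(con)
  other <- filter(truth$variants, .data$type != "SNV")
  readr::write_tsv(other, file.path(dir, "truth_indel_sv.bed"))
  readr::write_tsv(truth$alleles, file.path(dir, "truth_alleles.tsv"))
  readr::write_tsv(truth$sv_genotypes, file.path(dir, "truth_sv_genotypes.tsv"))
  if (!is.null(truth$vdj)) readr::write_tsv(truth$vdj, file.path(dir, "truth_vdj.tsv"))
  invisible(dir)
}

#' @rdname write_truth
#' @return For the reader, a list with `variants`, `alleles`,
#'   `sv_genotypes`, `vdj` (haplotype sequences are not serialized; they
#'   are reproducible from the variants via [apply_variants()]).
#' @export
read_truth <- function(dir) {
  lines <- readLines(file.path(dir, "truth_snv.vcf"))
  rec <- lines[!startsWith(lines, "#")]
  f <- stringr::str_split_fixed(rec, "\t", 10)
  snv <- tibble(type = "SNV", start = as.integer(f[, 2]) - 1L,
                end = as.integer(f[, 2]),
                ref = f[, 4], alt = f[, 5],
                hap = c("1/1" = 0L, "1|0" = 1L, "0|1" = 2L)[f[, 10]],
                origin = sub("^ORIGIN=", "", f[, 8]))
  other <- readr::read_tsv(file.path(dir, "truth_indel_sv.bed"),
                           show_col_types = FALSE,
                           col_types = readr::cols(ref = "c", alt = "c")) %>%
    mutate(ref = ifelse(is.na(.data$ref), "", .data$ref),
           alt = ifelse(is.na(.data$alt), "", .data$alt))
  vdj_path <- file.path(dir, "truth_vdj.tsv")
  list(variants = arrange(bind_rows(snv, other), .data$start, .data$end),
       alleles = readr::read_tsv(file.path(dir, "truth_alleles.tsv"),
                                 show_col_types = FALSE),
       sv_genotypes = readr::read_tsv(file.path(dir, "truth_sv_genotypes.tsv"),
                                      show_col_types = FALSE),
       vdj = if (file.exists(vdj_path))
         readr::read_tsv(vdj_path, show_col_types = FALSE) else NULL)
}

# --- SAM -------------------------------------------------------------------

sam_header <- function(ref) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_seq_name, nchar(ref$seq)),
    "@RG\tID:hap1\tSM:sample\tDS:haplotype1",
    "@RG\tID:hap2\tSM:sample\tDS:haplotype2",
    "@RG\tID:unassigned\tSM:sample\tDS:unassigned")
}

#' Write phased read alignments as SAM
#'
#' Reads carry their haplotype in the read-group tag (`RG:Z:hap1`,
#' `RG:Z:hap2`, `RG:Z:unassigned`) and an `HP:i` tag, so a genome browser
#' can split the pileup by haplotype.
#'
#' @param phase An `ig_phase`.
#' @param ref An `ig_reference`.
#' @param path Output SAM path.
#' @export
write_sam <- function(phase, ref, path) {
  a <- left_join(phase$alignments, phase$assignments, by = "read_id") %>%
    arrange(.data$pos)
  rg <- ifelse(a$hap == 1L, "hap1", ifelse(a$hap == 2L, "hap2", "unassigned"))
  flag <- ifelse(a$strand == -1L, 16L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tRG:Z:%s\tHP:i:%d",
                   a$read_id, flag, ref_seq_name, a$pos + 1L, a$cigar,
                   a$aln_seq, rg, a$hap)
  writeLines(c(sam_header(ref), lines), path)
  invisible(path)
}

#' Write contig alignments as SAM
#' @param contigs Contig tibble.
#' @param ref An `ig_reference`.
#' @param path Output SAM path.
#' @export
write_contigs_sam <- function(contigs, ref, path) {
  cc <- arrange(contigs, .data$ref_start)
  lines <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tHP:i:%d\tqv:f:%.1f",
                   cc$contig_id, ref_seq_name, cc$ref_start + 1L, cc$cigar,
                   cc$seq, cc$hap, cc$mean_qv)
  writeLines(c(sam_header(ref), lines), path)
  invisible(path)
}

#' Write contigs as FASTA
#'
#' Headers carry block id, haplotype and mean QV.
#' @param contigs Contig tibble.
#' @param path Output path.
#' @export
write_contigs_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$seq)
  names(x) <- sprintf("%s block:%s hap:%d qv:%.1f", contigs$contig_id,
                      contigs$block_id, contigs$hap, contigs$mean_qv)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write haplotype blocks as BED
#' @param blocks Block tibble.
#' @param path Output path.
#' @export
write_blocks_bed <- function(blocks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%d", ref_seq_name, blocks$start,
                   blocks$end, blocks$block_id, blocks$class, blocks$n_snv)
  writeLines(lines, path)
  invisible(path)
}

# --- VCF -------------------------------------------------------------------

vcf_header <- function(ref, info_lines) {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", ref_seq_name, ",length=", nchar(ref$seq), ">"),
    info_lines,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
}

#' Write phased het SNVs (phase stage output) as VCF
#' @param phase An `ig_phase`. @param ref An `ig_reference`.
#' @param path Output path.
#' @export
write_phased_snv_vcf <- function(phase, ref, path) {
  s <- phase$snvs
  hdr <- vcf_header(ref, "##INFO=<ID=PS,Number=1,Type=String,Description=\"Phase set (block id)\">")
  gt <- ifelse(s$hap_alt == 1L, "1|0", "0|1")
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tPS=%s\tGT\t%s",
                   ref_seq_name, s$pos + 1L, s$ref_base, s$alt_base,
                   s$block_id, gt)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write called SNVs as an annotated VCF
#'
#' INFO keys: CONTIG, SVREGION, CCSSUPPORT, FEATURE, REGION, BLOCK.
#' Genotypes are phased within blocks.
#'
#' @param calls An `ig_calls` tibble.
#' @param ref An `ig_reference`.
#' @param path Output path.
#' @export
write_calls_vcf <- function(calls, ref, path) {
  s <- filter(calls, .data$type == "SNV")
  hdr <- vcf_header(ref, c(
    "##INFO=<ID=CONTIG,Number=1,Type=String,Description=\"Detecting contig\">",
    "##INFO=<ID=SVREGION,Number=1,Type=String,Description=\"Overlapping embedded SV\">",
    "##INFO=<ID=CCSSUPPORT,Number=1,Type=String,Description=\"Alt seen in CCS pileup\">",
    "##INFO=<ID=FEATURE,Number=1,Type=String,Description=\"Gene feature class\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Segment region\">",
    "##INFO=<ID=BLOCK,Number=1,Type=String,Description=\"Haplotype block\">",
    "##FILTER=<ID=no_ccs_support,Description=\"Alt absent from CCS pileup\">"))
  info <- sprintf("CONTIG=%s;SVREGION=%s;CCSSUPPORT=%s;FEATURE=%s;REGION=%s;BLOCK=%s",
                  s$contig_id, ifelse(is.na(s$sv_id), ".", s$sv_id),
                  ifelse(s$ccs_support, "true", "false"), s$feature,
                  ifelse(is.na(s$region), ".", s$region),
                  ifelse(is.na(s$block_id), ".", s$block_id))
  lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT\t%s",
                   ref_seq_name, s$start + 1L, s$ref, s$alt, s$filter, info,
                   s$genotype)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write indels and SVs as BED with explicit allele sequences
#' @param calls An `ig_calls` tibble.
#' @param path Output path.
#' @export
write_calls_bed <- function(calls, path) {
  s <- filter(calls, .data$type != "SNV")
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s", ref_seq_name,
                   s$start, s$end, s$type, s$size_class, s$ref, s$alt,
                   s$genotype, ifelse(s$vdj_flag, "vdj_suspect", "."))
  writeLines(c("#chrom\tstart\tend\ttype\tsize_class\tref\talt\tgenotype\tflag",
               lines), path)
  invisible(path)
}

#' Write embedded SV genotypes as a symbolic-allele VCF
#' @param sv_genotypes Genotype tibble from [genotype_svs()].
#' @param ref An `ig_reference`.
#' @param path Output path.
#' @export
write_sv_vcf <- function(sv_genotypes, ref, path) {
  g <- left_join(sv_genotypes, ref$svs, by = "sv_id")
  hdr <- vcf_header(ref, c(
    "##ALT=<ID=DEL,Description=\"Absence of the embedded SV body\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Body end\">",
    "##INFO=<ID=SVID,Number=1,Type=String,Description=\"Embedded SV id\">"))
  state_code <- function(s) ifelse(s == "absent", "1", ifelse(s == "present", "0", "."))
  gt <- paste0(state_code(g$hap1), "|", state_code(g$hap2))
  gt[g$genotype == "no-call"] <- "./."
  lines <- sprintf("%s\t%d\t%s\tN\t<DEL>\t.\tPASS\tEND=%d;SVID=%s\tGT\t%s",
                   ref_seq_name, g$start + 1L, g$sv_id, g$end, g$sv_id, gt)
  writeLines(c(hdr, lines), path)
  invisible(path)
}
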