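# broom-style tidiers for the pipeline's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ig_phase <- function(x, ...) {
  left_join(x$snvs,
            select(x$blocks, "block_id", block_class = "class"),
            by = "block_id")
}

#' @export
glance.ig_phase <- function(x, ...) {
  tibble(n_reads = nrow(x$alignments),
         n_assigned = sum(x$assignments$hap %in% c(1L, 2L)),
         n_het_snvs = nrow(x$snvs),
         n_blocks = nrow(x$blocks),
         n_het_blocks = sum(x$blocks$class == "heterozygous"),
         het_bases = sum(x$blocks$end[x$blocks$class == "heterozygous"] -
                           x$blocks$start[x$blocks$class == "heterozygous"]))
}

#' @export
tidy.ig_assembly <- function(x, ...) {
  mutate(select(x$contigs, -"seq"),
         length = nchar(x$contigs$seq),
         ref_end = .data$ref_start + cigar_ref_len(x$contigs$cigar))
}

#' @export
glance.ig_assembly <- function(x, ...) {
  tibble(n_contigs = nrow(x$contigs),
         assembled_bases = sum(nchar(x$contigs$seq)),
         mean_qv = mean(x$contigs$mean_qv),
         n_uncovered = nrow(x$uncovered),
         uncovered_bases = sum(x$uncovered$end - x$uncovered$start))
}

#' @export
glance.ig_calls <- function(x, ...) {
  p <- filter(x, .data$filter == "PASS")
  tibble(n_snv = sum(p$type == "SNV"),
         n_indel = sum(p$type == "indel" & p$size_class == "indel"),
         n_indel_1bp = sum(p$size_class == "special"),
         n_sv = sum(p$type == "SV"),
         n_vdj_flagged = sum(p$vdj_flag))
}

#' @export
tidy.ig_comparison <- function(x, ...) x$sites

#' @export
glance.ig_comparison <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn,
         genotype_discordant = x$genotype_discordant,
         excluded_unmappable = x$excluded_unmappable,
         recall = x$recall, precision = x$precision)
}
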