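# Genotyping of the reference-embedded biallelic SVs from assembly
# alignments, read-level junction evidence, depth ratios and SNV
# corroboration. Evidence priority: contig span/junction > read junction
# > depth ratio > SNV corroboration; absence is only called with junction
# evidence so that pure coverage dropout degrades calls toward no-call
# rather than flipping them.

#' Genotype one reference-embedded SV region
#'
#' Per haplotype: `present` when a contig aligns contiguously across at
#' least `span_frac` of the SV body; `absent` when a contig (or at least
#' two reads) aligns across the deletion junction with a gap spanning at
#' least `span_frac` of the body. When contigs are silent the read-depth
#' channel is consulted: body depth below `depth_absent` times the flank
#' depth together with junction-spanning reads implies `absent`; at least
#' `depth_present` times the flank depth implies `present`. SNVs called
#' inside the body corroborate presence. Unresolvable haplotypes yield
#' `no-call` with the evidence retained.
#'
#' @param sv One row of the reference `svs` table.
#' @param assembly An `ig_assembly`.
#' @param phase An `ig_phase`.
#' @param calls An `ig_calls` tibble (may be empty).
#' @param config Pipeline configuration.
#' @return One-row tibble with `sv_id`, `hap1`, `hap2`, `genotype` and
#'   evidence columns.
#' @export
genotype_embedded_sv <- function(sv, assembly, phase, calls,
                                 config = ig_config()) {
  if (!isTRUE(sv$biallelic)) abort("SV region is not biallelic")
  body_len <- sv$end - sv$start
  span_frac <- config$sv_span_frac
  contigs <- assembly$contigs
  aln <- left_join(phase$alignments, phase$assignments, by = "read_id")
  aln$ref_end <- aln$pos + cigar_ref_len(aln$cigar)

  # aligned (non-deleted) and deleted columns of an alignment within body
  body_profile <- function(cigar, pos) {
    ev <- cigar_events(cigar, pos)
    dels <- filter(ev, .data$kind == "D")
    del_in <- sum(pmax(0L, pmin(dels$ref_end, sv$end) - pmax(dels$ref_start, sv$start)))
    span <- c(pos, pos + cpp_cigar_ref_len(cigar))
    tot_in <- max(0L, min(span[2], sv$end) - max(span[1], sv$start))
    c(aligned = tot_in - del_in, deleted = del_in,
      crosses = as.integer(span[1] < sv$start & span[2] > sv$end))
  }

  contig_state <- function(haps) {
    cc <- filter(contigs, .data$hap %in% haps)
    if (nrow(cc) == 0L) return("silent")
    prof <- t(vapply(seq_len(nrow(cc)), function(i)
      body_profile(cc$cigar[i], cc$ref_start[i]), c(aligned = 0, deleted = 0, crosses = 0)))
    if (any(prof[, "aligned"] >= span_frac * body_len)) return("present")
    if (any(prof[, "deleted"] >= span_frac * body_len & prof[, "crosses"] == 1L))
      return("absent")
    "silent"
  }
  read_junctions <- function(haps) {
    rr <- filter(aln, .data$hap %in% haps,
                 .data$pos < sv$start, .data$ref_end > sv$end)
    if (nrow(rr) == 0L) return(0L)
    sum(vapply(seq_len(nrow(rr)), function(i)
      body_profile(rr$cigar[i], rr$pos[i])["deleted"] >= span_frac * body_len,
      logical(1)))
  }
  depth_ratio <- function(haps) {
    rr <- if (identical(haps, c(1L, 2L, 0L))) aln else
      filter(aln, .data$hap %in% haps)
    if (nrow(rr) == 0L) return(NA_real_)
    cover <- function(s, e) {
      ov <- pmin(rr$ref_end, e) - pmax(rr$pos, s)
      sum(pmax(0L, ov)) / max(1L, e - s)
    }
    fl <- config$sv_flank
    flank <- (cover(max(0L, sv$start - fl), sv$start) +
                cover(sv$end, min(nchar_ref(phase), sv$end + fl))) / 2
    if (flank <= 0) return(NA_real_)
    cover(sv$start, sv$end) / flank
  }
  snv_in_body <- if (nrow(calls) > 0L)
    sum(calls$type == "SNV" & calls$start >= sv$start & calls$start < sv$end)
  else 0L

  resolve_hap <- function(h) {
    st <- contig_state(c(h, 0L))
    if (st != "silent") return(st)
    nj <- read_junctions(c(h, 0L))
    if (nj >= config$sv_min_junction_reads) return("absent")
    dr <- depth_ratio(c(h, 0L))
    if (!is.na(dr) && dr >= config$sv_depth_present) return("present")
    "no-call"
  }
  h1 <- resolve_hap(1L); h2 <- resolve_hap(2L)
  # hemizygous refinement: an unphased (hap-0) contig spanning the body is
  # built from the present haplotype's reads; the total depth ratio says
  # whether both haplotypes carry it
  both0 <- all(contigs$hap == 0L | !(contigs$hap %in% c(1L, 2L))) ||
    nrow(filter(contigs, .data$hap %in% c(1L, 2L),
                .data$ref_start < sv$end,
                .data$ref_start + cigar_ref_len(.data$cigar) > sv$start)) == 0L
  dr_tot <- depth_ratio(c(1L, 2L, 0L))
  nj_tot <- read_junctions(c(1L, 2L, 0L))
  if (both0 && h1 == h2 && h1 == "present" && !is.na(dr_tot)) {
    if (dr_tot < config$sv_depth_absent && nj_tot >= config$sv_min_junction_reads) {
      h1 <- "absent"; h2 <- "absent"
    } else if (dr_tot < config$sv_depth_present &&
               nj_tot >= config$sv_min_junction_reads) {
      h2 <- "absent"
    }
  }
  gt <- if (h1 == "no-call" || h2 == "no-call") "no-call"
        else paste(sort(c(h1, h2), decreasing = TRUE), collapse = "/")
  tibble(sv_id = sv$sv_id, hap1 = h1, hap2 = h2, genotype = gt,
         depth_ratio = dr_tot, junction_reads = nj_tot,
         snvs_in_body = as.integer(snv_in_body))
}

nchar_ref <- function(phase) ncol(phase$pileup)

#' Genotype all biallelic embedded SV regions
#'
#' Applies [genotype_embedded_sv()] to every biallelic SV region in
#' coordinate order. Non-biallelic (structurally complex) regions are
#' excluded from automatic genotyping and listed in the curation report.
#'
#' @param assembly,phase,calls,ref,config Pipeline objects.
#' @return List: `genotypes` (tibble), `curation` (excluded regions).
#' @export
genotype_svs <- function(assembly, phase, calls, ref, config = ig_config()) {
  svs <- arrange(ref$svs, .data$start)
  auto <- filter(svs, .data$biallelic)
  rows <- lapply(seq_len(nrow(auto)), function(i)
    genotype_embedded_sv(auto[i, ], assembly, phase, calls, config))
  list(genotypes = bind_rows(rows),
       curation = filter(svs, !.data$biallelic))
}
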