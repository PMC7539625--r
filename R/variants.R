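# Variant detection from contig-to-reference alignments: per-base SNVs
# from mismatch columns, sequence-resolved indels/SVs from gap runs (with
# nearby-event merging and left-normalization), genotypes phased within
# blocks, and the six per-SNV annotations.

# contig alignment events -> raw per-hap variant rows
contig_events <- function(contig, refseq, merge_gap = 10L) {
  ev <- cigar_events(contig$cigar, contig$ref_start)
  if (nrow(ev) == 0L) return(NULL)
  gapev <- filter(ev, .data$kind != "X")
  xev <- filter(ev, .data$kind == "X")
  merged <- list()
  if (nrow(gapev) > 0L) {
    gapev <- arrange(gapev, .data$ref_start)
    cs <- gapev$ref_start[1]; ce <- gapev$ref_end[1]
    qs <- gapev$q_start[1]; qe <- gapev$q_end[1]
    flush <- function() merged[[length(merged) + 1L]] <<-
      tibble(ref_start = cs, ref_end = ce, q_start = qs, q_end = qe)
    for (i in seq_len(nrow(gapev))[-1]) {
      # matched columns between events: reference distance minus any
      # intervening mismatch columns
      between_x <- sum(pmin(xev$ref_end, gapev$ref_start[i]) -
                         pmax(xev$ref_start, ce) > 0)
      sep <- (gapev$ref_start[i] - ce) - between_x
      if (sep < merge_gap) {
        ce <- gapev$ref_end[i]; qe <- gapev$q_end[i]
      } else {
        flush()
        cs <- gapev$ref_start[i]; ce <- gapev$ref_end[i]
        qs <- gapev$q_start[i]; qe <- gapev$q_end[i]
      }
    }
    flush()
  }
  rows <- list()
  mg <- bind_rows(merged)
  # mismatch columns outside merged gap regions become SNVs
  if (nrow(xev) > 0L) {
    for (i in seq_len(nrow(xev))) {
      for (off in seq_len(xev$ref_end[i] - xev$ref_start[i]) - 1L) {
        p <- xev$ref_start[i] + off
        if (nrow(mg) > 0L && any(p >= mg$ref_start & p < mg$ref_end)) next
        rows[[length(rows) + 1L]] <- tibble(
          start = p, end = p + 1L,
          ref = seq_sub(refseq, p, p + 1L),
          alt = substr(contig$seq, xev$q_start[i] + off + 1L, xev$q_start[i] + off + 1L))
      }
    }
  }
  if (nrow(mg) > 0L) {
    for (i in seq_len(nrow(mg))) {
      refa <- seq_sub(refseq, mg$ref_start[i], mg$ref_end[i])
      alta <- substr(contig$seq, mg$q_start[i] + 1L, mg$q_end[i])
      nv <- normalize_variant(mg$ref_start[i], refa, alta, refseq)
      rows[[length(rows) + 1L]] <- tibble(start = as.integer(nv$pos),
                                          end = as.integer(nv$pos + nchar(nv$ref)),
                                          ref = nv$ref, alt = nv$alt)
    }
  }
  if (length(rows) == 0L) return(NULL)
  bind_rows(rows) %>%
    mutate(hap = contig$hap, block_id = contig$block_id,
           contig_id = contig$contig_id, mean_qv = contig$mean_qv)
}

#' Call SNVs, indels and SVs from haplotype assemblies
#'
#' Walks each contig's reference alignment: mismatch columns become SNVs;
#' gap runs (insertions/deletions, merged when separated by fewer than 10
#' matched columns) become sequence-resolved indel/SV events, classified
#' by length change (1 bp events are indels with `size_class` `"special"`,
#' 2-49 bp are indels, >= 50 bp are SVs). Events are left-normalized
#' against the reference. Genotypes combine the two haplotypes per block
#' (phased `a|b` in heterozygous blocks, `1/1` in
#' homozygous-or-hemizygous blocks, haploid `1` where the other haplotype
#' has no contig). SNVs carry the annotation set: detecting contig id,
#' overlapping embedded-SV id, CCS read support, gene feature class,
#' segment region, and block id.
#'
#' @param assembly An `ig_assembly`.
#' @param phase The `ig_phase` the assembly came from.
#' @param ref An `ig_reference`.
#' @param config Pipeline configuration.
#' @return An `ig_calls` tibble.
#' @export
call_variants <- function(assembly, phase, ref, config = ig_config()) {
  refseq <- ref$seq
  contigs <- assembly$contigs
  if (nrow(contigs) == 0L)
    return(empty_calls())
  raw <- bind_rows(lapply(seq_len(nrow(contigs)), function(i)
    contig_events(contigs[i, ], refseq, config$event_merge_gap)))
  if (is.null(raw) || nrow(raw) == 0L) return(empty_calls())
  # conflicting contigs covering the same event on one haplotype: the
  # higher-QV contig wins
  raw <- raw %>% arrange(desc(.data$mean_qv)) %>%
    distinct(.data$start, .data$end, .data$ref, .data$alt, .data$hap,
             .keep_all = TRUE)
  # per-haplotype reference coverage from contig spans
  spans <- tibble(start = contigs$ref_start,
                  end = contigs$ref_start + cigar_ref_len(contigs$cigar),
                  hap = contigs$hap)
  cov1 <- intervals_union(filter(spans, .data$hap %in% c(1L, 0L)))
  cov2 <- intervals_union(filter(spans, .data$hap %in% c(2L, 0L)))
  calls <- raw %>%
    group_by(.data$start, .data$end, .data$ref, .data$alt) %>%
    summarise(haps = list(sort(unique(.data$hap))),
              block_id = first(.data$block_id),
              contig_id = first(.data$contig_id), .groups = "drop")
  gt_of <- function(start, haps) {
    h <- haps
    if (0L %in% h) return("1/1")
    on1 <- 1L %in% h; on2 <- 2L %in% h
    c1 <- point_in_intervals(start, cov1); c2 <- point_in_intervals(start, cov2)
    if (on1 && on2) return("1|1")
    if (on1) { if (c2) "1|0" else "1" }
    else     { if (c1) "0|1" else "1" }
  }
  calls$genotype <- vapply(seq_len(nrow(calls)),
                           function(i) gt_of(calls$start[i], calls$haps[[i]]), "")
  calls <- calls %>%
    mutate(hap = vapply(.data$haps, function(h)
             if (length(h) == 1L) h else if (identical(h, c(1L, 2L))) 3L else 0L,
             0L),
           delta = abs(nchar(.data$ref) - nchar(.data$alt)),
           type = dplyr::case_when(
             nchar(.data$ref) == 1L & nchar(.data$alt) == 1L ~ "SNV",
             .data$delta >= 50L ~ "SV",
             TRUE ~ "indel"),
           size_class = classify_event_length(.data$delta),
           zygosity = dplyr::case_when(
             .data$genotype == "1/1" ~ "hom_block",
             .data$genotype == "1" ~ "haploid",
             .data$genotype == "1|1" ~ "hom",
             TRUE ~ "het")) %>%
    select(-"haps")
  ann <- annotate_positions(calls$start, ref)
  calls <- bind_cols(calls, select(ann, -"pos"))
  # CCS pileup support for SNVs
  calls$ccs_support <- NA
  snv_i <- which(calls$type == "SNV")
  if (length(snv_i) > 0L) {
    bases <- c("A", "C", "G", "T")
    pl <- phase$pileup
    supp <- vapply(snv_i, function(i) {
      col <- pl[1:4, calls$start[i] + 1L]
      depth <- sum(col)
      altc <- col[match(calls$alt[i], bases)]
      altc >= config$ccs_support_reads && depth > 0 &&
        altc / depth >= config$ccs_support_fraction
    }, logical(1))
    calls$ccs_support[snv_i] <- supp
  }
  # haploid SNVs (one haplotype lacks a contig at the site) with a
  # saturated CCS pileup and no deletion on the other haplotype are
  # homozygous: the missing contig is a coverage seam, not hemizygosity
  hap_dels <- filter(calls, .data$alt == "", .data$end - .data$start >= 1000L)
  hapl_i <- which(calls$type == "SNV" & calls$genotype == "1")
  if (length(hapl_i) > 0L) {
    bases <- c("A", "C", "G", "T")
    pl <- phase$pileup
    for (i in hapl_i) {
      other <- setdiff(1:2, calls$hap[i])
      hemi <- nrow(filter(hap_dels, .data$start <= calls$start[i],
                          .data$end > calls$start[i],
                          .data$hap %in% c(other, 3L))) > 0L
      col <- pl[1:4, calls$start[i] + 1L]
      af <- col[match(calls$alt[i], bases)] / max(1, sum(col))
      if (!hemi && !is.na(af) && af >= 0.8) {
        calls$genotype[i] <- "1/1"
        calls$zygosity[i] <- "hom_inferred"
      }
    }
  }
  # PASS filter for SNVs: beyond the ccs_support annotation, require a
  # pileup deep enough to corroborate and an alt fraction consistent with
  # a real allele (coincident read errors at thin columns fail this)
  calls$filter <- "PASS"
  if (length(snv_i) > 0L) {
    bases <- c("A", "C", "G", "T")
    pl <- phase$pileup
    for (i in snv_i) {
      col <- pl[1:4, calls$start[i] + 1L]
      depth <- sum(col)
      altc <- col[match(calls$alt[i], bases)]
      if (isFALSE(calls$ccs_support[i])) calls$filter[i] <- "no_ccs_support"
      else if (depth < config$min_depth || altc < config$snv_filter_min_alt ||
               altc / max(1, depth) < config$min_alt_fraction)
        calls$filter[i] <- "low_support"
    }
  }
  vdj <- detect_vdj_artifact(calls, ref, config)
  calls$vdj_flag <- FALSE
  if (nrow(vdj) > 0L) {
    for (i in seq_len(nrow(vdj)))
      calls$vdj_flag[calls$start >= vdj$start[i] & calls$end <= vdj$end[i] &
                       calls$hap == vdj$hap[i]] <- TRUE
  }
  out <- arrange(calls, .data$start, .data$end)
  attr(out, "vdj") <- vdj
  class(out) <- c("ig_calls", class(out))
  out
}

empty_calls <- function() {
  structure(tibble(start = integer(), end = integer(), ref = character(),
                   alt = character(), genotype = character(), hap = integer(),
                   block_id = character(), contig_id = character(),
                   delta = integer(), type = character(), size_class = character(),
                   zygosity = character(), gene = character(), feature = character(),
                   region = character(), sv_id = character(), ccs_support = logical(),
                   filter = character(), vdj_flag = logical()),
            class = c("ig_calls", class(tibble())))
}

#' @rdname call_variants
#' @details `call_snvs()` and `call_indels_svs()` return the SNV and
#'   indel/SV subsets of [call_variants()] respectively.
#' @export
call_snvs <- function(assembly, phase, ref, config = ig_config()) {
  filter(call_variants(assembly, phase, ref, config), .data$type == "SNV")
}

#' @rdname call_variants
#' @export
call_indels_svs <- function(assembly, phase, ref, config = ig_config()) {
  filter(call_variants(assembly, phase, ref, config), .data$type != "SNV")
}

#' Flag a putative V(D)J-like somatic deletion
#'
#' A single-haplotype deletion of at least `vdj_min_len` whose right edge
#' lies within `vdj_margin` of the J-proximal end of the locus (the end
#' of the last J gene) is flagged; downstream gene-loss calls within it
#' are artifact-suspect.
#'
#' @param calls An `ig_calls` tibble.
#' @param ref An `ig_reference`.
#' @param config Pipeline configuration.
#' @return Tibble with `hap`, `start`, `end` (possibly empty).
#' @export
detect_vdj_artifact <- function(calls, ref, config = ig_config()) {
  jg <- filter(ref$genes, .data$segment == "J")
  j_end <- if (nrow(jg) > 0L) max(jg$end) else nchar(ref$seq)
  hits <- calls %>%
    filter(.data$type == "SV", .data$alt == "",
           .data$end - .data$start >= config$vdj_min_len,
           abs(.data$end - j_end) <= config$vdj_margin,
           .data$hap %in% c(1L, 2L))
  if (nrow(hits) == 0L) return(tibble(hap = integer(), start = integer(),
                                      end = integer()))
  select(hits, "hap", "start", "end")
}
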