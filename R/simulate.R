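# Synthetic locus, diploid truth set, and long-read generator.
#
# The generator emulates a targeted-capture IGH-like locus: a custom
# reference with embedded SV bodies (alternate allele = absence), V/D/J
# gene segments with LP1/intron/exon/RS features, a tandem-repeat region,
# an allele database, diploid haplotypes carrying SNVs/indels/SVs/novel
# alleles and an optional V(D)J-like one-haplotype deletion, and CCS-grade
# reads with a homopolymer-biased error model.

#' Generate a synthetic custom locus reference and allele database
#'
#' Builds a random base locus, places V, D and J gene segments (with LP1,
#' intron, exon and RS features), a tandem-repeat region, and embedded SV
#' insertion sequences (the first of which itself contains gene segments,
#' so that absence of the body deletes genes), then splices everything into
#' a custom reference via [build_reference()]. A germline allele database
#' is derived from the reference exons (`*01`) plus extra alleles with 1-2
#' substitutions (`*02`, ...).
#'
#' @param locus_len Target custom-reference length in bp (base length is
#'   this minus the summed embedded-SV lengths).
#' @param n_v,n_d,n_j Number of V, D and J gene segments on the base locus.
#' @param sv_lens Lengths of the embedded SV insertion bodies.
#' @param n_sv_genes Gene segments embedded inside the first SV body.
#' @param tr_motif_len,tr_copies Tandem-repeat motif length and copy number.
#' @param n_alt_alleles Number of genes given a second database allele.
#' @param seed Random seed.
#' @return A list of class `ig_locus` with elements `ref` (an
#'   `ig_reference`) and `db` (tibble `gene`, `allele`, `seq`).
#' @export
sim_locus <- function(locus_len = 600000L, n_v = 30L, n_d = 6L, n_j = 4L,
                      sv_lens = c(25000L, 10000L), n_sv_genes = 2L,
                      tr_motif_len = 59L, tr_copies = 6L,
                      n_alt_alleles = 6L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base_len <- locus_len - sum(sv_lens)
  stopifnot(base_len > 30000L)
  base <- random_dna(base_len)

  gene_model <- function(prefix, n, lo, hi, segment) {
    # per-segment gene architecture, plus strand, on base coords
    span <- switch(segment, V = 475L, D = 65L, J = 75L)
    starts <- round(seq(lo, hi - span, length.out = n) +
                      runif(n, -0.15, 0.15) * (hi - lo) / max(n, 2))
    starts <- as.integer(pmax(lo, pmin(hi - span, sort(starts))))
    g <- tibble(gene = paste0(prefix, seq_len(n)),
                segment = segment, strand = "+",
                start = starts, end = starts + span,
                functional = sample(c(rep("functional", ceiling(0.8 * n)),
                                      rep("ORF", ceiling(0.1 * n)),
                                      rep("pseudogene", n))[seq_len(n)]))
    f <- switch(segment,
      V = bind_rows(tibble(gene = g$gene, feature = "LP1", start = g$start, end = g$start + 55L),
                    tibble(gene = g$gene, feature = "intron", start = g$start + 55L, end = g$start + 140L),
                    tibble(gene = g$gene, feature = "exon", start = g$start + 140L, end = g$start + 436L),
                    tibble(gene = g$gene, feature = "RS", start = g$start + 436L, end = g$start + 475L)),
      D = bind_rows(tibble(gene = g$gene, feature = "RS", start = g$start, end = g$start + 20L),
                    tibble(gene = g$gene, feature = "exon", start = g$start + 20L, end = g$start + 45L),
                    tibble(gene = g$gene, feature = "RS", start = g$start + 45L, end = g$start + 65L)),
      J = bind_rows(tibble(gene = g$gene, feature = "exon", start = g$start, end = g$start + 50L),
                    tibble(gene = g$gene, feature = "RS", start = g$start + 50L, end = g$start + 75L)))
    list(genes = g, features = f)
  }
  v <- gene_model("IGHV1-", n_v, round(0.05 * base_len), round(0.64 * base_len), "V")
  d <- gene_model("IGHD1-", n_d, round(0.70 * base_len), round(0.78 * base_len), "D")
  j <- gene_model("IGHJ", n_j, round(0.80 * base_len), round(0.86 * base_len), "J")
  genes <- bind_rows(v$genes, d$genes, j$genes)
  features <- bind_rows(v$features, d$features, j$features)

  # tandem repeat spliced into a gene-free stretch of the base V region
  motif <- random_dna(tr_motif_len)
  tr_seq <- strrep(motif, tr_copies)
  gaps <- intervals_complement(genes[, c("start", "end")], round(0.05 * base_len),
                               round(0.64 * base_len))
  gaps <- filter(gaps, .data$end - .data$start > nchar(tr_seq) + 2000L)
  stopifnot(nrow(gaps) > 0L)
  tr_pos <- as.integer(gaps$start[1] + 1000L)
  base <- paste0(seq_sub(base, 0L, tr_pos), tr_seq,
                 seq_sub(base, tr_pos, base_len - nchar(tr_seq)))
  shift_tr <- function(p) ifelse(p >= tr_pos, p + nchar(tr_seq), p)
  genes <- mutate(genes, start = as.integer(shift_tr(.data$start)),
                  end = as.integer(shift_tr(.data$end)))
  features <- mutate(features, start = as.integer(shift_tr(.data$start)),
                     end = as.integer(shift_tr(.data$end)))

  # embedded SV insertion points in gene-free stretches of the V region
  gaps <- intervals_complement(bind_rows(genes[, c("start", "end")],
                                         tibble(start = tr_pos, end = tr_pos + nchar(tr_seq))),
                               round(0.06 * base_len), round(0.62 * base_len))
  gaps <- arrange(filter(gaps, .data$end - .data$start > 2500L), -(.data$end - .data$start))
  stopifnot(nrow(gaps) >= length(sv_lens))
  ins_pos <- sort(as.integer(gaps$start[seq_along(sv_lens)] +
                               (gaps$end[seq_along(sv_lens)] - gaps$start[seq_along(sv_lens)]) %/% 2L))
  # first SV body carries gene segments of its own
  sv_seqs <- vapply(sv_lens, random_dna, "")
  sv_gene_local <- tibble(gene = character(), start = integer(), end = integer())
  if (n_sv_genes > 0L && length(sv_lens) > 0L) {
    span <- 475L
    loc <- as.integer(seq(2000L, sv_lens[1] - span - 2000L, length.out = n_sv_genes))
    sv_gene_local <- tibble(gene = paste0("IGHV9-", seq_len(n_sv_genes)),
                            start = loc, end = loc + span)
  }
  ref <- build_reference(base,
                         insertions = tibble(pos = ins_pos, seq = sv_seqs,
                                             sv_id = paste0("sv", seq_along(sv_lens))),
                         genes = genes, features = features)
  if (nrow(sv_gene_local) > 0L) {
    body <- ref$svs[ref$svs$sv_id == "sv1", ]
    g2 <- tibble(gene = sv_gene_local$gene, segment = "V", strand = "+",
                 start = body$start + sv_gene_local$start,
                 end = body$start + sv_gene_local$end,
                 functional = "functional")
    f2 <- bind_rows(
      tibble(gene = g2$gene, feature = "LP1", start = g2$start, end = g2$start + 55L),
      tibble(gene = g2$gene, feature = "intron", start = g2$start + 55L, end = g2$start + 140L),
      tibble(gene = g2$gene, feature = "exon", start = g2$start + 140L, end = g2$start + 436L),
      tibble(gene = g2$gene, feature = "RS", start = g2$start + 436L, end = g2$start + 475L))
    ref$genes <- arrange(bind_rows(ref$genes, g2), .data$start)
    ref$features <- arrange(bind_rows(ref$features, f2), .data$start)
  }
  tr_custom <- shift_custom(tr_pos, ins_pos, sv_lens)
  ref$repeats <- tibble(start = tr_custom, end = tr_custom + nchar(tr_seq),
                        motif = motif, copies = as.integer(tr_copies))

  # allele database from reference exons
  exons <- filter(ref$features, .data$feature == "exon") %>%
    left_join(select(ref$genes, "gene", "strand", "functional"), by = "gene") %>%
    filter(.data$functional != "pseudogene")
  db <- exons %>%
    mutate(seq = vapply(seq_len(n()), function(i) {
      s <- seq_sub(ref$seq, exons$start[i], exons$end[i])
      if (exons$strand[i] == "-") revcomp(s) else s
    }, ""), allele = "01") %>%
    select("gene", "allele", "seq")
  alt_genes <- sample(db$gene[nchar(db$seq) > 100L],
                      min(n_alt_alleles, sum(nchar(db$seq) > 100L)))
  alt <- db %>% filter(.data$gene %in% alt_genes) %>%
    mutate(allele = "02",
           seq = vapply(.data$seq, function(s) {
             p <- sample(nchar(s), sample(1:2, 1))
             for (q in p) substr(s, q, q) <- other_base(substr(s, q, q))
             s
           }, ""))
  db <- arrange(bind_rows(db, alt), .data$gene, .data$allele)
  structure(list(ref = ref, db = db), class = "ig_locus")
}

shift_custom <- function(p, ins_pos, ins_lens) {
  as.integer(p + sum(ins_lens[ins_pos <= p]))
}

# ---------------------------------------------------------------------------

#' Simulate a diploid truth set over a custom reference
#'
#' Plants phased SNVs, indels (2-49 bp), SVs (>= 50 bp; deletion of an
#' embedded SV body, a novel deletion, and a tandem-repeat copy-number
#' expansion), novel and alternate database alleles, and an optional
#' V(D)J-like one-haplotype deletion whose right edge abuts the J-proximal
#' end of the locus. Variant footprints never overlap; random small
#' variants avoid gene exons so allele truth stays defined by the allele
#' specification. Each heterozygous indel/SV breakpoint has a heterozygous
#' SNV planted within linking distance, reflecting that divergent
#' haplotypes carry linked SNVs (read-backed phasing is SNV-based).
#'
#' @param locus An `ig_locus` from [sim_locus()] (or a list with `ref` and
#'   `db`).
#' @param n_snv_het,n_snv_hom Total heterozygous / homozygous SNVs.
#' @param n_indel Number of 2-49 bp indels (half heterozygous).
#' @param sv_spec Which SV classes to plant: any of `"embedded_del"`,
#'   `"novel_del"`, `"tr_expansion"`.
#' @param novel_del_len Length of the novel deletion.
#' @param n_novel_alleles Genes given a novel (not-in-database) allele via
#'   1-3 exonic substitutions on one haplotype.
#' @param n_known_alt Genes given the database `*02` allele on one
#'   haplotype.
#' @param vdj Plant a V(D)J-like deletion on haplotype 2.
#' @param link_dist Maximum distance from a het indel/SV breakpoint to its
#'   linked het SNV.
#' @param seed Random seed.
#' @return A list of class `ig_truth`: `variants` (tibble with `type`,
#'   `start`, `end`, `ref`, `alt`, `hap` (0 = both), `origin`), `hap_seqs`,
#'   `maps`, `alleles`, `sv_genotypes`, `vdj`.
#' @export
sim_diploid <- function(locus, n_snv_het = 200L, n_snv_hom = 100L,
                        n_indel = 20L, sv_spec = c("embedded_del", "novel_del",
                                                   "tr_expansion"),
                        novel_del_len = 2000L, n_novel_alleles = 3L,
                        n_known_alt = 2L, vdj = TRUE, link_dist = 2000L,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- locus$ref; db <- locus$db
  L <- nchar(ref$seq)
  vars <- tibble(type = character(), start = integer(), end = integer(),
                 ref = character(), alt = character(), hap = integer(),
                 origin = character())
  # regions barred to random variant placement
  occupied <- bind_rows(
    mutate(filter(ref$features, .data$feature == "exon"),
           start = .data$start - 20L, end = .data$end + 20L)[, c("start", "end")],
    mutate(ref$repeats[, c("start", "end")], start = .data$start - 200L,
           end = .data$end + 200L))
  block <- function(s, e, margin = 60L)
    occupied <<- bind_rows(occupied, tibble(start = s - margin, end = e + margin))

  add_var <- function(type, start, end, refa, alta, hap, origin) {
    vars <<- bind_rows(vars, tibble(type = type, start = as.integer(start),
                                    end = as.integer(end), ref = refa, alt = alta,
                                    hap = as.integer(hap), origin = origin))
  }
  plant_snv <- function(pos, hap, origin) {
    rb <- seq_sub(ref$seq, pos, pos + 1L)
    add_var("SNV", pos, pos + 1L, rb, other_base(rb), hap, origin)
    block(pos, pos + 1L)
  }
  free_pos <- function(width, lo = 2000L, hi = L - 2000L) {
    for (i in 1:500) {
      p <- as.integer(runif(1, lo, hi - width))
      if (!overlaps_any(p, p + width, occupied)) return(p)
    }
    abort("infeasible configuration: requested variant footprint exceeds free locus space")
  }
  linked_snv <- function(bp_left, bp_right, hap) {
    # one het SNV within link_dist on each side of a het event's breakpoints
    for (side in c("left", "right")) {
      for (i in 1:200) {
        p <- if (side == "left") as.integer(bp_left - runif(1, 300, link_dist))
             else as.integer(bp_right + runif(1, 300, link_dist))
        if (p > 50L && p < L - 50L && !overlaps_any(p, p + 1L, occupied)) {
          plant_snv(p, sample(1:2, 1), "linked")
          break
        }
      }
    }
  }

  # --- V(D)J-like deletion (hap 2), right edge at the J-proximal end -------
  # planted (pre-normalization) deletion intervals, used for gene-loss truth
  planted_dels <- tibble(start = integer(), end = integer(), hap = integer(),
                         origin = character())
  vdj_iv <- NULL
  jend <- max(filter(ref$genes, .data$segment == "J")$end)
  if (isTRUE(vdj)) {
    dstart <- min(filter(ref$genes, .data$segment == "D")$start)
    vs <- as.integer(dstart - 10000L)
    nv <- normalize_variant(vs, seq_sub(ref$seq, vs, jend), "", ref$seq)
    add_var("SV", nv$pos, nv$pos + (jend - vs), nv$ref, "", 2L, "vdj")
    planted_dels <- bind_rows(planted_dels,
                              tibble(start = vs, end = jend, hap = 2L,
                                     origin = "vdj"))
    block(vs, jend, 300L)
    vdj_iv <- tibble(hap = 2L, start = vs, end = jend)
    linked_snv(vs, jend, 2L)
  }

  # --- SVs ------------------------------------------------------------------
  svgt <- tibble(sv_id = ref$svs$sv_id,
                 hap1 = rep("present", nrow(ref$svs)),
                 hap2 = rep("present", nrow(ref$svs)))
  if ("embedded_del" %in% sv_spec && nrow(ref$svs) > 0L) {
    body <- ref$svs[1, ]
    nv <- normalize_variant(body$start,
                            seq_sub(ref$seq, body$start, body$end), "", ref$seq)
    add_var("SV", nv$pos, nv$pos + (body$end - body$start), nv$ref, "", 2L,
            "embedded_del")
    planted_dels <- bind_rows(planted_dels,
                              tibble(start = body$start, end = body$end,
                                     hap = 2L, origin = "embedded_del"))
    block(body$start, body$end, 300L)
    svgt$hap2[1] <- "absent"
    linked_snv(body$start, body$end, 2L)
  }
  if ("novel_del" %in% sv_spec) {
    p <- free_pos(novel_del_len + 600L, lo = round(0.05 * L), hi = round(0.6 * L))
    nv <- normalize_variant(p, seq_sub(ref$seq, p, p + novel_del_len), "", ref$seq)
    add_var("SV", nv$pos, nv$pos + novel_del_len, nv$ref, "", 1L, "novel_del")
    planted_dels <- bind_rows(planted_dels,
                              tibble(start = p, end = p + novel_del_len,
                                     hap = 1L, origin = "novel_del"))
    block(p, p + novel_del_len, 300L)
    linked_snv(p, p + novel_del_len, 1L)
  }
  if ("tr_expansion" %in% sv_spec && nrow(ref$repeats) > 0L) {
    tr <- ref$repeats[1, ]
    extra <- strrep(tr$motif, 2L)         # +2 copies = 118 bp for a 59-mer
    nv <- normalize_variant(tr$end, "", extra, ref$seq)
    add_var("SV", nv$pos, nv$pos, "", nv$alt, 2L, "tr_expansion")
    linked_snv(tr$start, tr$end, 2L)
  }

  # --- gene alleles ---------------------------------------------------------
  exon_tbl <- filter(ref$features, .data$feature == "exon") %>%
    left_join(select(ref$genes, "gene", "strand", "functional"), by = "gene")
  callable <- exon_tbl %>%
    filter(.data$functional != "pseudogene",
           !overlaps_any(.data$start, .data$end,
                         bind_rows(if (!is.null(vdj_iv)) vdj_iv[, c("start", "end")],
                                   filter(vars, .data$type == "SV")[, c("start", "end")])),
           .data$end - .data$start > 100L)
  multi <- db %>% count(.data$gene) %>% filter(.data$n > 1L) %>% pull(.data$gene)
  novel_pool <- setdiff(callable$gene, multi)   # a sub cannot recreate a db allele
  alt_pool <- intersect(callable$gene, multi)
  novel_genes <- sample(novel_pool, min(n_novel_alleles, length(novel_pool)))
  alt_genes <- sample(alt_pool, min(n_known_alt, length(alt_pool)))
  alleles <- tidyr::crossing(
    gene = unique(filter(exon_tbl, .data$functional != "pseudogene")$gene),
    hap = 1:2) %>%
    mutate(allele = "01", status = "known")
  set_allele <- function(g, h, allele, status) {
    idx <- alleles$gene == g & alleles$hap == h
    alleles$allele[idx] <<- allele
    alleles$status[idx] <<- status
  }
  for (g in novel_genes) {
    e <- exon_tbl[exon_tbl$gene == g, ]
    h <- sample(1:2, 1)
    k <- sample(1:3, 1)
    ps <- sort(sample(seq(e$start + 3L, e$end - 3L), k))
    for (p in ps) plant_snv(p, h, "novel_allele")
    set_allele(g, h, NA_character_, "novel")
  }
  for (g in alt_genes) {
    e <- exon_tbl[exon_tbl$gene == g, ]
    a2 <- db[db$gene == g & db$allele == "02", ]
    if (nrow(a2) == 0L) next
    refx <- seq_sub(ref$seq, e$start, e$end)
    altx <- if (e$strand == "-") revcomp(a2$seq) else a2$seq
    h <- sample(1:2, 1)
    d <- which(strsplit(refx, "")[[1]] != strsplit(altx, "")[[1]])
    for (p in d) add_var("SNV", e$start + p - 1L, e$start + p,
                         substr(refx, p, p), substr(altx, p, p), h, "allele_alt")
    block(e$start, e$end)
    set_allele(g, h, "02", "known")
  }
  # genes lost to the embedded-body deletion / V(D)J event (judged on the
  # planted intervals: normalization may slide an equivalent deletion)
  for (i in seq_len(nrow(ref$genes))) {
    g <- ref$genes[i, ]
    lost <- filter(planted_dels, .data$start <= g$start, .data$end >= g$end)
    for (k in seq_len(nrow(lost))) {
      st <- if (lost$origin[k] == "vdj") "vdj" else "deleted"
      if (g$functional != "pseudogene")
        set_allele(g$gene, lost$hap[k], NA_character_, st)
    }
  }

  # --- indels ---------------------------------------------------------------
  n_het_ind <- n_indel %/% 2L
  for (i in seq_len(n_indel)) {
    len <- sample(2:49, 1)
    is_del <- runif(1) < 0.5
    hap <- if (i <= n_het_ind) sample(1:2, 1) else 0L
    p <- free_pos(len + 120L)
    if (is_del) {
      nv <- normalize_variant(p, seq_sub(ref$seq, p, p + len), "", ref$seq)
      add_var("indel", nv$pos, nv$pos + len, nv$ref, "", hap, "random")
      block(nv$pos, nv$pos + len)
    } else {
      nv <- normalize_variant(p, "", random_dna(len), ref$seq)
      add_var("indel", nv$pos, nv$pos, "", nv$alt, hap, "random")
      block(nv$pos, nv$pos)
    }
    if (hap != 0L) linked_snv(p, p + if (is_del) len else 0L, hap)
  }

  # --- remaining SNV budget (all het SNVs, whatever their origin) -----------
  n_het_used <- sum(vars$type == "SNV" & vars$hap != 0L)
  for (i in seq_len(max(0L, n_snv_het - n_het_used)))
    plant_snv(free_pos(60L), sample(1:2, 1), "random")
  for (i in seq_len(n_snv_hom))
    plant_snv(free_pos(60L), 0L, "random")

  vars <- arrange(vars, .data$start, .data$end)
  h1 <- apply_variants(ref$seq, vars, 1L)
  h2 <- apply_variants(ref$seq, vars, 2L)
  structure(list(variants = vars,
                 hap_seqs = c(h1$seq, h2$seq),
                 maps = list(h1$map, h2$map),
                 alleles = arrange(alleles, .data$gene, .data$hap),
                 sv_genotypes = mutate(svgt,
                   genotype = paste(.data$hap1, .data$hap2, sep = "/")),
                 vdj = vdj_iv, ref_len = L),
            class = "ig_truth")
}

#' Apply a phased variant table to a reference sequence
#'
#' @param refseq Reference sequence (character scalar).
#' @param variants Variant tibble as produced by [sim_diploid()].
#' @param hap Haplotype to build (1 or 2); rows with `hap == 0` apply to
#'   both.
#' @return List with `seq` (the haplotype sequence) and `map`, a tibble of
#'   identity segments (`ref_start`, `ref_end`, `hap_start`).
#' @export
apply_variants <- function(refseq, variants, hap) {
  v <- variants %>% filter(.data$hap %in% c(!!hap, 0L)) %>%
    arrange(.data$start, .data$end)
  if (nrow(v) > 1L && any(v$start[-1] < v$end[-nrow(v)]))
    abort("variant footprints overlap")
  pieces <- character(0)
  map <- tibble(ref_start = integer(), ref_end = integer(), hap_start = integer())
  cur_ref <- 0L; cur_hap <- 0L
  for (i in seq_len(nrow(v))) {
    seg <- seq_sub(refseq, cur_ref, v$start[i])
    map <- bind_rows(map, tibble(ref_start = cur_ref, ref_end = v$start[i],
                                 hap_start = cur_hap))
    pieces <- c(pieces, seg, v$alt[i])
    cur_hap <- cur_hap + nchar(seg) + nchar(v$alt[i])
    cur_ref <- v$end[i]
  }
  seg <- seq_sub(refseq, cur_ref, nchar(refseq))
  map <- bind_rows(map, tibble(ref_start = cur_ref, ref_end = nchar(refseq),
                               hap_start = cur_hap))
  list(seq = paste(c(pieces, seg), collapse = ""), map = map)
}

# project a reference position onto a haplotype via its identity-segment
# map; positions inside a deletion snap to the downstream junction
hap_pos <- function(map, p) {
  i <- findInterval(p, map$ref_start)
  out <- integer(length(p))
  for (k in seq_along(p)) {
    ik <- i[k]
    if (ik >= 1L && p[k] < map$ref_end[ik])
      out[k] <- map$hap_start[ik] + p[k] - map$ref_start[ik]
    else if (ik < nrow(map)) out[k] <- map$hap_start[ik + 1L]
    else out[k] <- map$hap_start[nrow(map)] +
        (map$ref_end[nrow(map)] - map$ref_start[nrow(map)])
  }
  out
}

#' Extract the truth-haplotype sequence over a reference interval
#'
#' @param truth An `ig_truth`.
#' @param hap Haplotype (1 or 2).
#' @param start,end Reference interval (0-based half-open).
#' @return Character scalar (possibly shorter than the interval when a
#'   deletion overlaps it).
#' @export
truth_segment <- function(truth, hap, start, end) {
  m <- truth$maps[[hap]]
  seq_sub(truth$hap_seqs[hap], hap_pos(m, start), hap_pos(m, end))
}

# ---------------------------------------------------------------------------

#' Simulate CCS-grade reads from a diploid truth set
#'
#' Reads are sampled per haplotype to a target depth with normally
#' distributed lengths, random strand, an optional error model (mismatch
#' and indel rates, with indels biased into homopolymer runs), optional
#' coverage-dropout intervals (capture-bias stand-in), and a subread-pass
#' count per molecule. With zero error rates every read is an exact
#' substring of its source haplotype.
#'
#' @param truth An `ig_truth`.
#' @param coverage Target depth per haplotype.
#' @param read_len_mean,read_len_sd Read length distribution (bp).
#' @param error List with `mismatch`, `indel` (per-base rates) and
#'   `hp_bias` (fraction of indels forced into/adjacent to homopolymer
#'   runs of length >= 3).
#' @param dropout Tibble of reference intervals (`start`, `end`,
#'   `keep_prob`): reads overlapping them by more than half their length
#'   are kept with the given probability.
#' @param passes_lambda Mean extra passes; `n_passes = 2 + Poisson(lambda)`
#'   except for a `p_single` fraction of single-pass molecules.
#' @param p_single Fraction of molecules with a single pass (dropped by the
#'   pipeline's read filter).
#' @param sample_id Sample label carried into read ids.
#' @param seed Random seed.
#' @return Tibble: `read_id`, `seq`, `qual`, `n_passes`, `truth_hap`,
#'   `truth_start`, `truth_end`, `truth_strand`, `sample`.
#' @export
sim_reads <- function(truth, coverage = 20, read_len_mean = 6457,
                      read_len_sd = 1200,
                      error = list(mismatch = 0, indel = 0, hp_bias = 0),
                      dropout = NULL, passes_lambda = 6, p_single = 0,
                      sample_id = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  error <- utils::modifyList(list(mismatch = 0, indel = 0, hp_bias = 0), as.list(error))
  stopifnot(error$mismatch >= 0, error$mismatch <= 1,
            error$indel >= 0, error$indel <= 1)
  out <- list()
  for (h in 1:2) {
    hs <- truth$hap_seqs[h]
    L <- nchar(hs)
    n <- round(coverage * L / read_len_mean)
    lens <- pmin(L, pmax(500L, round(rnorm(n, read_len_mean, read_len_sd))))
    starts <- floor(runif(n, 0, L - lens + 1))
    keep <- rep(TRUE, n)
    if (!is.null(dropout) && nrow(dropout) > 0L) {
      dh <- mutate(dropout, start = hap_pos(truth$maps[[h]], .data$start),
                   end = hap_pos(truth$maps[[h]], .data$end))
      for (i in seq_len(nrow(dh))) {
        ov <- pmin(starts + lens, dh$end[i]) - pmax(starts, dh$start[i])
        in_do <- ov > lens / 2
        keep[in_do] <- keep[in_do] & (runif(sum(in_do)) < dh$keep_prob[i])
      }
    }
    starts <- starts[keep]; lens <- lens[keep]; n <- sum(keep)
    seqs <- substring(hs, starts + 1L, starts + lens)
    err_tot <- error$mismatch + error$indel
    if (err_tot > 0) seqs <- inject_errors(seqs, error)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    np <- ifelse(runif(n) < p_single, 1L, 2L + rpois(n, passes_lambda))
    q <- as.integer(round(phred(max(err_tot, 1e-7))))
    out[[h]] <- tibble(
      read_id = sprintf("%s/h%d/%06d/ccs", sample_id, h, seq_len(n)),
      seq = seqs,
      qual = strrep(intToUtf8(q + 33L), nchar(seqs)),
      n_passes = np, truth_hap = h, truth_start = as.integer(starts),
      truth_end = as.integer(starts + lens), truth_strand = strand,
      sample = sample_id)
  }
  bind_rows(out)
}

# substitution + homopolymer-biased indel injection
inject_errors <- function(seqs, error) {
  codes <- utf8ToInt("ACGT")
  vapply(seqs, function(s) {
    v <- utf8ToInt(s)
    n <- length(v)
    nmm <- rbinom(1, n, error$mismatch)
    if (nmm > 0) {
      p <- sample.int(n, nmm)
      idx <- match(v[p], codes)
      v[p] <- codes[((idx - 1L + sample.int(3L, nmm, replace = TRUE)) %% 4L) + 1L]
    }
    nind <- rbinom(1, n, error$indel)
    if (nind > 0) {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      hp <- which(r$lengths >= 3L)
      hp_pool <- if (length(hp) > 0L)
        unlist(lapply(hp, function(i) (ends[i] - r$lengths[i] + 1L):ends[i]))
      else integer(0)
      biased <- runif(nind) < error$hp_bias & length(hp_pool) > 0L
      pos <- integer(nind)
      pos[biased] <- hp_pool[sample.int(length(hp_pool), sum(biased), replace = TRUE)]
      pos[!biased] <- sample.int(n, sum(!biased), replace = TRUE)
      lens <- ifelse(runif(nind) < 0.9, 1L, 2L)
      del <- runif(nind) < 0.5
      for (i in order(-pos)) {
        p <- min(pos[i], length(v))
        if (del[i]) {
          v <- v[-(p:min(length(v), p + lens[i] - 1L))]
        } else {
          v <- append(v, codes[sample.int(4L, lens[i], replace = TRUE)], after = p)
        }
      }
    }
    intToUtf8(v)
  }, "", USE.NAMES = FALSE)
}

#' Combine or downsample per-sample readsets to simulated multiplex levels
#'
#' Holds the total sequencing yield fixed: at plex level `p` each simulated
#' sample receives `total_yield / p` bases, drawn from the pooled reads in
#' a seed-reproducible random order. One representative sample per plex
#' level is returned.
#'
#' @param readsets List of read tibbles (technical replicates).
#' @param plex_levels Integer vector of multiplex levels (>= 1).
#' @param seed Random seed.
#' @return Named list (one element per plex level) of read tibbles.
#' @export
sim_multiplex <- function(readsets, plex_levels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(plex_levels >= 1))
  pool <- bind_rows(readsets)
  total <- sum(nchar(pool$seq))
  ord <- sample.int(nrow(pool))
  cum <- cumsum(nchar(pool$seq[ord]))
  out <- lapply(plex_levels, function(p) {
    target <- total / p
    k <- findInterval(target, cum) + 1L
    pool[sort(ord[seq_len(min(k, nrow(pool)))]), ]
  })
  names(out) <- paste0("plex", plex_levels)
  out
}

#' Emit noisy subread copies per molecule
#'
#' A minimal stand-in for raw subreads: each read yields `n_passes`
#' substitution-noisy copies. Used to exercise the pass-count filter and
#' the subread-recruitment fallback; consensus machinery proper is out of
#' scope.
#'
#' @param reads Read tibble from [sim_reads()].
#' @param sub_rate Per-base substitution rate per copy.
#' @param seed Random seed.
#' @return Tibble with `molecule_id`, `copy`, `seq`.
#' @export
sim_subread_copies <- function(reads, sub_rate = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    k <- reads$n_passes[i]
    tibble(molecule_id = reads$read_id[i], copy = seq_len(k),
           seq = vapply(seq_len(k), function(j) {
             v <- strsplit(reads$seq[i], "")[[1]]
             nm <- rbinom(1, length(v), sub_rate)
             if (nm > 0) { p <- sample.int(length(v), nm); v[p] <- other_base(v[p]) }
             paste(v, collapse = "")
           }, ""))
  })
  bind_rows(rows)
}

#' Collapse subread copies by per-column majority vote
#'
#' @param subreads Tibble from [sim_subread_copies()].
#' @return Tibble with `molecule_id`, `n_passes`, `seq`.
#' @export
collapse_subreads <- function(subreads) {
  subreads %>% group_by(.data$molecule_id) %>%
    summarise(n_passes = dplyr::n(), seq = {
      m <- do.call(rbind, strsplit(.data$seq, ""))
      paste(apply(m, 2, function(col) names(sort(table(col), decreasing = TRUE))[1]),
            collapse = "")
    }, .groups = "drop")
}
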