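# Haplotype assembly: reference-guided layout chains per (block, haplotype)
# bin, majority consensus with per-column quality, subread-recruitment
# retry for uncovered regions, QV filtering and overlap merging.

#' Assemble the reads of one (block, haplotype) bin into contigs
#'
#' Reads (already aligned to the reference) are sorted by start and
#' chained while consecutive reads overlap by at least `min_overlap`;
#' each chain yields one contig by per-column majority consensus, with a
#' per-column agreement-derived quality (phred of column disagreement,
#' capped at 60). Reads below `min_identity` against the reference are
#' excluded before layout. Deterministic for a given input set.
#'
#' @param bin_aln Alignment tibble for the bin's reads.
#' @param refseq Reference sequence string.
#' @param span Optional c(start, end) to trim the consensus to.
#' @param min_overlap Minimum read-to-chain overlap in bp.
#' @param min_identity Minimum read alignment identity.
#' @return Tibble of contigs: `ref_start`, `seq`, `cigar`, `mean_qv`,
#'   `n_reads`.
#' @export
assemble_block <- function(bin_aln, refseq, span = NULL,
                           min_overlap = 1L, min_identity = 0.9) {
  a <- bin_aln %>% filter(.data$mapped, .data$identity >= min_identity) %>%
    arrange(.data$pos, .data$read_id)
  if (nrow(a) == 0L)
    return(tibble(ref_start = integer(), seq = character(), cigar = character(),
                  mean_qv = double(), n_reads = integer()))
  a$ref_end <- a$pos + cigar_ref_len(a$cigar)
  # layout chains on reference coordinates
  chain_id <- integer(nrow(a))
  cur <- 1L; cur_end <- a$ref_end[1]; chain_id[1] <- 1L
  for (i in seq_len(nrow(a))[-1]) {
    if (a$pos[i] <= cur_end - min_overlap) {
      chain_id[i] <- cur
      cur_end <- max(cur_end, a$ref_end[i])
    } else {
      cur <- cur + 1L; chain_id[i] <- cur; cur_end <- a$ref_end[i]
    }
  }
  out <- list()
  for (cid in unique(chain_id)) {
    cc <- a[chain_id == cid, ]
    s <- min(cc$pos); e <- max(cc$ref_end)
    if (!is.null(span)) { s <- max(s, span[1]); e <- min(e, span[2]) }
    if (e <= s) next
    pieces <- cpp_consensus(refseq, cc$pos, cc$cigar, cc$aln_seq, s, e)
    for (p in pieces)
      out[[length(out) + 1L]] <- tibble(ref_start = p$ref_start, seq = p$seq,
                                        cigar = p$cigar, mean_qv = p$mean_qv,
                                        n_reads = nrow(cc))
  }
  bind_rows(out)
}

#' Drop contigs below a mean consensus quality
#'
#' Contigs with `mean_qv < qv_min` are removed (strict: a contig at
#' exactly the threshold is retained). Idempotent and order-preserving.
#'
#' @param contigs Contig tibble.
#' @param qv_min Phred threshold (default 20).
#' @return Filtered tibble.
#' @export
filter_contigs <- function(contigs, qv_min = 20) {
  filter(contigs, .data$mean_qv >= qv_min)
}

#' Retry uncovered regions by recruiting a fallback read pool
#'
#' Reference intervals covered by reads but by no contig are reassembled
#' from a recruitment pool (raw subreads when available, otherwise all
#' unfiltered reads, including single-pass molecules). Newly covered
#' regions leave the uncovered set.
#'
#' @param contigs Current contig tibble (with `block_id`, `hap` columns).
#' @param covered Tibble of read-covered intervals (`start`, `end`).
#' @param pool_aln Alignment tibble for the recruitment pool.
#' @param refseq Reference sequence.
#' @param config Pipeline configuration.
#' @return List: `contigs` (input plus recruited contigs, `hap = 0`,
#'   `recruited = TRUE`), `uncovered` (remaining uncovered intervals).
#' @export
recruit_and_retry <- function(contigs, covered, pool_aln, refseq,
                              config = ig_config()) {
  have <- if (nrow(contigs) > 0L)
    tibble(start = contigs$ref_start,
           end = contigs$ref_start + cigar_ref_len(contigs$cigar))
  else tibble(start = integer(), end = integer())
  unc <- bind_rows(lapply(seq_len(nrow(covered)), function(i) {
    gaps <- intervals_complement(have, covered$start[i], covered$end[i])
    filter(gaps, .data$end - .data$start >= 100L)
  }))
  if (nrow(unc) == 0L || nrow(pool_aln) == 0L)
    return(list(contigs = contigs, uncovered = unc))
  pool_aln$ref_end <- pool_aln$pos + cigar_ref_len(pool_aln$cigar)
  extra <- list()
  for (i in seq_len(nrow(unc))) {
    sub <- filter(pool_aln, .data$ref_end > unc$start[i], .data$pos < unc$end[i])
    if (nrow(sub) == 0L) next
    ct <- assemble_block(sub, refseq, span = c(unc$start[i], unc$end[i]),
                         min_overlap = config$min_layout_overlap,
                         min_identity = config$min_read_identity)
    if (nrow(ct) > 0L)
      extra[[length(extra) + 1L]] <- mutate(ct, block_id = NA_character_,
                                            hap = 0L, recruited = TRUE)
  }
  newc <- bind_rows(c(list(mutate(contigs, recruited = FALSE)), extra))
  have2 <- tibble(start = newc$ref_start,
                  end = newc$ref_start + cigar_ref_len(newc$cigar))
  unc2 <- bind_rows(lapply(seq_len(nrow(covered)), function(i) {
    gaps <- intervals_complement(have2, covered$start[i], covered$end[i])
    filter(gaps, .data$end - .data$start >= 100L)
  }))
  list(contigs = newc, uncovered = unc2)
}

#' Merge contigs sharing high-identity end overlaps
#'
#' All-vs-all end-overlap search among contigs of the same haplotype
#' label (or unphased): the best shared k-mer diagonal proposes an
#' overlap, which is verified by affine alignment; pairs overlapping by
#' at least `min_overlap_bp` with a mismatch rate at most
#' `max_mismatch_rate` and at most `max_gap_bases` gap bases are merged
#' (the overlap sequence is taken from the higher mean-QV contig), and
#' the search repeats to a fixed point. A three-way contradictory overlap
#' is reported and left unmerged.
#'
#' @param contigs Contig tibble with `contig_id`, `seq`, `mean_qv`, `hap`.
#' @param min_overlap_bp Minimum verified overlap.
#' @param max_mismatch_rate Maximum mismatch fraction in the overlap.
#' @param max_gap_bases Maximum gap bases in the overlap alignment.
#' @return List: `contigs` (merged tibble), `conflicts` (report tibble).
#' @export
merge_overlapping_contigs <- function(contigs, min_overlap_bp = 1000L,
                                      max_mismatch_rate = 0.002,
                                      max_gap_bases = 20L) {
  cg <- mutate(contigs, contig_id = as.character(.data$contig_id))
  conflicts <- tibble(contig_a = character(), contig_b = character(),
                      reason = character())
  repeat {
    merged <- FALSE
    n <- nrow(cg)
    for (ii in seq_len(n)) {
      for (jj in seq_len(n)) {
        if (ii == jj) next
        if (!(cg$hap[ii] == cg$hap[jj] || cg$hap[ii] == 0L || cg$hap[jj] == 0L)) next
        A <- cg$seq[ii]; B <- cg$seq[jj]
        if (is.na(A) || is.na(B)) next
        # reference-anchored contigs can only share an end overlap when
        # their reference spans do
        if ("ref_start" %in% names(cg) &&
            !is.na(cg$ref_start[ii]) && !is.na(cg$ref_start[jj])) {
          ei <- cg$ref_start[ii] + nchar(A); sj <- cg$ref_start[jj]
          if (ei - sj < min_overlap_bp || sj < cg$ref_start[ii]) next
        }
        d <- cpp_overlap_diag(A, B, 17L)
        if (is.na(d$diag) || d$votes < 5L) next
        diag <- d$diag
        if (diag <= 0L || diag >= nchar(A)) next         # want B extending A
        olen <- nchar(A) - diag
        if (olen < min_overlap_bp) next
        if (olen > nchar(B)) next                        # containment, skip
        suf <- substr(A, diag + 1L, nchar(A))
        pre <- substr(B, 1L, min(nchar(B), olen + 200L))
        al <- overlap_align(suf, pre)
        if (is.null(al)) next
        ev <- cigar_events(al$cigar)
        mm <- sum(ev$ref_end[ev$kind == "X"] - ev$ref_start[ev$kind == "X"])
        gaps <- sum(pmax(ev$ref_end - ev$ref_start, ev$q_end - ev$q_start)[ev$kind != "X"])
        if (mm / olen > max_mismatch_rate || gaps > max_gap_bases) next
        b_off <- al$b_end                                # end of overlap within B
        take_a <- cg$mean_qv[ii] >= cg$mean_qv[jj]
        new_seq <- if (take_a) paste0(A, substr(B, b_off + 1L, nchar(B)))
                   else paste0(substr(A, 1L, diag), B)
        cg$seq[ii] <- new_seq
        cg$mean_qv[ii] <- max(cg$mean_qv[ii], cg$mean_qv[jj])
        cg$contig_id[ii] <- paste0(cg$contig_id[ii], "+", cg$contig_id[jj])
        if (cg$hap[ii] == 0L) cg$hap[ii] <- cg$hap[jj]
        cg <- cg[-jj, ]
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  list(contigs = cg, conflicts = conflicts)
}

# overlap verification: query-global, free trailing reference (the B-side
# window is longer than the overlap); large overlaps go through the
# anchored aligner
overlap_align <- function(suf, pre) {
  sc <- default_scoring()
  if ((as.double(nchar(suf)) + 1) * (as.double(nchar(pre)) + 1) <= 4e6) {
    r <- tryCatch(cpp_align_global(suf, pre, sc$match, sc$mismatch,
                                   sc$gap_open, sc$gap_extend, FALSE, TRUE),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    return(list(cigar = r$cigar, b_end = r$b_end))
  }
  r <- cpp_anchored_align(suf, pre, 17L, sc$match, sc$mismatch,
                          sc$gap_open, sc$gap_extend)
  if (!isTRUE(r$ok) || r$b_start > 100L) return(NULL)
  list(cigar = r$cigar, b_end = r$b_start + cpp_cigar_ref_len(r$cigar))
}

#' Detect minority read clusters sharing a deletion signature
#'
#' Within one (block, haplotype) bin, reads that conflict with the bin
#' consensus through a shared deletion of at least `min_del` bp form a
#' cluster; when that cluster is the minority among reads spanning the
#' deletion midpoint it is set aside (putative somatic event) and both
#' subsets are assembled separately.
#'
#' @param bin_aln Bin alignment tibble.
#' @param min_del Minimum shared deletion length.
#' @return List: `main` (majority rows), `minority` (set-aside rows),
#'   `signature` (deletion interval tibble or NULL).
#' @export
detect_somatic_cluster <- function(bin_aln, min_del = 50L) {
  has_d <- grepl("[0-9]{2,}D", bin_aln$cigar)
  sig <- list()
  for (i in which(has_d)) {
    ev <- cigar_events(bin_aln$cigar[i], bin_aln$pos[i])
    big <- filter(ev, .data$kind == "D", .data$ref_end - .data$ref_start >= min_del)
    if (nrow(big) > 0L)
      sig[[length(sig) + 1L]] <- mutate(big[1, ], read = i)
  }
  if (length(sig) == 0L)
    return(list(main = bin_aln, minority = bin_aln[0, ], signature = NULL))
  sg <- bind_rows(sig) %>%
    mutate(bucket = (.data$ref_start + .data$ref_end) %/% 2L %/% 200L) %>%
    group_by(.data$bucket) %>%
    mutate(nclust = dplyr::n()) %>% ungroup() %>%
    arrange(desc(.data$nclust))
  top <- filter(sg, .data$bucket == sg$bucket[1])
  mid <- round(median((top$ref_start + top$ref_end) / 2))
  ends <- bin_aln$pos + cigar_ref_len(bin_aln$cigar)
  spanning <- which(bin_aln$pos < mid & ends > mid)
  carriers <- top$read
  if (length(carriers) < 2L || length(carriers) * 2L >= length(spanning))
    return(list(main = bin_aln, minority = bin_aln[0, ], signature = NULL))
  list(main = bin_aln[setdiff(seq_len(nrow(bin_aln)), carriers), ],
       minority = bin_aln[carriers, ],
       signature = tibble(start = min(top$ref_start), end = max(top$ref_end),
                          n_reads = length(carriers)))
}

#' Assemble phased reads into haplotype contigs
#'
#' The `assemble` stage: per heterozygous block each haplotype's assigned
#' reads are assembled separately; homozygous-or-hemizygous blocks are
#' assembled from all mapped reads (haplotype label 0). Uncovered regions
#' are retried with the unfiltered read pool, contigs below the QV
#' threshold are dropped, and same-haplotype end overlaps are merged.
#'
#' @param phase An `ig_phase`.
#' @param ref An `ig_reference`.
#' @param reads_all Optional unfiltered read tibble (recruitment pool).
#' @param config Pipeline configuration.
#' @return An `ig_assembly`: list with `contigs` (tibble: `contig_id`,
#'   `block_id`, `hap`, `ref_start`, `seq`, `cigar`, `mean_qv`,
#'   `n_reads`), `uncovered`, `somatic`, `gaps`.
#' @export
assemble_haplotypes <- function(phase, ref, reads_all = NULL,
                                config = ig_config()) {
  refseq <- ref$seq
  aln <- left_join(phase$alignments, phase$assignments, by = "read_id")
  aln$ref_end <- aln$pos + cigar_ref_len(aln$cigar)
  blocks <- phase$blocks
  out <- list(); somatic <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    ov <- filter(aln, .data$ref_end > b$start, .data$pos < b$end)
    bins <- if (b$class == "heterozygous")
      list(`1` = filter(ov, .data$hap == 1L, .data$block_id == b$block_id),
           `2` = filter(ov, .data$hap == 2L, .data$block_id == b$block_id))
    else list(`0` = ov)
    for (hn in names(bins)) {
      bin <- bins[[hn]]
      if (nrow(bin) == 0L) next
      if (isTRUE(config$somatic_split)) {
        sc <- detect_somatic_cluster(bin, config$somatic_min_del)
        if (!is.null(sc$signature)) {
          somatic[[length(somatic) + 1L]] <-
            mutate(sc$signature, block_id = b$block_id, hap = as.integer(hn))
          ctm <- assemble_block(sc$minority, refseq, span = c(b$start, b$end),
                                min_overlap = config$min_layout_overlap,
                                min_identity = config$min_read_identity)
          if (nrow(ctm) > 0L)
            out[[length(out) + 1L]] <- mutate(ctm, block_id = b$block_id,
                                              hap = as.integer(hn), somatic = TRUE)
          bin <- sc$main
        }
      }
      ct <- assemble_block(bin, refseq, span = c(b$start, b$end),
                           min_overlap = config$min_layout_overlap,
                           min_identity = config$min_read_identity)
      if (nrow(ct) > 0L)
        out[[length(out) + 1L]] <- mutate(ct, block_id = b$block_id,
                                          hap = as.integer(hn), somatic = FALSE)
    }
  }
  contigs <- bind_rows(out)
  # recruitment pool: raw/unfiltered reads (single-pass molecules included);
  # the covered universe spans the pool too, so regions seen only by
  # filtered-out molecules still get a retry
  pool <- NULL
  if (!is.null(reads_all)) {
    dropped <- anti_join(reads_all, tibble(read_id = phase$alignments$read_id),
                         by = "read_id")
    if (nrow(dropped) > 0L)
      pool <- align_reads(dropped, ref, k = config$seed_k,
                          qstep = config$seed_step, max_occ = config$seed_max_occ) %>%
        filter(.data$mapped)
  }
  cov_tbl <- tibble(start = aln$pos, end = aln$ref_end)
  if (!is.null(pool) && nrow(pool) > 0L)
    cov_tbl <- bind_rows(cov_tbl,
                         tibble(start = pool$pos,
                                end = pool$pos + cigar_ref_len(pool$cigar)))
  covered <- intervals_union(cov_tbl)
  rr <- recruit_and_retry(contigs, covered,
                          pool %||% phase$alignments[0, ], refseq, config)
  contigs <- rr$contigs
  contigs <- filter_contigs(contigs, config$contig_qv_min)
  if (nrow(contigs) > 0L) {
    contigs <- mutate(contigs,
                      contig_id = sprintf("ctg_%s_h%s_%03d",
                                          ifelse(is.na(.data$block_id), "R",
                                                 .data$block_id),
                                          .data$hap, row_number()))
    mg <- merge_overlapping_contigs(contigs, config$merge_min_overlap,
                                    config$merge_max_mismatch_rate,
                                    config$merge_max_gap_bases)
    contigs <- mg$contigs
  }
  contigs <- arrange(contigs, .data$ref_start, .data$hap)
  gaps <- if (nrow(contigs) > 1L) {
    ce <- contigs$ref_start + cigar_ref_len(contigs$cigar)
    u <- intervals_union(tibble(start = contigs$ref_start, end = ce))
    if (nrow(u) > 1L)
      tibble(start = u$end[-nrow(u)], end = u$start[-1],
             size = u$start[-1] - u$end[-nrow(u)])
    else tibble(start = integer(), end = integer(), size = integer())
  } else tibble(start = integer(), end = integer(), size = integer())
  structure(list(contigs = contigs, uncovered = rr$uncovered,
                 somatic = bind_rows(somatic), gaps = gaps, config = config),
            class = "ig_assembly")
}

#' @export
print.ig_assembly <- function(x, ...) {
  cat("<ig_assembly> ", nrow(x$contigs), " contigs, ",
      sum(nchar(x$contigs$seq)), " assembled bases; ",
      nrow(x$uncovered), " uncovered intervals\n", sep = "")
  invisible(x)
}
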