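# Read-backed phasing: heterozygous SNV candidates from pileups, greedy
# fixed-point read partitioning, SV-aware rescue of reads inside
# one-haplotype deletions, and haplotype-block construction.

#' Drop molecules with too few subread passes
#'
#' Consensus reads built from a single pass are unreliable; the pipeline
#' requires at least 2 passes by default.
#'
#' @param reads Read tibble with an `n_passes` column.
#' @param min_passes Minimum pass count (kept if `n_passes >= min_passes`).
#' @return Order-preserving filtered tibble.
#' @export
filter_ccs_reads <- function(reads, min_passes = 2L) {
  filter(reads, .data$n_passes >= min_passes)
}

#' Detect heterozygous SNV candidates from a read pileup
#'
#' A position is a candidate when base depth reaches `min_depth` and the
#' second-most-common base has a frequency within
#' `[min_alt_fraction, max_alt_fraction]`. Substitutions only.
#'
#' @param alignments Alignment tibble from [align_reads()] (mapped rows used).
#' @param ref An `ig_reference` or sequence string.
#' @param min_depth Minimum base depth.
#' @param min_alt_fraction,max_alt_fraction Allowed minor-base frequency band.
#' @return Tibble: `pos`, `ref_base`, `alt_base`, `depth`, `alt_frac`.
#' @export
detect_het_candidates <- function(alignments, ref, min_depth = 10L,
                                  min_alt_fraction = 0.25,
                                  max_alt_fraction = 0.75) {
  refseq <- if (inherits(ref, "ig_reference")) ref$seq else ref
  a <- filter(alignments, .data$mapped)
  counts <- cpp_pileup(nchar(refseq), a$pos, a$cigar, a$aln_seq)
  base_counts <- counts[1:4, , drop = FALSE]
  depth <- colSums(base_counts)
  top <- apply(base_counts, 2, max)
  # cheap prefilter, exact stats only for surviving columns
  cand <- which(depth >= min_depth & (depth - top) >= depth * min_alt_fraction)
  if (length(cand) == 0L)
    return(tibble(pos = integer(), ref_base = character(), alt_base = character(),
                  depth = integer(), alt_frac = double()))
  bases <- c("A", "C", "G", "T")
  rows <- lapply(cand, function(p) {
    cc <- base_counts[, p]
    o <- order(cc, decreasing = TRUE)
    second <- cc[o[2]]
    f <- second / depth[p]
    if (f < min_alt_fraction || f > max_alt_fraction) return(NULL)
    rb <- seq_sub(refseq, p - 1L, p)
    major <- bases[o[1]]; minor <- bases[o[2]]
    altb <- if (major == rb) minor else major
    tibble(pos = p - 1L, ref_base = rb, alt_base = altb,
           depth = as.integer(depth[p]), alt_frac = f)
  })
  bind_rows(rows)
}

#' Assign reads to haplotypes from candidate het SNVs
#'
#' Greedy agreement phasing: connected components of sites (linked by reads
#' covering two or more sites) are phased left to right from the leftmost
#' candidate, then read assignment and per-site phase are iterated to a
#' fixed point (at most `max_rounds` rounds). A read is assigned to the
#' haplotype whose current allele string it matches at the majority of the
#' het sites it covers; ties are left unassigned. Afterwards, unassigned
#' reads lying wholly inside a large (>= `rescue_min_del`) deletion carried
#' by one haplotype's assigned reads are rescued to the other haplotype:
#' such reads cover no het site by construction, but their position is
#' only compatible with the intact haplotype.
#'
#' @param alignments Alignment tibble ([align_reads()]).
#' @param candidates Candidate tibble ([detect_het_candidates()]).
#' @param max_rounds Fixed-point iteration cap.
#' @param rescue_min_del Minimum deletion length for SV-aware rescue.
#' @return List: `snvs` (candidates + `hap_alt`, which haplotype carries
#'   the alt), `assignments` (`read_id`, `hap` with 0 = unassigned),
#'   `bases` (read x site allele matrix, internal).
#' @export
assign_reads <- function(alignments, candidates, max_rounds = 10L,
                         rescue_min_del = 1000L) {
  a <- filter(alignments, .data$mapped)
  if (nrow(candidates) == 0L)
    return(list(snvs = mutate(candidates, hap_alt = integer(0)),
                assignments = tibble(read_id = a$read_id, hap = 0L)))
  sites <- candidates$pos
  B <- cpp_read_bases_at(a$pos, a$cigar, a$aln_seq, as.integer(sites))
  bases <- c("A", "C", "G", "T")
  refi <- match(candidates$ref_base, bases)
  alti <- match(candidates$alt_base, bases)
  # allele matrix: NA not covered / other base, 0 ref, 1 alt
  AL <- matrix(NA_integer_, nrow(B), ncol(B))
  for (j in seq_len(ncol(B))) {
    AL[B[, j] == refi[j], j] <- 0L
    AL[B[, j] == alti[j], j] <- 1L
  }
  covered <- !is.na(AL)
  # components via shared reads
  comp <- seq_len(ncol(AL))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(AL))) {
      js <- which(covered[i, ])
      if (length(js) > 1L) {
        m <- min(comp[js])
        if (any(comp[js] != m)) { comp[js] <- m; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  # phase init: leftmost site of each component anchors hap1 = ref; later
  # sites oriented by majority vote against already-phased sites
  phase <- rep(NA_integer_, ncol(AL))   # allele carried by haplotype 1
  for (cc in unique(comp)) {
    js <- which(comp == cc)
    phase[js[1]] <- 0L
    for (j in js[-1]) {
      prev <- js[!is.na(phase[js]) & js < j]
      vote <- 0L
      ri <- which(covered[, j])
      for (i in ri) {
        pj <- prev[covered[i, prev]]
        if (length(pj) == 0L) next
        agree <- sum((AL[i, pj] == phase[pj])) - sum((AL[i, pj] != phase[pj]))
        vote <- vote + ifelse(AL[i, j] == 0L, agree, -agree)
      }
      phase[j] <- if (vote >= 0L) 0L else 1L
    }
  }
  hap <- rep(0L, nrow(AL))
  for (round in seq_len(max_rounds)) {
    m1 <- sweep(AL, 2, phase, "==")
    s1 <- rowSums(m1, na.rm = TRUE)
    s2 <- rowSums(!m1, na.rm = TRUE)
    newhap <- ifelse(s1 > s2, 1L, ifelse(s2 > s1, 2L, 0L))
    newhap[rowSums(covered) == 0L] <- 0L
    # re-estimate phase from assigned reads
    newphase <- phase
    for (j in seq_len(ncol(AL))) {
      a1 <- AL[newhap == 1L, j]; a2 <- AL[newhap == 2L, j]
      v1 <- sum(a1 == 1L, na.rm = TRUE) + sum(a2 == 0L, na.rm = TRUE)
      v0 <- sum(a1 == 0L, na.rm = TRUE) + sum(a2 == 1L, na.rm = TRUE)
      if (v1 != v0) newphase[j] <- ifelse(v1 > v0, 1L, 0L)
    }
    if (identical(newhap, hap) && identical(newphase, phase)) { hap <- newhap; break }
    hap <- newhap; phase <- newphase
  }
  snvs <- mutate(candidates, hap_alt = ifelse(phase == 1L, 1L, 2L))
  assignments <- tibble(read_id = a$read_id, hap = hap)
  # SV-aware rescue
  resc <- rescue_reads(a, assignments, rescue_min_del)
  list(snvs = snvs, assignments = resc, bases = AL)
}

# reads wholly inside a >= min_del deletion carried by >= 2 assigned reads
# of one haplotype are assigned to the other haplotype
rescue_reads <- function(a, assignments, min_del = 1000L) {
  asg <- assignments$hap
  dels <- list()
  has_big_d <- grepl(sprintf("[0-9]{%d,}D", nchar(as.character(min_del))), a$cigar)
  for (i in which(asg != 0L & has_big_d)) {
    ev <- cigar_events(a$cigar[i], a$pos[i])
    big <- filter(ev, .data$kind == "D", .data$ref_end - .data$ref_start >= min_del)
    if (nrow(big) > 0L)
      dels[[length(dels) + 1L]] <- mutate(big, hap = asg[i])[, c("ref_start", "ref_end", "hap")]
  }
  if (length(dels) == 0L) return(assignments)
  # cluster footprints coarsely: noisy reads place the junction within a
  # few bases of each other
  dd <- bind_rows(dels) %>%
    mutate(bs = .data$ref_start %/% 200L, be = .data$ref_end %/% 200L) %>%
    group_by(.data$bs, .data$be, .data$hap) %>%
    summarise(n = dplyr::n(), ref_start = round(median(.data$ref_start)),
              ref_end = round(median(.data$ref_end)), .groups = "drop") %>%
    filter(.data$n >= 2L)
  if (nrow(dd) == 0L) return(assignments)
  ends <- a$pos + cigar_ref_len(a$cigar)
  for (k in seq_len(nrow(dd))) {
    inside <- asg == 0L & a$pos >= dd$ref_start[k] - 50L & ends <= dd$ref_end[k] + 50L
    asg[inside] <- 3L - dd$hap[k]
  }
  tibble(read_id = assignments$read_id, hap = asg)
}

#' Define haplotype blocks from phased SNVs and read spans
#'
#' Two het SNVs share a block when at least one assigned read covers both
#' (transitive closure). Heterozygous block intervals run from the first
#' to the last SNV, extended to the boundaries of the reads assigned in
#' the block (trimmed at midpoints if neighbouring blocks would overlap);
#' the gaps between them over the read-covered locus become
#' homozygous-or-hemizygous blocks. The union of blocks tiles the covered
#' locus without overlap.
#'
#' @param snvs Phased SNV tibble from [assign_reads()].
#' @param assignments Read assignment tibble.
#' @param alignments Alignment tibble.
#' @return Tibble: `block_id`, `start`, `end`, `class`, `n_snv`.
#' @export
define_blocks <- function(snvs, assignments, alignments) {
  a <- filter(alignments, .data$mapped) %>%
    left_join(assignments, by = "read_id")
  a$ref_end <- a$pos + cigar_ref_len(a$cigar)
  covered <- intervals_union(tibble(start = a$pos, end = a$ref_end))
  if (nrow(snvs) == 0L) {
    return(mutate(covered, block_id = paste0("B", row_number()),
                  class = "homozygous_or_hemizygous", n_snv = 0L)[,
             c("block_id", "start", "end", "class", "n_snv")])
  }
  snvs <- arrange(snvs, .data$pos)
  asg <- filter(a, .data$hap %in% c(1L, 2L))
  # union-find over sites joined by an assigned read covering both
  comp <- seq_len(nrow(snvs))
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (i in seq_len(nrow(asg))) {
    js <- which(snvs$pos >= asg$pos[i] & snvs$pos < asg$ref_end[i])
    if (length(js) > 1L) {
      r <- find(js[1])
      for (j in js[-1]) comp[find(j)] <- r
    }
  }
  roots <- vapply(seq_along(comp), find, 0L)
  het <- snvs %>% mutate(root = roots) %>% group_by(.data$root) %>%
    summarise(snv_start = min(.data$pos), snv_end = max(.data$pos) + 1L,
              n_snv = dplyr::n(), .groups = "drop") %>%
    arrange(.data$snv_start)
  # extend to assigned-read boundaries
  het$start <- het$snv_start; het$end <- het$snv_end
  for (i in seq_len(nrow(het))) {
    rr <- asg[asg$ref_end > het$snv_start[i] & asg$pos < het$snv_end[i], ]
    if (nrow(rr) > 0L) {
      het$start[i] <- min(rr$pos)
      het$end[i] <- max(rr$ref_end)
    }
  }
  # trim overlaps between consecutive het blocks at the midpoint
  if (nrow(het) > 1L) for (i in seq_len(nrow(het) - 1L)) {
    if (het$end[i] > het$start[i + 1L]) {
      lo <- max(het$snv_end[i], het$start[i + 1L])
      hi <- min(het$snv_start[i + 1L], het$end[i])
      mid <- as.integer((max(lo, hi) + min(lo, hi)) %/% 2L)
      mid <- max(het$snv_end[i], min(mid, het$snv_start[i + 1L]))
      het$end[i] <- mid; het$start[i + 1L] <- mid
    }
  }
  het_iv <- tibble(start = het$start, end = het$end, class = "heterozygous",
                   n_snv = het$n_snv)
  hom <- intervals_complement(het_iv[, c("start", "end")],
                              min(covered$start), max(covered$end))
  # keep only hom stretches that are actually covered by reads
  hom <- bind_rows(lapply(seq_len(nrow(hom)), function(i) {
    ov <- filter(covered, .data$end > hom$start[i], .data$start < hom$end[i])
    mutate(ov, start = pmax(.data$start, hom$start[i]),
           end = pmin(.data$end, hom$end[i]))
  }))
  blocks <- bind_rows(het_iv,
                      if (nrow(hom) > 0L)
                        mutate(hom, class = "homozygous_or_hemizygous", n_snv = 0L)) %>%
    filter(.data$end > .data$start) %>%
    arrange(.data$start) %>%
    mutate(block_id = paste0("B", row_number())) %>%
    select("block_id", "start", "end", "class", "n_snv")
  blocks
}

#' Phase reads against a custom reference
#'
#' The `phase` stage: filters molecules by subread passes, aligns reads,
#' detects heterozygous SNV candidates, partitions reads into haplotypes
#' and defines haplotype blocks.
#'
#' @param reads Read tibble ([sim_reads()] or [read_fastq_reads()]).
#' @param ref An `ig_reference`.
#' @param config Pipeline configuration ([ig_config()]).
#' @return An `ig_phase` object: list with `snvs` (phased SNVs incl.
#'   `block_id`), `blocks`, `assignments`, `alignments`, `pileup`.
#' @export
phase_reads <- function(reads, ref, config = ig_config()) {
  kept <- filter_ccs_reads(reads, config$min_passes)
  aln <- align_reads(kept, ref, k = config$seed_k, qstep = config$seed_step,
                     max_occ = config$seed_max_occ)
  aln <- filter(aln, .data$mapped, .data$identity >= config$min_read_identity)
  cand <- detect_het_candidates(aln, ref, config$min_depth,
                                config$min_alt_fraction, config$max_alt_fraction)
  ph <- assign_reads(aln, cand, config$max_phase_rounds, config$rescue_min_del)
  blocks <- define_blocks(ph$snvs, ph$assignments, aln)
  snvs <- ph$snvs
  if (nrow(snvs) > 0L) {
    bi <- findInterval(snvs$pos, blocks$start)
    snvs$block_id <- blocks$block_id[pmax(bi, 1L)]
  } else snvs$block_id <- character(0)
  # block membership: phase orientation is only defined within a block, so
  # a read belongs to the block whose het sites it covers (rescued reads:
  # the block containing their span midpoint)
  asg <- ph$assignments
  asg$block_id <- NA_character_
  if (nrow(snvs) > 0L && !is.null(ph$bases)) {
    first_site <- apply(!is.na(ph$bases), 1, function(z) which(z)[1])
    has_site <- !is.na(first_site)
    asg$block_id[has_site] <- snvs$block_id[first_site[has_site]]
    rescued <- asg$hap %in% c(1L, 2L) & !has_site
    if (any(rescued)) {
      mid <- (aln$pos + aln$pos + cigar_ref_len(aln$cigar)) %/% 2L
      bi <- findInterval(mid[rescued], blocks$start)
      asg$block_id[rescued] <- blocks$block_id[pmax(bi, 1L)]
    }
  }
  ph$assignments <- asg
  refseq <- ref$seq
  pl <- cpp_pileup(nchar(refseq), aln$pos, aln$cigar, aln$aln_seq)
  structure(list(snvs = snvs, blocks = blocks, assignments = ph$assignments,
                 alignments = aln, pileup = pl, config = config),
            class = "ig_phase")
}

#' @export
print.ig_phase <- function(x, ...) {
  cat("<ig_phase> ", nrow(x$alignments), " aligned reads, ",
      nrow(x$snvs), " phased het SNVs, ", nrow(x$blocks), " blocks (",
      sum(x$blocks$class == "heterozygous"), " heterozygous)\n", sep = "")
  invisible(x)
}

#' Relabel block haplotypes to parental origin from trio genotypes
#'
#' Long-range phase mode: given parental genotype dosages at phased SNV
#' positions, each block's haplotype labels are flipped (or kept) so that
#' haplotype 1 matches the transmission pattern implied by the parents,
#' by majority vote over the block's SNVs. Blocks without an informative
#' site keep their local labels.
#'
#' @param phase An `ig_phase`.
#' @param trio Tibble with `pos`, `mother_dosage`, `father_dosage`
#'   (0/1/2 copies of the alt allele).
#' @return The `ig_phase` with flipped `hap_alt` labels where the vote
#'   demanded it, plus a `parental` column on `snvs` and a
#'   `parental_resolved` flag on `blocks`.
#' @export
relabel_parental <- function(phase, trio) {
  snvs <- left_join(phase$snvs, trio, by = "pos")
  # informative: alt present in exactly one parent
  snvs <- mutate(snvs, informative = !is.na(.data$mother_dosage) &
                   !is.na(.data$father_dosage) &
                   xor(.data$mother_dosage > 0, .data$father_dosage > 0),
                 alt_parent = ifelse(.data$mother_dosage > 0, "maternal", "paternal"))
  flips <- snvs %>% filter(.data$informative) %>% group_by(.data$block_id) %>%
    summarise(flip = sum((.data$hap_alt == 1L) != (.data$alt_parent == "maternal")) >
                dplyr::n() / 2, .groups = "drop")
  snvs <- left_join(snvs, flips, by = "block_id") %>%
    mutate(hap_alt = ifelse(!is.na(.data$flip) & .data$flip,
                            3L - .data$hap_alt, .data$hap_alt),
           parental = ifelse(.data$block_id %in% flips$block_id,
                             ifelse(.data$hap_alt == 1L, "maternal", "paternal"),
                             NA_character_))
  phase$snvs <- select(snvs, -"informative", -"alt_parent", -"flip")
  phase$blocks <- mutate(phase$blocks,
                         parental_resolved = .data$block_id %in% flips$block_id)
  phase
}
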