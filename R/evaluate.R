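# Evaluation machinery: call-set concordance, truth derivation from
# haplotype alignment, trio Mendelian checks, phase switch errors,
# assembly concordance with homopolymer-indel classification, exact
# Hardy-Weinberg tests, accessibility partitioning, imputation
# signal-to-noise, and the multiplex downsampling sweep.

# genotype string ("0/1", "1|0", "1", "1/1") -> alt-allele dosage and ploidy
gt_dosage <- function(gt) {
  al <- strsplit(gsub("\\|", "/", gt), "/", fixed = FALSE)
  tibble(dosage = vapply(al, function(a) sum(a == "1"), 0),
         ploidy = lengths(al))
}

#' Compare an SNV call set against a truth set
#'
#' A query SNV is a true positive only when position and alleles match
#' and the genotypes agree as allele multisets (phased and unphased
#' genotypes compare equal when the alleles match). A matched position
#' with a different genotype is discordant and counts toward both false
#' positives and false negatives. Rows flagged unmappable (e.g. inside
#' embedded SV regions absent from a comparison assembly) are excluded
#' into a separate bucket, never counted as false positives.
#'
#' @param query Tibble: `pos`, `ref`, `alt`, `genotype`, optional
#'   `mappable` (logical).
#' @param truth Tibble with the same columns.
#' @return A list of class `ig_comparison`: counts, rates and the joined
#'   per-site table.
#' @export
compare_snv_callsets <- function(query, truth) {
  q <- as_tibble(query)
  if (!"mappable" %in% names(q)) q$mappable <- TRUE
  excluded <- filter(q, !.data$mappable)
  q <- filter(q, .data$mappable)
  qd <- bind_cols(q, gt_dosage(q$genotype))
  td <- bind_cols(as_tibble(truth), gt_dosage(truth$genotype))
  j <- dplyr::full_join(
    select(qd, "pos", "ref", "alt", q_dosage = "dosage"),
    select(td, "pos", "ref", "alt", t_dosage = "dosage"),
    by = c("pos", "ref", "alt"))
  j <- mutate(j, category = case_when(
    !is.na(.data$q_dosage) & !is.na(.data$t_dosage) &
      .data$q_dosage == .data$t_dosage ~ "TP",
    !is.na(.data$q_dosage) & !is.na(.data$t_dosage) ~ "discordant",
    is.na(.data$t_dosage) ~ "FP",
    TRUE ~ "FN"))
  tp <- sum(j$category == "TP")
  disc <- sum(j$category == "discordant")
  fp <- sum(j$category == "FP") + disc
  fn <- sum(j$category == "FN") + disc
  structure(list(
    tp = tp, fp = fp, fn = fn, genotype_discordant = disc,
    excluded_unmappable = nrow(excluded),
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sites = j), class = "ig_comparison")
}

#' @export
print.ig_comparison <- function(x, ...) {
  cat("<ig_comparison> TP ", x$tp, "  FP ", x$fp, "  FN ", x$fn,
      "  discordant ", x$genotype_discordant,
      "  excluded ", x$excluded_unmappable, "\n", sep = "")
  cat(sprintf("  recall %.4f  precision %.4f\n", x$recall, x$precision))
  invisible(x)
}

#' Derive a truth SNV set by aligning two haplotype sequences
#'
#' Aligns a query haplotype to a reference haplotype and emits every
#' mismatch column as a truth SNV (the ground-truth construction used
#' when two finished assemblies of the same locus are available).
#'
#' @param hap_query,hap_ref Sequences.
#' @return Tibble: `pos` (on `hap_ref`), `ref`, `alt`.
#' @export
derive_truth_from_haplotype_alignment <- function(hap_query, hap_ref) {
  al <- align_sequences(hap_query, hap_ref)
  ev <- filter(cigar_events(al$cigar, al$b_start), .data$kind == "X")
  if (nrow(ev) == 0L) return(tibble(pos = integer(), ref = character(),
                                    alt = character()))
  bind_rows(lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    n <- e$ref_end - e$ref_start
    tibble(pos = seq(e$ref_start, e$ref_end - 1L),
           ref = strsplit(seq_sub(hap_ref, e$ref_start, e$ref_end), "")[[1]],
           alt = strsplit(substr(hap_query, e$q_start + 1L, e$q_end), "")[[1]])
  }))
}

#' Check genotypes for Mendelian consistency in a trio
#'
#' A site violates Mendelian inheritance when no assignment of one child
#' allele to each parent is possible.
#'
#' @param child,mother,father Tibbles with `pos` and `genotype`.
#' @return Tibble of violating sites with the three genotypes.
#' @export
mendelian_check <- function(child, mother, father) {
  j <- child %>%
    inner_join(mother, by = "pos", suffix = c("", "_m")) %>%
    inner_join(father, by = "pos", suffix = c("", "_f"))
  alleles_of <- function(gt) strsplit(gsub("\\|", "/", gt), "/")
  ca <- alleles_of(j$genotype)
  ma <- alleles_of(j$genotype_m)
  fa <- alleles_of(j$genotype_f)
  viol <- vapply(seq_len(nrow(j)), function(i) {
    c2 <- ca[[i]]
    if (length(c2) == 1L) c2 <- c(c2, c2)   # haploid treated permissively
    !((c2[1] %in% ma[[i]] && c2[2] %in% fa[[i]]) ||
        (c2[2] %in% ma[[i]] && c2[1] %in% fa[[i]]))
  }, logical(1))
  j[viol, ]
}

#' Count phase switch errors per haplotype block
#'
#' For each block with at least two evaluable heterozygous sites, counts
#' the adjacent site pairs whose inferred relative phase differs from the
#' truth phase. The count is invariant under global relabeling of either
#' argument's haplotypes (it is the minimum over the two orientations).
#'
#' @param inferred Tibble: `block_id`, `pos`, `hap_alt` (1 or 2).
#' @param truth Tibble: `pos`, `hap_alt`.
#' @return Tibble: `block_id`, `n_sites`, `switches`.
#' @export
switch_error_count <- function(inferred, truth) {
  j <- inner_join(inferred, truth, by = "pos", suffix = c("", "_truth")) %>%
    arrange(.data$block_id, .data$pos)
  j %>% group_by(.data$block_id) %>%
    summarise(n_sites = dplyr::n(), switches = {
      o <- (.data$hap_alt == .data$hap_alt_truth)
      if (length(o) < 2L) 0L else sum(o[-1] != o[-length(o)])
    }, .groups = "drop")
}

#' Assembly concordance against an orthogonal sequence
#'
#' Aligns an assembly to an orthogonal (validation) sequence and reports
#' base accuracy, substitution count, indel events with lengths, and the
#' fraction of 1-2 bp indels in or adjacent to homopolymer runs (>= 3
#' identical bases).
#'
#' @param assembly_seq,ortho_seq Sequences.
#' @return List: `accuracy`, `substitutions`, `indels` (tibble with
#'   `pos`, `len`, `type`, `homopolymer`), `hp_fraction_1_2bp`.
#' @export
assembly_concordance <- function(assembly_seq, ortho_seq) {
  al <- align_sequences(assembly_seq, ortho_seq)
  ev <- cigar_events(al$cigar, al$b_start)
  subs <- sum(ev$ref_end[ev$kind == "X"] - ev$ref_start[ev$kind == "X"])
  gaps <- filter(ev, .data$kind != "X")
  runs <- homopolymer_runs(ortho_seq)
  indels <- if (nrow(gaps) > 0L) {
    tibble(pos = gaps$ref_start,
           len = pmax(gaps$ref_end - gaps$ref_start, gaps$q_end - gaps$q_start),
           type = ifelse(gaps$kind == "D", "deletion", "insertion"),
           homopolymer = in_homopolymer(gaps$ref_start, runs))
  } else tibble(pos = integer(), len = integer(), type = character(),
                homopolymer = logical())
  small <- filter(indels, .data$len <= 2L)
  err_bases <- subs + sum(indels$len)
  list(accuracy = 1 - err_bases / max(1L, nchar(assembly_seq)),
       substitutions = subs, indels = indels,
       hp_fraction_1_2bp = if (nrow(small) > 0L) mean(small$homopolymer)
                           else NA_real_)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: the p-value sums the probabilities, given the
#' allele counts, of all heterozygote counts with probability at most
#' that of the observed table. Monomorphic sites return p = 1 by
#' convention. A chi-square approximation is available as an option.
#'
#' @param n_aa,n_ab,n_bb Genotype counts.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return p-value in `[0, 1]`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, method = c("exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0L) abort("no genotypes")
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0L || n_b == 0L) return(1)
  if (method == "chisq") {
    p <- n_a / (2 * n)
    e <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    x2 <- sum((c(n_aa, n_ab, n_bb) - e)^2 / e)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(n_het | n, n_a) up to a shared constant
  lp <- vapply(hets, function(h) {
    haa <- (n_a - h) %/% 2L; hbb <- (n_b - h) %/% 2L
    h * log(2) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb)
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  if (!n_ab %in% hets)
    abort("observed heterozygote count inconsistent with allele counts")
  # tables as or more extreme in heterozygote count: at least as far from
  # the conditional expectation of the het count as the observed table
  center <- n_a * n_b / (2 * n - 1)
  dev <- abs(hets - center)
  min(1, sum(pr[dev >= abs(n_ab - center) - 1e-9]))
}

#' Partition SNVs by accessibility-mask membership
#'
#' @param pos Integer vector of SNV positions.
#' @param mask Tibble of sorted, non-overlapping intervals (`start`, `end`).
#' @return List: `inside`, `outside`, `n`, and the per-SNV logical.
#' @export
accessibility_partition <- function(pos, mask) {
  if (nrow(mask) == 0L) {
    inside <- rep(FALSE, length(pos))
  } else {
    m <- arrange(as_tibble(mask), .data$start)
    idx <- findInterval(pos, m$start)
    inside <- idx >= 1L & pos < m$end[pmax(idx, 1L)]
  }
  list(inside = sum(inside), outside = sum(!inside), n = length(pos),
       in_mask = inside)
}

#' Compare a call set to imputed sets at hard-call thresholds
#'
#' For each threshold set reports the overlap, the imputed-only and
#' query-only counts, and the signal-to-noise ratio
#' `overlap / imputed-only` (infinite when nothing is imputed-only).
#'
#' @param query_pos Positions called by the query method.
#' @param imputed_sets Named list of position vectors (one per threshold).
#' @return Tibble: `threshold`, `overlap`, `imputed_only`, `query_only`,
#'   `snr`.
#' @export
imputation_comparison <- function(query_pos, imputed_sets) {
  stopifnot(length(imputed_sets) >= 1L)
  bind_rows(lapply(names(imputed_sets), function(nm) {
    imp <- imputed_sets[[nm]]
    ov <- length(intersect(query_pos, imp))
    io <- length(setdiff(imp, query_pos))
    qo <- length(setdiff(query_pos, imp))
    tibble(threshold = nm, overlap = ov, imputed_only = io, query_only = qo,
           snr = if (io == 0L) Inf else ov / io)
  }))
}

#' Run the pipeline across multiplex levels and score each call set
#'
#' Runs phase/assemble/detect on each plex level's readset, then scores
#' SNV calls against the simulator truth and against the designated
#' ground-truth run (the first, highest-coverage plex level). Multiplex
#' comparisons are position-level (an SNV counts as recovered when called
#' at the same position with the same alleles, regardless of genotype),
#' the way downsampled call sets are compared against a top-coverage
#' reference call set.
#'
#' @param plex_readsets Named list from [sim_multiplex()].
#' @param locus An `ig_locus`.
#' @param truth An `ig_truth`.
#' @param config Pipeline configuration.
#' @return Tibble with one row per plex level: mean coverage, SNV count,
#'   recall and false-positive rate vs truth and vs the ground-truth run.
#' @export
multiplex_sweep <- function(plex_readsets, locus, truth, config = ig_config()) {
  truth_snvs <- truth_snv_table(truth, locus$ref)
  runs <- lapply(names(plex_readsets), function(nm) {
    run_pipeline(locus$ref, plex_readsets[[nm]], locus$db, config = config)
  })
  names(runs) <- names(plex_readsets)
  gt_set <- snv_call_table(runs[[1]]$calls)
  site_metrics <- function(q, t) {
    qk <- paste(q$pos, q$ref, q$alt)
    tk <- paste(t$pos, t$ref, t$alt)
    tp <- sum(qk %in% tk)
    list(recall = if (length(tk) > 0) tp / length(tk) else NA_real_,
         fp_rate = if (length(qk) > 0) (length(qk) - tp) / length(qk) else 0)
  }
  bind_rows(lapply(names(runs), function(nm) {
    q <- snv_call_table(runs[[nm]]$calls)
    vs_truth <- site_metrics(q, truth_snvs)
    vs_gt <- site_metrics(q, gt_set)
    tibble(plex = nm,
           n_reads = nrow(plex_readsets[[nm]]),
           mean_coverage = sum(nchar(plex_readsets[[nm]]$seq)) / nchar(locus$ref$seq),
           n_snv = nrow(q),
           recall_truth = vs_truth$recall, fp_rate_truth = vs_truth$fp_rate,
           recall_gt = vs_gt$recall, fp_rate_gt = vs_gt$fp_rate)
  }))
}

# truth variants -> comparable SNV table (pos/ref/alt/genotype)
#' Truth SNVs as a comparable call table
#' @param truth An `ig_truth`. @param ref An `ig_reference`.
#' @return Tibble: `pos`, `ref`, `alt`, `genotype`.
#' @export
truth_snv_table <- function(truth, ref) {
  truth$variants %>% filter(.data$type == "SNV") %>%
    transmute(pos = .data$start, ref = .data$ref, alt = .data$alt,
              genotype = ifelse(.data$hap == 0L, "1/1",
                                ifelse(.data$hap == 1L, "1|0", "0|1")))
}

# calls -> comparable SNV table (PASS rows)
#' PASS SNV calls as a comparable table
#' @param calls An `ig_calls` tibble.
#' @return Tibble: `pos`, `ref`, `alt`, `genotype`.
#' @export
snv_call_table <- function(calls) {
  calls %>% filter(.data$type == "SNV", .data$filter == "PASS") %>%
    transmute(pos = .data$start, ref = .data$ref, alt = .data$alt,
              genotype = .data$genotype)
}
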