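# Gene-segment allele assignment: extract exon sequences from haplotype
# contigs via the alignment projection, match them exactly against the
# germline database, flag novel alleles with a diff list against the
# nearest database allele, and count supporting reads by exact substring
# match.

#' Load a germline allele database from FASTA
#'
#' Headers follow the `gene*allele` convention. Sequences containing
#' ambiguity codes are rejected: exact-match semantics must be
#' unambiguous.
#'
#' @param path FASTA file.
#' @return Tibble: `gene`, `allele`, `seq`.
#' @export
read_allele_db <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  seqs <- toupper(as.character(x))
  if (any(grepl("[^ACGT]", seqs)))
    abort("allele database contains ambiguity codes; only A/C/G/T are allowed")
  parts <- stringr::str_split_fixed(nm, stringr::fixed("*"), 2)
  db <- tibble(gene = parts[, 1], allele = parts[, 2], seq = unname(seqs))
  if (anyDuplicated(paste(db$gene, db$allele)))
    abort("duplicate gene*allele names in database")
  dup <- db %>% group_by(.data$gene) %>%
    summarise(d = anyDuplicated(.data$seq) > 0L, .groups = "drop")
  if (any(dup$d)) abort("duplicate allele sequences within a gene")
  db
}

#' Write an allele database to FASTA
#' @param db Tibble (`gene`, `allele`, `seq`).
#' @param path Output path.
#' @export
write_allele_db <- function(db, path) {
  x <- Biostrings::DNAStringSet(db$seq)
  names(x) <- paste0(db$gene, "*", db$allele)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Extract per-gene, per-haplotype exon sequences from contigs
#'
#' The gene's exon interval is projected through each covering contig's
#' reference alignment; minus-strand genes are reverse-complemented so
#' the returned sequence is in allele-database orientation. Genes not
#' covered by a contig are `not_assembled`; genes whose exon lies inside
#' a called deletion on that haplotype are `deleted`; genes inside a
#' flagged V(D)J interval on that haplotype are `vdj_suspect`.
#'
#' @param assembly An `ig_assembly`.
#' @param ref An `ig_reference`.
#' @param calls An `ig_calls` tibble (for deletion status).
#' @param vdj Flagged V(D)J interval tibble (or NULL).
#' @return Tibble: `gene`, `hap`, `seq` (NA when absent), `absence`
#'   (NA, `"deleted"`, `"not_assembled"` or `"vdj_suspect"`), `contig_id`.
#' @export
extract_gene_sequences <- function(assembly, ref, calls = empty_calls(),
                                   vdj = NULL) {
  exons <- filter(ref$features, .data$feature == "exon") %>%
    left_join(select(ref$genes, "gene", "strand", "functional"), by = "gene") %>%
    filter(.data$functional != "pseudogene")
  contigs <- assembly$contigs
  dels <- filter(calls, .data$alt == "", .data$type %in% c("SV", "indel"))
  out <- list()
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    for (h in 1:2) {
      row <- tibble(gene = e$gene, hap = h, seq = NA_character_,
                    absence = NA_character_, contig_id = NA_character_)
      deln <- filter(dels, .data$start <= e$start, .data$end >= e$end,
                     .data$hap %in% c(h, 3L, 0L) |
                       .data$genotype %in% c("1/1", "1|1"))
      vdj_hit <- !is.null(vdj) && nrow(vdj) > 0L &&
        any(vdj$hap == h & vdj$start <= e$start & vdj$end >= e$end)
      if (vdj_hit) {
        row$absence <- "vdj_suspect"
      } else if (nrow(deln) > 0L) {
        row$absence <- "deleted"
      } else {
        cc <- filter(contigs, .data$hap %in% c(h, 0L))
        got <- FALSE
        for (k in seq_len(nrow(cc))) {
          pr <- project_interval(cc$cigar[k], cc$ref_start[k], e$start, e$end)
          if (is.null(pr)) next
          s <- substr(cc$seq[k], pr[1] + 1L, pr[2])
          row$seq <- if (e$strand == "-") revcomp(s) else s
          row$contig_id <- cc$contig_id[k]
          got <- TRUE
          break
        }
        if (!got) row$absence <- "not_assembled"
      }
      out[[length(out) + 1L]] <- row
    }
  }
  bind_rows(out)
}

#' Assign a database allele to one extracted gene sequence
#'
#' Exact full-length match gives a known allele; otherwise the sequence
#' is novel and the nearest database allele (by edit distance;
#' lexicographically first on ties, which are flagged) is reported with a
#' substitution/indel diff list.
#'
#' @param gene_seq Extracted sequence (upper-case).
#' @param gene Gene name.
#' @param db Allele database tibble.
#' @return List: `status` (`known`/`novel`), `allele`, `nearest`,
#'   `tie` (logical), `diffs` (tibble, empty for known).
#' @export
assign_allele <- function(gene_seq, gene, db) {
  entries <- filter(db, .data$gene == !!gene)
  if (nrow(entries) == 0L) abort(paste0("no database alleles for gene ", gene))
  if (is.na(gene_seq) || nchar(gene_seq) == 0L) abort("empty gene sequence")
  hit <- which(entries$seq == gene_seq)
  if (length(hit) > 0L)
    return(list(status = "known", allele = entries$allele[hit[1]],
                nearest = entries$allele[hit[1]], tie = FALSE,
                diffs = tibble(pos = integer(), ref = character(),
                               alt = character())))
  dd <- as.integer(adist(gene_seq, entries$seq))
  o <- order(dd, entries$allele)
  nearest <- entries[o[1], ]
  tie <- sum(dd == dd[o[1]]) > 1L
  al <- align_sequences(gene_seq, nearest$seq, mode = "global")
  ev <- cigar_events(al$cigar)
  diffs <- bind_rows(lapply(seq_len(nrow(ev)), function(i) {
    e <- ev[i, ]
    if (e$kind == "X")
      tibble(pos = seq(e$ref_start, e$ref_end - 1L),
             ref = strsplit(substr(nearest$seq, e$ref_start + 1L, e$ref_end), "")[[1]],
             alt = strsplit(substr(gene_seq, e$q_start + 1L, e$q_end), "")[[1]])
    else if (e$kind == "I")
      tibble(pos = e$ref_start, ref = "",
             alt = substr(gene_seq, e$q_start + 1L, e$q_end))
    else
      tibble(pos = e$ref_start,
             ref = substr(nearest$seq, e$ref_start + 1L, e$ref_end), alt = "")
  }))
  list(status = "novel", allele = NA_character_, nearest = nearest$allele,
       tie = tie, diffs = diffs)
}

#' Count reads containing an allele sequence as an exact substring
#'
#' Forward and reverse-complement matches both count; each read counts at
#' most once. An approximate mode admits up to `max_mismatch` mismatches.
#'
#' @param allele_seq Allele sequence.
#' @param reads Read tibble (uses `seq`).
#' @param max_mismatch Allowed mismatches (0 = exact, the default).
#' @return Integer count.
#' @export
count_read_support <- function(allele_seq, reads, max_mismatch = 0L) {
  if (nrow(reads) == 0L) return(0L)
  count_support_set(allele_seq, Biostrings::DNAStringSet(reads$seq), max_mismatch)
}

count_support_set <- function(allele_seq, subj, max_mismatch = 0L) {
  fwd <- Biostrings::vcountPattern(allele_seq, subj, max.mismatch = max_mismatch)
  rev <- Biostrings::vcountPattern(revcomp(allele_seq), subj,
                                   max.mismatch = max_mismatch)
  sum(fwd + rev > 0L)
}

#' Call gene alleles from haplotype assemblies
#'
#' Extracts each functional/ORF gene's exon sequence per haplotype,
#' assigns database alleles (novel sequences get a nearest-allele diff
#' list), and counts supporting CCS reads by exact substring match.
#'
#' @param assembly,ref,calls Pipeline objects.
#' @param db Allele database tibble.
#' @param reads Read tibble used for support counting.
#' @param vdj Flagged V(D)J interval tibble (or NULL).
#' @return An `ig_alleles` tibble: `gene`, `hap`, `status`, `allele`,
#'   `nearest`, `tie`, `n_diffs`, `seq`, `support`, `contig_id`.
#' @export
call_alleles <- function(assembly, ref, db, calls = empty_calls(),
                         reads = NULL, vdj = NULL) {
  ext <- extract_gene_sequences(assembly, ref, calls, vdj)
  subj <- if (!is.null(reads)) Biostrings::DNAStringSet(reads$seq) else NULL
  support_cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(ext)), function(i) {
    e <- ext[i, ]
    base <- tibble(gene = e$gene, hap = e$hap, status = NA_character_,
                   allele = NA_character_, nearest = NA_character_,
                   tie = FALSE, n_diffs = NA_integer_, seq = e$seq,
                   support = NA_integer_, contig_id = e$contig_id)
    if (!is.na(e$absence)) {
      base$status <- e$absence
      return(base)
    }
    asn <- assign_allele(e$seq, e$gene, db)
    base$status <- asn$status
    base$allele <- asn$allele
    base$nearest <- asn$nearest
    base$tie <- asn$tie
    base$n_diffs <- nrow(asn$diffs)
    if (!is.null(subj)) {
      base$support <- if (!is.null(support_cache[[e$seq]])) support_cache[[e$seq]]
                      else support_cache[[e$seq]] <- count_support_set(e$seq, subj)
    }
    base
  })
  out <- bind_rows(rows)
  class(out) <- c("ig_alleles", class(out))
  out
}

#' Collapse per-gene allele calls to a non-redundant rollup
#'
#' @param alleles An `ig_alleles` tibble.
#' @return Distinct (gene, allele-or-sequence) combinations with the
#'   number of haplotypes carrying each.
#' @export
allele_rollup <- function(alleles) {
  alleles %>%
    filter(.data$status %in% c("known", "novel")) %>%
    group_by(.data$gene, .data$status, .data$allele, .data$seq) %>%
    summarise(n_haps = dplyr::n(), .groups = "drop") %>%
    arrange(.data$gene)
}
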