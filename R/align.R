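# Alignment surface: anchored long-read mapping against the custom
# reference and general pairwise alignment with the pipeline's affine
# scoring (match 1, mismatch -2, gap open -4, gap extend -1; ties broken
# deterministically). Cigars use =, X, I, D (S for unalignable read ends).

default_scoring <- function() list(match = 1L, mismatch = -2L,
                                   gap_open = -4L, gap_extend = -1L)

#' Align reads to a custom locus reference
#'
#' k-mer anchored alignment: unique seed matches are chained colinearly
#' (both strands tried) and inter-anchor segments are resolved with an
#' affine-gap DP, so multi-kilobase haplotype deletions appear as single
#' deletion operations in the cigar rather than split alignments.
#'
#' @param reads Read tibble (needs `read_id`, `seq`).
#' @param ref An `ig_reference` or a plain sequence string.
#' @param k Seed length.
#' @param qstep Query seed stride.
#' @param max_occ Maximum reference occurrences for a usable seed.
#' @param scoring List with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @return The read tibble joined with `pos` (0-based reference start),
#'   `strand`, `cigar`, `aln_seq` (read sequence in reference orientation),
#'   `score`, `identity`, `mapped`.
#' @export
align_reads <- function(reads, ref, k = 17L, qstep = 10L, max_occ = 8L,
                        scoring = default_scoring()) {
  refseq <- if (inherits(ref, "ig_reference")) ref$seq else ref
  m <- cpp_map_reads(refseq, reads$seq, as.integer(k), as.integer(qstep),
                     as.integer(max_occ), scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  bind_cols(reads, as_tibble(m))
}

#' Pairwise-align two sequences with affine gap penalties
#'
#' Full quadratic Gotoh DP for small problems; k-mer anchored alignment
#' with DP-filled segments for large ones (`mode = "auto"`).
#'
#' @param a Query sequence. @param b Reference-side sequence.
#' @param mode `"auto"`, `"global"` (force full DP) or `"anchored"`.
#' @param scoring Scoring list, see [align_reads()].
#' @param k Anchor seed length for the anchored mode.
#' @return List with `score`, `cigar`, `b_start`.
#' @export
align_sequences <- function(a, b, mode = c("auto", "global", "anchored"),
                            scoring = default_scoring(), k = 17L) {
  mode <- match.arg(mode)
  big <- (as.double(nchar(a)) + 1) * (as.double(nchar(b)) + 1) > 4e6
  if (mode == "global" || (mode == "auto" && !big)) {
    r <- cpp_align_global(a, b, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend, FALSE, FALSE)
    r$b_start <- 0L
    return(r[c("score", "cigar", "b_start")])
  }
  r <- cpp_anchored_align(a, b, as.integer(k), scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend)
  if (!isTRUE(r$ok)) abort("sequences could not be anchored for alignment")
  r[c("score", "cigar", "b_start")]
}

#' Extract mismatch/insertion/deletion events from an alignment
#'
#' @param cigar Extended cigar string (=, X, I, D ops).
#' @param ref_start 0-based reference start of the alignment.
#' @return Tibble with `kind` (`"X"`, `"I"`, `"D"`), `ref_start`,
#'   `ref_end`, `q_start`, `q_end`.
#' @export
cigar_events <- function(cigar, ref_start = 0L) {
  m <- cpp_cigar_events(cigar, as.integer(ref_start))
  tibble(kind = c("X", "I", "D")[m[, "kind"]],
         ref_start = as.integer(unname(m[, "ref_start"])),
         ref_end = as.integer(unname(m[, "ref_end"])),
         q_start = as.integer(unname(m[, "q_start"])),
         q_end = as.integer(unname(m[, "q_end"])))
}

cigar_ref_len <- function(cigar) vapply(cigar, cpp_cigar_ref_len, 0L, USE.NAMES = FALSE)

# project a reference interval into query coordinates along an alignment;
# returns c(q_start, q_end) or NULL when not fully covered
project_interval <- function(cigar, ref_start, s, e) {
  r <- cpp_project_interval(cigar, as.integer(ref_start), as.integer(s), as.integer(e))
  if (r[3] == 0L) return(NULL)
  r[1:2]
}
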