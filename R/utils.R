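# Internal helpers: 0-based half-open coordinates everywhere; sequences are
# plain upper-case character scalars unless stated otherwise.

seq_sub <- function(s, start, end) substr(s, start + 1L, end)

seq_len_chr <- function(s) nchar(s)

#' Reverse-complement a DNA string
#'
#' @param s A character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Generate a random DNA sequence
#'
#' Uniform base composition; used by the synthetic locus generator.
#'
#' @param n Length in bases.
#' @return A single character string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random point substitution of one base
other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "",
         USE.NAMES = FALSE)
}

# homopolymer runs (length >= min_run) of a sequence, 0-based half-open
homopolymer_runs <- function(s, min_run = 3L) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$lengths >= min_run
  tibble(start = starts[keep], end = ends[keep], base = r$values[keep])
}

# does 0-based position p fall in / adjacent to a homopolymer run?
in_homopolymer <- function(pos, runs, slack = 1L) {
  if (nrow(runs) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= runs$start - slack & p < runs$end + slack),
         logical(1))
}

# interval utilities (tibbles with start/end, 0-based half-open) ------------

intervals_union <- function(iv) {
  if (nrow(iv) == 0L) return(iv[, c("start", "end")])
  iv <- arrange(iv, .data$start, .data$end)
  out_s <- iv$start[1]; out_e <- iv$end[1]
  ss <- c(); ee <- c()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= out_e) out_e <- max(out_e, iv$end[i])
    else { ss <- c(ss, out_s); ee <- c(ee, out_e); out_s <- iv$start[i]; out_e <- iv$end[i] }
  }
  tibble(start = c(ss, out_s), end = c(ee, out_e))
}

intervals_complement <- function(iv, lo, hi) {
  u <- intervals_union(iv)
  u <- filter(u, .data$end > lo, .data$start < hi)
  if (nrow(u) == 0L) return(tibble(start = lo, end = hi))
  s <- c(lo, u$end); e <- c(u$start, hi)
  keep <- e > s
  tibble(start = s[keep], end = e[keep])
}

point_in_intervals <- function(pos, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= iv$start & p < iv$end), logical(1))
}

overlaps_any <- function(start, end, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(start)))
  mapply(function(s, e) any(s < iv$end & e > iv$start), start, end)
}

# variant normalization ------------------------------------------------------
# Trim shared prefix/suffix then left-shift against the reference until the
# representation is leftmost (VCF-style normalization without anchor bases).
normalize_variant <- function(pos, ref_allele, alt_allele, refseq) {
  # trim common suffix
  while (nchar(ref_allele) > 0L && nchar(alt_allele) > 0L &&
         substr(ref_allele, nchar(ref_allele), nchar(ref_allele)) ==
         substr(alt_allele, nchar(alt_allele), nchar(alt_allele)) &&
         !(nchar(ref_allele) == 1L && nchar(alt_allele) == 1L)) {
    ref_allele <- substr(ref_allele, 1L, nchar(ref_allele) - 1L)
    alt_allele <- substr(alt_allele, 1L, nchar(alt_allele) - 1L)
  }
  # trim common prefix
  while (nchar(ref_allele) > 0L && nchar(alt_allele) > 0L &&
         substr(ref_allele, 1L, 1L) == substr(alt_allele, 1L, 1L) &&
         !(nchar(ref_allele) == 1L && nchar(alt_allele) == 1L)) {
    ref_allele <- substr(ref_allele, 2L, nchar(ref_allele))
    alt_allele <- substr(alt_allele, 2L, nchar(alt_allele))
    pos <- pos + 1L
  }
  # left-shift pure indels while the base entering on the left equals the
  # base leaving on the right
  if (xor(nchar(ref_allele) == 0L, nchar(alt_allele) == 0L)) {
    longer <- if (nchar(ref_allele) > 0L) ref_allele else alt_allele
    while (pos > 0L) {
      left <- seq_sub(refseq, pos - 1L, pos)
      lastc <- substr(longer, nchar(longer), nchar(longer))
      if (left != lastc) break
      longer <- paste0(left, substr(longer, 1L, nchar(longer) - 1L))
      pos <- pos - 1L
    }
    if (nchar(ref_allele) > 0L) ref_allele <- longer else alt_allele <- longer
  }
  list(pos = pos, ref = ref_allele, alt = alt_allele)
}

#' Classify a variant event by its length change
#'
#' Events with a 1 bp length change are reported as indels with a separate
#' `size_class` of 1 (they are tallied apart from the 2-49 bp indel class);
#' 2-49 bp changes are indels; changes of 50 bp or more are structural
#' variants.
#'
#' @param delta Absolute length change in bases (vectorized).
#' @return Character vector: `"special"` (1 bp), `"indel"` (2-49 bp), or
#'   `"SV"` (>= 50 bp); `"SNV"` for a 0 bp change (substitution).
#' @export
classify_event_length <- function(delta) {
  dplyr::case_when(
    delta == 0 ~ "SNV",
    delta == 1 ~ "special",
    delta >= 2 & delta <= 49 ~ "indel",
    delta >= 50 ~ "SV"
  )
}

phred <- function(err) ifelse(err < 1e-6, 60, pmin(60, -10 * log10(err)))

new_id <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
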