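# Independent oracles, deliberately naive: plain-R quadratic DP for
# affine-gap alignment scores, brute-force interval/substring scans, and
# full-enumeration Hardy-Weinberg probabilities.

# full quadratic Gotoh DP, scores only (no traceback)
oracle_align_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = -4, gap_extend = -1) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e9
  H <- matrix(NEG, n + 1, m + 1); E <- H; F <- H
  H[1, 1] <- 0
  for (j in seq_len(m) + 1) E[1, j] <- gap_open + gap_extend * (j - 1)
  for (i in seq_len(n) + 1) F[i, 1] <- gap_open + gap_extend * (i - 1)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      E[i, j] <- max(E[i, j - 1] + gap_extend,
                     H[i, j - 1] + gap_open + gap_extend,
                     F[i, j - 1] + gap_open + gap_extend, E[i, j])
      F[i, j] <- max(F[i - 1, j] + gap_extend,
                     H[i - 1, j] + gap_open + gap_extend,
                     E[i - 1, j] + gap_open + gap_extend, F[i, j])
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(H[i - 1, j - 1], E[i - 1, j - 1], F[i - 1, j - 1]) + s
    }
  }
  max(H[n + 1, m + 1], E[n + 1, m + 1], F[n + 1, m + 1])
}

# naive O(n*m) substring scan over reads (forward and reverse complement)
oracle_read_support <- function(pattern, reads) {
  rc <- revcomp(pattern)
  hits <- 0L
  for (s in reads$seq) {
    found <- FALSE
    for (p in c(pattern, rc)) {
      if (nchar(p) > nchar(s)) next
      for (i in seq_len(nchar(s) - nchar(p) + 1L)) {
        if (substr(s, i, i + nchar(p) - 1L) == p) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- hits + 1L
  }
  hits
}

# exact HWE p-value by full enumeration of heterozygote counts
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # P(nab = h | n, n_a) via counting: n! / (naa! h! nbb!) * 2^h
  pr <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2; hbb <- (n_b - h) / 2
    exp(lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
          h * log(2))
  }, 0)
  pr <- pr / sum(pr)
  center <- n_a * n_b / (2 * n - 1)
  sum(pr[abs(hets - center) >= abs(n_ab - center) - 1e-9])
}

# brute-force per-position annotation scan
oracle_annotate <- function(pos, ref) {
  g <- ref$genes; f <- ref$features; svs <- ref$svs
  regions <- do.call(rbind, lapply(split(g, g$segment), function(x)
    data.frame(segment = x$segment[1], start = min(x$start), end = max(x$end))))
  out <- lapply(pos, function(p) {
    gi <- which(g$start <= p & p < g$end)
    fi <- which(f$start <= p & p < f$end)
    si <- which(svs$start <= p & p < svs$end)
    ri <- which(regions$start <= p & p < regions$end)
    if (length(si) > 1L) si <- si[which.min(svs$end[si] - svs$start[si])]
    tibble::tibble(
      pos = p,
      gene = if (length(gi) > 0) g$gene[gi[1]] else NA_character_,
      feature = if (length(fi) > 0) f$feature[fi[order(f$end[fi] - f$start[fi])][1]]
                else "intergenic",
      region = if (length(ri) > 0) paste0(regions$segment[ri[1]], "-region")
               else NA_character_,
      sv_id = if (length(si) > 0) svs$sv_id[si] else NA_character_)
  })
  do.call(rbind, out)
}
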