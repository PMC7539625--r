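test_that("error-free tiling reads assemble into one exact contig", {
  set.seed(71)
  ref <- random_dna(60000L)
  rd <- tile_reads(ref, 5000L, 55000L)
  aln <- align_reads(rd, ref)
  ct <- assemble_block(aln, ref)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$ref_start, 5000L)
  expect_identical(ct$seq, substr(ref, 5001L, 55000L))
  expect_equal(ct$mean_qv, 60)

  # an internal coverage gap yields two contigs flanking it
  rd2 <- dplyr::bind_rows(tile_reads(ref, 5000L, 20000L, ids = "l"),
                          tile_reads(ref, 25000L, 40000L, ids = "r"))
  ct2 <- assemble_block(align_reads(rd2, ref), ref)
  expect_equal(nrow(ct2), 2L)
  expect_lte(ct2$ref_start[1] + nchar(ct2$seq[1]), 20000L)
  expect_equal(ct2$ref_start[2], 25000L)

  # empty bin
  expect_equal(nrow(assemble_block(aln[0, ], ref)), 0L)
})

test_that("noisy consensus reaches 99.9% identity at 40x over repeated seeds", {
  set.seed(72)
  ref <- random_dna(12000L)
  worst <- 1
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 160L
    starts <- sample(0:(12000L - 3000L), n, replace = TRUE)
    seqs <- substring(ref, starts + 1L, starts + 3000L)
    seqs <- ighap:::inject_errors(seqs, list(mismatch = 0.006, indel = 0.004,
                                             hp_bias = 0.6))
    rd <- tibble::tibble(read_id = sprintf("n%03d", 1:n), seq = seqs)
    ct <- assemble_block(align_reads(rd, ref), ref)
    big <- ct[which.max(nchar(ct$seq)), ]
    span <- substr(ref, big$ref_start + 1L, big$ref_start + ighap:::cigar_ref_len(big$cigar))
    acc <- assembly_concordance(big$seq, span)$accuracy
    worst <- min(worst, acc)
  }
  expect_gte(worst, 0.999)
})

test_that("contig QV filter is strict at the threshold and idempotent", {
  ct <- tibble::tibble(contig_id = c("a", "b", "c"),
                       mean_qv = c(19, 20, 60), seq = "A")
  kept <- filter_contigs(ct)
  expect_identical(kept$contig_id, c("b", "c"))     # 20 retained, 19 dropped
  expect_identical(filter_contigs(kept), kept)      # idempotent
  expect_equal(nrow(filter_contigs(ct[0, ])), 0L)
})

test_that("recruitment reassembles regions covered only by filtered-out molecules", {
  set.seed(73)
  ref <- random_dna(40000L)
  # high-pass reads cover the flanks, single-pass molecules the middle
  rd <- dplyr::bind_rows(
    dplyr::mutate(tile_reads(ref, 0L, 15000L, ids = "a"), n_passes = 8L),
    dplyr::mutate(tile_reads(ref, 14000L, 26500L, ids = "mid"), n_passes = 1L),
    dplyr::mutate(tile_reads(ref, 25000L, 40000L, ids = "b"), n_passes = 8L))
  cfg <- ig_config(min_depth = 3L)
  ph <- phase_reads(rd, structure(list(seq = ref,
                                       genes = tibble::tibble(gene = character(),
                                                              segment = character(),
                                                              strand = character(),
                                                              start = integer(),
                                                              end = integer(),
                                                              functional = character()),
                                       features = tibble::tibble(),
                                       svs = tibble::tibble(sv_id = character(),
                                                            start = integer(),
                                                            end = integer()),
                                       liftover = tibble::tibble(),
                                       base_len = nchar(ref),
                                       repeats = tibble::tibble()),
                                  class = "ig_reference"), cfg)
  asm <- assemble_haplotypes(ph, structure(list(seq = ref), class = "ig_reference"),
                             reads_all = rd, config = cfg)
  expect_true(any(asm$contigs$recruited))
  expect_equal(nrow(asm$uncovered), 0L)
  spans <- tibble::tibble(start = asm$contigs$ref_start,
                          end = asm$contigs$ref_start +
                            ighap:::cigar_ref_len(asm$contigs$cigar))
  u <- ighap:::intervals_union(spans)
  expect_lte(u$start[1], 100L)
  expect_gte(max(u$end), 39000L)

  # with no recruitment pool the uncovered set is unchanged
  covered <- tibble::tibble(start = 0L, end = 40000L)
  partial <- dplyr::filter(asm$contigs, !recruited)
  rr <- recruit_and_retry(partial, covered, ph$alignments[0, ], ref, cfg)
  expect_gt(nrow(rr$uncovered), 0L)
  # full coverage: nothing to retry
  rr2 <- recruit_and_retry(asm$contigs, covered, ph$alignments[0, ], ref, cfg)
  expect_equal(nrow(rr2$uncovered), 0L)
})

test_that("contigs sharing clean terminal overlaps merge to the truth sequence", {
  set.seed(74)
  truth <- random_dna(30000L)
  mk <- function(s, e, id, qv = 60)
    tibble::tibble(contig_id = id, seq = substr(truth, s + 1L, e),
                   mean_qv = qv, hap = 1L)
  # exact 5000 bp terminal overlap
  two <- dplyr::bind_rows(mk(0L, 12000L, "c1"), mk(7000L, 20000L, "c2"))
  m <- merge_overlapping_contigs(two)
  expect_equal(nrow(m$contigs), 1L)
  expect_equal(nchar(m$contigs$seq), 12000L + 13000L - 5000L)
  expect_identical(m$contigs$seq, substr(truth, 1, 20000L))

  # three chained contigs collapse to the full truth
  three <- dplyr::bind_rows(mk(0L, 12000L, "c1"), mk(9000L, 21000L, "c2"),
                            mk(19500L, 30000L, "c3"))
  m3 <- merge_overlapping_contigs(three)
  expect_equal(nrow(m3$contigs), 1L)
  expect_identical(m3$contigs$seq, truth)

  # an overlap below the identity threshold is left unmerged
  noisy <- mk(7000L, 20000L, "c2x")
  sseq <- strsplit(noisy$seq, "")[[1]]
  p <- sample(5000, 120)    # 120 mismatches in the 5 kb overlap (2.4%)
  sseq[p] <- sample(c("A", "C", "G", "T"), 120, TRUE)
  noisy$seq <- paste(sseq, collapse = "")
  m4 <- merge_overlapping_contigs(dplyr::bind_rows(mk(0L, 12000L, "c1"), noisy))
  expect_equal(nrow(m4$contigs), 2L)

  # different haplotypes never merge
  m5 <- merge_overlapping_contigs(dplyr::bind_rows(
    mk(0L, 12000L, "c1"), dplyr::mutate(mk(7000L, 20000L, "c2"), hap = 2L)))
  expect_equal(nrow(m5$contigs), 2L)
})

test_that("minority read clusters sharing a deletion are set aside", {
  set.seed(75)
  ref <- random_dna(30000L)
  main <- tile_reads(ref, 0L, 30000L, read_len = 5000L, step = 400L, ids = "m")
  delhap <- paste0(substr(ref, 1, 10000), substr(ref, 15001, 30000))
  som_starts <- seq(6000L, 8000L, by = 500L)
  som <- tibble::tibble(read_id = sprintf("s%02d", seq_along(som_starts)),
                        seq = substring(delhap, som_starts + 1L, som_starts + 9000L),
                        qual = "I", n_passes = 8L)
  aln <- align_reads(dplyr::bind_rows(main, som), ref)
  sc <- detect_somatic_cluster(aln)
  expect_false(is.null(sc$signature))
  expect_setequal(sc$minority$read_id, som$read_id)
  expect_equal(sc$signature$start, 10000L, tolerance = 5)
  # without carriers there is no cluster
  sc0 <- detect_somatic_cluster(align_reads(main, ref))
  expect_null(sc0$signature)
})

test_that("noiseless end-to-end assembly equals the truth haplotypes exactly", {
  st <- tiny_study()
  run <- tiny_run()
  cg <- run$assembly$contigs
  expect_gt(nrow(cg), 0L)
  for (i in seq_len(nrow(cg))) {
    s <- cg$ref_start[i]
    e <- s + ighap:::cigar_ref_len(cg$cigar[i])
    hits <- vapply(1:2, function(h)
      identical(truth_segment(st$tr, h, s, e), cg$seq[i]), logical(1))
    expect_true(any(hits), info = cg$contig_id[i])
  }
  # one contig per haplotype per heterozygous block
  per_bin <- dplyr::count(dplyr::filter(cg, !is.na(block_id), hap != 0L),
                          block_id, hap)
  expect_true(all(per_bin$n == 1L))
  # after merging, no two same-haplotype contigs overlap by >= 1 kb
  for (h in 1:2) {
    ch <- dplyr::arrange(dplyr::filter(cg, hap %in% c(h, 0L)), ref_start)
    if (nrow(ch) < 2L) next
    ends <- ch$ref_start + ighap:::cigar_ref_len(ch$cigar)
    expect_true(all(ch$ref_start[-1] > ends[-nrow(ch)] - 1000L))
  }
})
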