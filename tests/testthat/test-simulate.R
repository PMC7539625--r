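test_that("diploid truth construction is internally consistent", {
  st <- tiny_study()
  tr <- st$tr; ref <- st$loc$ref
  # zero variants: haplotypes equal the reference
  loc0 <- st$loc
  tr0 <- sim_diploid(loc0, n_snv_het = 0L, n_snv_hom = 0L, n_indel = 0L,
                     sv_spec = character(0), n_novel_alleles = 0L,
                     n_known_alt = 0L, vdj = FALSE, seed = 1)
  expect_identical(tr0$hap_seqs[1], ref$seq)
  expect_identical(tr0$hap_seqs[2], ref$seq)
  # one het SNV: exactly one differing position
  tr1 <- sim_diploid(loc0, n_snv_het = 1L, n_snv_hom = 0L, n_indel = 0L,
                     sv_spec = character(0), n_novel_alleles = 0L,
                     n_known_alt = 0L, vdj = FALSE, seed = 2)
  v <- tr1$variants
  carrier <- tr1$hap_seqs[v$hap[1]]
  other <- tr1$hap_seqs[3 - v$hap[1]]
  expect_identical(other, ref$seq)
  d <- which(strsplit(carrier, "")[[1]] != strsplit(ref$seq, "")[[1]])
  expect_equal(d, v$start[1] + 1L)
  # a lone large deletion shortens the carrier haplotype by exactly its span
  trd <- sim_diploid(loc0, n_snv_het = 0L, n_snv_hom = 0L, n_indel = 0L,
                     sv_spec = "embedded_del", n_novel_alleles = 0L,
                     n_known_alt = 0L, vdj = FALSE, link_dist = 2000L, seed = 3)
  del <- dplyr::filter(trd$variants, origin == "embedded_del")
  expect_equal(nchar(trd$hap_seqs[2]), nchar(ref$seq) - (del$end - del$start))
  expect_equal(nchar(trd$hap_seqs[1]), nchar(ref$seq))
})

test_that("planted variants are visible in the haplotype sequences", {
  tr <- tiny_study()$tr
  ref <- tiny_study()$loc$ref
  snvs <- dplyr::filter(tr$variants, type == "SNV")
  for (i in sample(nrow(snvs), 20)) {
    v <- snvs[i, ]
    haps <- if (v$hap == 0L) 1:2 else v$hap
    for (h in haps) {
      # the alt base sits immediately left of the image of the footprint end
      hp <- ighap:::hap_pos(tr$maps[[h]], v$end)
      expect_identical(substr(tr$hap_seqs[h], hp, hp), unname(v$alt))
    }
    if (v$hap != 0L) {
      o <- 3L - v$hap
      hp <- ighap:::hap_pos(tr$maps[[o]], v$start)
      expect_identical(substr(tr$hap_seqs[o], hp + 1L, hp + 1L), unname(v$ref))
    }
  }
})

test_that("truth set round-trips through VCF/BED/TSV serialization", {
  tr <- tiny_study()$tr
  dir <- withr::local_tempdir()
  write_truth(tr, dir)
  back <- read_truth(dir)
  v1 <- dplyr::arrange(tr$variants, start, end, hap)
  v2 <- dplyr::arrange(back$variants, start, end, hap)
  expect_equal(as.data.frame(v2), as.data.frame(v1))
  expect_equal(as.data.frame(back$alleles), as.data.frame(tr$alleles))
  expect_equal(as.data.frame(back$sv_genotypes), as.data.frame(tr$sv_genotypes))
  expect_equal(as.data.frame(back$vdj), as.data.frame(tr$vdj))
})

test_that("error-free reads are exact substrings of their haplotype", {
  st <- tiny_study()
  rd <- st$rd
  for (i in sample(nrow(rd), 50)) {
    src <- substr(st$tr$hap_seqs[rd$truth_hap[i]], rd$truth_start[i] + 1L,
                  rd$truth_end[i])
    got <- if (rd$truth_strand[i] == "-") revcomp(rd$seq[i]) else rd$seq[i]
    expect_identical(got, src)
  }
})

test_that("read counts track requested depth within Poisson-scale variation", {
  loc <- sim_locus(locus_len = 60000L, n_v = 4L, n_d = 2L, n_j = 2L,
                   sv_lens = c(4000L, 2000L), n_sv_genes = 1L, seed = 31)
  tr <- sim_diploid(loc, n_snv_het = 5L, n_snv_hom = 5L, n_indel = 0L,
                    sv_spec = character(0), n_novel_alleles = 0L,
                    n_known_alt = 0L, vdj = FALSE, seed = 32)
  L <- nchar(tr$hap_seqs[1])
  mean_len <- 6000
  counts <- vapply(1:50, function(s) {
    rd <- sim_reads(tr, coverage = 10, read_len_mean = mean_len,
                    read_len_sd = 0, seed = 100 + s)
    sum(rd$truth_hap == 1L)
  }, 0)
  expect_equal(mean(counts), round(10 * L / mean_len), tolerance = 0.02)
})

test_that("coverage dropout thins reads inside the interval, not outside", {
  loc <- sim_locus(locus_len = 60000L, n_v = 4L, n_d = 2L, n_j = 2L,
                   sv_lens = c(4000L, 2000L), n_sv_genes = 1L, seed = 41)
  tr <- sim_diploid(loc, n_snv_het = 0L, n_snv_hom = 0L, n_indel = 0L,
                    sv_spec = character(0), n_novel_alleles = 0L,
                    n_known_alt = 0L, vdj = FALSE, seed = 42)
  dropout <- tibble::tibble(start = 20000L, end = 30000L, keep_prob = 0.2)
  depth_at <- function(rd, p) sum(rd$truth_start <= p & rd$truth_end > p)
  inside <- outside <- 0
  for (s in 1:10) {
    rd <- sim_reads(tr, coverage = 15, dropout = dropout, seed = 200 + s)
    inside <- inside + depth_at(rd, 25000L)
    outside <- outside + depth_at(rd, 45000L)
  }
  expect_lt(inside, outside * 0.6)
  # outside the dropout, mean total depth (two haplotypes at 15x each)
  # within 3 standard errors of target
  expect_equal(outside / 10, 30, tolerance = 3 * sqrt(30 / 10) / 30)
})

test_that("injected indels are homopolymer-biased at the configured rate", {
  set.seed(55)
  src <- paste0(random_dna(150), strrep("A", 12), random_dna(60),
                strrep("G", 9), random_dna(150))
  runs <- ighap:::homopolymer_runs(src)
  b <- 0.7
  n_events <- 0L; n_hp <- 0L
  reads <- rep(src, 1500)
  noisy <- ighap:::inject_errors(reads, list(mismatch = 0, indel = 0.05,
                                             hp_bias = b))
  for (s in noisy) {
    al <- align_sequences(s, src, mode = "global")
    ev <- dplyr::filter(cigar_events(al$cigar), kind != "X")
    if (nrow(ev) == 0L) next
    n_events <- n_events + nrow(ev)
    n_hp <- n_hp + sum(ighap:::in_homopolymer(ev$ref_start, runs, slack = 2L))
  }
  expect_gte(n_events, 10000L)
  expect_gte(n_hp / n_events, b)
})

test_that("multiplex downsampling holds total yield fixed and is reproducible", {
  st <- tiny_study()
  reps <- lapply(1:8, function(r)
    dplyr::mutate(st$rd, sample = paste0("R", r),
                  read_id = paste0("R", r, "/", read_id)))
  total <- sum(vapply(reps, function(x) sum(nchar(x$seq)), 0))
  mx <- sim_multiplex(reps, c(2L, 40L), seed = 9)
  y2 <- sum(nchar(mx$plex2$seq))
  y40 <- sum(nchar(mx$plex40$seq))
  expect_equal(y2, total / 2, tolerance = 2 * 7000 / (total / 2))
  expect_equal(y40, total / 40, tolerance = 2 * 7000 / (total / 40))
  # 8 replicates combined to 2-plex: per-sample yield ~ 4x a single replicate
  expect_equal(y2 / sum(nchar(reps[[1]]$seq)), 4, tolerance = 0.05)
  # determinism and label-independence
  mx2 <- sim_multiplex(reps, c(2L, 40L), seed = 9)
  expect_identical(mx$plex40$read_id, mx2$plex40$read_id)
  mx3 <- sim_multiplex(reps, c(8L, 8L), seed = 9)
  expect_identical(mx3[[1]]$read_id, mx3[[2]]$read_id)
})

test_that("subread copies collapse back to the molecule consensus", {
  set.seed(77)
  rd <- tibble::tibble(read_id = c("m1", "m2"),
                       seq = c(random_dna(300L), random_dna(300L)),
                       n_passes = c(9L, 11L))
  sub <- sim_subread_copies(rd, sub_rate = 0.02, seed = 78)
  expect_equal(nrow(sub), 20L)
  cons <- collapse_subreads(sub)
  expect_identical(sort(cons$molecule_id), c("m1", "m2"))
  expect_identical(cons$seq[cons$molecule_id == "m1"], rd$seq[1])
  expect_identical(cons$seq[cons$molecule_id == "m2"], rd$seq[2])
})

test_that("reads and truth survive a FASTQ round trip", {
  st <- tiny_study()
  rd <- head(st$rd, 25)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(rd, path)
  back <- read_fastq_reads(path)
  expect_equal(as.data.frame(back), as.data.frame(rd))
})
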