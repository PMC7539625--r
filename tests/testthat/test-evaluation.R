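test_that("call-set comparison applies the genotype-discordance rule", {
  mk <- function(pos, gt) tibble::tibble(pos = pos, ref = "A", alt = "G",
                                         genotype = gt)
  # identical sets of 100
  q <- mk(1:100, "0/1")
  cmp <- compare_snv_callsets(q, q)
  expect_equal(c(cmp$tp, cmp$fp, cmp$fn), c(100L, 0L, 0L))
  expect_equal(cmp$recall, 1)
  # matched position, different genotype: discordant, counted as FP and FN
  cmp2 <- compare_snv_callsets(mk(1L, "0/1"), mk(1L, "1/1"))
  expect_equal(cmp2$genotype_discordant, 1L)
  expect_equal(cmp2$tp, 0L)
  expect_equal(cmp2$fp, 1L)
  expect_equal(cmp2$fn, 1L)
  # phased vs unphased with the same allele multiset compare equal
  cmp3 <- compare_snv_callsets(mk(1L, "1|0"), mk(1L, "0/1"))
  expect_equal(cmp3$tp, 1L)
  # disjoint sets
  cmp4 <- compare_snv_callsets(mk(1:10, "0/1"), mk(11:20, "0/1"))
  expect_equal(c(cmp4$fp, cmp4$fn), c(10L, 10L))
  # unmappable query records are excluded, never FP
  q5 <- dplyr::mutate(mk(1:10, "0/1"), mappable = c(rep(TRUE, 8), FALSE, FALSE))
  cmp5 <- compare_snv_callsets(q5, mk(1:8, "0/1"))
  expect_equal(cmp5$fp, 0L)
  expect_equal(cmp5$excluded_unmappable, 2L)
  # conservation: TP + FN equals truth size
  expect_equal(cmp5$tp + cmp5$fn - cmp5$genotype_discordant, 8L)
})

test_that("haplotype-alignment truth derivation finds exactly the planted SNVs", {
  set.seed(111)
  hap_ref <- random_dna(20000L)
  expect_equal(nrow(derive_truth_from_haplotype_alignment(hap_ref, hap_ref)), 0L)
  hq <- strsplit(hap_ref, "")[[1]]
  at <- c(5000L, 9000L, 15000L)
  for (p in at) hq[p] <- ifelse(hq[p] == "A", "T", "A")
  tt <- derive_truth_from_haplotype_alignment(paste(hq, collapse = ""), hap_ref)
  expect_equal(tt$pos, at - 1L)
  # agrees with the simulator truth list over random small fixtures
  st <- tiny_study()
  tr <- st$tr
  win <- c(150000 %/% 3, 150000 %/% 3 + 30000)  # SNV-only window
  for (h in 1:2) {
    seg <- truth_segment(tr, h, 0L, nchar(st$loc$ref$seq))
    der <- derive_truth_from_haplotype_alignment(seg, st$loc$ref$seq)
    want <- dplyr::filter(tr$variants, type == "SNV", hap %in% c(h, 0L))
    expect_setequal(der$pos, want$start)
  }
})

test_that("Mendelian checks flag impossible transmissions only", {
  ch <- tibble::tibble(pos = 1:4, genotype = c("0/1", "1/1", "0/1", "0/0"))
  mo <- tibble::tibble(pos = 1:4, genotype = c("0/0", "0/0", "0/1", "0/1"))
  fa <- tibble::tibble(pos = 1:4, genotype = c("1/1", "0/1", "0/1", "0/1"))
  v <- mendelian_check(ch, mo, fa)
  expect_equal(v$pos, 2L)      # child 1/1 needs an alt from each parent
  # a transmitted-haplotype trio fixture has zero violations
  st <- tiny_study()
  tr <- st$tr
  child_snv <- dplyr::filter(tr$variants, type == "SNV")
  child <- tibble::tibble(pos = child_snv$start,
                          genotype = ifelse(child_snv$hap == 0L, "1/1", "0/1"))
  # parent genotypes built by transmitting the child's haplotypes
  mo2 <- tibble::tibble(pos = child_snv$start,
                        genotype = ifelse(child_snv$hap %in% c(1L, 0L), "0/1", "0/0"))
  fa2 <- tibble::tibble(pos = child_snv$start,
                        genotype = ifelse(child_snv$hap %in% c(2L, 0L), "0/1", "0/0"))
  expect_equal(nrow(mendelian_check(child, mo2, fa2)), 0L)
  # planted violations are all detected
  bad_pos <- sample(child$pos, 5)
  mo3 <- dplyr::mutate(mo2, genotype = ifelse(pos %in% bad_pos, "0/0", genotype))
  fa3 <- dplyr::mutate(fa2, genotype = ifelse(pos %in% bad_pos, "0/0", genotype))
  ch3 <- dplyr::mutate(child, genotype = ifelse(pos %in% bad_pos, "1/1", genotype))
  v3 <- mendelian_check(ch3, mo3, fa3)
  expect_setequal(v3$pos, bad_pos)
})

test_that("switch errors count adjacent phase flips, orientation-free", {
  inf <- tibble::tibble(block_id = "B1", pos = 1:6, hap_alt = c(1,1,1,2,2,2))
  tru_perfect <- tibble::tibble(pos = 1:6, hap_alt = c(1,1,1,2,2,2))
  expect_equal(switch_error_count(inf, tru_perfect)$switches, 0L)
  # one internal flip: a single switch
  tru_flip <- tibble::tibble(pos = 1:6, hap_alt = c(1,1,1,1,1,1))
  expect_equal(switch_error_count(inf, tru_flip)$switches, 1L)
  # global relabeling changes nothing
  inf_fl <- dplyr::mutate(inf, hap_alt = 3 - hap_alt)
  expect_equal(switch_error_count(inf_fl, tru_flip)$switches, 1L)
  # random phasing of n sites: mean switches ~ (n-1)/2
  set.seed(121)
  n <- 12L
  tru <- tibble::tibble(pos = seq_len(n), hap_alt = rep(1L, n))
  sims <- vapply(1:1000, function(i) {
    r <- tibble::tibble(block_id = "B", pos = seq_len(n),
                        hap_alt = sample(c(1L, 2L), n, TRUE))
    switch_error_count(r, tru)$switches
  }, 0L)
  se <- sqrt((n - 1) * 0.25 / 1000)
  expect_lt(abs(mean(sims) - (n - 1) / 2), 3 * se)
})

test_that("assembly concordance counts edits and classifies homopolymer indels", {
  set.seed(131)
  s <- random_dna(10000L)
  cc <- assembly_concordance(s, s)
  expect_equal(cc$accuracy, 1)
  expect_equal(cc$substitutions, 0L)
  expect_equal(nrow(cc$indels), 0L)
  # a 2 bp insertion inside an AAAAA run is homopolymer-associated 1/1
  base <- paste0(random_dna(500L), "AAAAA", random_dna(500L))
  ins <- paste0(substr(base, 1, 502), "AA", substr(base, 503, nchar(base)))
  cc2 <- assembly_concordance(ins, base)
  expect_equal(nrow(cc2$indels), 1L)
  expect_equal(cc2$hp_fraction_1_2bp, 1)
  # 1 kb toy with three planted edits: hand-computed accuracy
  toy <- random_dna(1000L)
  ed <- strsplit(toy, "")[[1]]
  ed[200] <- ifelse(ed[200] == "A", "C", "A")   # substitution
  ed <- ed[-500]                                # 1 bp deletion
  ed <- append(ed, c("G", "G", "G"), after = 700)  # 3 bp insertion
  edited <- paste(ed, collapse = "")
  cc3 <- assembly_concordance(edited, toy)
  expect_equal(cc3$substitutions, 1L)
  expect_setequal(cc3$indels$len, c(1L, 3L))
  expect_equal(cc3$accuracy, 1 - (1 + 1 + 3) / nchar(edited))
})

test_that("the exact HWE test matches enumeration and the chi-square limit", {
  # balanced proportions at allele frequency one half
  expect_equal(hwe_test(25, 50, 25), 1)
  # extreme heterozygote deficit
  expect_lt(hwe_test(50, 0, 50), 1e-6)
  # monomorphic convention
  expect_equal(hwe_test(40, 0, 0), 1)
  # full-enumeration oracle for all tables with n <= 50
  set.seed(141)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    na <- sample(0:(2 * n), 1)
    rare <- min(na, 2 * n - na)
    h <- sample(seq(rare %% 2, rare, by = 2), 1)
    naa <- (na - h) / 2
    nbb <- n - naa - h
    expect_equal(hwe_test(naa, h, nbb), oracle_hwe(naa, h, nbb),
                 tolerance = 1e-12, info = paste(naa, h, nbb))
  }
  # chi-square agreement for large balanced fixtures (observed = expected
  # at allele frequency one half); note that for slightly unbalanced
  # tables any full-ordering exact test exceeds the chi-square tail by up
  # to the probability atom at the mode (~0.03 at n = 1000), so agreement
  # is asserted at the balanced tables the convention is defined on
  for (n in c(100L, 400L, 1000L)) {
    p_ex <- hwe_test(n / 4, n / 2, n / 4)
    p_ch <- hwe_test(n / 4, n / 2, n / 4, method = "chisq")
    expect_lt(abs(p_ex - p_ch), 0.02)
  }
  # and in the far tail both agree that the deviation is extreme
  expect_lt(hwe_test(260, 480, 260, method = "chisq") -
              hwe_test(260, 480, 260), 0.02)
})

test_that("accessibility partitioning matches a brute-force membership scan", {
  mask <- tibble::tibble(start = c(100L, 500L, 900L), end = c(200L, 700L, 1200L))
  all_in <- accessibility_partition(c(150L, 160L, 600L), mask)
  expect_equal(all_in$outside, 0L)
  none <- accessibility_partition(c(150L, 160L), mask[0, ])
  expect_equal(none$inside, 0L)
  set.seed(151)
  pos <- sample(0:1500, 10000L, replace = TRUE)
  got <- accessibility_partition(pos, mask)
  want <- vapply(pos, function(p) any(p >= mask$start & p < mask$end), logical(1))
  expect_equal(got$in_mask, want)
  expect_equal(got$inside + got$outside, got$n)
})

test_that("imputation comparison computes the signal-to-noise ratio", {
  q <- 1:100
  sets <- list(t01 = c(1:90, 200:229), t10 = 1:50)
  r <- imputation_comparison(q, sets)
  expect_equal(r$overlap, c(90L, 50L))
  expect_equal(r$imputed_only, c(30L, 0L))
  expect_equal(r$snr[1], 3)
  expect_true(is.infinite(r$snr[2]))
  ident <- imputation_comparison(q, list(same = q))
  expect_equal(ident$query_only, 0L)
  expect_equal(ident$imputed_only, 0L)
})
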