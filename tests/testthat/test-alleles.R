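test_that("the allele database loader enforces unambiguous, unique entries", {
  db <- tiny_study()$loc$db
  path <- withr::local_tempfile(fileext = ".fasta")
  write_allele_db(db, path)
  back <- read_allele_db(path)
  expect_equal(as.data.frame(back), as.data.frame(db))
  # ambiguity codes are refused
  bad <- db
  bad$seq[1] <- sub("A", "N", bad$seq[1])
  write_allele_db(bad, path)
  expect_error(read_allele_db(path), "ambiguity")
})

test_that("allele assignment: exact match, novel with diff list, deterministic ties", {
  db <- tibble::tibble(gene = "g",
                       allele = c("01", "02", "03"),
                       seq = c("ACGTACGTACGTACGTACGT",
                               "ACGTACGTACGAACGTACGT",
                               "ACGTACGTCCGTACGTACGT"))
  hit <- assign_allele(db$seq[2], "g", db)
  expect_equal(hit$status, "known")
  expect_equal(hit$allele, "02")
  # one substitution away from *01 (and equally far from nothing else)
  novel <- "ACGTACGTACGTACGTACGA"
  asn <- assign_allele(novel, "g", db)
  expect_equal(asn$status, "novel")
  expect_equal(asn$nearest, "01")
  expect_equal(nrow(asn$diffs), 1L)
  expect_equal(asn$diffs$pos, 19L)
  # equidistant from *02 and *03: lexicographically first, tie flagged
  twoaway <- "ACGTACGTCCGAACGTACGT"
  asn2 <- assign_allele(twoaway, "g", db)
  expect_equal(asn2$nearest, "02")
  expect_true(asn2$tie)
  expect_error(assign_allele("", "g", db), "empty")
  expect_error(assign_allele("ACGT", "nope", db), "no database alleles")
})

test_that("read support counts exact substring hits, matching the naive scan", {
  set.seed(101)
  allele <- random_dna(60L)
  mk_read <- function(with) {
    if (with == "fwd") paste0(random_dna(50L), allele, random_dna(50L))
    else if (with == "rev") paste0(random_dna(30L), revcomp(allele), random_dna(70L))
    else random_dna(160L)
  }
  reads <- tibble::tibble(
    seq = vapply(c(rep("fwd", 7), rep("rev", 5), rep("no", 6)), mk_read, ""))
  expect_equal(count_read_support(allele, reads), 12L)
  expect_equal(count_read_support(allele, reads[0, ]), 0L)
  # random spot checks against the brute-force oracle
  for (i in 1:5) {
    pat <- random_dna(sample(10:40, 1))
    rds <- tibble::tibble(seq = replicate(20, {
      if (runif(1) < 0.3) paste0(random_dna(20L), pat, random_dna(20L))
      else random_dna(80L)
    }))
    expect_equal(count_read_support(pat, rds), oracle_read_support(pat, rds))
  }
})

test_that("gene extraction reports sequences, deletions, gaps and V(D)J suspects", {
  st <- tiny_study()
  run <- tiny_run()
  ext <- extract_gene_sequences(run$assembly, st$loc$ref, run$calls, run$vdj)
  truth <- st$tr$alleles
  j <- dplyr::inner_join(ext, truth, by = c("gene", "hap"), suffix = c("", "_t"))
  # genes lost to the embedded deletion: 'deleted' on one haplotype label
  del_genes <- unique(truth$gene[truth$status == "deleted"])
  for (g in del_genes)
    expect_setequal(j$absence[j$gene == g],
                    c(NA_character_, "deleted")[1:2])
  vdj_genes <- unique(truth$gene[truth$status == "vdj"])
  for (g in vdj_genes)
    expect_true("vdj_suspect" %in% j$absence[j$gene == g])
  # present genes come back with a sequence
  expect_true(all(!is.na(j$seq[is.na(j$absence)])))
})

test_that("noiseless allele calls (known, alternate, novel) are exact per gene", {
  st <- tiny_study()
  run <- tiny_run()
  al <- run$alleles
  truth <- st$tr$alleles
  map_status <- function(s) ifelse(s == "vdj_suspect", "vdj", s)
  for (g in unique(truth$gene)) {
    tg <- dplyr::arrange(truth[truth$gene == g, ], status, allele)
    cg <- al[al$gene == g, ]
    expect_equal(nrow(cg), 2L, info = g)
    # unordered comparison over haplotypes (block label symmetry)
    expect_setequal(paste(map_status(cg$status),
                          ifelse(is.na(cg$allele), ".", cg$allele)),
                    paste(tg$status, ifelse(is.na(tg$allele), ".", tg$allele)))
  }
  # known calls round-trip: re-assigning the emitted sequence returns the name
  known <- dplyr::filter(al, status == "known")
  for (i in sample(nrow(known), min(8, nrow(known)))) {
    again <- assign_allele(known$seq[i], known$gene[i], st$loc$db)
    expect_equal(again$allele, known$allele[i])
  }
  # novel alleles are never reported as known and support is positive
  nov <- dplyr::filter(al, status == "novel")
  expect_equal(nrow(nov), sum(truth$status == "novel"))
  expect_true(all(nov$n_diffs >= 1L))
  expect_true(all(dplyr::filter(al, !is.na(support))$support >= 0L))
  expect_true(all(dplyr::filter(al, status %in% c("known", "novel"))$support > 0L))
  # the non-redundant rollup collapses identical per-gene calls
  ru <- allele_rollup(al)
  expect_true(all(ru$n_haps %in% 1:2))
})
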