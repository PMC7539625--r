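test_that("insertion splicing shifts coordinates by cumulative inserted length", {
  set.seed(1)
  base <- random_dna(1000L)
  genes <- tibble::tibble(gene = "g1", segment = "V", strand = "+",
                          start = 200L, end = 300L, functional = "functional")
  ref <- build_reference(base,
                         insertions = tibble::tibble(pos = 100L,
                                                     seq = random_dna(10L),
                                                     sv_id = "s1"),
                         genes = genes)
  expect_equal(nchar(ref$seq), 1010L)
  expect_equal(ref$genes$start, 210L)
  expect_equal(ref$genes$end, 310L)

  # zero insertions: identity
  ref0 <- build_reference(base, genes = genes)
  expect_identical(ref0$seq, base)
  expect_equal(ref0$liftover$custom_start, ref0$liftover$base_start)

  # two insertions: locate the second body by brute-force splicing and its
  # unique flanking 21-mers
  ins <- tibble::tibble(pos = c(100L, 500L),
                        seq = c(random_dna(10L), random_dna(20L)),
                        sv_id = c("s1", "s2"))
  ref2 <- build_reference(base, insertions = ins, genes = genes)
  expected <- paste0(substr(base, 1, 100), ins$seq[1],
                     substr(base, 101, 500), ins$seq[2],
                     substr(base, 501, 1000))
  expect_identical(ref2$seq, expected)
  left_flank <- substr(base, 480, 500)
  hit <- regexpr(left_flank, ref2$seq, fixed = TRUE)[1]
  expect_equal(hit - 1L + 21L, 510L)          # body starts at custom 510
  body <- ref2$svs[ref2$svs$sv_id == "s2", ]
  expect_equal(c(body$start, body$end), c(510L, 530L))
})

test_that("invalid insertion tables and split genes are rejected", {
  base <- strrep("ACGT", 250L)
  genes <- tibble::tibble(gene = "g1", segment = "V", strand = "+",
                          start = 90L, end = 120L, functional = "functional")
  mk <- function(pos, id = paste0("s", seq_along(pos)))
    tibble::tibble(pos = pos, seq = rep("AAAA", length(pos)), sv_id = id)
  expect_error(build_reference(base, mk(c(500L, 100L))), "sorted")
  expect_error(build_reference(base, mk(1500L)), "inside")
  expect_error(build_reference(base, mk(c(100L, 200L), c("a", "a"))), "duplicate")
  expect_error(build_reference(base, mk(100L), genes = genes), "overlap")
})

test_that("liftover maps both directions, refuses insertion bodies, round-trips", {
  ref <- mini_ref()
  # left of the insertion: unchanged
  lo <- liftover_intervals(tibble::tibble(start = 10L, end = 50L), ref,
                           "custom_to_base")
  expect_equal(c(lo$start, lo$end), c(10L, 50L))
  # inside the inserted body: none
  body <- ref$svs[1, ]
  lo2 <- liftover_intervals(tibble::tibble(start = body$start + 10L,
                                           end = body$start + 20L),
                            ref, "custom_to_base")
  expect_true(is.na(lo2$start))
  expect_false(lo2$mappable)
  # outside the source: error
  expect_error(liftover_intervals(tibble::tibble(start = -1L, end = 5L), ref,
                                  "custom_to_base"), "outside")
  # round trip on random mappable intervals
  set.seed(11)
  for (i in 1:50) {
    s <- sample(0:(ref$base_len - 20L), 1)
    iv <- tibble::tibble(start = s, end = s + sample(1:19, 1))
    fwd <- liftover_intervals(iv, ref, "base_to_custom")
    if (!fwd$mappable) next
    back <- liftover_intervals(fwd[, c("start", "end")], ref, "custom_to_base")
    if (back$mappable)
      expect_equal(c(back$start, back$end), c(iv$start, iv$end))
  }
})

test_that("liftover map conserves length: segments plus bodies tile the custom sequence", {
  for (ref in list(mini_ref(), tiny_study()$loc$ref)) {
    seg <- sum(ref$liftover$custom_end - ref$liftover$custom_start)
    bodies <- sum(ref$svs$end - ref$svs$start)
    expect_equal(seg + bodies, nchar(ref$seq))
    # deleting every body string reproduces the base sequence
    keep <- rep(TRUE, nchar(ref$seq))
    for (i in seq_len(nrow(ref$svs)))
      keep[(ref$svs$start[i] + 1L):ref$svs$end[i]] <- FALSE
    chars <- strsplit(ref$seq, "")[[1]]
    expect_equal(nchar(paste(chars[keep], collapse = "")), ref$base_len)
  }
})

test_that("building then deleting insertion bodies recovers the base on random fixtures", {
  set.seed(5)
  for (i in 1:5) {
    base <- random_dna(2000L)
    npos <- sample(1:3, 1)
    pos <- sort(sample(100:1900, npos))
    while (any(diff(pos) < 10)) pos <- sort(sample(100:1900, npos))
    ins <- tibble::tibble(pos = pos,
                          seq = vapply(sample(5:50, npos, TRUE), random_dna, ""),
                          sv_id = paste0("s", seq_len(npos)))
    ref <- build_reference(base, ins)
    out <- ref$seq
    for (j in rev(seq_len(nrow(ref$svs))))
      out <- paste0(substr(out, 1, ref$svs$start[j]),
                    substr(out, ref$svs$end[j] + 1L, nchar(out)))
    expect_identical(out, base)
  }
})

test_that("position annotation matches a brute-force interval scan", {
  ref <- tiny_study()$loc$ref
  # targeted cases
  ex <- dplyr::filter(ref$features, feature == "exon")[1, ]
  g <- ref$genes$gene[ref$genes$gene == ex$gene]
  ann <- annotate_positions(ex$start + 2L, ref)
  expect_equal(ann$gene, ex$gene)
  expect_equal(ann$feature, "exon")
  expect_equal(ann$region, paste0(ref$genes$segment[ref$genes$gene == ex$gene][1],
                                  "-region"))
  body <- ref$svs[1, ]
  ann2 <- annotate_positions(body$start + 5L, ref)
  expect_equal(ann2$sv_id, body$sv_id)
  # far right tail: intergenic, no region, no sv
  ann3 <- annotate_positions(nchar(ref$seq) - 5L, ref)
  expect_true(is.na(ann3$gene))
  expect_equal(ann3$feature, "intergenic")
  expect_true(is.na(ann3$sv_id))
  # 10,000 random positions against the oracle
  set.seed(99)
  pos <- sample(0:(nchar(ref$seq) - 1L), 10000L, replace = TRUE)
  got <- annotate_positions(pos, ref)
  want <- oracle_annotate(pos, ref)
  expect_equal(got$gene, want$gene)
  expect_equal(got$feature, want$feature)
  expect_equal(got$region, want$region)
  expect_equal(got$sv_id, want$sv_id)
})
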