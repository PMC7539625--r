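# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# a small diploid study: 120 kb locus, 2 embedded SVs, full variant menu
tiny_study <- function() {
  fixture("tiny_study", function() {
    loc <- sim_locus(locus_len = 120000L, n_v = 8L, n_d = 3L, n_j = 2L,
                     sv_lens = c(8000L, 4000L), n_alt_alleles = 3L, seed = 421L)
    tr <- sim_diploid(loc, n_snv_het = 40L, n_snv_hom = 20L, n_indel = 6L,
                      novel_del_len = 800L, n_novel_alleles = 2L,
                      n_known_alt = 1L, seed = 422L)
    rd <- sim_reads(tr, coverage = 20, seed = 423L)
    list(loc = loc, tr = tr, rd = rd)
  })
}

# the same study run through the pipeline (noiseless)
tiny_run <- function() {
  fixture("tiny_run", function() {
    st <- tiny_study()
    run_pipeline(st$loc$ref, st$rd, st$loc$db)
  })
}

# minimal reference with two genes and one embedded SV, for unit tests
mini_ref <- function() {
  fixture("mini_ref", function() {
    set.seed(7)
    base <- random_dna(3000L)
    genes <- tibble::tibble(
      gene = c("IGHV1-1", "IGHJ1"), segment = c("V", "J"),
      strand = c("+", "-"), start = c(300L, 2400L), end = c(500L, 2500L),
      functional = "functional")
    feats <- tibble::tibble(
      gene = c("IGHV1-1", "IGHV1-1", "IGHJ1"),
      feature = c("LP1", "exon", "exon"),
      start = c(300L, 360L, 2400L), end = c(360L, 500L, 2500L))
    build_reference(base,
                    insertions = tibble::tibble(pos = 1000L,
                                                seq = random_dna(400L),
                                                sv_id = "svA"),
                    genes = genes, features = feats)
  })
}

# exact reads tiling a window of a sequence, pre-aligned
tile_reads <- function(seqsrc, from, to, read_len = 2000L, step = 500L,
                       ids = "t") {
  starts <- seq(from, max(from, to - read_len), by = step)
  tibble::tibble(
    read_id = sprintf("%s%04d", ids, seq_along(starts)),
    seq = substring(seqsrc, starts + 1L, pmin(nchar(seqsrc), starts + read_len)),
    qual = strrep("I", nchar(substring(seqsrc, starts + 1L,
                                       pmin(nchar(seqsrc), starts + read_len)))),
    n_passes = 8L)
}
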