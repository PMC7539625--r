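# Run configuration and stage orchestration. Every tunable threshold
# named by the other modules lives here with its default; a config can be
# serialized to YAML and reloaded to reproduce a run.

#' Pipeline configuration
#'
#' Returns the full set of stage parameters with their defaults;
#' overrides are given as named arguments. Notable parameters:
#' `min_passes` (2; molecules with fewer subread passes are dropped),
#' `contig_qv_min` (20; contigs with mean consensus QV below this are
#' filtered), `min_depth`/`min_alt_fraction`/`max_alt_fraction`
#' (10/0.25/0.75; het candidate detection), merge thresholds
#' (1000 bp / 0.002 / 20 gap bases), SV genotyping thresholds
#' (0.8 span fraction, 0.2x/0.6x depth ratios), and the V(D)J flag rule
#' (>= 10 kb, right edge within 5 kb of the J-proximal end).
#'
#' @param ... Named overrides.
#' @return A named list of class `ig_config`.
#' @export
ig_config <- function(...) {
  cfg <- list(
    # read filter / mapping
    min_passes = 2L, seed_k = 17L, seed_step = 10L, seed_max_occ = 1L,
    min_read_identity = 0.85,
    # het candidates / phasing
    min_depth = 10L, min_alt_fraction = 0.25, max_alt_fraction = 0.75,
    max_phase_rounds = 10L, rescue_min_del = 1000L,
    # assembly
    min_layout_overlap = 1L, contig_qv_min = 20,
    merge_min_overlap = 1000L, merge_max_mismatch_rate = 0.002,
    merge_max_gap_bases = 20L, somatic_split = TRUE, somatic_min_del = 50L,
    # variant calling
    event_merge_gap = 10L, ccs_support_reads = 2L, ccs_support_fraction = 0.1,
    snv_filter_min_alt = 3L, sv_boundary = 50L,
    # SV genotyping
    sv_span_frac = 0.8, sv_flank = 2000L, sv_depth_absent = 0.2,
    sv_depth_present = 0.6, sv_min_junction_reads = 2L,
    # V(D)J artifact flag
    vdj_min_len = 10000L, vdj_margin = 5000L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = c("ig_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return An `ig_config` (for the reader); the path (for the writer).
#' @export
read_config <- function(path) {
  do.call(ig_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config An `ig_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline: phase, assemble, detect
#'
#' Orchestrates phasing, haplotype assembly, variant detection, embedded
#' SV genotyping and allele calling. A stage failure halts with an error
#' naming the stage; when an output directory is given, outputs of the
#' completed stages are preserved on disk.
#'
#' @param ref An `ig_reference`.
#' @param reads Read tibble.
#' @param db Allele database tibble (or NULL to skip allele calling,
#'   which then fails the detect stage as missing input).
#' @param config Pipeline configuration.
#' @param outdir Optional output directory.
#' @return An `ig_run`: list with `phase`, `assembly`, `calls`,
#'   `sv_genotypes`, `alleles`, `vdj`, `coverage`, `config`.
#' @export
run_pipeline <- function(ref, reads, db = NULL, config = ig_config(),
                         outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
  }
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  ph <- stage("phase", phase_reads(reads, ref, config))
  if (!is.null(outdir)) {
    write_sam(ph, ref, file.path(outdir, "phased_reads.sam"))
    write_blocks_bed(ph$blocks, file.path(outdir, "blocks.bed"))
    write_phased_snv_vcf(ph, ref, file.path(outdir, "phased_snvs.vcf"))
  }

  asm <- stage("assemble", assemble_haplotypes(ph, ref, reads_all = reads,
                                               config = config))
  if (!is.null(outdir)) {
    write_contigs_fasta(asm$contigs, file.path(outdir, "assembly.fasta"))
    write_contigs_sam(asm$contigs, ref, file.path(outdir, "assembly.sam"))
    readr::write_tsv(asm$uncovered, file.path(outdir, "uncovered.bed"),
                     col_names = FALSE)
    readr::write_tsv(asm$gaps, file.path(outdir, "gap_sizes.tsv"))
  }

  calls <- stage("detect", call_variants(asm, ph, ref, config))
  vdj <- attr(calls, "vdj")
  svg <- stage("detect", genotype_svs(asm, ph, calls, ref, config))
  if (is.null(db)) stage("detect", abort("allele database missing"))
  al <- stage("detect", call_alleles(asm, ref, db, calls, reads, vdj))

  cov <- coverage_summary(ph)
  run <- structure(list(phase = ph, assembly = asm, calls = calls,
                        sv_genotypes = svg$genotypes, sv_curation = svg$curation,
                        alleles = al, vdj = vdj, coverage = cov,
                        config = config),
                   class = "ig_run")
  if (!is.null(outdir)) {
    write_calls_vcf(calls, ref, file.path(outdir, "variants_snv.vcf"))
    write_calls_bed(calls, file.path(outdir, "variants_indel_sv.bed"))
    readr::write_tsv(run$sv_genotypes, file.path(outdir, "sv_genotypes.tsv"))
    write_sv_vcf(run$sv_genotypes, ref, file.path(outdir, "sv_genotypes.vcf"))
    readr::write_tsv(select(al, -"tie"), file.path(outdir, "alleles.tsv"))
    write_summary(run, file.path(outdir, "summary.txt"))
  }
  run
}

#' @export
print.ig_run <- function(x, ...) {
  cat("<ig_run>\n")
  print(x$phase)
  print(x$assembly)
  cat("  calls: ", sum(x$calls$type == "SNV"), " SNVs, ",
      sum(x$calls$type == "indel"), " indels, ",
      sum(x$calls$type == "SV"), " SVs; ",
      nrow(x$sv_genotypes), " embedded SVs genotyped\n", sep = "")
  invisible(x)
}

# per-position depth and threshold table from the phase pileup
coverage_summary <- function(phase, thresholds = c(1, 5, 10, 20, 50, 100)) {
  depth <- colSums(phase$pileup[1:4, , drop = FALSE])
  tibble(threshold = thresholds,
         bases = vapply(thresholds, function(t) sum(depth >= t), 0),
         fraction = vapply(thresholds, function(t) mean(depth >= t), 0))
}

#' Write the run summary page
#'
#' Plain-text summary: locus coverage at depth thresholds (empirical
#' cumulative coverage), variant counts by class, embedded SV genotypes,
#' the per-gene allele table and the novel-allele list.
#'
#' @param run An `ig_run`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_summary <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("== run summary ==")
  w("")
  w("-- locus coverage (CCS reads) --")
  w("depth_threshold\tbases\tfraction")
  for (i in seq_len(nrow(run$coverage)))
    w(run$coverage$threshold[i], "\t", run$coverage$bases[i], "\t",
      sprintf("%.4f", run$coverage$fraction[i]))
  w("")
  w("-- haplotype blocks --")
  w("blocks\t", nrow(run$phase$blocks))
  w("heterozygous_blocks\t", sum(run$phase$blocks$class == "heterozygous"))
  w("phased_snvs\t", nrow(run$phase$snvs))
  w("")
  w("-- assembly --")
  w("contigs\t", nrow(run$assembly$contigs))
  w("assembled_bases\t", sum(nchar(run$assembly$contigs$seq)))
  w("uncovered_intervals\t", nrow(run$assembly$uncovered))
  w("")
  w("-- variant counts --")
  cc <- run$calls %>% filter(.data$filter == "PASS") %>%
    count(.data$type, .data$size_class)
  w("type\tsize_class\tn")
  for (i in seq_len(nrow(cc))) w(cc$type[i], "\t", cc$size_class[i], "\t", cc$n[i])
  w("")
  w("-- embedded SV genotypes --")
  w("sv_id\tgenotype")
  for (i in seq_len(nrow(run$sv_genotypes)))
    w(run$sv_genotypes$sv_id[i], "\t", run$sv_genotypes$genotype[i])
  w("")
  w("-- alleles --")
  w("gene\thap\tstatus\tallele\tsupport")
  for (i in seq_len(nrow(run$alleles)))
    w(run$alleles$gene[i], "\t", run$alleles$hap[i], "\t",
      run$alleles$status[i], "\t",
      ifelse(is.na(run$alleles$allele[i]), ".", run$alleles$allele[i]), "\t",
      ifelse(is.na(run$alleles$support[i]), ".", run$alleles$support[i]))
  w("")
  w("-- novel alleles --")
  nov <- filter(run$alleles, .data$status == "novel")
  if (nrow(nov) == 0L) w("(none)")
  for (i in seq_len(nrow(nov)))
    w(nov$gene[i], "\thap", nov$hap[i], "\tnearest *", nov$nearest[i],
      "\tdiffs ", nov$n_diffs[i], "\t", nov$seq[i])
  invisible(path)
}
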