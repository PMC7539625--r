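#' Build a custom locus reference with embedded SV sequences
#'
#' Splices known SV insertion sequences into a base locus sequence at their
#' positions, producing the expanded custom reference the rest of the
#' pipeline maps against. Each insertion body is registered as a biallelic
#' SV region (the alternate allele being absence of the body), gene and
#' feature annotations are shifted by the cumulative inserted length to
#' their left, and a liftover map between base and custom coordinates is
#' constructed.
#'
#' All coordinates are 0-based, half-open. Genes whose locus interval
#' spans an insertion point are rejected: the embedded SVs sit between
#' genes and a split annotation would be undefined.
#'
#' @param base_seq Base locus sequence (single character string).
#' @param insertions Tibble with columns `pos` (0-based insertion point on
#'   the base sequence, strictly inside it, sorted, non-coincident), `seq`
#'   (inserted sequence) and `sv_id` (unique label). May have zero rows.
#' @param genes Tibble of gene annotations on base coordinates: `gene`,
#'   `segment` (`"V"`, `"D"` or `"J"`), `strand` (`"+"`/`"-"`), `start`,
#'   `end`, `functional` (`"functional"`, `"ORF"`, `"pseudogene"`).
#' @param features Tibble of gene features on base coordinates: `gene`,
#'   `feature` (`"exon"`, `"intron"`, `"LP1"`, `"RS"`), `start`, `end`.
#' @return An object of class `ig_reference`: a list with `seq`, `genes`,
#'   `features`, `svs`, `liftover`, `base_len` and `repeats` (tandem-repeat
#'   metadata, possibly empty).
#' @export
build_reference <- function(base_seq,
                            insertions = tibble(pos = integer(), seq = character(),
                                                sv_id = character()),
                            genes = tibble(gene = character(), segment = character(),
                                           strand = character(), start = integer(),
                                           end = integer(), functional = character()),
                            features = tibble(gene = character(), feature = character(),
                                              start = integer(), end = integer())) {
  L <- nchar(base_seq)
  ins <- as_tibble(insertions)
  if (nrow(ins) > 0L) {
    if (is.unsorted(ins$pos, strictly = TRUE))
      abort("insertion positions must be sorted and non-coincident")
    if (any(ins$pos <= 0L | ins$pos >= L))
      abort("insertion positions must lie strictly inside the base sequence")
    if (anyDuplicated(ins$sv_id)) abort("duplicate sv_id")
    bad <- vapply(ins$pos, function(p)
      any(genes$start < p & genes$end > p), logical(1))
    if (any(bad))
      abort(paste0("gene annotations overlap insertion point(s): ",
                   paste(ins$sv_id[bad], collapse = ", ")))
  }
  # splice
  cuts <- c(0L, ins$pos, L)
  pieces <- character(0)
  svs <- tibble(sv_id = character(), start = integer(), end = integer(),
                alt_is_absence = logical(), biallelic = logical(),
                source = character())
  lift <- tibble(custom_start = integer(), custom_end = integer(),
                 base_start = integer(), base_end = integer())
  off <- 0L
  for (i in seq_len(length(cuts) - 1L)) {
    bs <- cuts[i]; be <- cuts[i + 1L]
    pieces <- c(pieces, seq_sub(base_seq, bs, be))
    lift <- bind_rows(lift, tibble(custom_start = bs + off, custom_end = be + off,
                                   base_start = bs, base_end = be))
    if (i <= nrow(ins)) {
      l <- nchar(ins$seq[i])
      pieces <- c(pieces, ins$seq[i])
      svs <- bind_rows(svs, tibble(sv_id = ins$sv_id[i],
                                   start = be + off, end = be + off + l,
                                   alt_is_absence = TRUE, biallelic = TRUE,
                                   source = "embedded"))
      off <- off + l
    }
  }
  shift <- function(p) {
    if (nrow(ins) == 0L) return(as.integer(p))
    as.integer(p + vapply(p, function(x)
      sum(nchar(ins$seq)[ins$pos <= x]), numeric(1)))
  }
  genes <- mutate(as_tibble(genes), start = shift(.data$start), end = shift(.data$end))
  features <- mutate(as_tibble(features), start = shift(.data$start), end = shift(.data$end))
  structure(list(seq = paste(pieces, collapse = ""),
                 genes = genes, features = features, svs = svs,
                 liftover = lift, base_len = L,
                 repeats = tibble(start = integer(), end = integer(),
                                  motif = character(), copies = integer())),
            class = "ig_reference")
}

#' @export
print.ig_reference <- function(x, ...) {
  cat("<ig_reference> ", nchar(x$seq), " bp custom locus (base ", x$base_len,
      " bp)\n", sep = "")
  cat("  genes: ", nrow(x$genes), "  features: ", nrow(x$features),
      "  embedded SVs: ", nrow(x$svs), "\n", sep = "")
  invisible(x)
}

#' Lift intervals between base and custom coordinates
#'
#' Maps intervals through the liftover table of an [build_reference()]
#' result. Custom-coordinate intervals intersecting an embedded insertion
#' body (which has no image in the base assembly) return `NA`.
#'
#' @param intervals Tibble with `start` and `end` columns (0-based
#'   half-open) on the source coordinate system.
#' @param ref An `ig_reference`.
#' @param direction `"custom_to_base"` or `"base_to_custom"`.
#' @return The input tibble with `start`/`end` replaced by image
#'   coordinates, plus a logical `mappable` column; unmappable rows carry
#'   `NA` coordinates.
#' @export
liftover_intervals <- function(intervals, ref,
                               direction = c("custom_to_base", "base_to_custom")) {
  direction <- match.arg(direction)
  lift <- ref$liftover
  src_len <- if (direction == "custom_to_base") nchar(ref$seq) else ref$base_len
  iv <- as_tibble(intervals)
  if (any(iv$start < 0L | iv$end > src_len | iv$start >= iv$end))
    abort("interval outside the source sequence")
  map_one <- function(s, e) {
    if (direction == "custom_to_base") {
      if (nrow(ref$svs) > 0L && any(s < ref$svs$end & e > ref$svs$start))
        return(c(NA_integer_, NA_integer_))
      seg <- lift[s >= lift$custom_start & s < lift$custom_end, ]
      seg2 <- lift[e > lift$custom_start & e <= lift$custom_end, ]
      if (nrow(seg) == 0L || nrow(seg2) == 0L) return(c(NA_integer_, NA_integer_))
      c(seg$base_start[1] + (s - seg$custom_start[1]),
        seg2$base_start[1] + (e - seg2$custom_start[1]))
    } else {
      seg <- lift[s >= lift$base_start & s < lift$base_end, ]
      seg2 <- lift[e > lift$base_start & e <= lift$base_end, ]
      if (nrow(seg) == 0L || nrow(seg2) == 0L) return(c(NA_integer_, NA_integer_))
      c(seg$custom_start[1] + (s - seg$base_start[1]),
        seg2$custom_start[1] + (e - seg2$base_start[1]))
    }
  }
  img <- t(mapply(map_one, iv$start, iv$end))
  mutate(iv, start = as.integer(img[, 1]), end = as.integer(img[, 2]),
         mappable = !is.na(.data$start))
}

#' Annotate custom-reference positions with gene, feature, region and SV
#'
#' For each position reports the overlapping gene (if any), the gene
#' feature class (`exon`, `intron`, `LP1`, `RS`, or `intergenic` when in no
#' feature), the segment region (`V-region`, `D-region`, `J-region` spans
#' from the first to the last gene of each segment class), and the id of
#' any embedded SV region containing the position (innermost, i.e.
#' smallest, wins for nested regions).
#'
#' @param pos Integer vector of 0-based positions on the custom reference.
#' @param ref An `ig_reference`.
#' @return Tibble with columns `pos`, `gene`, `feature`, `region`, `sv_id`.
#' @export
annotate_positions <- function(pos, ref) {
  stopifnot(all(pos >= 0L & pos < nchar(ref$seq)))
  pos <- as.integer(pos)
  g <- ref$genes; f <- ref$features; svs <- ref$svs
  # genes and features are non-overlapping; findInterval over sorted starts
  hit <- function(iv) {
    if (nrow(iv) == 0L) return(rep(NA_integer_, length(pos)))
    o <- order(iv$start)
    idx <- findInterval(pos, iv$start[o])
    inside <- idx >= 1L & pos < iv$end[o][pmax(idx, 1L)]
    ifelse(inside, o[pmax(idx, 1L)], NA_integer_)
  }
  gi <- hit(g)
  fi <- hit(f)
  gene <- ifelse(is.na(gi), NA_character_, g$gene[gi])
  feature <- ifelse(is.na(fi), "intergenic", f$feature[fi])
  regions <- g %>% group_by(.data$segment) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  region <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(regions)))
    region[pos >= regions$start[i] & pos < regions$end[i]] <-
      paste0(regions$segment[i], "-region")
  # SV regions may nest: assign larger first so the innermost overwrites
  sv <- rep(NA_character_, length(pos))
  if (nrow(svs) > 0L) {
    for (i in order(-(svs$end - svs$start)))
      sv[pos >= svs$start[i] & pos < svs$end[i]] <- svs$sv_id[i]
  }
  tibble(pos = pos, gene = gene, feature = feature, region = region, sv_id = sv)
}
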