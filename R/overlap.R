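# Interval intersection of polymorphic miRNA genes with QTL, fragile sites
# and host genes, and host-gene context classification. Overlap is decided
# on the full hairpin span (seeds are only 6-7 nt) and requires at least one
# shared base of the closed 1-based intervals; QTL and fragile sites are
# treated as unstranded.

#' Intersect miRNA hairpins with genomic features
#'
#' @inheritParams mature_table
#' @param features feature tibble ([read_features_bed()] or the gene rows of
#'   [read_gene_models()]): columns `name, kind, chrom, start, end, strand`.
#' @param contained require the hairpin to be fully contained in the feature
#'   instead of any-intersection (default FALSE).
#' @return tibble with one row per overlapping (miRNA, feature) pair:
#'   `mirna, feature, kind, orientation` (`sense`/`antisense` when the
#'   feature is stranded, otherwise `unstranded`), deterministically
#'   ordered.
#' @export
intersect_features <- function(mirna, features, contained = FALSE) {
  empty <- tibble(mirna = character(), feature = character(),
                  kind = character(), orientation = character())
  if (nrow(mirna) == 0 || nrow(features) == 0) return(empty)
  missing_chrom <- setdiff(unique(mirna$chrom), unique(features$chrom))
  if (length(missing_chrom) > 0) {
    inform(sprintf("intersect_features: no features on chromosome(s): %s",
                   paste(missing_chrom, collapse = ", ")))
  }
  gr_m <- GenomicRanges::GRanges(mirna$chrom, IRanges::IRanges(mirna$start, mirna$end))
  gr_f <- GenomicRanges::GRanges(features$chrom, IRanges::IRanges(features$start, features$end))
  ov <- GenomicRanges::findOverlaps(gr_m, gr_f, ignore.strand = TRUE,
                                    type = if (contained) "within" else "any")
  if (length(ov) == 0) return(empty)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  fs <- features$strand[si]
  ms <- mirna$strand[qi]
  out <- tibble(
    mirna = mirna$name[qi], feature = features$name[si], kind = features$kind[si],
    orientation = dplyr::case_when(
      is.na(fs) | fs %in% c("*", ".") ~ "unstranded",
      fs == ms ~ "sense",
      TRUE ~ "antisense"
    )
  )
  arrange(out, .data$mirna, .data$kind, .data$feature)
}

#' Classify host-gene context of miRNA hairpins
#'
#' For every (hairpin, gene) pair with at least one shared base, reports the
#' transcriptional orientation (sense when strands agree) and the exonic
#' context against the *exon union* of the gene (merged exon intervals, so
#' transcript isoforms are not double-counted): `exonic` when the hairpin
#' span is fully covered by exons, `intronic` when it shares no base with
#' them, `exon_and_intron` otherwise.
#'
#' @inheritParams mature_table
#' @param genes tibble from [read_gene_models()] (gene and exon rows).
#' @return tibble with columns `mirna, feature, kind = "gene", orientation,
#'   context`.
#' @export
host_gene_context <- function(mirna, genes) {
  gene_rows <- genes %>% filter(.data$kind == "gene")
  exon_rows <- genes %>% filter(.data$kind == "exon")
  ov <- intersect_features(mirna, gene_rows)
  if (nrow(ov) == 0) {
    return(mutate(ov, context = character(0)))
  }
  ov$context <- vapply(seq_len(nrow(ov)), function(i) {
    h <- mirna[match(ov$mirna[i], mirna$name), ]
    ex <- exon_rows %>% filter(.data$parent == ov$feature[i])
    hp_rng <- IRanges::IRanges(h$start, h$end)
    if (nrow(ex) == 0) return("intronic")
    ex_union <- IRanges::reduce(IRanges::IRanges(ex$start, ex$end))
    covered <- sum(IRanges::width(IRanges::intersect(hp_rng, ex_union)))
    if (covered == IRanges::width(hp_rng)) "exonic"
    else if (covered == 0L) "intronic"
    else "exon_and_intron"
  }, character(1))
  arrange(ov, .data$mirna, .data$feature)
}

#' Per-miRNA overlap counts
#'
#' @param records overlap tibble from [intersect_features()] or
#'   [host_gene_context()].
#' @return tibble with columns `mirna, kind, n_features` counting overlapped
#'   features per miRNA and feature kind.
#' @export
summarize_overlaps <- function(records) {
  if (nrow(records) == 0) {
    return(tibble(mirna = character(), kind = character(), n_features = integer()))
  }
  records %>%
    count(.data$mirna, .data$kind, name = "n_features") %>%
    arrange(.data$kind, dplyr::desc(.data$n_features), .data$mirna)
}

#' Per-kind overlap totals, with the most-overlapped miRNA
#'
#' @inheritParams summarize_overlaps
#' @return tibble with one row per feature kind: total overlap records,
#'   number of distinct miRNAs involved, the maximum per-miRNA count, and
#'   the miRNA(s) achieving it (ties listed lexicographically,
#'   comma-separated).
#' @export
overlap_totals <- function(records) {
  per <- summarize_overlaps(records)
  if (nrow(per) == 0) {
    return(tibble(kind = character(), n_overlaps = integer(),
                  n_mirnas = integer(), max_count = integer(),
                  top_mirnas = character()))
  }
  per %>%
    group_by(.data$kind) %>%
    summarise(
      n_overlaps = sum(.data$n_features),
      n_mirnas = n_distinct(.data$mirna),
      max_count = max(.data$n_features),
      top_mirnas = paste(sort(.data$mirna[.data$n_features == max(.data$n_features)]),
                         collapse = ","),
      .groups = "drop"
    ) %>%
    arrange(.data$kind)
}
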