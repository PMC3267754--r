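# Region classification of variants against miRNA gene architecture.
#
# A variant is classified by the set of REFERENCE bases it affects:
#   snv        the single substituted base
#   mnp        all substituted bases
#   deletion   the deleted bases (the shared VCF anchor base is excluded)
#   insertion  the two flanking reference bases, so an insertion strictly
#              between two seed positions counts as seed
# For every hairpin the variant touches, each overlapped mature yields one
# annotation (seed if any affected base maps to mature positions 2-8, else
# mature_nonseed); a hairpin hit outside all matures yields one precursor
# annotation. Seed membership is carried for both definitions: positions 2-7
# (6mer) and 2-8 (7mer).

#' Affected reference span of a variant
#'
#' @param pos,ref,alt vectors describing variants (VCF-style, 1-based).
#' @return tibble with columns `a_start, a_end`: the genomic span of the
#'   reference bases affected by each variant.
#' @export
affected_span <- function(pos, ref, alt) {
  vclass <- variant_class(ref, alt)
  anchored <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
  a_start <- dplyr::case_when(
    vclass == "deletion" & anchored ~ pos + 1L,
    TRUE ~ pos
  )
  a_end <- dplyr::case_when(
    vclass == "snv" ~ pos,
    vclass == "mnp" ~ pos + nchar(ref) - 1L,
    vclass == "deletion" ~ pos + nchar(ref) - 1L,
    vclass == "insertion" ~ pos + 1L
  )
  tibble(a_start = as.integer(a_start), a_end = as.integer(a_end))
}

#' Classify a single-base substitution as transition or transversion
#'
#' Purines are A and G; pyrimidines are C and U (T). A substitution within a
#' set is a transition, across the sets a transversion. The class is
#' complement-invariant, so either genomic or transcript orientation gives
#' the same answer.
#'
#' @param ref_base,alt_base character vectors of single bases (DNA or RNA).
#' @return character vector, `"transition"` or `"transversion"`.
#' @export
#' @examples
#' classify_substitution("A", "G") # transition
#' classify_substitution("A", "C") # transversion
classify_substitution <- function(ref_base, alt_base) {
  r <- as_rna(ref_base)
  a <- as_rna(alt_base)
  if (any(nchar(r) != 1L | nchar(a) != 1L)) {
    abort("classify_substitution() expects single bases")
  }
  if (any(!r %in% RNA_BASES | !a %in% RNA_BASES)) {
    abort("alleles must be one of A, C, G, U/T")
  }
  if (any(r == a)) abort("identical REF and ALT alleles are not a substitution")
  if_else((r %in% PURINES) == (a %in% PURINES), "transition", "transversion")
}

# Expand variants x hairpins into one row per affected reference base that
# lies inside the hairpin, with hairpin- and (per mature) mature-frame
# positions. Internal workhorse shared by the annotator.
.affected_bases <- function(variants, mirna) {
  hp <- mirna %>%
    mutate(hp_row = row_number()) %>%
    select("hp_row", hairpin = "name", "chrom",
           h_start = "start", h_end = "end", h_strand = "strand",
           h_seq = "sequence")
  sp <- affected_span(variants$pos, variants$ref, variants$alt)
  va <- variants %>%
    mutate(v_row = row_number(), a_start = sp$a_start, a_end = sp$a_end)

  # candidate (variant, hairpin) pairs by interval overlap, per chromosome
  gr_v <- GenomicRanges::GRanges(va$chrom, IRanges::IRanges(va$a_start, va$a_end))
  gr_h <- GenomicRanges::GRanges(hp$chrom, IRanges::IRanges(hp$h_start, hp$h_end))
  ov <- GenomicRanges::findOverlaps(gr_v, gr_h, ignore.strand = TRUE)
  if (length(ov) == 0) {
    return(tibble(v_row = integer(), hp_row = integer(), g = integer(),
                  base_idx = integer(), hpos = integer()))
  }
  pairs <- tibble(v_row = S4Vectors::queryHits(ov), hp_row = S4Vectors::subjectHits(ov))
  pairs <- dplyr::bind_cols(
    pairs,
    va[pairs$v_row, c("a_start", "a_end", "pos", "ref", "alt", "vclass")],
    hp[pairs$hp_row, c("hairpin", "h_start", "h_end", "h_strand", "h_seq")]
  )
  # one row per affected base
  bases <- pairs %>%
    mutate(g = purrr::map2(.data$a_start, .data$a_end, seq)) %>%
    tidyr::unnest("g") %>%
    filter(.data$g >= .data$h_start, .data$g <= .data$h_end) %>%
    mutate(
      base_idx = .data$g - .data$a_start + 1L, # index within the affected span
      hpos = if_else(.data$h_strand == "+",
                     .data$g - .data$h_start + 1L,
                     .data$h_end - .data$g + 1L)
    )
  bases
}

#' Annotate variants against miRNA gene architecture
#'
#' Classifies each variant by the region it hits (`seed`, `mature_nonseed`,
#' `precursor`) for every hairpin it overlaps, producing one row per
#' (variant, mature) pair plus one precursor row per hairpin hit outside all
#' matures. A variant inside two overlapping matures yields one row per
#' mature (seed membership is mature-specific).
#'
#' `ref_rna`/`alt_rna` are the transcript-oriented (5'->3', RNA alphabet)
#' alleles of the affected bases clipped to the annotated mature (or hairpin
#' for precursor rows); the original VCF alleles are kept in `ref`/`alt`.
#' When hairpin sequences are available, the reference allele is verified
#' against them; a disagreement sets `ref_mismatch = TRUE` rather than
#' dropping the record.
#'
#' @param variants tibble from [read_vcf()] (`id, chrom, pos, ref, alt,
#'   vclass`).
#' @param mirna hairpin tibble from [read_mirna_gff()], with sequences
#'   attached for transcript-allele and REF-check support.
#' @param include_outside also emit `region = "outside"` rows for variants
#'   overlapping no hairpin (default FALSE).
#' @return tibble with columns `id, chrom, pos, ref, alt, vclass, hairpin,
#'   mature, region, mature_position, seed6_member, seed7_member,
#'   substitution, ref_rna, alt_rna, ref_mismatch, dnp_group, run_length,
#'   derived`, deterministically ordered.
#' @export
annotate_variants <- function(variants, mirna, include_outside = FALSE) {
  empty <- tibble(
    id = character(), chrom = character(), pos = integer(), ref = character(),
    alt = character(), vclass = character(), hairpin = character(),
    strand = character(),
    mature = character(), region = character(), mature_position = integer(),
    seed6_member = logical(), seed7_member = logical(),
    substitution = character(), ref_rna = character(), alt_rna = character(),
    ref_mismatch = logical(), dnp_group = character(),
    run_length = integer(), derived = logical()
  )
  if (nrow(variants) == 0) return(empty)
  variants <- as_tibble(variants)
  if (!"vclass" %in% names(variants)) {
    variants$vclass <- variant_class(variants$ref, variants$alt)
  }
  bases <- .affected_bases(variants, mirna)
  mt <- mature_table(mirna) %>%
    mutate(mt_row = row_number()) %>%
    select("mt_row", "hairpin", mature = "mature",
           m_start = "start", m_end = "end", m_len = "length")

  rows <- list()
  if (nrow(bases) > 0) {
    # per-base mature positions for every mature of the hairpin
    bm <- bases %>%
      inner_join(mt, by = "hairpin", relationship = "many-to-many") %>%
      mutate(mpos = genome_to_mature_pos(.data$g, .data$m_start, .data$m_end,
                                         .data$h_strand)) %>%
      filter(!is.na(.data$mpos))
    if (nrow(bm) > 0) {
      mature_rows <- bm %>%
        group_by(.data$v_row, .data$hp_row, .data$mt_row) %>%
        summarise(
          hairpin = first(.data$hairpin), mature = first(.data$mature),
          h_strand = first(.data$h_strand), h_seq = first(.data$h_seq),
          h_start = first(.data$h_start), h_end = first(.data$h_end),
          mature_position = min(.data$mpos),
          seed6_member = any(.data$mpos >= 2L & .data$mpos <= 7L),
          seed7_member = any(.data$mpos >= 2L & .data$mpos <= 8L),
          m_off = first(.data$m_start), m_end2 = first(.data$m_end),
          # transcript-oriented alleles clipped to this mature
          ref_rna = .oriented_allele(.data$ref, .data$base_idx, .data$mpos,
                                     .data$h_strand[1]),
          alt_rna = .oriented_allele(.data$alt, .data$base_idx, .data$mpos,
                                     .data$h_strand[1]),
          .groups = "drop"
        ) %>%
        mutate(region = if_else(.data$seed7_member, "seed", "mature_nonseed"))
      rows <- c(rows, list(mature_rows))
    }
    # precursor rows: hairpin hit, no mature hit
    prec <- bases %>%
      dplyr::distinct(.data$v_row, .data$hp_row, .keep_all = TRUE) %>%
      anti_join(
        if (nrow(bm) > 0) dplyr::distinct(bm, .data$v_row, .data$hp_row) else
          tibble(v_row = integer(), hp_row = integer()),
        by = c("v_row", "hp_row")
      )
    if (nrow(prec) > 0) {
      prec_bases <- bases %>%
        dplyr::semi_join(prec, by = c("v_row", "hp_row")) %>%
        mutate(mpos = .data$hpos) # hairpin frame stands in for orientation order
      prec_rows <- prec_bases %>%
        group_by(.data$v_row, .data$hp_row) %>%
        summarise(
          hairpin = first(.data$hairpin), mature = NA_character_,
          h_strand = first(.data$h_strand), h_seq = first(.data$h_seq),
          h_start = first(.data$h_start), h_end = first(.data$h_end),
          mature_position = NA_integer_,
          seed6_member = FALSE, seed7_member = FALSE,
          m_off = NA_integer_, m_end2 = NA_integer_,
          ref_rna = .oriented_allele(.data$ref, .data$base_idx, .data$hpos,
                                     .data$h_strand[1]),
          alt_rna = .oriented_allele(.data$alt, .data$base_idx, .data$hpos,
                                     .data$h_strand[1]),
          .groups = "drop"
        ) %>%
        mutate(region = "precursor")
      rows <- c(rows, list(prec_rows))
    }
  }
  ann <- if (length(rows) > 0) bind_rows(rows) else
    tibble(v_row = integer(), hp_row = integer(), hairpin = character(),
           mature = character(), region = character(),
           mature_position = integer(), seed6_member = logical(),
           seed7_member = logical(), ref_rna = character(),
           alt_rna = character(), h_strand = character(), h_seq = character(),
           h_start = integer(), h_end = integer())

  out <- dplyr::bind_cols(
    variants[ann$v_row, c("id", "chrom", "pos", "ref", "alt", "vclass")],
    ann[, c("hairpin", "h_strand", "mature", "region", "mature_position",
            "seed6_member", "seed7_member", "ref_rna", "alt_rna")]
  )
  out <- rename(out, strand = "h_strand")
  # substitution class only for SNVs
  out$substitution <- NA_character_
  is_snv <- out$vclass == "snv"
  if (any(is_snv)) {
    out$substitution[is_snv] <- classify_substitution(out$ref_rna[is_snv],
                                                      out$alt_rna[is_snv])
  }
  # REF verification against the hairpin sequence (warn, never drop)
  out$ref_mismatch <- .ref_mismatch(variants, ann)
  out$dnp_group <- NA_character_
  out$run_length <- NA_integer_
  out$derived <- FALSE

  if (include_outside && nrow(variants) > 0) {
    hit <- unique(ann$v_row)
    off <- setdiff(seq_len(nrow(variants)), hit)
    if (length(off) > 0) {
      outside <- variants[off, c("id", "chrom", "pos", "ref", "alt", "vclass")] %>%
        mutate(hairpin = NA_character_, strand = NA_character_,
               mature = NA_character_,
               region = "outside", mature_position = NA_integer_,
               seed6_member = FALSE, seed7_member = FALSE,
               substitution = if_else(.data$vclass == "snv",
                                      classify_substitution(.data$ref, .data$alt),
                                      NA_character_),
               ref_rna = NA_character_, alt_rna = NA_character_,
               ref_mismatch = NA, dnp_group = NA_character_,
               run_length = NA_integer_, derived = FALSE)
      out <- bind_rows(out, outside)
    }
  }
  arrange(out, .data$chrom, .data$pos, .data$id, .data$alt,
          .data$hairpin, .data$mature)
}

# Transcript-oriented allele string for the affected bases of one
# (variant, mature/hairpin) group: order bases by mature position, take the
# allele characters, complement on the minus strand.
.oriented_allele <- function(allele, base_idx, mpos, strand) {
  ord <- order(mpos)
  chars <- substr(allele[ord], base_idx[ord], base_idx[ord])
  s <- as_rna(paste(chars, collapse = ""))
  if (strand == "-") complement_rna(s) else s
}

# REF-vs-hairpin-sequence check per annotation row. Compares each affected
# reference base (genomic + strand) with the hairpin base at that genomic
# position. NA when the hairpin sequence is unavailable or the variant is an
# insertion (its flanking-base REF letters are not part of the allele).
.ref_mismatch <- function(variants, ann) {
  if (nrow(ann) == 0) return(logical(0))
  sp <- affected_span(variants$pos, variants$ref, variants$alt)
  v_pos <- variants$pos[ann$v_row]
  v_ref <- variants$ref[ann$v_row]
  v_class <- variants$vclass[ann$v_row]
  a_start <- sp$a_start[ann$v_row]
  a_end <- sp$a_end[ann$v_row]
  vapply(seq_len(nrow(ann)), function(i) {
    if (is.na(ann$h_seq[i]) || v_class[i] == "insertion") return(NA)
    g <- seq(a_start[i], a_end[i])
    g <- g[g >= ann$h_start[i] & g <= ann$h_end[i]]
    if (length(g) == 0) return(NA)
    ref_chars <- substring(v_ref[i], g - v_pos[i] + 1L, g - v_pos[i] + 1L)
    hpos <- if (ann$h_strand[i] == "+") g - ann$h_start[i] + 1L else ann$h_end[i] - g + 1L
    hp_chars <- substring(ann$h_seq[i], hpos, hpos)
    ref_rna <- as_rna(ref_chars)
    if (ann$h_strand[i] == "-") ref_rna <- complement_rna(ref_rna)
    any(ref_rna != hp_chars)
  }, logical(1))
}

#' Merge adjacent SNVs into double-nucleotide polymorphism runs
#'
#' SNVs at genomically adjacent positions within the same hairpin are grouped
#' into maximal runs. Runs of length 2 are labelled `dnp`, longer runs
#' `mnp_run`. The per-SNV member rows are retained (with `dnp_group` filled)
#' and one derived merged row per run is appended (`derived = TRUE`), whose
#' alleles are the concatenated member alleles in transcript orientation.
#' VCF-native MNP records already carry `vclass = "mnp"` and are left as-is;
#' both representations end up labelled the same way downstream.
#'
#' The operation is idempotent and independent of input order: previously
#' derived rows are recomputed, not duplicated.
#'
#' @param annotated tibble from [annotate_variants()].
#' @return the input with `dnp_group`/`run_length` assigned and derived
#'   merged rows appended, deterministically ordered.
#' @export
merge_dnps <- function(annotated) {
  ann <- annotated %>% filter(!.data$derived)
  ann$dnp_group <- NA_character_
  ann$run_length <- NA_integer_
  snv <- ann %>%
    filter(.data$vclass == "snv", !is.na(.data$hairpin)) %>%
    dplyr::distinct(.data$hairpin, .data$pos)
  if (nrow(snv) == 0) {
    return(arrange(ann, .data$chrom, .data$pos, .data$id, .data$alt,
                   .data$hairpin, .data$mature))
  }
  runs <- snv %>%
    arrange(.data$hairpin, .data$pos) %>%
    group_by(.data$hairpin) %>%
    mutate(run = cumsum(c(1L, diff(.data$pos) != 1L))) %>%
    group_by(.data$hairpin, .data$run) %>%
    mutate(run_length = n(),
           dnp_group = sprintf("%s:%d", .data$hairpin[1], min(.data$pos))) %>%
    ungroup() %>%
    filter(.data$run_length >= 2L) %>%
    select("hairpin", "pos", "dnp_group", "run_length")
  if (nrow(runs) == 0) {
    return(arrange(ann, .data$chrom, .data$pos, .data$id, .data$alt,
                   .data$hairpin, .data$mature))
  }
  ann <- ann %>%
    select(-"dnp_group", -"run_length") %>%
    left_join(runs, by = c("hairpin", "pos")) %>%
    mutate(dnp_group = if_else(.data$vclass == "snv", .data$dnp_group, NA_character_),
           run_length = if_else(.data$vclass == "snv", .data$run_length, NA_integer_))

  # one derived merged record per run x mature-assignment
  members <- ann %>%
    filter(!is.na(.data$dnp_group)) %>%
    group_by(.data$dnp_group, .data$mature) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    # for multiallelic positions keep the first ALT at each position
    dplyr::distinct(.data$pos, .keep_all = TRUE) %>%
    summarise(
      id = paste(.data$id, collapse = "+"),
      chrom = first(.data$chrom), pos = min(.data$pos),
      ref = paste(.data$ref, collapse = ""), alt = paste(.data$alt, collapse = ""),
      hairpin = first(.data$hairpin),
      region = c("precursor", "mature_nonseed", "seed")[
        max(match(.data$region, c("precursor", "mature_nonseed", "seed")))],
      mature_position = if (all(is.na(.data$mature_position))) NA_integer_ else
        min(.data$mature_position, na.rm = TRUE),
      seed6_member = any(.data$seed6_member),
      seed7_member = any(.data$seed7_member),
      # member rows are single bases; concatenate in 5'->3' mature order
      strand = first(.data$strand),
      ref_rna = paste(.data$ref_rna[order(
        if (first(.data$strand) == "-") -.data$pos else .data$pos)], collapse = ""),
      alt_rna = paste(.data$alt_rna[order(
        if (first(.data$strand) == "-") -.data$pos else .data$pos)], collapse = ""),
      ref_mismatch = any(.data$ref_mismatch),
      run_length = first(.data$run_length),
      .groups = "drop"
    ) %>%
    mutate(
      vclass = if_else(.data$run_length == 2L, "dnp", "mnp_run"),
      substitution = NA_character_, derived = TRUE
    )
  out <- bind_rows(ann, members)
  arrange(out, .data$chrom, .data$pos, .data$id, .data$alt,
          .data$hairpin, .data$mature, .data$derived)
}
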