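# Seed-switch screen: does a mutant seed become identical to the seed of a
# different annotated miRNA? Matching is exact string equality on seed
# sequences, computed separately for the 6mer (positions 2-7) and 7mer
# (positions 2-8) definitions. The canonical example is the +13 G>A
# substitution in miR-96, whose mutant seed perfectly matches miR-514.

#' Build a seed-string index over all mature miRNAs
#'
#' Matures sharing a seed (seed families) share a key, so a lookup may name
#' several miRNAs; matures shorter than `k + 1` nt carry no seed and are
#' excluded.
#'
#' @inheritParams mature_table
#' @param k seed length, 6 or 7.
#' @return tibble with columns `seed, mature, hairpin, k`, one row per
#'   mature.
#' @export
build_seed_index <- function(mirna, k = 7) {
  stopifnot(length(k) == 1L, k %in% c(6L, 7L))
  mt <- mature_sequences(mirna)
  mt <- mt[!is.na(mt$sequence) & mt$length >= k + 1L, , drop = FALSE]
  if (nrow(mt) == 0) {
    return(tibble(seed = character(), mature = character(),
                  hairpin = character(), k = integer()))
  }
  out <- tibble(
    seed = extract_seed(mt$sequence, k),
    mature = mt$mature, hairpin = mt$hairpin, k = as.integer(k)
  )
  arrange(out, .data$seed, .data$mature)
}

#' Apply a substitution to a mature miRNA sequence
#'
#' Length-preserving: only SNV/MNP-style substitutions are supported. The
#' reference allele is checked against the sequence at the stated position.
#'
#' @param mature_seq mature sequence, 5'->3' RNA.
#' @param mature_position 1-based position of the first substituted base.
#' @param ref_rna,alt_rna transcript-oriented alleles of equal length.
#' @return the mutant sequence.
#' @export
#' @examples
#' apply_variant_to_mature("ACGUA", 3, "G", "A") # "ACAUA"
apply_variant_to_mature <- function(mature_seq, mature_position, ref_rna, alt_rna) {
  stopifnot(length(mature_seq) == 1L)
  if (nchar(ref_rna) != nchar(alt_rna)) {
    abort("only length-preserving substitutions can be applied to a mature sequence")
  }
  lo <- mature_position
  hi <- mature_position + nchar(ref_rna) - 1L
  if (lo < 1L || hi > nchar(mature_seq)) {
    abort(sprintf("substitution span %d-%d outside mature sequence (length %d)",
                  lo, hi, nchar(mature_seq)))
  }
  found <- substr(mature_seq, lo, hi)
  if (found != ref_rna) {
    abort(sprintf("reference allele mismatch at mature position %d: expected %s, sequence has %s",
                  mature_position, ref_rna, found))
  }
  paste0(substr(mature_seq, 1L, lo - 1L), alt_rna,
         substr(mature_seq, hi + 1L, nchar(mature_seq)))
}

#' Screen seed variants for seed-switch events
#'
#' For every annotated seed variant (SNV, MNP, or merged DNP run), the mutant
#' mature sequence is computed, its 6mer and 7mer seeds extracted, and each
#' looked up among the wild-type seeds of all annotated matures. A hit is
#' emitted when the mutant seed exactly equals the seed of a *different*
#' mature; self-matches are suppressed. Membership is k-specific: a variant
#' at mature position 8 leaves the 6mer seed unchanged and can only produce
#' 7mer switches.
#'
#' @param annotated tibble from [annotate_variants()] (optionally after
#'   [merge_dnps()]; derived merged rows are screened too, their members are
#'   not double-counted as separate MNPs).
#' @param mirna hairpin tibble with sequences, used both for mature
#'   sequences and to build the k = 6 and k = 7 seed indexes.
#' @return tibble with columns `variant, source_mature, source_hairpin, k,
#'   wildtype_seed, mutant_seed, matched_mature, matched_hairpin`, one row
#'   per matched mature, deterministically ordered.
#' @export
find_seed_switches <- function(annotated, mirna) {
  index <- list(`6` = build_seed_index(mirna, 6L), `7` = build_seed_index(mirna, 7L))
  mt <- mature_sequences(mirna)
  seqs <- setNames(mt$sequence, mt$mature)

  cand <- annotated %>%
    filter(.data$region == "seed",
           .data$vclass %in% c("snv", "mnp", "dnp", "mnp_run"),
           !is.na(.data$mature))
  # when merged runs are present, screen the merged record, not its members
  if (any(cand$derived)) {
    cand <- cand %>% filter(is.na(.data$dnp_group) | .data$derived)
  }
  out <- list()
  for (i in seq_len(nrow(cand))) {
    v <- cand[i, ]
    wt <- seqs[[v$mature]]
    if (is.null(wt) || is.na(wt)) next
    mut <- apply_variant_to_mature(wt, v$mature_position, v$ref_rna, v$alt_rna)
    for (k in c(6L, 7L)) {
      member <- if (k == 6L) v$seed6_member else v$seed7_member
      if (!isTRUE(member) || nchar(wt) < k + 1L) next
      wt_seed <- extract_seed(wt, k)
      mut_seed <- extract_seed(mut, k)
      if (mut_seed == wt_seed) next
      idx <- index[[as.character(k)]]
      hits <- idx[idx$seed == mut_seed & idx$mature != v$mature, , drop = FALSE]
      if (nrow(hits) == 0) next
      out[[length(out) + 1L]] <- tibble(
        variant = v$id, source_mature = v$mature, source_hairpin = v$hairpin,
        k = k, wildtype_seed = wt_seed, mutant_seed = mut_seed,
        matched_mature = hits$mature, matched_hairpin = hits$hairpin
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(variant = character(), source_mature = character(),
                  source_hairpin = character(), k = integer(),
                  wildtype_seed = character(), mutant_seed = character(),
                  matched_mature = character(), matched_hairpin = character()))
  }
  bind_rows(out) %>%
    arrange(.data$variant, .data$source_mature, .data$k, .data$matched_mature)
}
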