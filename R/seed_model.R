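# Coordinate arithmetic between genome, hairpin and mature miRNA frames.
#
# Conventions used throughout the package:
#   * genomic coordinates are 1-based inclusive (GFF3/VCF native);
#   * hairpin sequences are stored 5'->3' in transcript orientation, in the
#     RNA alphabet, so sequence operations never need to know the strand;
#   * a mature miRNA is located inside its hairpin by `offset` (1-based start
#     within the hairpin sequence) and `length`.

RNA_BASES <- c("A", "C", "G", "U")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases and converts T to U. Characters outside `A C G U T N`
#' (case-insensitive) are an error.
#'
#' @param x character vector of nucleotide strings (DNA or RNA).
#' @return character vector in the `A C G U N` alphabet.
#' @export
#' @examples
#' as_rna("acgt") # "ACGU"
as_rna <- function(x) {
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    abort(sprintf(
      "sequence contains characters outside {A,C,G,U,T,N}: %s",
      paste(utils::head(x[bad], 3L), collapse = ", ")
    ))
  }
  out
}

#' Complement / reverse-complement RNA strings
#'
#' @param x character vector of RNA strings (`A C G U N`).
#' @return character vector of the same length.
#' @export
complement_rna <- function(x) chartr("ACGUN", "UGCAN", x)

#' @rdname complement_rna
#' @export
revcomp_rna <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

#' Flatten a miRNA table to one row per mature miRNA
#'
#' The package represents a set of miRNA genes as a tibble with one hairpin
#' per row and a nested `matures` list-column (see [read_mirna_gff()]).
#' `mature_table()` unnests it to one row per mature, carrying the hairpin
#' coordinates, strand and (if present) sequence alongside.
#'
#' @param mirna hairpin tibble with columns `name, chrom, start, end, strand`,
#'   optionally `sequence`, and a `matures` list-column of tibbles with
#'   columns `name, start, end, offset, length`.
#' @return tibble with columns `hairpin, chrom, strand, hairpin_start,
#'   hairpin_end, hairpin_sequence, mature, start, end, offset, length`.
#' @export
mature_table <- function(mirna) {
  stopifnot(is.data.frame(mirna))
  if (nrow(mirna) == 0) {
    return(tibble(
      hairpin = character(), chrom = character(), strand = character(),
      hairpin_start = integer(), hairpin_end = integer(),
      hairpin_sequence = character(), mature = character(),
      start = integer(), end = integer(), offset = integer(), length = integer()
    ))
  }
  hp <- mirna %>%
    select(
      hairpin = "name", "chrom", "strand",
      hairpin_start = "start", hairpin_end = "end",
      hairpin_sequence = dplyr::any_of("sequence"), "matures"
    )
  if (!"hairpin_sequence" %in% names(hp)) hp$hairpin_sequence <- NA_character_
  out <- tidyr::unnest(hp, "matures", names_sep = NULL)
  rename(out, mature = "name")
}

#' Extract mature miRNA sequences from their hairpins
#'
#' @inheritParams mature_table
#' @return the [mature_table()] tibble with a `sequence` column holding each
#'   mature sequence 5'->3' (transcript orientation, RNA alphabet).
#' @export
mature_sequences <- function(mirna) {
  mt <- mature_table(mirna)
  mt$sequence <- substr(mt$hairpin_sequence, mt$offset, mt$offset + mt$length - 1L)
  mt$sequence[is.na(mt$hairpin_sequence)] <- NA_character_
  mt
}

#' Map genomic positions into mature-miRNA coordinates (and back)
#'
#' `genome_to_mature_pos()` converts a genomic position to the 1-based
#' position within a mature miRNA read 5'->3'; on the minus strand position 1
#' is the genomic *end* of the mature. Positions outside the mature span map
#' to `NA`. `mature_to_genome_pos()` is the inverse.
#'
#' @param gpos,mpos integer vectors of genomic / mature positions.
#' @param m_start,m_end integer vectors: genomic span of the mature (1-based
#'   inclusive).
#' @param strand character vector, `"+"` or `"-"`.
#' @return integer vector, `NA` where the input falls outside the mature.
#' @export
#' @examples
#' genome_to_mature_pos(1010, 1010, 1030, "+") # 1
#' genome_to_mature_pos(1030, 1010, 1030, "-") # 1
genome_to_mature_pos <- function(gpos, m_start, m_end, strand) {
  n <- max(length(gpos), length(m_start), length(m_end), length(strand))
  gpos <- rep_len(gpos, n); m_start <- rep_len(m_start, n)
  m_end <- rep_len(m_end, n); strand <- rep_len(strand, n)
  pos <- ifelse(strand == "+", gpos - m_start + 1L, m_end - gpos + 1L)
  pos[gpos < m_start | gpos > m_end] <- NA_integer_
  as.integer(pos)
}

#' @rdname genome_to_mature_pos
#' @export
mature_to_genome_pos <- function(mpos, m_start, m_end, strand) {
  n <- max(length(mpos), length(m_start), length(m_end), length(strand))
  mpos <- rep_len(mpos, n); m_start <- rep_len(m_start, n)
  m_end <- rep_len(m_end, n); strand <- rep_len(strand, n)
  gpos <- ifelse(strand == "+", m_start + mpos - 1L, m_end - mpos + 1L)
  gpos[mpos < 1L | mpos > (m_end - m_start + 1L)] <- NA_integer_
  as.integer(gpos)
}

#' Extract the seed from a mature miRNA sequence
#'
#' The seed region is nucleotides 2..7 (`k = 6`, the minimal 6mer match) or
#' 2..8 (`k = 7`) counted from the 5' end of the mature miRNA; position 1 is
#' never part of the seed.
#'
#' @param mature_seq character vector of mature sequences (5'->3', RNA).
#' @param k seed length, 6 or 7.
#' @return character vector of seed sequences of length `k`.
#' @export
#' @examples
#' extract_seed("UAAGGCACGCGGU", k = 6) # "AAGGCA"
extract_seed <- function(mature_seq, k = 7) {
  stopifnot(length(k) == 1L, k %in% c(6L, 7L))
  short <- nchar(mature_seq) < k + 1L
  if (any(short)) {
    abort(sprintf(
      "mature sequence shorter than %d nt, cannot take seed positions 2-%d: %s",
      k + 1L, k + 1L, paste(utils::head(mature_seq[short], 3L), collapse = ", ")
    ))
  }
  substr(mature_seq, 2L, k + 1L)
}

#' Seed regions of every mature miRNA, with genomic coordinates
#'
#' For each mature of length >= `k + 1` returns the seed sequence and the
#' genomic interval it occupies, obtained by mapping mature positions
#' `2..k+1` back to the genome (on the minus strand the genomic interval is
#' the reverse-complement image of those positions).
#'
#' @inheritParams mature_table
#' @param k seed length, 6 or 7.
#' @return tibble with columns `hairpin, mature, chrom, strand, k,
#'   seed_sequence, seed_start, seed_end` (genomic, 1-based inclusive).
#' @export
seed_regions <- function(mirna, k = 7) {
  stopifnot(length(k) == 1L, k %in% c(6L, 7L))
  mt <- mature_sequences(mirna)
  mt <- mt[mt$length >= k + 1L, , drop = FALSE]
  if (nrow(mt) == 0) {
    return(tibble(
      hairpin = character(), mature = character(), chrom = character(),
      strand = character(), k = integer(), seed_sequence = character(),
      seed_start = integer(), seed_end = integer()
    ))
  }
  g1 <- mature_to_genome_pos(2L, mt$start, mt$end, mt$strand)
  g2 <- mature_to_genome_pos(k + 1L, mt$start, mt$end, mt$strand)
  seed_seq <- extract_seed(mt$sequence, k)
  tibble(
    hairpin = mt$hairpin, mature = mt$mature, chrom = mt$chrom,
    strand = mt$strand, k = as.integer(k),
    seed_sequence = seed_seq,
    seed_start = pmin(g1, g2), seed_end = pmax(g1, g2)
  )
}
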