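# Readers and writers for the external formats the toolkit touches.
#
# Internal coordinates are 1-based inclusive everywhere (the GFF3/VCF
# convention); BED's 0-based half-open intervals are converted at this
# boundary and nowhere else. Sequences are normalized to the RNA alphabet on
# the way in; VCF alleles are kept as given (DNA, + strand) for provenance
# and converted to transcript orientation during annotation.

HAIRPIN_TYPES <- c("miRNA_primary_transcript", "pre_miRNA")
MATURE_TYPE <- "miRNA"

.first_or_na <- function(x) {
  vapply(x, function(p) if (length(p) >= 1L) as.character(p)[[1L]] else NA_character_,
         character(1))
}

#' Read a miRBase-style miRNA GFF3 annotation
#'
#' Expects hairpin records (`miRNA_primary_transcript` or `pre_miRNA`) with
#' child mature records (`miRNA`) referencing their hairpin through a
#' `Derives_from` or `Parent` attribute. Names follow the miRBase case
#' convention: precursors "mir", matures "miR".
#'
#' @param path GFF3 file.
#' @param fasta optional hairpin FASTA ([read_hairpin_fasta()]); sequences
#'   are paired by hairpin name and their length checked against the
#'   annotated span.
#' @return tibble with one hairpin per row: `name, chrom, start, end, strand,
#'   sequence` (NA unless `fasta` given), a `matures` list-column of tibbles
#'   (`name, start, end, offset, length`), and a `meta` list-column holding
#'   any extra GFF3 attributes verbatim.
#' @export
read_mirna_gff <- function(path, fasta = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  df$seqnames <- as.character(df$seqnames)
  if (!"ID" %in% names(df)) df$ID <- NA_character_
  if (!"Name" %in% names(df)) df$Name <- df$ID
  df$Name <- ifelse(is.na(df$Name), df$ID, df$Name)
  parent <- rep(NA_character_, nrow(df))
  if ("Derives_from" %in% names(df)) parent <- .first_or_na(df$Derives_from)
  if ("Parent" %in% names(df)) {
    p2 <- .first_or_na(df$Parent)
    parent <- ifelse(is.na(parent), p2, parent)
  }
  df$parent_id <- parent

  known <- c("seqnames", "start", "end", "width", "strand", "source", "type",
             "score", "phase", "ID", "Name", "Parent", "Derives_from", "parent_id")
  extra_cols <- setdiff(names(df), known)
  df$meta <- lapply(seq_len(nrow(df)), function(i) {
    m <- as.list(df[i, extra_cols, drop = FALSE])
    m[!vapply(m, function(v) all(is.na(unlist(v))), logical(1))]
  })

  hp <- df[df$type %in% HAIRPIN_TYPES, , drop = FALSE]
  mat <- df[df$type == MATURE_TYPE, , drop = FALSE]
  if (nrow(mat) > 0 && anyNA(mat$parent_id)) {
    abort(sprintf("orphan mature record(s) without Derives_from/Parent: %s",
                  paste(mat$Name[is.na(mat$parent_id)], collapse = ", ")))
  }
  unknown <- setdiff(mat$parent_id, hp$ID)
  if (length(unknown) > 0) {
    abort(sprintf("mature record(s) reference unknown hairpin(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  # mature span must lie within its hairpin span, same chromosome and strand
  idx <- match(mat$parent_id, hp$ID)
  bad <- mat$start < hp$start[idx] | mat$end > hp$end[idx] |
    mat$seqnames != hp$seqnames[idx] | mat$strand != hp$strand[idx]
  if (any(bad)) {
    abort(sprintf("mature record(s) extend outside their hairpin span: %s",
                  paste(mat$Name[bad], collapse = ", ")))
  }

  matures <- lapply(seq_len(nrow(hp)), function(i) {
    mm <- mat[which(mat$parent_id == hp$ID[i]), , drop = FALSE]
    offset <- if (hp$strand[i] == "-") hp$end[i] - mm$end + 1L else mm$start - hp$start[i] + 1L
    out <- tibble(
      name = mm$Name, start = as.integer(mm$start), end = as.integer(mm$end),
      offset = as.integer(offset), length = as.integer(mm$end - mm$start + 1L),
      meta = mm$meta
    )
    arrange(out, .data$offset, .data$name)
  })

  out <- tibble(
    name = hp$Name, chrom = hp$seqnames,
    start = as.integer(hp$start), end = as.integer(hp$end),
    strand = hp$strand, sequence = NA_character_,
    matures = matures, meta = hp$meta
  )
  out <- arrange(out, .data$chrom, .data$start, .data$name)
  if (!is.null(fasta)) out <- attach_hairpin_sequences(out, fasta)
  out
}

#' Attach hairpin sequences to a miRNA annotation table
#'
#' @param mirna hairpin tibble from [read_mirna_gff()].
#' @param fasta path to a hairpin FASTA file, or the tibble returned by
#'   [read_hairpin_fasta()].
#' @return `mirna` with the `sequence` column filled. A sequence whose length
#'   disagrees with the annotated hairpin span is an error naming the
#'   hairpin.
#' @export
attach_hairpin_sequences <- function(mirna, fasta) {
  seqs <- if (is.character(fasta)) read_hairpin_fasta(fasta) else fasta
  idx <- match(mirna$name, seqs$name)
  seq <- seqs$sequence[idx]
  have <- !is.na(seq)
  bad <- have & nchar(seq) != (mirna$end - mirna$start + 1L)
  if (any(bad)) {
    abort(sprintf(
      "hairpin sequence length disagrees with annotated span for: %s",
      paste(mirna$name[bad], collapse = ", ")
    ))
  }
  mirna$sequence <- seq
  mirna
}

#' Write a miRNA annotation table as miRBase-style GFF3
#'
#' Emits one `miRNA_primary_transcript` record per hairpin followed by its
#' `miRNA` children (linked via `Derives_from`).
#'
#' @inheritParams mature_table
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mirna_gff <- function(mirna, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(mirna))) {
    h <- mirna[i, ]
    lines <- c(lines, paste(
      h$chrom, "seedvar", "miRNA_primary_transcript", h$start, h$end, ".",
      h$strand, ".", sprintf("ID=%s;Name=%s", h$name, h$name), sep = "\t"
    ))
    mm <- h$matures[[1]]
    for (j in seq_len(nrow(mm))) {
      lines <- c(lines, paste(
        h$chrom, "seedvar", "miRNA", mm$start[j], mm$end[j], ".",
        h$strand, ".",
        sprintf("ID=%s;Name=%s;Derives_from=%s", mm$name[j], mm$name[j], h$name),
        sep = "\t"
      ))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read hairpin sequences from FASTA
#'
#' Sequences may use T or U and any case; they are normalized to the
#' upper-case RNA alphabet. Characters outside `A C G U T N` are an error.
#'
#' @param path FASTA file.
#' @return tibble with columns `name` (first whitespace-delimited token of
#'   the header) and `sequence` (RNA alphabet).
#' @export
read_hairpin_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  tibble(name = nm, sequence = unname(as_rna(as.character(ss))))
}

#' Write hairpin sequences to FASTA
#'
#' @param seqs tibble with columns `name` and `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hairpin_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Classify a REF/ALT allele pair
#'
#' @param ref,alt character vectors of alleles.
#' @return `"snv"` (both length 1), `"mnp"` (equal lengths > 1),
#'   `"insertion"` or `"deletion"`.
#' @export
variant_class <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "snv",
    nchar(ref) == nchar(alt) ~ "mnp",
    nchar(ref) > nchar(alt) ~ "deletion",
    TRUE ~ "insertion"
  )
}

#' Read variants from a VCF file
#'
#' Multiallelic records are expanded to one row per ALT allele. Positions
#' stay 1-based; alleles stay on the + strand as given. Records with a
#' malformed position or allele string are skipped with a message naming the
#' record number.
#'
#' @param path VCF 4.x file.
#' @return tibble with columns `id, chrom, pos, ref, alt, vclass`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCF drops to a vector
  fx <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0) {
    return(tibble(id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), vclass = character()))
  }
  pos <- suppressWarnings(as.integer(fx$POS))
  allele_ok <- function(a) grepl("^[ACGTNacgtn]+$", a)
  bad <- is.na(pos) | is.na(fx$REF) | !allele_ok(fx$REF) |
    is.na(fx$ALT) | fx$ALT == "."
  if (any(bad)) {
    inform(sprintf("read_vcf: skipped %d malformed/monomorphic record(s): %s",
                   sum(bad), paste(which(bad), collapse = ", ")))
  }
  out <- tibble(
    id = fx$ID, chrom = fx$CHROM, pos = pos,
    ref = toupper(fx$REF), alt = toupper(fx$ALT)
  )[!bad, , drop = FALSE]
  out <- tidyr::separate_rows(out, "alt", sep = ",")
  bad_alt <- !allele_ok(out$alt)
  if (any(bad_alt)) {
    inform(sprintf("read_vcf: dropped %d malformed ALT allele(s)", sum(bad_alt)))
    out <- out[!bad_alt, , drop = FALSE]
  }
  out$id <- ifelse(is.na(out$id) | out$id == ".",
                   sprintf("%s:%d_%s>%s", out$chrom, out$pos, out$ref, out$alt),
                   out$id)
  out$vclass <- variant_class(out$ref, out$alt)
  arrange(out, .data$chrom, .data$pos, .data$id, .data$alt)
}

#' Read genomic features (QTL, fragile sites) from BED
#'
#' BED's 0-based half-open coordinates are converted to the internal 1-based
#' inclusive convention (`start + 1`, `end`). Lines with `start >= end` are
#' rejected with a message.
#'
#' @param path BED3/BED4 file.
#' @param kind feature kind label, e.g. `"qtl"` or `"fragile_site"`.
#' @return tibble with columns `name, kind, chrom, start, end, strand`
#'   (strand `"*"`: QTL and fragile sites carry no strand semantics).
#' @export
read_features_bed <- function(path, kind = "qtl") {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) {
    return(tibble(name = character(), kind = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  start0 <- suppressWarnings(as.integer(df$X2))
  end0 <- suppressWarnings(as.integer(df$X3))
  bad <- is.na(start0) | is.na(end0) | start0 >= end0
  if (any(bad)) {
    inform(sprintf("read_features_bed: rejected %d line(s) with start >= end or malformed coordinates",
                   sum(bad)))
  }
  name <- if ("X4" %in% names(df)) df$X4 else NA_character_
  out <- tibble(
    name = name, kind = kind, chrom = df$X1,
    start = start0 + 1L, end = end0, strand = "*"
  )[!bad, , drop = FALSE]
  out$name <- ifelse(is.na(out$name),
                     sprintf("%s:%d-%d", out$chrom, out$start, out$end), out$name)
  arrange(out, .data$chrom, .data$start, .data$name)
}

#' Write genomic features to BED (inverse of [read_features_bed()])
#'
#' @param features tibble with `chrom, start, end, name` (internal 1-based
#'   inclusive coordinates).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_bed <- function(features, path) {
  readr::write_tsv(
    tibble(chrom = features$chrom, start = features$start - 1L,
           end = features$end, name = features$name),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read host-gene models (gene + exon records) from GFF3
#'
#' @param path GFF3 file with `gene` and `exon` features; exons reference
#'   their gene via `Parent`.
#' @return tibble with columns `name, kind` (`"gene"`/`"exon"`), `parent`
#'   (gene name, NA for genes), `chrom, start, end, strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  if (!"ID" %in% names(df)) df$ID <- NA_character_
  if (!"Name" %in% names(df)) df$Name <- df$ID
  df$Name <- ifelse(is.na(df$Name), df$ID, df$Name)
  parent <- if ("Parent" %in% names(df)) .first_or_na(df$Parent) else NA_character_
  keep <- df$type %in% c("gene", "exon")
  out <- tibble(
    name = df$Name[keep], kind = df$type[keep], parent = parent[keep],
    chrom = as.character(df$seqnames)[keep],
    start = as.integer(df$start)[keep], end = as.integer(df$end)[keep],
    strand = as.character(df$strand)[keep]
  )
  # exons must carry a parent gene
  orphan <- out$kind == "exon" & is.na(out$parent)
  if (any(orphan)) {
    abort(sprintf("exon record(s) without Parent gene: %s",
                  paste(out$name[orphan], collapse = ", ")))
  }
  arrange(out, .data$chrom, .data$start, .data$kind, .data$name)
}

#' Write host-gene models as GFF3 (inverse of [read_gene_models()])
#'
#' @param genes tibble as returned by [read_gene_models()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- "##gff-version 3"
  gg <- genes[genes$kind == "gene", , drop = FALSE]
  ee <- genes[genes$kind == "exon", , drop = FALSE]
  for (i in seq_len(nrow(gg))) {
    g <- gg[i, ]
    lines <- c(lines, paste(g$chrom, "seedvar", "gene", g$start, g$end, ".",
                            g$strand, ".", sprintf("ID=%s;Name=%s", g$name, g$name),
                            sep = "\t"))
    ex <- ee[ee$parent == g$name, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(ex$chrom[j], "seedvar", "exon", ex$start[j],
                              ex$end[j], ".", ex$strand[j], ".",
                              sprintf("ID=%s;Name=%s;Parent=%s",
                                      ex$name[j], ex$name[j], g$name),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a strain phenotype table
#'
#' @param path delimited file (TSV) with columns `strain, sex, genotype,
#'   trait, group, value`.
#' @return tibble with those columns; rows with non-finite values are dropped
#'   with a message.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("strain", "sex", "genotype", "trait", "group", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("phenotype table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  df$value <- as.numeric(df$value)
  bad <- !is.finite(df$value)
  if (any(bad)) {
    inform(sprintf("read_phenotypes: dropped %d row(s) with non-finite values", sum(bad)))
  }
  as_tibble(df[!bad, need, drop = FALSE])
}

CATALOG_COLS <- c(
  "id", "chrom", "pos", "ref", "alt", "vclass", "hairpin", "strand",
  "mature", "region",
  "mature_position", "seed6_member", "seed7_member", "substitution",
  "ref_rna", "alt_rna", "ref_mismatch", "dnp_group", "run_length", "derived"
)

#' Write an annotated-variant catalog as TSV
#'
#' One row per (variant, mature) annotation pair, sorted stably by
#' chromosome, position, hairpin, mature and variant id. Both granularities
#' of multi-nucleotide events are present: the per-SNV member rows and the
#' derived merged row per run (`derived = TRUE`), so consumers can count
#' either way.
#'
#' @param annotated tibble from [annotate_variants()] / [merge_dnps()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(annotated, path) {
  for (cc in setdiff(CATALOG_COLS, names(annotated))) {
    annotated[[cc]] <- switch(cc,
      mature_position = NA_integer_, run_length = NA_integer_,
      seed6_member = NA, seed7_member = NA, ref_mismatch = NA, derived = FALSE,
      NA_character_
    )
  }
  out <- annotated %>%
    select(all_of(CATALOG_COLS)) %>%
    arrange(.data$chrom, .data$pos, .data$hairpin, .data$mature, .data$id, .data$alt)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a catalog written by [write_catalog()]
#'
#' @param path TSV file.
#' @return tibble with the catalog columns, typed as written.
#' @export
read_catalog <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    pos = readr::col_integer(),
                    mature_position = readr::col_integer(),
                    run_length = readr::col_integer(),
                    seed6_member = readr::col_logical(),
                    seed7_member = readr::col_logical(),
                    ref_mismatch = readr::col_logical(),
                    derived = readr::col_logical(),
                    .default = readr::col_character()
                  ))
}
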