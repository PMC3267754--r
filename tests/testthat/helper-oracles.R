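# Independent brute-force oracles. These are deliberately written with plain
# loops, explicit truth tables and per-base walks, sharing no code with the
# package internals they check.

ORACLE_COMP <- c(A = "U", C = "G", G = "C", U = "A")

oracle_rna1 <- function(b) {
  b <- toupper(b)
  if (b == "T") "U" else b
}

# full 12-pair transition/transversion truth table, written out by hand
ORACLE_TITV <- c(
  "A>G" = "transition", "G>A" = "transition",
  "C>U" = "transition", "U>C" = "transition",
  "A>C" = "transversion", "C>A" = "transversion",
  "A>U" = "transversion", "U>A" = "transversion",
  "G>C" = "transversion", "C>G" = "transversion",
  "G>U" = "transversion", "U>G" = "transversion"
)

# affected reference bases of a variant, re-derived from first principles
oracle_affected <- function(pos, ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1 && la == 1) return(pos)
  if (lr == la) return(pos:(pos + lr - 1))
  if (lr > la) { # deletion; skip the shared anchor base if present
    if (substr(ref, 1, 1) == substr(alt, 1, 1)) return((pos + 1):(pos + lr - 1))
    return(pos:(pos + lr - 1))
  }
  c(pos, pos + 1) # insertion: the two flanking reference bases
}

# Per-base brute-force classifier: walks every mature of every hairpin base
# by base from its 5' end and records, for each variant, every
# (hairpin, mature) assignment with region, 5'-most mature position and
# (for SNVs) the transition/transversion class of the transcript-oriented
# substitution.
oracle_annotate <- function(variants, mirna) {
  # plain vectors, to keep the brute-force loops cheap
  h_name <- mirna$name; h_chrom <- mirna$chrom
  h_start <- mirna$start; h_end <- mirna$end; h_strand <- mirna$strand
  h_mats <- lapply(mirna$matures, function(mm) {
    list(name = mm$name, start = mm$start, end = mm$end)
  })
  v_id <- variants$id; v_chrom <- variants$chrom
  v_pos <- variants$pos; v_ref <- variants$ref; v_alt <- variants$alt

  rows <- vector("list", 4 * length(v_id))
  nr <- 0
  for (vi in seq_along(v_id)) {
    bases <- oracle_affected(v_pos[vi], v_ref[vi], v_alt[vi])
    is_snv <- nchar(v_ref[vi]) == 1 && nchar(v_alt[vi]) == 1
    for (hi in seq_along(h_name)) {
      if (h_chrom[hi] != v_chrom[vi]) next
      inside <- bases[bases >= h_start[hi] & bases <= h_end[hi]]
      if (length(inside) == 0) next
      titv <- NA_character_
      if (is_snv) {
        r <- oracle_rna1(v_ref[vi]); a <- oracle_rna1(v_alt[vi])
        if (h_strand[hi] == "-") { r <- ORACLE_COMP[[r]]; a <- ORACLE_COMP[[a]] }
        titv <- ORACLE_TITV[[paste0(r, ">", a)]]
      }
      mm <- h_mats[[hi]]
      hit_mature <- FALSE
      for (mi in seq_along(mm$name)) {
        # walk the mature base by base from its 5' end
        walk <- if (h_strand[hi] == "+") seq(mm$start[mi], mm$end[mi]) else
          seq(mm$end[mi], mm$start[mi])
        mpos <- match(inside, walk)
        mpos <- mpos[!is.na(mpos)]
        if (length(mpos) == 0) next
        hit_mature <- TRUE
        nr <- nr + 1
        rows[[nr]] <- list(
          id = v_id[vi], hairpin = h_name[hi], mature = mm$name[mi],
          region = if (any(mpos >= 2 & mpos <= 8)) "seed" else "mature_nonseed",
          mature_position = min(mpos), substitution = titv,
          seed6_member = any(mpos >= 2 & mpos <= 7),
          seed7_member = any(mpos >= 2 & mpos <= 8)
        )
      }
      if (!hit_mature) {
        nr <- nr + 1
        rows[[nr]] <- list(
          id = v_id[vi], hairpin = h_name[hi], mature = NA_character_,
          region = "precursor", mature_position = NA_integer_,
          substitution = titv, seed6_member = FALSE, seed7_member = FALSE
        )
      }
    }
  }
  rows <- rows[seq_len(nr)]
  if (nr == 0) {
    return(tibble::tibble(id = character(), hairpin = character(),
                          mature = character(), region = character(),
                          mature_position = integer(),
                          substitution = character(),
                          seed6_member = logical(), seed7_member = logical()))
  }
  pick <- function(f, mode) vapply(rows, `[[`, vector(mode, 1), f)
  out <- tibble::tibble(
    id = pick("id", "character"), hairpin = pick("hairpin", "character"),
    mature = pick("mature", "character"), region = pick("region", "character"),
    mature_position = pick("mature_position", "integer"),
    substitution = pick("substitution", "character"),
    seed6_member = pick("seed6_member", "logical"),
    seed7_member = pick("seed7_member", "logical")
  )
  dplyr::arrange(out, id, hairpin, mature)
}

# quadratic double-loop interval intersection on closed 1-based intervals
oracle_overlap <- function(mirna, features) {
  out <- list()
  for (i in seq_len(nrow(mirna))) {
    for (j in seq_len(nrow(features))) {
      if (mirna$chrom[i] == features$chrom[j] &&
          mirna$start[i] <= features$end[j] &&
          features$start[j] <= mirna$end[i]) {
        out[[length(out) + 1]] <- tibble::tibble(
          mirna = mirna$name[i], feature = features$name[j],
          kind = features$kind[j]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(mirna = character(), feature = character(),
                          kind = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), mirna, kind, feature)
}

# per-base membership host-gene context
oracle_host_context <- function(mirna, genes) {
  gene_rows <- genes[genes$kind == "gene", ]
  out <- list()
  for (i in seq_len(nrow(mirna))) {
    h <- mirna[i, ]
    for (j in seq_len(nrow(gene_rows))) {
      g <- gene_rows[j, ]
      if (h$chrom != g$chrom || h$start > g$end || g$start > h$end) next
      ex <- genes[genes$kind == "exon" & !is.na(genes$parent) &
                    genes$parent == g$name, ]
      in_exon <- vapply(seq(h$start, h$end), function(p) {
        any(p >= ex$start & p <= ex$end)
      }, logical(1))
      ctx <- if (all(in_exon)) "exonic" else if (!any(in_exon)) "intronic"
             else "exon_and_intron"
      orient <- if (g$strand %in% c("*", ".")) "unstranded"
                else if (g$strand == h$strand) "sense" else "antisense"
      out[[length(out) + 1]] <- tibble::tibble(
        mirna = h$name, feature = g$name, orientation = orient, context = ctx
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(mirna = character(), feature = character(),
                          orientation = character(), context = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), mirna, feature)
}

# Mirror a fixture: reverse-complement every chromosome and flip all strands.
# Hairpin/mature sequences are stored in transcript orientation, so they must
# come out unchanged; SNV alleles (+ strand) complement and positions mirror.
mirror_fixture <- function(fx) {
  L <- nchar(fx$genome[[1]])
  stopifnot(all(nchar(fx$genome) == L))
  mir <- fx$mirna
  new_matures <- purrr::map2(mir$matures, seq_len(nrow(mir)), function(mm, i) {
    out <- mm
    out$start <- L - mm$end + 1L
    out$end <- L - mm$start + 1L
    out[order(out$offset), ]
  })
  mir2 <- mir
  mir2$start <- L - mir$end + 1L
  mir2$end <- L - mir$start + 1L
  mir2$strand <- ifelse(mir$strand == "+", "-", "+")
  mir2$matures <- new_matures
  v <- fx$variants
  stopifnot(all(v$vclass == "snv"))
  comp_dna <- c(A = "T", C = "G", G = "C", T = "A")
  v2 <- v
  v2$pos <- L - v$pos + 1L
  v2$ref <- unname(comp_dna[v$ref])
  v2$alt <- unname(comp_dna[v$alt])
  list(mirna = mir2, variants = v2, L = L)
}
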