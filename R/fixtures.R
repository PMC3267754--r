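# Deterministic synthetic fixtures: a toy genome with miRNA hairpins on both
# strands, planted variants of every region class, planted DNP runs, planted
# seed-switch pairs, QTL/fragile-site intervals, host-gene models, and a
# strain-structured phenotype table -- all with machine-readable ground
# truth, so every pipeline step is testable without downloads.
#
# Fixture genomes are short (a few tens of kb per chromosome) and i.i.d.
# uniform over the four bases except for planted motifs. Accidental seed
# collisions among random 6mers are expected (4^6 = 4096 keys); they are
# detected post hoc by the generator's own string logic and recorded in the
# ground truth rather than forbidden, so the truth file stays truthful.

DNA_BASES <- c("A", "C", "G", "T")
.dna_comp <- function(x) chartr("ACGTN", "TGCAN", x)
.dna_revcomp <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(.dna_comp(s), "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}
.dna_transition <- function(ref, alt) {
  pur <- c("A", "G")
  if_else((ref %in% pur) == (alt %in% pur), "transition", "transversion")
}

MPD_GROUPS <- c("behavior", "blood-clinical chemistry", "blood-hematology",
                "body composition", "body weight size and growth", "bone",
                "immune system", "metabolism")

#' Specify a synthetic fixture
#'
#' Collects every knob of the fixture generator with defaults sized for
#' desk-scale tests. Counts of planted variants are per region class; the
#' phenotype design is a balanced two-genotype inbred panel with strain
#' nested in genotype and both sexes.
#'
#' @param seed random seed (the generator is fully deterministic given it).
#' @param n_chromosomes,n_mirnas,fraction_minus_strand genome layout.
#' @param n_seed_variants,n_mature_variants,n_precursor_variants,n_outside_variants
#'   planted SNVs per region class.
#' @param n_planted_dnps planted adjacent-SNV runs of length 2.
#' @param n_planted_mnp_runs planted runs of length 3.
#' @param n_planted_seed_switches planted donor/acceptor seed-switch pairs.
#' @param n_qtl,n_fragile_sites,n_host_genes feature counts.
#' @param strains_per_genotype,sexes,n_per_cell,n_null_traits,n_effect_traits,effect_size,noise_sd,sex_effect
#'   phenotype design: number of inbred strains per genotype level, sexes,
#'   observations per (strain, sex) cell, counts of null and genotype-
#'   affected traits, the planted genotype effect (trait units), residual
#'   noise SD, and a fixed sex effect.
#' @return a `seedvar_fixture_spec` list, validated.
#' @export
fixture_spec <- function(seed = 1L, n_chromosomes = 3L, n_mirnas = 30L,
                         fraction_minus_strand = 0.5,
                         n_seed_variants = 10L, n_mature_variants = 10L,
                         n_precursor_variants = 10L, n_outside_variants = 10L,
                         n_planted_dnps = 3L, n_planted_mnp_runs = 1L,
                         n_planted_seed_switches = 3L,
                         n_qtl = 20L, n_fragile_sites = 8L, n_host_genes = 6L,
                         strains_per_genotype = 7L, sexes = c("f", "m"),
                         n_per_cell = 5L, n_null_traits = 20L,
                         n_effect_traits = 5L, effect_size = 2,
                         noise_sd = 1, sex_effect = 0.5) {
  spec <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    n_mirnas = as.integer(n_mirnas),
    fraction_minus_strand = fraction_minus_strand,
    n_seed_variants = as.integer(n_seed_variants),
    n_mature_variants = as.integer(n_mature_variants),
    n_precursor_variants = as.integer(n_precursor_variants),
    n_outside_variants = as.integer(n_outside_variants),
    n_planted_dnps = as.integer(n_planted_dnps),
    n_planted_mnp_runs = as.integer(n_planted_mnp_runs),
    n_planted_seed_switches = as.integer(n_planted_seed_switches),
    n_qtl = as.integer(n_qtl), n_fragile_sites = as.integer(n_fragile_sites),
    n_host_genes = as.integer(n_host_genes),
    strains_per_genotype = as.integer(strains_per_genotype),
    sexes = sexes, n_per_cell = as.integer(n_per_cell),
    n_null_traits = as.integer(n_null_traits),
    n_effect_traits = as.integer(n_effect_traits),
    effect_size = effect_size, noise_sd = noise_sd, sex_effect = sex_effect
  )
  counts <- unlist(spec[grepl("^n_", names(spec))])
  if (any(counts < 0)) abort("fixture counts must be non-negative")
  if (spec$n_chromosomes < 1L) abort("need at least one chromosome")
  if (spec$fraction_minus_strand < 0 || spec$fraction_minus_strand > 1) {
    abort("fraction_minus_strand must be in [0, 1]")
  }
  if (spec$n_planted_seed_switches > floor(spec$n_mirnas / 2)) {
    abort("more planted seed switches than miRNA pairs available (need n_mirnas >= 2 per switch)")
  }
  if (spec$n_host_genes > spec$n_mirnas) {
    abort("more host genes than miRNAs to host")
  }
  structure(spec, class = "seedvar_fixture_spec")
}

# ---- internal helpers -------------------------------------------------------

.rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

.transcript_base <- function(genome, chrom, gpos, strand) {
  b <- substr(genome[[chrom]], gpos, gpos)
  if (strand == "-") .dna_comp(b) else b
}

.set_plus_base <- function(genome, chrom, gpos, base) {
  substr(genome[[chrom]], gpos, gpos) <- base
  genome
}

# genomic positions of mature positions `mpos` (vectorized)
.mat_g <- function(mpos, m_start, m_end, strand) {
  if (strand == "+") m_start + mpos - 1L else m_end - mpos + 1L
}

#' Generate a synthetic fixture with ground truth
#'
#' Builds the genome, places hairpins with nested matures on both strands,
#' plants seed-switch pairs (by copying a donor seed into an acceptor mature
#' up to one substitution, then emitting that substitution as the variant),
#' plants SNVs of every region class, DNP runs, QTL/fragile-site intervals,
#' host genes with controlled exonic context, and a phenotype table with a
#' known genotype effect. Writes all files to `outdir` and returns the
#' parsed objects plus the ground truth.
#'
#' All randomness flows from `spec$seed`; two runs of the same spec produce
#' byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with `spec`, `dir`, `paths` (named file paths),
#'   `genome` (named character vector of chromosome sequences), tibbles
#'   `mirna`, `variants`, `features`, `genes`, `phenotypes`, and `truth`
#'   (list of ground-truth tibbles: `variants`, `dnp_runs`, `seed_switches`,
#'   `overlaps`, `host_context`, `phenotypes`).
#' @export
generate_fixture <- function(spec = fixture_spec(), outdir = tempfile("fixture")) {
  stopifnot(inherits(spec, "seedvar_fixture_spec"))
  set.seed(spec$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # ---- genome layout --------------------------------------------------------
  slots_per_chrom <- ceiling(spec$n_mirnas / spec$n_chromosomes)
  chrom_len <- max(4000L, slots_per_chrom * 200L + 1000L)
  if (chrom_len > 100000L) abort("fixture spec needs chromosomes above 100 kb; reduce n_mirnas or add chromosomes")
  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  genome <- setNames(vapply(chroms, function(x) .rand_dna(chrom_len), character(1)),
                     chroms)

  # ---- hairpins with nested matures ----------------------------------------
  hp <- vector("list", spec$n_mirnas)
  chrom_slot <- setNames(rep(0L, length(chroms)), chroms)
  for (i in seq_len(spec$n_mirnas)) {
    chrom <- chroms[((i - 1L) %% spec$n_chromosomes) + 1L]
    chrom_slot[chrom] <- chrom_slot[chrom] + 1L
    slot_base <- (chrom_slot[chrom] - 1L) * 200L + 500L
    h_start <- slot_base + 40L + sample.int(11L, 1L) - 1L
    hlen <- sample(80:110, 1L)
    h_end <- h_start + hlen - 1L
    strand <- if (stats::runif(1) < spec$fraction_minus_strand) "-" else "+"
    off1 <- sample(9:14, 1L)
    len1 <- sample(20:23, 1L)
    n_mat <- 1L + stats::rbinom(1L, 1L, 0.7)
    mm <- tibble(name = sprintf("syn-miR-%d-5p", i), offset = off1, length = len1)
    if (n_mat == 2L) {
      len2 <- sample(20:23, 1L)
      tail_gap <- sample(4:9, 1L)
      off2 <- hlen - tail_gap - len2 + 1L
      if (off2 > off1 + len1) {
        mm <- bind_rows(mm, tibble(name = sprintf("syn-miR-%d-3p", i),
                                   offset = off2, length = len2))
      }
    }
    if (strand == "+") {
      mm$start <- h_start + mm$offset - 1L
      mm$end <- mm$start + mm$length - 1L
    } else {
      mm$end <- h_end - mm$offset + 1L
      mm$start <- mm$end - mm$length + 1L
    }
    hp[[i]] <- tibble(
      name = sprintf("syn-mir-%d", i), chrom = chrom,
      start = h_start, end = h_end, strand = strand,
      matures = list(mm[, c("name", "start", "end", "offset", "length")])
    )
  }
  mirna <- bind_rows(hp)

  # ---- plant seed-switch pairs (edits the genome) ---------------------------
  switch_truth <- list()
  switch_variants <- list()
  if (spec$n_planted_seed_switches > 0L) {
    picks <- sample.int(spec$n_mirnas, 2L * spec$n_planted_seed_switches)
    for (j in seq_len(spec$n_planted_seed_switches)) {
      di <- picks[2L * j - 1L]
      ai <- picks[2L * j]
      don <- mirna[di, ]
      acc <- mirna[ai, ]
      dm <- don$matures[[1]][1, ]
      am <- acc$matures[[1]][1, ]
      q <- sample(2:7, 1L)
      donor_bases <- vapply(2:8, function(p) {
        .transcript_base(genome, don$chrom,
                         .mat_g(p, dm$start, dm$end, don$strand), don$strand)
      }, character(1))
      target <- donor_bases
      target[q - 1L] <- sample(setdiff(DNA_BASES, donor_bases[q - 1L]), 1L)
      for (p in 2:8) {
        g <- .mat_g(p, am$start, am$end, acc$strand)
        plus <- if (acc$strand == "-") .dna_comp(target[p - 1L]) else target[p - 1L]
        genome <- .set_plus_base(genome, acc$chrom, g, plus)
      }
      g_q <- .mat_g(q, am$start, am$end, acc$strand)
      ref_plus <- if (acc$strand == "-") .dna_comp(target[q - 1L]) else target[q - 1L]
      alt_plus <- if (acc$strand == "-") .dna_comp(donor_bases[q - 1L]) else donor_bases[q - 1L]
      vid <- sprintf("sw_%d", j)
      switch_variants[[j]] <- tibble(
        id = vid, chrom = acc$chrom, pos = g_q, ref = ref_plus, alt = alt_plus,
        vclass = "snv", hairpin = acc$name, strand = acc$strand,
        mature = am$name, region = "seed", mature_position = q,
        seed6_member = TRUE, seed7_member = TRUE,
        substitution = .dna_transition(ref_plus, alt_plus),
        planted_switch = TRUE
      )
      switch_truth[[j]] <- tibble(
        variant = vid, source_mature = am$name,
        matched_mature = dm$name, k = c(6L, 7L), planted = TRUE
      )
    }
  }

  # ---- hairpin sequences (transcript orientation, RNA) ----------------------
  mirna$sequence <- vapply(seq_len(nrow(mirna)), function(i) {
    s <- substr(genome[[mirna$chrom[i]]], mirna$start[i], mirna$end[i])
    if (mirna$strand[i] == "-") s <- .dna_revcomp(s)
    as_rna(s)
  }, character(1))

  # ---- position class pools per hairpin -------------------------------------
  pools <- list(seed = list(), mature_nonseed = list(), precursor = list())
  for (i in seq_len(nrow(mirna))) {
    h <- mirna[i, ]
    mm <- h$matures[[1]]
    seed_rows <- mature_rows <- list()
    all_m_g <- integer()
    seed_g <- integer()
    for (j in seq_len(nrow(mm))) {
      m <- mm[j, ]
      mpos_all <- seq_len(m$length)
      g_all <- .mat_g(mpos_all, m$start, m$end, h$strand)
      all_m_g <- c(all_m_g, g_all)
      in_seed <- mpos_all >= 2L & mpos_all <= 8L
      seed_g <- c(seed_g, g_all[in_seed])
      rows <- tibble(chrom = h$chrom, pos = g_all, hairpin = h$name,
                     strand = h$strand, mature = m$name, mature_position = mpos_all)
      seed_rows[[j]] <- rows[in_seed, ]
      mature_rows[[j]] <- rows[!in_seed, ]
    }
    prec_g <- setdiff(seq(h$start, h$end), all_m_g)
    pools$seed[[i]] <- bind_rows(seed_rows)
    pools$mature_nonseed[[i]] <- bind_rows(mature_rows)
    pools$precursor[[i]] <- tibble(chrom = h$chrom, pos = prec_g,
                                   hairpin = h$name, strand = h$strand,
                                   mature = NA_character_,
                                   mature_position = NA_integer_)
  }
  pools <- lapply(pools, bind_rows)

  # positions blocked for new variants (planted variants +- 1 base, so no
  # accidental adjacency creates unplanted DNP runs)
  blocked <- new.env(parent = emptyenv())
  .block <- function(chrom, pos, margin = 1L) {
    for (p in (pos - margin):(pos + margin)) {
      assign(sprintf("%s:%d", chrom, p), TRUE, envir = blocked)
    }
  }
  .is_blocked <- function(chrom, pos) {
    exists(sprintf("%s:%d", chrom, pos), envir = blocked)
  }
  for (sv in switch_variants) .block(sv$chrom, sv$pos)

  .draw_from_pool <- function(pool, n_want, class_name) {
    if (n_want == 0L) return(pool[0, ])
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    taken <- list()
    for (r in seq_len(nrow(pool))) {
      if (length(taken) == n_want) break
      row <- pool[r, ]
      if (.is_blocked(row$chrom, row$pos)) next
      .block(row$chrom, row$pos)
      taken[[length(taken) + 1L]] <- row
    }
    if (length(taken) < n_want) {
      abort(sprintf("fixture spec infeasible: only %d free %s positions for %d variants",
                    length(taken), class_name, n_want))
    }
    bind_rows(taken)
  }

  .make_snvs <- function(rows, region, prefix) {
    if (nrow(rows) == 0) {
      return(tibble(id = character(), chrom = character(), pos = integer(),
                    ref = character(), alt = character(), vclass = character(),
                    hairpin = character(), strand = character(),
                    mature = character(), region = character(),
                    mature_position = integer(), seed6_member = logical(),
                    seed7_member = logical(), substitution = character(),
                    planted_switch = logical()))
    }
    ref <- vapply(seq_len(nrow(rows)), function(i)
      substr(genome[[rows$chrom[i]]], rows$pos[i], rows$pos[i]), character(1))
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1),
                  USE.NAMES = FALSE)
    tibble(
      id = sprintf("%s_%d", prefix, seq_len(nrow(rows))),
      chrom = rows$chrom, pos = rows$pos, ref = ref, alt = alt, vclass = "snv",
      hairpin = rows$hairpin, strand = rows$strand, mature = rows$mature,
      region = region, mature_position = rows$mature_position,
      seed6_member = !is.na(rows$mature_position) &
        rows$mature_position >= 2L & rows$mature_position <= 7L,
      seed7_member = !is.na(rows$mature_position) &
        rows$mature_position >= 2L & rows$mature_position <= 8L,
      substitution = .dna_transition(ref, alt), planted_switch = FALSE
    )
  }

  seed_v <- .make_snvs(.draw_from_pool(pools$seed, spec$n_seed_variants, "seed"),
                       "seed", "seedv")
  mat_v <- .make_snvs(.draw_from_pool(pools$mature_nonseed, spec$n_mature_variants,
                                      "mature"), "mature_nonseed", "matv")
  prec_v <- .make_snvs(.draw_from_pool(pools$precursor, spec$n_precursor_variants,
                                       "precursor"), "precursor", "precv")

  # outside variants: anywhere not overlapping a hairpin
  outside_rows <- list()
  if (spec$n_outside_variants > 0L) {
    tries <- 0L
    while (length(outside_rows) < spec$n_outside_variants) {
      tries <- tries + 1L
      if (tries > 50000L) abort("fixture spec infeasible: cannot place outside variants")
      chrom <- sample(chroms, 1L)
      pos <- sample.int(chrom_len, 1L)
      hs <- mirna[mirna$chrom == chrom, ]
      if (any(pos >= hs$start & pos <= hs$end)) next
      if (.is_blocked(chrom, pos)) next
      .block(chrom, pos, margin = 0L)
      outside_rows[[length(outside_rows) + 1L]] <-
        tibble(chrom = chrom, pos = pos, hairpin = NA_character_,
               strand = NA_character_, mature = NA_character_,
               mature_position = NA_integer_)
    }
  }
  out_v <- .make_snvs(bind_rows(outside_rows), "outside", "outv")

  # ---- planted DNP / MNP runs (precursor region) ----------------------------
  run_specs <- c(rep(2L, spec$n_planted_dnps), rep(3L, spec$n_planted_mnp_runs))
  dnp_members <- list()
  dnp_runs <- list()
  if (length(run_specs) > 0L) {
    prec_pool <- pools$precursor
    for (ri in seq_along(run_specs)) {
      len <- run_specs[ri]
      placed <- FALSE
      for (hpn in sample(unique(prec_pool$hairpin))) {
        cand <- prec_pool %>% filter(.data$hairpin == hpn) %>% arrange(.data$pos)
        ok_start <- cand$pos[vapply(cand$pos, function(p) {
          all((p:(p + len - 1L)) %in% cand$pos) &&
            !any(vapply((p - 1L):(p + len), .is_blocked,
                        logical(1), chrom = cand$chrom[1]))
        }, logical(1))]
        if (length(ok_start) == 0L) next
        p0 <- sample(ok_start, 1L)
        chrom <- cand$chrom[1]
        for (p in (p0 - 1L):(p0 + len)) .block(chrom, p, margin = 0L)
        h <- mirna[mirna$name == hpn, ]
        ids <- sprintf("dnp%d_%s", ri, letters[seq_len(len)])
        mem <- .make_snvs(tibble(chrom = chrom, pos = p0:(p0 + len - 1L),
                                 hairpin = hpn, strand = h$strand,
                                 mature = NA_character_,
                                 mature_position = NA_integer_),
                          "precursor", sprintf("dnp%d", ri))
        mem$id <- ids
        dnp_members[[ri]] <- mem
        dnp_runs[[ri]] <- tibble(
          dnp_group = sprintf("%s:%d", hpn, p0), hairpin = hpn,
          start_pos = p0, run_length = len,
          label = if (len == 2L) "dnp" else "mnp_run",
          member_ids = paste(ids, collapse = "+")
        )
        placed <- TRUE
        break
      }
      if (!placed) abort("fixture spec infeasible: cannot place a DNP run")
    }
  }

  truth_variants <- bind_rows(c(list(seed_v, mat_v, prec_v, out_v),
                                dnp_members, switch_variants)) %>%
    arrange(.data$chrom, .data$pos, .data$id)

  # ---- expected seed-switch hits (planted + accidental), generator-side ----
  mt_all <- mature_sequences(mirna)
  seed_tbl <- list(
    `6` = tibble(mature = mt_all$mature,
                 seed = substr(mt_all$sequence, 2L, 7L))[mt_all$length >= 7L, ],
    `7` = tibble(mature = mt_all$mature,
                 seed = substr(mt_all$sequence, 2L, 8L))[mt_all$length >= 8L, ]
  )
  sv <- truth_variants %>% filter(.data$region == "seed")
  expected_switches <- list()
  for (i in seq_len(nrow(sv))) {
    v <- sv[i, ]
    wt <- mt_all$sequence[mt_all$mature == v$mature]
    alt_t <- as_rna(if (v$strand == "-") .dna_comp(v$alt) else v$alt)
    mut <- wt
    substr(mut, v$mature_position, v$mature_position) <- alt_t
    for (k in c(6L, 7L)) {
      if (v$mature_position > k + 1L) next
      mut_seed <- substr(mut, 2L, k + 1L)
      tb <- seed_tbl[[as.character(k)]]
      hits <- tb$mature[tb$seed == mut_seed & tb$mature != v$mature]
      if (length(hits) == 0L) next
      expected_switches[[length(expected_switches) + 1L]] <- tibble(
        variant = v$id, source_mature = v$mature, matched_mature = hits, k = k,
        planted = v$planted_switch
      )
    }
  }
  truth_switches <- if (length(expected_switches) > 0L) {
    bind_rows(expected_switches) %>%
      arrange(.data$variant, .data$k, .data$matched_mature)
  } else {
    tibble(variant = character(), source_mature = character(),
           matched_mature = character(), k = integer(), planted = logical())
  }

  # ---- QTL and fragile-site features ---------------------------------------
  .make_features <- function(n, kind, prefix) {
    if (n == 0L) {
      return(tibble(name = character(), kind = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character()))
    }
    rows <- lapply(seq_len(n), function(i) {
      if (stats::runif(1) < 0.6 && nrow(mirna) > 0) {
        h <- mirna[sample.int(nrow(mirna), 1L), ]
        s <- max(1L, h$start - sample(50:800, 1L))
        e <- min(chrom_len, h$end + sample(50:800, 1L))
        chrom <- h$chrom
      } else {
        chrom <- sample(chroms, 1L)
        s <- sample.int(chrom_len - 1600L, 1L)
        e <- s + sample(100:1500, 1L)
      }
      tibble(name = sprintf("%s_%d", prefix, i), kind = kind, chrom = chrom,
             start = as.integer(s), end = as.integer(e), strand = "*")
    })
    bind_rows(rows)
  }
  qtl <- .make_features(spec$n_qtl, "qtl", "qtl")
  fragile <- .make_features(spec$n_fragile_sites, "fragile_site", "fra")
  features <- bind_rows(qtl, fragile)

  # ground-truth overlaps by exhaustive double loop (closed intervals)
  truth_overlaps <- list()
  for (i in seq_len(nrow(mirna))) {
    for (j in seq_len(nrow(features))) {
      if (mirna$chrom[i] == features$chrom[j] &&
          mirna$start[i] <= features$end[j] &&
          features$start[j] <= mirna$end[i]) {
        truth_overlaps[[length(truth_overlaps) + 1L]] <-
          tibble(mirna = mirna$name[i], feature = features$name[j],
                 kind = features$kind[j])
      }
    }
  }
  truth_overlaps <- if (length(truth_overlaps) > 0L) {
    bind_rows(truth_overlaps) %>% arrange(.data$mirna, .data$kind, .data$feature)
  } else tibble(mirna = character(), feature = character(), kind = character())

  # ---- host genes with controlled exonic context ----------------------------
  contexts <- c("exonic", "intronic", "exon_and_intron")
  gene_rows <- list()
  hostable <- which(mirna$start > 200L & mirna$end < chrom_len - 200L)
  if (spec$n_host_genes > length(hostable)) {
    abort("fixture spec infeasible: not enough hairpins clear of chromosome ends to host genes")
  }
  host_idx <- if (spec$n_host_genes > 0L) sample(hostable, spec$n_host_genes) else integer()
  for (gi in seq_along(host_idx)) {
    h <- mirna[host_idx[gi], ]
    ctx <- contexts[((gi - 1L) %% 3L) + 1L]
    sense <- gi %% 2L == 1L
    gstrand <- if (sense) h$strand else setdiff(c("+", "-"), h$strand)
    g_start <- h$start - 150L
    g_end <- h$end + 150L
    gname <- sprintf("gene_%d", gi)
    ex <- switch(ctx,
      exonic = tibble(start = h$start - 20L, end = h$end + 20L),
      intronic = tibble(start = c(g_start, h$end + 10L),
                        end = c(h$start - 10L, g_end)),
      exon_and_intron = tibble(start = g_start,
                               end = h$start + (h$end - h$start) %/% 2L)
    )
    gene_rows[[length(gene_rows) + 1L]] <- bind_rows(
      tibble(name = gname, kind = "gene", parent = NA_character_,
             chrom = h$chrom, start = g_start, end = g_end, strand = gstrand),
      tibble(name = sprintf("%s_exon%d", gname, seq_len(nrow(ex))),
             kind = "exon", parent = gname, chrom = h$chrom,
             start = ex$start, end = ex$end, strand = gstrand)
    )
  }
  genes <- if (length(gene_rows) > 0L) bind_rows(gene_rows) else
    tibble(name = character(), kind = character(), parent = character(),
           chrom = character(), start = integer(), end = integer(),
           strand = character())

  # ground-truth host context by per-base membership, over ALL overlapping
  # (hairpin, gene) pairs (a gene may also overlap a neighbouring hairpin)
  truth_host <- list()
  gene_only <- genes[genes$kind == "gene", , drop = FALSE]
  for (i in seq_len(nrow(mirna))) {
    for (j in seq_len(nrow(gene_only))) {
      g <- gene_only[j, ]
      h <- mirna[i, ]
      if (h$chrom != g$chrom || h$start > g$end || g$start > h$end) next
      ex <- genes[genes$kind == "exon" & genes$parent == g$name, , drop = FALSE]
      hp_pos <- seq(h$start, h$end)
      in_exon <- vapply(hp_pos, function(p) any(p >= ex$start & p <= ex$end),
                        logical(1))
      ctx <- if (all(in_exon)) "exonic" else if (!any(in_exon)) "intronic"
             else "exon_and_intron"
      truth_host[[length(truth_host) + 1L]] <- tibble(
        mirna = h$name, feature = g$name,
        orientation = if (g$strand %in% c("*", ".")) "unstranded"
                      else if (g$strand == h$strand) "sense" else "antisense",
        context = ctx
      )
    }
  }
  truth_host <- if (length(truth_host) > 0L) {
    bind_rows(truth_host) %>% arrange(.data$mirna, .data$feature)
  } else tibble(mirna = character(), feature = character(),
                orientation = character(), context = character())

  # ---- phenotypes -----------------------------------------------------------
  sim <- simulate_phenotypes(
    n_null_traits = spec$n_null_traits, n_effect_traits = spec$n_effect_traits,
    effect_size = spec$effect_size, noise_sd = spec$noise_sd,
    sex_effect = spec$sex_effect,
    strains_per_genotype = spec$strains_per_genotype, sexes = spec$sexes,
    n_per_cell = spec$n_per_cell
  )
  phenotypes <- sim$phenotypes
  traits <- sim$traits

  truth <- list(
    variants = truth_variants,
    dnp_runs = if (length(dnp_runs) > 0L) bind_rows(dnp_runs) %>%
      arrange(.data$dnp_group) else
      tibble(dnp_group = character(), hairpin = character(),
             start_pos = integer(), run_length = integer(),
             label = character(), member_ids = character()),
    seed_switches = truth_switches,
    overlaps = truth_overlaps,
    host_context = truth_host,
    phenotypes = traits[, c("trait", "group", "delta")]
  )

  paths <- .write_fixture_files(outdir, genome, mirna, truth_variants, qtl,
                                fragile, genes, phenotypes, truth)
  invisible(list(spec = spec, dir = outdir, paths = paths, genome = genome,
                 mirna = mirna, variants = truth_variants, features = features,
                 genes = genes, phenotypes = phenotypes, truth = truth))
}

.write_fixture_files <- function(outdir, genome, mirna, variants, qtl, fragile,
                                 genes, phenotypes, truth) {
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gff = file.path(outdir, "mirna.gff3"),
    fasta = file.path(outdir, "hairpins.fa"),
    vcf = file.path(outdir, "variants.vcf"),
    qtl = file.path(outdir, "qtl.bed"),
    fragile = file.path(outdir, "fragile_sites.bed"),
    genes = file.path(outdir, "genes.gff3"),
    phenotypes = file.path(outdir, "phenotypes.tsv"),
    truth = file.path(outdir, "ground_truth.json")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), paths$genome)
  write_mirna_gff(mirna, paths$gff)
  write_hairpin_fasta(mirna[, c("name", "sequence")], paths$fasta)
  write_vcf_lines(variants, paths$vcf)
  write_features_bed(qtl, paths$qtl)
  write_features_bed(fragile, paths$fragile)
  write_gene_models(genes, paths$genes)
  readr::write_tsv(phenotypes, paths$phenotypes, progress = FALSE)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns", digits = NA,
                       na = "null", pretty = TRUE)
  paths
}

#' Simulate a strain-structured phenotype table
#'
#' Emulates a multi-trait inbred-strain phenotype panel: two genotype levels
#' (CC, TT) with strains nested in genotype, both sexes, a fixed sex effect,
#' and i.i.d. Gaussian residuals. Null traits have no genotype effect;
#' effect traits shift the TT strains by `effect_size`. Strain-level
#' heterogeneity beyond the genotype effect is deliberately absent, so the
#' residual-error genotype test is exact under the null.
#'
#' @param n_null_traits,n_effect_traits trait counts.
#' @param effect_size planted genotype effect (trait units).
#' @param noise_sd residual standard deviation.
#' @param sex_effect fixed additive effect of the first sex level.
#' @param strains_per_genotype,sexes,n_per_cell panel design.
#' @param seed optional seed; when NULL the current RNG state is used.
#' @return list with `phenotypes` (tibble: `strain, sex, genotype, trait,
#'   group, value`) and `traits` (tibble: `trait, group, delta`).
#' @export
simulate_phenotypes <- function(n_null_traits = 20L, n_effect_traits = 5L,
                                effect_size = 2, noise_sd = 1, sex_effect = 0.5,
                                strains_per_genotype = 7L, sexes = c("f", "m"),
                                n_per_cell = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_strain <- 2L * strains_per_genotype
  strains <- sprintf("S%02d", seq_len(n_strain))
  genotype <- rep(c("CC", "TT"), each = strains_per_genotype)
  traits <- bind_rows(
    tibble(trait = sprintf("null_%03d", seq_len(n_null_traits)), delta = 0),
    tibble(trait = sprintf("eff_%03d", seq_len(n_effect_traits)),
           delta = effect_size)
  )
  traits$group <- sample(MPD_GROUPS, nrow(traits), replace = TRUE)
  pheno <- vector("list", nrow(traits))
  cells0 <- tidyr::expand_grid(strain = strains, sex = sexes,
                               rep = seq_len(n_per_cell))
  cells0$genotype <- genotype[match(cells0$strain, strains)]
  for (ti in seq_len(nrow(traits))) {
    cells <- cells0
    cells$value <- 10 +
      (cells$genotype == "TT") * traits$delta[ti] +
      (cells$sex == sexes[1]) * sex_effect +
      rnorm(nrow(cells), sd = noise_sd)
    pheno[[ti]] <- tibble(strain = cells$strain, sex = cells$sex,
                          genotype = cells$genotype, trait = traits$trait[ti],
                          group = traits$group[ti], value = cells$value)
  }
  list(phenotypes = bind_rows(pheno), traits = traits)
}

#' Write variants as a minimal VCF 4.2 file
#'
#' @param variants tibble with `id, chrom, pos, ref, alt` (1-based, + strand
#'   alleles).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf_lines <- function(variants, path) {
  v <- variants %>% arrange(.data$chrom, .data$pos, .data$id)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=seedvar",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t"),
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", v$chrom, v$pos, v$id, v$ref, v$alt)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a fixture ground-truth file
#'
#' @param path `ground_truth.json` written by [generate_fixture()].
#' @return list of ground-truth tibbles.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(gt, as_tibble)
}

#' The canonical miR-96 / miR-514 style seed-switch fixture
#'
#' A fully deterministic two-miRNA fixture reproducing the classic seed-
#' switch relationship: a G>A substitution at position +13 of a miR-96-like
#' hairpin (mature position 5, inside the seed) turns its seed into the seed
#' of a miR-514-like miRNA. The mature sequences are the published miR-96-5p
#' and miR-514a-3p sequences; hairpin flanks and the surrounding genome are
#' synthetic padding, hence the `syn-` names.
#'
#' @param outdir output directory (created if missing).
#' @return invisibly, a list shaped like [generate_fixture()]'s return value
#'   (without features/genes/phenotypes).
#' @export
mir96_like_fixture <- function(outdir = tempfile("mir96")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mature96 <- "UUUGGCACUAGCACAUUUUUGCU"   # hsa-miR-96-5p
  mature514 <- "AUUGACACUUCUGUGAGUAGA"    # hsa-miR-514a-3p
  h96 <- paste0("GGAUCCGA", mature96, "GCUAGCUAGCUAGCUAGCUAGCUAGCUAG")
  h514 <- paste0("AUCGAUCGAU", mature514, "GCAUGCAUGCAUGCAUGCAUGCAUGCAUG")
  stopifnot(nchar(h96) == 60L, nchar(h514) == 60L)
  chrom <- "chrSyn96"
  genome_str <- strrep("ACGT", 125L)
  substr(genome_str, 101L, 160L) <- chartr("U", "T", h96)
  substr(genome_str, 301L, 360L) <- chartr("U", "T", h514)
  genome <- setNames(genome_str, chrom)
  mirna <- tibble(
    name = c("syn-mir-96-like", "syn-mir-514-like"), chrom = chrom,
    start = c(101L, 301L), end = c(160L, 360L), strand = "+",
    sequence = c(h96, h514),
    matures = list(
      tibble(name = "syn-miR-96-like-5p", start = 109L, end = 131L,
             offset = 9L, length = 23L),
      tibble(name = "syn-miR-514-like-3p", start = 311L, end = 331L,
             offset = 11L, length = 21L)
    )
  )
  # hairpin position +13 = mature position 5 (G in the seed); G>A
  variants <- tibble(
    id = "mir96_plus13_G_A", chrom = chrom, pos = 113L, ref = "G", alt = "A",
    vclass = "snv", hairpin = "syn-mir-96-like", strand = "+",
    mature = "syn-miR-96-like-5p", region = "seed", mature_position = 5L,
    seed6_member = TRUE, seed7_member = TRUE,
    substitution = "transition", planted_switch = TRUE
  )
  truth <- list(
    variants = variants,
    seed_switches = tibble(
      variant = "mir96_plus13_G_A", source_mature = "syn-miR-96-like-5p",
      matched_mature = "syn-miR-514-like-3p", k = c(6L, 7L), planted = TRUE
    )
  )
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    gff = file.path(outdir, "mirna.gff3"),
    fasta = file.path(outdir, "hairpins.fa"),
    vcf = file.path(outdir, "variants.vcf"),
    truth = file.path(outdir, "ground_truth.json")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), paths$genome)
  write_mirna_gff(mirna, paths$gff)
  write_hairpin_fasta(mirna[, c("name", "sequence")], paths$fasta)
  write_vcf_lines(variants, paths$vcf)
  jsonlite::write_json(truth, paths$truth, dataframe = "columns", digits = NA,
                       na = "null", pretty = TRUE)
  invisible(list(dir = outdir, paths = paths, genome = genome, mirna = mirna,
                 variants = variants, truth = truth))
}
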