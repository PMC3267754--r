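# Seed-switch detection: exact seed-string matching at k = 6 and k = 7.

test_that("seed index groups matures by seed string", {
  mirna <- tibble::tibble(
    name = c("mir-1", "mir-2"), chrom = "c1",
    start = c(101L, 301L), end = c(130L, 330L), strand = "+",
    sequence = c(paste0("A", "UUGGCA", strrep("ACG", 7), "GC"),
                 paste0("G", "UUGGCA", strrep("CGA", 7), "GC")),
    matures = list(
      tibble::tibble(name = "miR-1", start = 101L, end = 130L, offset = 1L, length = 30L),
      tibble::tibble(name = "miR-2", start = 301L, end = 330L, offset = 1L, length = 30L)
    )
  )
  idx <- build_seed_index(mirna, 6)
  # identical positions 2-7 -> one key with both matures
  expect_equal(sort(idx$mature[idx$seed == "UUGGCA"]), c("miR-1", "miR-2"))
  expect_equal(nrow(build_seed_index(mirna[0, ], 6)), 0)
})

test_that("seed index key set equals a brute-force distinct-seed set", {
  fx <- medium_fixture()
  for (k in c(6, 7)) {
    idx <- build_seed_index(fx$mirna, k)
    mt <- mature_sequences(fx$mirna)
    mt <- mt[mt$length >= k + 1, ]
    brute <- unique(substr(mt$sequence, 2, k + 1))
    expect_setequal(unique(idx$seed), brute)
    expect_equal(nrow(idx), nrow(mt)) # every long-enough mature indexed once
  }
})

test_that("variant application checks the reference and is an involution", {
  expect_equal(apply_variant_to_mature("ACGUA", 3, "G", "A"), "ACAUA")
  expect_equal(apply_variant_to_mature("ACGUA", 2, "CG", "GC"), "AGCUA")
  expect_error(apply_variant_to_mature("ACGUA", 3, "C", "A"), "mismatch")
  # applying ref->alt then alt->ref restores the original
  mut <- apply_variant_to_mature("UUUGGCACUAG", 5, "G", "A")
  expect_equal(apply_variant_to_mature(mut, 5, "A", "G"), "UUUGGCACUAG")
})

test_that("the miR-96-like fixture yields exactly the miR-514-like switch", {
  fx <- mir96_like_fixture(tempfile("m96"))
  mirna <- read_mirna_gff(fx$paths$gff, fasta = fx$paths$fasta)
  variants <- read_vcf(fx$paths$vcf)
  ann <- annotate_variants(variants, mirna)
  hits <- find_seed_switches(ann, mirna)
  expect_equal(nrow(hits), 2) # one matched mature at each k
  expect_setequal(hits$k, c(6, 7))
  expect_true(all(hits$source_mature == "syn-miR-96-like-5p"))
  expect_true(all(hits$matched_mature == "syn-miR-514-like-3p"))
  expect_equal(hits$mutant_seed[hits$k == 7], "UUGACAC")
  # no variant, no hits
  expect_equal(nrow(find_seed_switches(ann[0, ], mirna)), 0)
  # reversing the substitution on the mutant background yields no hit:
  # the A-carrying miR-96-like seed is the miR-514 seed, so A>G restores
  # the wild type, which matches no other annotated mature
  mut_mirna <- mirna
  mut_mirna$sequence[1] <- sub("UUUGGCAC", "UUUGACAC", mirna$sequence[1])
  rev_var <- variants
  rev_var$ref <- "A"
  rev_var$alt <- "G"
  ann_rev <- annotate_variants(rev_var, mut_mirna)
  expect_equal(nrow(find_seed_switches(ann_rev, mut_mirna)), 0)
})

test_that("planted switch pairs are recovered with no spurious hits", {
  fx <- medium_fixture()
  p <- parse_fixture(fx)
  ann <- merge_dnps(annotate_variants(p$variants, p$mirna))
  hits <- find_seed_switches(ann, p$mirna)
  got <- dplyr::arrange(
    tibble::tibble(variant = hits$variant, source_mature = hits$source_mature,
                   matched_mature = hits$matched_mature, k = hits$k),
    variant, k, matched_mature)
  want <- dplyr::arrange(
    fx$truth$seed_switches[, c("variant", "source_mature", "matched_mature", "k")],
    variant, k, matched_mature)
  expect_equal(as.data.frame(got), as.data.frame(want))
  # every planted pair is present (recall 1) and nothing else (precision 1)
  planted <- fx$truth$seed_switches[fx$truth$seed_switches$planted, ]
  found <- paste(hits$variant, hits$matched_mature, hits$k)
  expect_true(all(paste(planted$variant, planted$matched_mature, planted$k)
                  %in% found))
})

test_that("a 7mer switch between two matures implies the 6mer seeds also match", {
  fx <- medium_fixture()
  p <- parse_fixture(fx)
  ann <- annotate_variants(p$variants, p$mirna)
  hits <- find_seed_switches(ann, p$mirna)
  h7 <- hits[hits$k == 7, ]
  for (i in seq_len(nrow(h7))) {
    expect_equal(substr(h7$mutant_seed[i], 1, 6),
                 extract_seed(paste0("N", h7$mutant_seed[i]), 6))
    # pair-level: the same (variant, matched) appears at k = 6 unless the
    # variant sits at mature position 8 (6mer seed unchanged there)
    src <- ann[ann$id == h7$variant[i] & ann$mature == h7$source_mature[i], ]
    if (src$mature_position != 8) {
      expect_true(any(hits$k == 6 &
                        hits$variant == h7$variant[i] &
                        hits$matched_mature == h7$matched_mature[i]))
    }
  }
})

test_that("a variant at mature position 8 can only switch the 7mer seed", {
  # build a donor whose 7mer seed differs from the acceptor only at seed
  # position 8 (mature position 8)
  acc <- paste0("A", "CCCAAA", "G", strrep("U", 14)) # seed7 CCCAAAG
  don <- paste0("A", "CCCAAA", "C", strrep("G", 14)) # seed7 CCCAAAC
  mirna <- tibble::tibble(
    name = c("mir-acc", "mir-don"), chrom = "c1",
    start = c(101L, 301L), end = c(122L, 322L), strand = "+",
    sequence = c(acc, don),
    matures = list(
      tibble::tibble(name = "miR-acc", start = 101L, end = 122L, offset = 1L, length = 22L),
      tibble::tibble(name = "miR-don", start = 301L, end = 322L, offset = 1L, length = 22L)
    )
  )
  v <- tibble::tibble(id = "pos8", chrom = "c1", pos = 108L, ref = "G", alt = "C")
  ann <- annotate_variants(v, mirna)
  expect_equal(ann$region, "seed")
  expect_false(ann$seed6_member)
  hits <- find_seed_switches(ann, mirna)
  expect_equal(hits$k, 7L)
  expect_equal(hits$matched_mature, "miR-don")
})
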