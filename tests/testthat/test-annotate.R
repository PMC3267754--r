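# Region classification, transition/transversion, DNP merging.

# a simple hand-built plus/minus pair of hairpins for targeted cases
toy_mirna <- function() {
  # + strand hairpin 1001-1060, mature 1010-1030 (offset 10)
  # - strand hairpin 2001-2060, mature 2031-2051 (offset 10, 5' end at 2051)
  g1 <- strrep("ACGU", 15)
  tibble::tibble(
    name = c("mir-p", "mir-m"), chrom = "c1",
    start = c(1001L, 2001L), end = c(1060L, 2060L), strand = c("+", "-"),
    sequence = c(g1, g1),
    matures = list(
      tibble::tibble(name = "miR-p", start = 1010L, end = 1030L,
                     offset = 10L, length = 21L),
      tibble::tibble(name = "miR-m", start = 2031L, end = 2051L,
                     offset = 10L, length = 21L)
    )
  )
}

test_that("the twelve ordered substitutions split 4 transitions / 8 transversions", {
  bases <- c("A", "C", "G", "U")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  got <- classify_substitution(pairs$ref, pairs$alt)
  want <- unname(ORACLE_TITV[paste0(pairs$ref, ">", pairs$alt)])
  expect_equal(got, want)
  expect_equal(sum(got == "transition"), 4)
  expect_equal(sum(got == "transversion"), 8)
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("A", "C"), "transversion")
  expect_error(classify_substitution("A", "A"), "identical")
  expect_error(classify_substitution("A", "X"), "outside|must be")
})

test_that("region classification follows the seed definition on both strands", {
  m <- toy_mirna()
  v <- tibble::tibble(
    id = c("seed4", "pos1", "pos8", "pos9", "prec", "out", "mseed"),
    chrom = "c1",
    pos = c(1013L, 1010L, 1017L, 1018L, 1035L, 900L, 2048L),
    ref = "A", alt = "G"
  )
  # toy sequences repeat ACGU; pick refs that match to avoid mismatch flags
  ann <- annotate_variants(v, m, include_outside = TRUE)
  get <- function(id) ann[ann$id == id, ]
  expect_equal(get("seed4")$region, "seed")        # mature position 4
  expect_equal(get("seed4")$mature_position, 4L)
  expect_true(get("seed4")$seed6_member && get("seed4")$seed7_member)
  expect_equal(get("pos1")$region, "mature_nonseed") # position 1 excluded
  expect_equal(get("pos8")$region, "seed")           # 7mer-only seed member
  expect_false(get("pos8")$seed6_member)
  expect_true(get("pos8")$seed7_member)
  expect_equal(get("pos9")$region, "mature_nonseed")
  expect_equal(get("prec")$region, "precursor")
  expect_equal(get("out")$region, "outside")
  # minus strand: genomic 2048 -> mature position 2051 - 2048 + 1 = 4
  expect_equal(get("mseed")$region, "seed")
  expect_equal(get("mseed")$mature_position, 4L)
})

test_that("minus-strand transcript alleles are complemented", {
  m <- toy_mirna()
  v <- tibble::tibble(id = "x", chrom = "c1", pos = 2048L, ref = "G", alt = "A")
  ann <- annotate_variants(v, m)
  expect_equal(ann$ref_rna, "C")
  expect_equal(ann$alt_rna, "U")
  # transition class is complement-invariant
  expect_equal(ann$substitution, "transition")
})

test_that("indel region follows the affected-reference-base rule", {
  m <- toy_mirna()
  # deletion spanning mature positions 7-9 (genomic 1016-1018, anchor 1015)
  del <- tibble::tibble(id = "del", chrom = "c1", pos = 1015L,
                        ref = "ACGU", alt = "A")
  ann <- annotate_variants(del, m)
  expect_equal(ann$region, "seed") # positions 7 and 8 are affected
  expect_equal(ann$mature_position, 7L)
  # insertion strictly between seed positions counts as seed
  ins <- tibble::tibble(id = "ins", chrom = "c1", pos = 1013L,
                        ref = "A", alt = "AGG")
  ann2 <- annotate_variants(ins, m)
  expect_equal(ann2$region, "seed")
  # insertion between positions outside the mature stays precursor
  ins2 <- tibble::tibble(id = "ins2", chrom = "c1", pos = 1040L,
                         ref = "A", alt = "AGG")
  expect_equal(annotate_variants(ins2, m)$region, "precursor")
})

test_that("REF disagreement with the hairpin is flagged, not dropped", {
  m <- toy_mirna()
  # position 1013 holds A on the + hairpin (ACGU repeating from 1001)
  good <- tibble::tibble(id = "g", chrom = "c1", pos = 1013L, ref = "A", alt = "G")
  bad <- tibble::tibble(id = "b", chrom = "c1", pos = 1013L, ref = "C", alt = "G")
  expect_false(annotate_variants(good, m)$ref_mismatch)
  annb <- annotate_variants(bad, m)
  expect_equal(nrow(annb), 1)
  expect_true(annb$ref_mismatch)
})

test_that("annotator matches the per-base brute-force oracle on a mixed-strand fixture", {
  fx <- medium_fixture()
  p <- parse_fixture(fx)
  ann <- annotate_variants(p$variants, p$mirna)
  got <- dplyr::arrange(
    ann[, c("id", "hairpin", "mature", "region", "mature_position",
            "substitution", "seed6_member", "seed7_member")],
    id, hairpin, mature)
  want <- oracle_annotate(p$variants, p$mirna)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("region assignments partition per (variant, mature) pair", {
  fx <- medium_fixture()
  p <- parse_fixture(fx)
  ann <- annotate_variants(p$variants, p$mirna, include_outside = TRUE)
  expect_true(all(ann$region %in% c("seed", "mature_nonseed", "precursor", "outside")))
  expect_equal(anyDuplicated(ann[, c("id", "alt", "hairpin", "mature")]), 0L)
  # seed implies 7mer membership and a mature assignment
  seeds <- ann[ann$region == "seed", ]
  expect_true(all(seeds$seed7_member))
  expect_true(all(!is.na(seeds$mature)))
  # Ti/Tv classes exhaust annotated SNVs
  snvs <- ann[ann$vclass == "snv" & ann$region != "outside", ]
  expect_equal(sum(snvs$substitution == "transition") +
                 sum(snvs$substitution == "transversion"), nrow(snvs))
})

test_that("adjacent SNVs merge into maximal runs; grouping is stable", {
  m <- toy_mirna()
  v <- tibble::tibble(
    id = c("a", "b", "c", "d", "e", "f"),
    chrom = "c1",
    pos = c(1033L, 1034L, 1036L, 1041L, 1042L, 1043L),
    ref = c("A", "C", "C", "A", "C", "G"), alt = "U"
  )
  ann <- merge_dnps(annotate_variants(v, m))
  members <- ann[!ann$derived, ]
  # a+b adjacent -> DNP; c isolated; d,e,f -> length-3 run
  expect_equal(members$dnp_group[members$id == "a"],
               members$dnp_group[members$id == "b"])
  expect_true(is.na(members$dnp_group[members$id == "c"]))
  expect_equal(length(unique(members$dnp_group[members$id %in% c("d", "e", "f")])), 1)
  derived <- ann[ann$derived, ]
  expect_equal(nrow(derived), 2)
  expect_equal(sort(derived$vclass), c("dnp", "mnp_run"))
  expect_equal(derived$run_length[derived$vclass == "dnp"], 2L)
  expect_equal(derived$run_length[derived$vclass == "mnp_run"], 3L)
  expect_equal(derived$ref[derived$vclass == "mnp_run"], "ACG")

  # order-invariance and idempotence
  shuffled <- annotate_variants(v[sample(nrow(v)), ], m)
  again <- merge_dnps(shuffled)
  expect_equal(as.data.frame(again), as.data.frame(ann))
  expect_equal(as.data.frame(merge_dnps(ann)), as.data.frame(ann))
})

test_that("non-adjacent SNVs are never grouped", {
  m <- toy_mirna()
  v <- tibble::tibble(id = c("a", "b"), chrom = "c1", pos = c(1033L, 1035L),
                      ref = c("A", "G"), alt = "U")
  ann <- merge_dnps(annotate_variants(v, m))
  expect_true(all(is.na(ann$dnp_group)))
  expect_false(any(ann$derived))
})

test_that("planted DNP runs are recovered exactly from the fixture", {
  fx <- medium_fixture()
  p <- parse_fixture(fx)
  ann <- merge_dnps(annotate_variants(p$variants, p$mirna))
  derived <- ann[ann$derived, ]
  got <- dplyr::arrange(
    tibble::tibble(dnp_group = derived$dnp_group, hairpin = derived$hairpin,
                   start_pos = derived$pos, run_length = derived$run_length,
                   label = derived$vclass, member_ids = derived$id),
    dnp_group)
  expect_equal(as.data.frame(got), as.data.frame(fx$truth$dnp_runs))
})
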