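# Interval intersection and host-gene context.

test_that("overlap uses closed intervals: touching is overlap, adjacency is not", {
  mirna <- tibble::tibble(
    name = "mir-1", chrom = "c1", start = 100L, end = 200L, strand = "+",
    sequence = NA_character_,
    matures = list(tibble::tibble(name = "miR-1", start = 110L, end = 130L,
                                  offset = 11L, length = 21L))
  )
  qtl <- tibble::tibble(name = "qtlA", kind = "qtl", chrom = "c1",
                        start = 150L, end = 5000L, strand = "*")
  expect_equal(nrow(intersect_features(mirna, qtl)), 1)
  expect_equal(intersect_features(mirna, qtl)$orientation, "unstranded")
  adjacent <- tibble::tibble(name = "f", kind = "qtl", chrom = "c1",
                             start = 201L, end = 300L, strand = "*")
  expect_equal(nrow(intersect_features(mirna, adjacent)), 0)
  shared_base <- tibble::tibble(name = "f", kind = "qtl", chrom = "c1",
                                start = 200L, end = 300L, strand = "*")
  expect_equal(nrow(intersect_features(mirna, shared_base)), 1)
  # containment flag
  expect_equal(nrow(intersect_features(mirna, shared_base, contained = TRUE)), 0)
  containing <- tibble::tibble(name = "f", kind = "qtl", chrom = "c1",
                               start = 50L, end = 500L, strand = "*")
  expect_equal(nrow(intersect_features(mirna, containing, contained = TRUE)), 1)
})

test_that("intersection matches the quadratic double-loop oracle on random intervals", {
  set.seed(11)
  n_m <- 120; n_f <- 80
  mirna <- tibble::tibble(
    name = sprintf("mir-%03d", seq_len(n_m)),
    chrom = sample(c("c1", "c2"), n_m, replace = TRUE),
    start = sample.int(50000, n_m),
    strand = sample(c("+", "-"), n_m, replace = TRUE),
    sequence = NA_character_,
    matures = replicate(n_m, tibble::tibble(
      name = character(), start = integer(), end = integer(),
      offset = integer(), length = integer()), simplify = FALSE)
  )
  mirna$end <- mirna$start + sample(60:110, n_m, replace = TRUE)
  features <- tibble::tibble(
    name = sprintf("f%03d", seq_len(n_f)), kind = "qtl",
    chrom = sample(c("c1", "c2"), n_f, replace = TRUE),
    start = sample.int(50000, n_f), strand = "*"
  )
  features$end <- features$start + sample(100:3000, n_f, replace = TRUE)
  got <- suppressMessages(intersect_features(mirna, features))
  want <- oracle_overlap(mirna, features)
  expect_equal(as.data.frame(got[, c("mirna", "feature", "kind")]),
               as.data.frame(want))
})

test_that("host context classifies exonic/intronic/boundary cases", {
  mirna <- tibble::tibble(
    name = c("mir-ex", "mir-in", "mir-bd"), chrom = "c1",
    start = c(1000L, 3000L, 5000L), end = c(1080L, 3080L, 5080L),
    strand = c("+", "+", "-"), sequence = NA_character_,
    matures = list(tibble::tibble(name = character(), start = integer(),
                                  end = integer(), offset = integer(),
                                  length = integer()))[c(1, 1, 1)]
  )
  genes <- dplyr::bind_rows(
    # same-strand gene with one exon containing the first hairpin
    tibble::tibble(name = "gA", kind = "gene", parent = NA, chrom = "c1",
                   start = 900L, end = 1200L, strand = "+"),
    tibble::tibble(name = "gA_e1", kind = "exon", parent = "gA", chrom = "c1",
                   start = 950L, end = 1100L, strand = "+"),
    # opposite-strand gene whose exons flank the second hairpin
    tibble::tibble(name = "gB", kind = "gene", parent = NA, chrom = "c1",
                   start = 2800L, end = 3300L, strand = "-"),
    tibble::tibble(name = c("gB_e1", "gB_e2"), kind = "exon", parent = "gB",
                   chrom = "c1", start = c(2800L, 3100L),
                   end = c(2900L, 3300L), strand = "-"),
    # gene with an exon boundary inside the third hairpin
    tibble::tibble(name = "gC", kind = "gene", parent = NA, chrom = "c1",
                   start = 4800L, end = 5300L, strand = "-"),
    tibble::tibble(name = "gC_e1", kind = "exon", parent = "gC", chrom = "c1",
                   start = 4800L, end = 5040L, strand = "-")
  )
  hc <- host_gene_context(mirna, genes)
  row <- function(m) hc[hc$mirna == m, ]
  expect_equal(row("mir-ex")$orientation, "sense")
  expect_equal(row("mir-ex")$context, "exonic")
  expect_equal(row("mir-in")$orientation, "antisense")
  expect_equal(row("mir-in")$context, "intronic")
  expect_equal(row("mir-bd")$orientation, "sense") # both minus strand
  expect_equal(row("mir-bd")$context, "exon_and_intron")
  expect_true(all(hc$context %in% c("exonic", "intronic", "exon_and_intron")))
})

test_that("host context matches the per-base membership oracle on the fixture", {
  fx <- medium_fixture()
  mirna <- read_mirna_gff(fx$paths$gff)
  genes <- read_gene_models(fx$paths$genes)
  got <- host_gene_context(mirna, genes)
  want <- oracle_host_context(mirna, genes)
  expect_equal(as.data.frame(got[, c("mirna", "feature", "orientation", "context")]),
               as.data.frame(want))
})

test_that("overlap summaries count per miRNA and report ties lexicographically", {
  expect_equal(nrow(summarize_overlaps(
    tibble::tibble(mirna = character(), feature = character(),
                   kind = character(), orientation = character()))), 0)
  rec <- tibble::tibble(
    mirna = c(rep("mirA", 7), rep("mirB", 3), rep("mirC", 7)),
    feature = sprintf("q%d", 1:17), kind = "qtl", orientation = "unstranded"
  )
  per <- summarize_overlaps(rec)
  expect_equal(per$n_features[per$mirna == "mirA"], 7L)
  expect_equal(per$n_features[per$mirna == "mirB"], 3L)
  tot <- overlap_totals(rec)
  expect_equal(tot$n_overlaps, 17L)
  expect_equal(tot$max_count, 7L)
  expect_equal(tot$top_mirnas, "mirA,mirC") # tie, lexicographic
  # per-miRNA counts sum to the record count
  expect_equal(sum(per$n_features), nrow(rec))
})

test_that("fixture overlap records match the generator's ground truth", {
  fx <- medium_fixture()
  mirna <- read_mirna_gff(fx$paths$gff)
  qtl <- read_features_bed(fx$paths$qtl, kind = "qtl")
  fra <- read_features_bed(fx$paths$fragile, kind = "fragile_site")
  got <- suppressMessages(intersect_features(mirna, dplyr::bind_rows(qtl, fra)))
  expect_equal(as.data.frame(dplyr::arrange(got[, c("mirna", "feature", "kind")],
                                            mirna, kind, feature)),
               as.data.frame(dplyr::arrange(fx$truth$overlaps,
                                            mirna, kind, feature)))
})
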