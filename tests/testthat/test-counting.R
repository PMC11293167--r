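anchor <- "GACGAAACACC"

test_that("handcrafted reads count to the right guides", {
  lib <- toy_library()
  reads <- c(
    paste0("TT", anchor, lib$spacer[1], "GTTT"),
    paste0("CCAA", anchor, lib$spacer[1], "G"),
    paste0(anchor, lib$spacer[2], "GTTTAAG"),
    paste0("TTTTTTTT", lib$spacer[3], "GGGG"),   # no anchor -> unmapped
    paste0("AC", anchor, "ACGTAC")               # too short after anchor
  )
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  counts <- count_guides(c(s1 = fq), lib, anchor = anchor)
  expect_equal(counts$s1, c(2L, 1L, 0L))
  tot <- count_totals(counts)
  expect_equal(tot$reads, 5L)
  expect_equal(tot$mapped, 3L)
  expect_equal(tot$unmapped, 2L)
})

test_that("an empty FASTQ gives all-zero counts and zero unmapped", {
  lib <- toy_library()
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(character(0), fq)
  counts <- count_guides(c(s1 = fq), lib, anchor = anchor)
  expect_equal(counts$s1, c(0L, 0L, 0L))
  expect_equal(count_totals(counts)$unmapped, 0L)
})

test_that("counting conserves reads and is order-independent", {
  lib <- toy_library()
  reads <- sample(c(
    rep(paste0("T", anchor, lib$spacer[1], "GAGT"), 20),
    rep(paste0("T", anchor, lib$spacer[3], "GAGT"), 7),
    rep("ACGTACGTACGTACGTACGTACGTACGTACGTACG", 4)
  ))
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq1)
  write_fastq(rev(reads), fq2)
  c1 <- count_guides(c(a = fq1), lib, anchor = anchor)
  c2 <- count_guides(c(a = fq2), lib, anchor = anchor)
  expect_equal(c1$a, c2$a)
  tot <- count_totals(c1)
  expect_equal(tot$mapped + tot$unmapped, tot$reads)
  expect_equal(sum(c1$a), tot$mapped)
  # agrees with the read-by-read oracle
  oracle <- brute_count(reads, lib$spacer, anchor)
  expect_equal(unname(oracle$counts), c1$a)
  expect_equal(oracle$unmapped, tot$unmapped)
})

test_that("duplicate spacers in the library are rejected", {
  lib <- toy_library()
  lib$spacer[2] <- lib$spacer[1]
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(character(0), fq)
  expect_error(count_guides(c(a = fq), lib, anchor = anchor),
               class = "secrescreen_data_error")
})

test_that("one-mismatch mode rescues single-substitution spacers", {
  lib <- toy_library()
  mutant <- sub("^A", "G", lib$spacer[1])  # 1 mismatch vs guide A
  reads <- c(paste0(anchor, mutant, "GT"),
             paste0(anchor, lib$spacer[2], "GT"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  exact <- count_guides(c(a = fq), lib, anchor = anchor, max_mismatches = 0)
  expect_equal(exact$a, c(0L, 1L, 0L))
  fuzzy <- count_guides(c(a = fq), lib, anchor = anchor, max_mismatches = 1)
  expect_equal(fuzzy$a, c(1L, 1L, 0L))
})

test_that("normalization is pseudocounted CPM that sums to a million", {
  lib <- toy_library()
  counts <- tibble::tibble(guide_id = lib$guide_id, gene_id = lib$gene_id,
                           s1 = c(5L, 5L, 5L), s2 = c(17L, 2L, 900L))
  norm <- normalize_counts(counts)
  expect_equal(norm$s1, rep(1e6 / 3, 3))
  expect_equal(sum(norm$s1), 1e6)
  expect_equal(sum(norm$s2), 1e6)
  # independent arithmetic
  expect_equal(norm$s2, (counts$s2 + 0.5) / (919 + 0.5 * 3) * 1e6)
  zero <- dplyr::mutate(counts, s2 = 0L)
  expect_error(normalize_counts(zero), class = "secrescreen_data_error")
})

test_that("log2 fold changes match closed-form arithmetic", {
  # equal totals and library size: lfc depends only on the pseudocounted ratio
  counts <- tibble::tibble(
    guide_id = c("gA", "gB"), gene_id = c("geneA", "geneB"),
    pre = c(100L, 25L), post = c(25L, 100L)
  )
  lfc <- guide_lfc(counts)
  expect_equal(lfc$lfc[1], log2(25.5 / 100.5))
  expect_equal(lfc$lfc[1], -1.9787, tolerance = 1e-4)
  expect_equal(lfc$lfc[2], -lfc$lfc[1])
})

test_that("identical samples give zero lfc, including all-zero guides", {
  counts <- tibble::tibble(
    guide_id = c("g1", "g2", "g3"), gene_id = c("a", "b", "c"),
    pre = c(10L, 0L, 50L), post = c(10L, 0L, 50L)
  )
  lfc <- guide_lfc(counts)
  expect_equal(lfc$lfc, c(0, 0, 0))
})

test_that("swapping pre and post negates every lfc", {
  counts <- tibble::tibble(
    guide_id = sprintf("g%02d", 1:30), gene_id = sprintf("gene%02d", 1:30),
    pre = rpois(30, 200), post = rpois(30, 120)
  )
  fwd <- guide_lfc(counts, pre = "pre", post = "post")
  rev <- guide_lfc(counts, pre = "post", post = "pre")
  expect_equal(fwd$lfc, -rev$lfc)
  expect_error(compute_lfc(normalize_counts(counts), post = "missing"),
               class = "secrescreen_data_error")
})
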