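# build a one-contig genome object around a given CDS sequence
toy_genome <- function(cds, flank5 = "ATATATATAT", flank3 = "ATATATATAT",
                       strand = "+") {
  contig <- paste0(flank5, cds, flank3)
  genome <- Biostrings::DNAStringSet(stats::setNames(contig, "chr1"))
  genes <- tibble::tibble(gene_id = "gene1", seqnames = "chr1",
                          start = nchar(flank5) + 1,
                          end = nchar(flank5) + nchar(cds),
                          strand = strand)
  list(genome = genome, genes = genes)
}

test_that("a single sense-strand PAM yields the expected spacer and cut site", {
  # 60-nt CDS, hand-built so the only NGG (or CCN) in the searched half
  # sits at CDS positions 30-32 on the sense strand
  spacer <- "CATCATCATGATGATGATGA"   # positions 10-29
  cds <- paste0("ATGATTATT", spacer, "AGGATTATTATTATTATTATCATCATCATTAA")
  expect_equal(nchar(cds), 61)  # 9 + 20 + 32
  cds <- substr(cds, 1, 60)
  tg <- toy_genome(cds)
  g <- design_guides(tg$genome, tg$genes,
                     params = design_params(cds_window_frac = 0.5,
                                            guides_per_gene = 4))
  expect_equal(nrow(g), 1)
  expect_equal(g$spacer, spacer)
  expect_equal(g$pam, "AGG")
  expect_equal(g$strand, "+")
  expect_equal(g$cut_offset, 27)
})

test_that("a window with no PAM on either strand yields no guides", {
  # A/T-only CDS: no G or C anywhere, so no NGG / CCN possible
  cds <- strrep("ATA", 20)
  tg <- toy_genome(cds)
  expect_message(
    g <- design_guides(tg$genome, tg$genes),
    "no passing guides"
  )
  expect_equal(nrow(g), 0)
  expect_equal(attr(g, "no_guide_genes"), "gene1")
})

test_that("unknown gene ids are a lookup error naming the offender", {
  tg <- toy_genome(strrep("ATG", 30))
  err <- expect_error(design_guides(tg$genome, tg$genes, gene_ids = "nope"),
                      class = "secrescreen_data_error")
  expect_match(conditionMessage(err), "nope")
})

test_that("every emitted spacer+PAM occurs exactly once in the genome", {
  sim <- simulate_genome(sim_config(n_genes = 20, seed = 23))
  g <- design_guides(sim)
  expect_gt(nrow(g), 20)
  genome_fwd <- as.character(sim$genome[[1]])
  genome_rev <- as.character(Biostrings::reverseComplement(sim$genome[[1]]))
  for (i in seq_len(nrow(g))) {
    target <- paste0(g$spacer[i], g$pam[i])
    hits <- length(gregexpr(target, genome_fwd, fixed = TRUE)[[1]]) *
      (regexpr(target, genome_fwd, fixed = TRUE) > 0) +
      length(gregexpr(target, genome_rev, fixed = TRUE)[[1]]) *
      (regexpr(target, genome_rev, fixed = TRUE) > 0)
    expect_equal(as.integer(hits), 1)
  }
})

test_that("guides respect the 5' CDS window and per-gene cap", {
  sim <- simulate_genome(sim_config(n_genes = 15, seed = 31))
  params <- design_params(cds_window_frac = 0.5, guides_per_gene = 3)
  g <- design_guides(sim, params = params)
  expect_true(all(table(g$gene_id) <= 3))
  lens <- with(sim$genes, stats::setNames(end - start + 1, gene_id))
  expect_true(all(g$cut_offset <= floor(0.5 * lens[g$gene_id])))
  expect_true(all(g$cut_offset >= 1))
  # ranked 5'-most first within each gene
  by_gene <- split(g$cut_offset, g$gene_id)
  expect_true(all(vapply(by_gene, function(x) !is.unsorted(x), logical(1))))
})

test_that("every spacer is a substring of its CDS window on some strand", {
  sim <- simulate_genome(sim_config(n_genes = 10, seed = 37))
  g <- design_guides(sim)
  for (i in seq_len(nrow(g))) {
    row <- sim$genes[sim$genes$gene_id == g$gene_id[i], ]
    cds <- substr(as.character(sim$genome[[1]]), row$start, row$end)
    if (row$strand == "-") cds <- secrescreen:::revcomp(cds)
    found <- grepl(g$spacer[i], cds, fixed = TRUE) ||
      grepl(secrescreen:::revcomp(g$spacer[i]), cds, fixed = TRUE)
    expect_true(found)
  }
})

test_that("design is symmetric under reverse-complementing the genome", {
  sim <- simulate_genome(sim_config(n_genes = 8, seed = 41))
  g1 <- design_guides(sim)
  L <- Biostrings::width(sim$genome)[1]
  flipped_genome <- Biostrings::reverseComplement(sim$genome)
  names(flipped_genome) <- "chr1"
  flipped_genes <- dplyr::mutate(
    sim$genes,
    new_start = L - .data$end + 1, new_end = L - .data$start + 1,
    strand = ifelse(.data$strand == "+", "-", "+"),
    start = .data$new_start, end = .data$new_end
  )[, c("gene_id", "seqnames", "start", "end", "strand")]
  g2 <- design_guides(flipped_genome, flipped_genes)
  expect_identical(sort(paste(g1$spacer, g1$pam)),
                   sort(paste(g2$spacer, g2$pam)))
  expect_identical(g1$cut_offset[order(g1$guide_id)],
                   g2$cut_offset[order(g2$guide_id)])
})

test_that("oligo emission substitutes the spacer into the template once", {
  guides <- tibble::tibble(guide_id = "g1_g1", gene_id = "g1",
                           spacer = "ACGTACGTACGTACGTACGT",
                           pam = "CGG", strand = "+", cut_offset = 21L)
  ol <- emit_oligos(guides, template = "AAA{SPACER}TTT")
  expect_equal(ol$oligo, "AAAACGTACGTACGTACGTACGTTTT")
  expect_equal(nchar(ol$oligo), 26)
  expect_equal(ol$oligo_id, "g1.g1_g1")
  expect_error(emit_oligos(guides, template = "AAATTT"),
               class = "secrescreen_config_error")
  expect_error(emit_oligos(guides, template = "{SPACER}{SPACER}"),
               class = "secrescreen_config_error")
  # empty table: empty result, no error
  expect_equal(nrow(emit_oligos(guides[0, ])), 0)
})

test_that("a full library emits at most guides_per_gene oligos per gene, all unique", {
  sim <- simulate_genome(sim_config(n_genes = 30, seed = 43))
  g <- design_guides(sim, params = design_params(guides_per_gene = 4))
  ol <- emit_oligos(g)
  expect_lte(nrow(ol), 30 * 4)
  expect_false(anyDuplicated(ol$oligo_id) > 0)
})
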