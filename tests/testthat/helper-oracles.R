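# Independent oracles used across tests. These deliberately use different
# algorithms (direct enumeration, brute-force scans) from the package
# implementations they check.

# one-sided sup of ECDF_x - ECDF_y by direct evaluation at every pooled
# point with double loops (no sorting tricks shared with the implementation)
brute_ks_d_plus <- function(x, y) {
  pts <- c(x, y)
  d <- vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))
  max(0, d)
}

# classic unweighted running-sum enrichment statistic computed from hit /
# miss ECDF differences position by position
brute_unweighted_es <- function(ranked_ids, set) {
  hit <- ranked_ids %in% set
  nh <- sum(hit)
  nm <- length(ranked_ids) - nh
  p_hit <- cumsum(hit) / nh
  p_miss <- cumsum(!hit) / nm
  dev <- p_hit - p_miss
  pos <- max(dev, 0)
  neg <- min(dev, 0)
  # same tie-break as the package: the positive branch wins exact ties
  if (pos >= -neg - 1e-12) pos else neg
}

# exhaustive-order guide-count oracle: count spacer occurrences after the
# anchor with plain string operations, one read at a time
brute_count <- function(reads, spacers, anchor) {
  counts <- setNames(integer(length(spacers)), spacers)
  unmapped <- 0L
  for (r in reads) {
    i <- regexpr(anchor, r, fixed = TRUE)
    matched <- FALSE
    if (i > 0) {
      sp <- substr(r, i + nchar(anchor), i + nchar(anchor) + nchar(spacers[1]) - 1)
      if (nchar(sp) == nchar(spacers[1]) && sp %in% spacers) {
        counts[sp] <- counts[sp] + 1L
        matched <- TRUE
      }
    }
    if (!matched) unmapped <- unmapped + 1L
  }
  list(counts = counts, unmapped = unmapped)
}

# small guide library for counting tests
toy_library <- function() {
  tibble::tibble(
    guide_id = c("gA", "gB", "gC"),
    gene_id = c("geneA", "geneB", "geneC"),
    spacer = c("ACGTACGTACGTACGTACGT",
               "TTTTCCCCGGGGAAAATTCC",
               "GACGATTACAGGACCAGTCA")
  )
}

write_fastq <- function(reads, path) {
  if (length(reads) == 0) {
    file.create(path)
    return(path)
  }
  writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n",
                    strrep("I", nchar(reads))), path)
  path
}

# simulated acceptance-scale screen shared by essentiality tests; cached so
# the suite pays for it once
acceptance_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config()  # packaged defaults: 361 genes, 6 guides, seed 17
      genes <- sprintf("g%03d", seq_len(cfg$n_genes))
      guides <- tibble::tibble(
        guide_id = paste0(rep(genes, each = cfg$guides_per_gene), "_g",
                          seq_len(cfg$guides_per_gene)),
        gene_id = rep(genes, each = cfg$guides_per_gene)
      )
      truth <- simulate_truth(genes, cfg)
      counts <- simulate_screen_counts(guides, truth, cfg)
      fit <- score_essentiality(guide_lfc(counts))
      cache <<- list(cfg = cfg, truth = truth, counts = counts, fit = fit)
    }
    cache
  }
})
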