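#' Plant ground truth for a simulated knockout screen
#'
#' Marks a random `frac_essential` fraction of genes as essential with
#' fitness factor `1 / depletion_factor` (all other genes have fitness 1),
#' and assigns each gene a true secretion status used when emitting
#' signal-peptide prediction tables. The number of essential genes is
#' `round(frac_essential * n_genes)`.
#'
#' @param gene_ids Character vector of gene ids.
#' @param config A [sim_config()].
#' @param frac_secreted Fraction of genes whose protein carries a true
#'   signal peptide in the simulated predictions.
#' @return A tibble with `gene_id`, `essential` (logical), `fitness`
#'   (expected post/pre abundance ratio), `secreted` (logical).
#' @export
simulate_truth <- function(gene_ids, config = sim_config(),
                           frac_secreted = 0.7) {
  stopifnot(inherits(config, "sim_config"))
  check_fraction(frac_secreted, "frac_secreted")
  n <- length(gene_ids)
  n_ess <- round(config$frac_essential * n)
  with_seed(config$seed + 1L, {
    essential <- gene_ids %in% sample(gene_ids, n_ess)
    secreted <- as.logical(runif(n) < frac_secreted)
    tibble(
      gene_id = gene_ids,
      essential = essential,
      fitness = ifelse(essential, 1 / config$depletion_factor, 1),
      secreted = secreted
    )
  })
}

#' Simulate pre- and post-selection guide counts
#'
#' Draws negative-binomial read counts for every guide in the library.
#' Per-guide baseline means are lognormal around `nb_mean` (sd 0.5 on the
#' log2 scale), emulating the skew of real pooled libraries; post-selection
#' means are multiplied by the gene's fitness factor, so guides hitting
#' essential genes deplete by `depletion_factor` in expectation. Count
#' variance follows `mu + dispersion * mu^2` (Poisson when dispersion is 0).
#' Fixing the seed makes the tables byte-identical across runs.
#'
#' @param guides A guide table with `guide_id` and `gene_id` (e.g. from
#'   [design_guides()]).
#' @param truth A tibble from [simulate_truth()] covering every gene in
#'   `guides`; its `fitness` column drives depletion, so partial
#'   essentiality can be planted by editing it.
#' @param config A [sim_config()].
#' @return A tibble with `guide_id`, `gene_id`, and integer count columns
#'   `pre` and `post`.
#' @examples
#' g <- tibble::tibble(guide_id = c("a_g1", "a_g2", "b_g1", "b_g2"),
#'                     gene_id = c("a", "a", "b", "b"))
#' tr <- tibble::tibble(gene_id = c("a", "b"), essential = c(TRUE, FALSE),
#'                      fitness = c(1 / 8, 1), secreted = TRUE)
#' simulate_screen_counts(g, tr, sim_config(n_genes = 2, seed = 3))
#' @export
simulate_screen_counts <- function(guides, truth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(guides) == 0) {
    abort("`guides` is empty: nothing to simulate.",
          class = "secrescreen_data_error")
  }
  missing <- setdiff(guides$gene_id, truth$gene_id)
  if (length(missing) > 0) {
    abort(paste0("guides target genes absent from `truth`: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "secrescreen_data_error")
  }
  fitness <- truth$fitness[match(guides$gene_id, truth$gene_id)]
  n <- nrow(guides)
  with_seed(config$seed + 2L, {
    mu <- config$nb_mean * 2^rnorm(n, 0, 0.5)
    pre <- rcounts(n, mu, config$nb_dispersion)
    post <- rcounts(n, mu * fitness, config$nb_dispersion)
    tibble(
      guide_id = guides$guide_id,
      gene_id = guides$gene_id,
      pre = pre,
      post = post
    )
  })
}

rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Emit simulated amplicon reads for one sample as FASTQ
#'
#' Writes `counts[[sample]]` reads per guide, each read being a 5' pad, the
#' constant anchor, the guide spacer, and a 3' pad, optionally corrupted by
#' uniform substitution noise. Read order is shuffled so downstream counting
#' cannot rely on grouping.
#'
#' @param counts A count table with `guide_id` and the column named by
#'   `sample`.
#' @param guides Guide table with `guide_id` and `spacer`.
#' @param sample Name of the count column to emit.
#' @param path Output FASTQ path (plain text; counting also accepts `.gz`).
#' @param anchor Constant sequence placed immediately 5' of the spacer.
#' @param error_rate Per-base substitution probability in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return `path`, invisibly.
#' @export
emit_screen_fastq <- function(counts, guides, sample, path,
                              anchor = "GACGAAACACC",
                              error_rate = 0, seed = 1) {
  check_fraction(error_rate, "error_rate")
  stopifnot(sample %in% names(counts))
  spacer <- guides$spacer[match(counts$guide_id, guides$guide_id)]
  if (anyNA(spacer)) {
    abort("some guides in `counts` are missing from `guides`.",
          class = "secrescreen_data_error")
  }
  n_reads <- counts[[sample]]
  with_seed(seed, {
    reads <- paste0("TTGT", anchor, rep(spacer, n_reads), "GTTTAAGAGC")
    if (length(reads) > 0 && error_rate > 0) {
      reads <- mutate_reads(reads, error_rate)
    }
    reads <- sample(reads)
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (length(reads) > 0) {
      qual <- strrep("I", nchar(reads))
      writeLines(paste0("@read", seq_along(reads), "\n", reads, "\n+\n", qual),
                 con)
    }
  })
  invisible(path)
}

# uniform substitution noise over a character vector of reads
mutate_reads <- function(reads, rate) {
  chars <- strsplit(reads, "")
  vapply(chars, function(x) {
    hit <- runif(length(x)) < rate
    if (any(hit)) {
      x[hit] <- vapply(x[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(x, collapse = "")
  }, character(1))
}

#' Emit a simulated signal-peptide prediction table
#'
#' Writes a short-format prediction TSV (comment header lines, id column,
#' `SP(Sec/SPI)` probability column) for a set of genes: truly secreted
#' proteins get high Sec/SPI probabilities (mostly above 0.5), others low.
#'
#' @param truth A tibble from [simulate_truth()].
#' @param path Output TSV path.
#' @param seed Integer RNG seed.
#' @return `path`, invisibly.
#' @export
emit_signalp_tsv <- function(truth, path, seed = 1) {
  with_seed(seed, {
    p <- ifelse(truth$secreted,
                stats::rbeta(nrow(truth), 8, 2),
                stats::rbeta(nrow(truth), 1.5, 8))
    preds <- tibble(protein_id = truth$gene_id, sp_prob = round(p, 6))
    write_signalp(preds, path)
  })
  invisible(path)
}
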