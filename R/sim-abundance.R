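#' Simulate paired per-protein abundances across two cultivation phases
#'
#' Draws per-protein log10 relative abundances for the biomass-accumulation
#' (`outgrowth`, glycerol) and induction (`production`, methanol) phases
#' from a bivariate normal with correlation parameter `rho`, emulating the
#' observation that most secreted proteins keep similar abundance across the
#' two carbon sources. The sample Pearson correlation converges to `rho` as
#' `n` grows; at `rho = 1` the pairs are exactly collinear.
#'
#' @param n Number of proteins (>= 2).
#' @param rho Target Pearson correlation in `[-1, 1]`.
#' @param seed Integer RNG seed.
#' @param mean_log10,sd_log10 Marginal mean and standard deviation of the
#'   log10 abundances (defaults emulate summed peptide areas around 1e6).
#' @return A tidy tibble with one row per protein and phase: `protein_id`,
#'   `phase` (`outgrowth`/`production`), `rel_abundance` (log10 scale).
#' @examples
#' ab <- simulate_abundance(134, rho = 0.93, seed = 7)
#' abundance_correlation(ab)
#' @export
simulate_abundance <- function(n, rho = 0.93, seed = 1,
                               mean_log10 = 6, sd_log10 = 0.8) {
  check_count(n, "n", min = 2)
  check_fraction(rho, "rho", lo = -1, hi = 1)
  with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    a <- mean_log10 + sd_log10 * z1
    b <- mean_log10 + sd_log10 * (rho * z1 + sqrt(1 - rho^2) * z2)
    ids <- sprintf("P%04d", seq_len(n))
    tibble(
      protein_id = rep(ids, 2),
      phase = rep(c("outgrowth", "production"), each = n),
      rel_abundance = c(a, b)
    )
  })
}

#' Write a simulated abundance table as a replicate-level AUC TSV
#'
#' Converts log10 relative abundances back to total area-under-curve values
#' and splits each total across `n_replicates` replicate columns (random
#' proportions), producing the TSV dialect [load_abundance()] consumes. This
#' closes the loop between the simulator and the secretome module:
#' `load_abundance()` recovers `rel_abundance = log10(sum of replicates)`.
#'
#' @param abundance A tibble from [simulate_abundance()].
#' @param path Output TSV path.
#' @param n_replicates Number of replicate AUC columns.
#' @param seed Integer RNG seed for the replicate split.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(abundance, path, n_replicates = 4, seed = 1) {
  check_count(n_replicates, "n_replicates", min = 1)
  with_seed(seed, {
    total <- 10^abundance$rel_abundance
    w <- matrix(runif(nrow(abundance) * n_replicates),
                nrow = nrow(abundance))
    w <- w / rowSums(w)
    auc <- w * total
    colnames(auc) <- sprintf("auc_%d", seq_len(n_replicates))
    out <- bind_cols(
      abundance[, c("protein_id", "phase")],
      as_tibble(auc)
    )
    readr::write_tsv(out, path)
  })
  invisible(path)
}
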