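#' Simulation configuration for the packaged screen emulation
#'
#' Bundles every tunable of the synthetic-data module: genome layout, pooled
#' library shape, negative-binomial count noise, gene-level depletion for the
#' planted essential subset, and the cross-phase correlation of simulated
#' protein abundances. The defaults are the packaged "acceptance simulation":
#' a 361-gene secretome-sized universe with 6 guides per gene, 10% essential
#' genes depleted 8-fold, negative-binomial counts with mean 500 and
#' dispersion 0.1, and paired log10 abundances at correlation 0.93.
#'
#' @param n_genes Number of annotated coding sequences to simulate.
#' @param cds_len_range Length range (nt) for simulated CDSs; lengths are
#'   rounded to multiples of 3 and must be at least 23 nt so a 20-nt spacer
#'   plus NGG PAM fits.
#' @param gc_content Genome GC fraction in `[0, 1]`.
#' @param guides_per_gene Guides simulated per gene.
#' @param frac_essential Fraction of genes planted as essential.
#' @param depletion_factor Expected pre/post count ratio for guides hitting
#'   essential genes; must be >= 1 (1 means no depletion, the exchangeable
#'   null).
#' @param nb_mean Expected pre-selection read count per guide.
#' @param nb_dispersion Negative-binomial dispersion; count variance is
#'   `mu + dispersion * mu^2`. Zero gives Poisson counts.
#' @param abundance_rho Target Pearson correlation of paired per-protein
#'   log10 abundances across cultivation phases.
#' @param n_replicates Replicate cultivations per abundance measurement.
#' @param intergenic_len_range Length range (nt) of intergenic spacers
#'   between simulated CDSs.
#' @param seed Integer RNG seed; fixing it makes every simulated artifact
#'   byte-identical across runs.
#'
#' @return A list of validated parameters with class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 1)
#' cfg$depletion_factor
#' @export
sim_config <- function(n_genes = 361,
                       cds_len_range = c(300, 1800),
                       gc_content = 0.41,
                       guides_per_gene = 6,
                       frac_essential = 0.10,
                       depletion_factor = 8,
                       nb_mean = 500,
                       nb_dispersion = 0.1,
                       abundance_rho = 0.93,
                       n_replicates = 4,
                       intergenic_len_range = c(150, 400),
                       seed = 17) {
  check_count(n_genes, "n_genes", min = 0)
  if (!is.numeric(cds_len_range) || length(cds_len_range) != 2 ||
      any(is.na(cds_len_range)) || cds_len_range[1] > cds_len_range[2]) {
    abort("`cds_len_range` must be a non-decreasing length-2 numeric vector.",
          class = "secrescreen_config_error")
  }
  if (cds_len_range[1] < 23) {
    abort("`cds_len_range` lengths must be >= 23 nt (spacer + PAM must fit).",
          class = "secrescreen_config_error")
  }
  check_fraction(gc_content, "gc_content")
  check_count(guides_per_gene, "guides_per_gene", min = 1)
  check_fraction(frac_essential, "frac_essential")
  if (!is.numeric(depletion_factor) || length(depletion_factor) != 1 ||
      is.na(depletion_factor) || depletion_factor < 1) {
    abort("`depletion_factor` must be a single number >= 1.",
          class = "secrescreen_config_error")
  }
  check_positive(nb_mean, "nb_mean")
  check_fraction(nb_dispersion, "nb_dispersion", lo = 0, hi = Inf)
  check_fraction(abundance_rho, "abundance_rho", lo = -1, hi = 1)
  check_count(n_replicates, "n_replicates", min = 1)
  check_count(seed, "seed")

  structure(
    list(
      n_genes = as.integer(n_genes),
      cds_len_range = as.integer(cds_len_range),
      gc_content = gc_content,
      guides_per_gene = as.integer(guides_per_gene),
      frac_essential = frac_essential,
      depletion_factor = depletion_factor,
      nb_mean = nb_mean,
      nb_dispersion = nb_dispersion,
      abundance_rho = abundance_rho,
      n_replicates = as.integer(n_replicates),
      intergenic_len_range = as.integer(intergenic_len_range),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = "..")))
  }
  invisible(x)
}
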