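#' One-sided two-sample Kolmogorov-Smirnov depletion test
#'
#' Tests whether a gene's guide log2 fold changes are stochastically
#' smaller than the background distribution (i.e. the gene's guides are
#' depleted). The statistic is the one-sided supremum of
#' `ECDF_gene(x) - ECDF_background(x)`, evaluated at every pooled data
#' point (right-continuous convention handles ties). The asymptotic
#' one-sided p-value is `exp(-2 * m * D^2)` with
#' `m = n_g * n_b / (n_g + n_b)`, clamped to `(0, 1]`; an exact
#' permutation p-value is available for small guide counts.
#'
#' @param gene_lfcs Numeric vector of the gene's guide LFCs (>= 2 values).
#' @param background_lfcs Numeric vector of background LFCs (>= 2 values).
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Number of label permutations when
#'   `method = "permutation"`.
#' @param seed RNG seed for the permutation null (required for that
#'   method).
#' @return A list with `statistic` (D in `[0, 1]`), `p_value`, `n_gene`,
#'   `n_background`, `method`.
#' @examples
#' ks_depletion_test(c(-3, -2), c(0, 1, 2))  # D = 1, p = exp(-2.4)
#' @export
ks_depletion_test <- function(gene_lfcs, background_lfcs,
                              method = c("asymptotic", "permutation"),
                              n_perm = 1999, seed = NULL) {
  method <- match.arg(method)
  if (length(gene_lfcs) < 2 || length(background_lfcs) < 2) {
    abort("both samples need at least 2 values.",
          class = "secrescreen_data_error")
  }
  if (!all(is.finite(gene_lfcs)) || !all(is.finite(background_lfcs))) {
    abort("non-finite LFC values.", class = "secrescreen_data_error")
  }
  D <- ks_d_plus(gene_lfcs, background_lfcs)
  ng <- length(gene_lfcs)
  nb <- length(background_lfcs)
  if (method == "asymptotic") {
    m <- ng * nb / (ng + nb)
    p <- min(1, exp(-2 * m * D^2))
  } else {
    if (is.null(seed)) {
      abort("`seed` is required for the permutation method.",
            class = "secrescreen_config_error")
    }
    pooled <- c(gene_lfcs, background_lfcs)
    p <- with_seed(seed, {
      hits <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(ng + nb, ng)
        ks_d_plus(pooled[idx], pooled[-idx]) >= D
      }, logical(1))
      (1 + sum(hits)) / (n_perm + 1)
    })
  }
  list(statistic = D, p_value = p, n_gene = ng, n_background = nb,
       method = method)
}

# one-sided sup of ECDF_x - ECDF_y over the pooled points
ks_d_plus <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  sx <- sort(x)
  sy <- sort(y)
  fx <- findInterval(pts, sx) / length(x)
  fy <- findInterval(pts, sy) / length(y)
  max(0, max(fx - fy))
}
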