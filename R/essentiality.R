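#' Score gene essentiality from guide log2 fold changes
#'
#' For each gene, compares the gene's guide LFC distribution against a
#' background of all guides from other genes (leave-one-gene-out) with the
#' one-sided KS depletion test, and defines the essentiality score as
#' `1 - p`. Scores lie in `[0, 1]` and depend only on the ranks of the
#' LFCs; genes with fewer than `min_guides` guides are reported with a
#' missing score and no call. Results are ordered by score (descending,
#' ties broken by gene id).
#'
#' @param lfc A tibble with `gene_id` and `lfc` per guide (from
#'   [compute_lfc()] / [guide_lfc()]).
#' @param min_guides Minimum guides for a gene to be scored (default 2).
#' @param threshold Score above which a gene is called essential
#'   (strictly greater; default 0.5).
#' @param method p-value method passed to [ks_depletion_test()].
#' @param n_perm,seed Permutation settings when
#'   `method = "permutation"`.
#' @return An object of class `"essentiality"` with a `results` tibble
#'   (`gene_id`, `n_guides`, `ks_stat`, `p_value`, `score`,
#'   `essential_call`) and the parameters used. Use [tidy()] / [glance()]
#'   to extract tibbles and [autoplot()] to plot.
#' @examples
#' lfc <- tibble::tibble(
#'   gene_id = rep(c("a", "b"), each = 3),
#'   lfc = c(-3, -2.5, -2.8, 0.1, -0.2, 0.3)
#' )
#' fit <- score_essentiality(lfc)
#' tidy(fit)
#' @export
score_essentiality <- function(lfc, min_guides = 2, threshold = 0.5,
                               method = c("asymptotic", "permutation"),
                               n_perm = 1999, seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("gene_id", "lfc") %in% names(lfc)))
  check_count(min_guides, "min_guides", min = 2)
  check_fraction(threshold, "threshold")

  genes <- split(lfc$lfc, lfc$gene_id)
  n_guides <- lengths(genes)
  if (all(n_guides < min_guides)) {
    abort("every gene has fewer than `min_guides` guides; nothing to score.",
          class = "secrescreen_data_error")
  }
  all_lfc <- lfc$lfc
  gene_of <- lfc$gene_id

  res <- purrr::map_dfr(names(genes), function(g) {
    x <- genes[[g]]
    if (length(x) < min_guides) {
      return(tibble(gene_id = g, n_guides = length(x),
                    ks_stat = NA_real_, p_value = NA_real_,
                    score = NA_real_, essential_call = NA))
    }
    bg <- all_lfc[gene_of != g]
    if (length(bg) < 2) {
      return(tibble(gene_id = g, n_guides = length(x),
                    ks_stat = NA_real_, p_value = NA_real_,
                    score = NA_real_, essential_call = NA))
    }
    ks <- ks_depletion_test(x, bg, method = method, n_perm = n_perm,
                            seed = if (is.null(seed)) NULL else seed)
    tibble(gene_id = g, n_guides = length(x),
           ks_stat = ks$statistic, p_value = ks$p_value,
           score = 1 - ks$p_value,
           essential_call = (1 - ks$p_value) > threshold)
  })
  res <- arrange(res, desc(.data$score), .data$gene_id)

  structure(
    list(results = res,
         params = list(min_guides = min_guides, threshold = threshold,
                       method = method, n_perm = n_perm, seed = seed)),
    class = "essentiality"
  )
}

#' @export
print.essentiality <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<essentiality> %d genes (%d scored), %d called essential at score > %.2f\n",
    g$n_genes, g$n_scored, g$n_essential, x$params$threshold))
  print(head(x$results, 10))
  invisible(x)
}

#' @rdname score_essentiality
#' @param x An `"essentiality"` object.
#' @param ... Unused.
#' @export
tidy.essentiality <- function(x, ...) {
  x$results
}

#' @rdname score_essentiality
#' @export
glance.essentiality <- function(x, ...) {
  r <- x$results
  tibble(
    n_genes = nrow(r),
    n_scored = sum(!is.na(r$score)),
    n_essential = sum(r$essential_call, na.rm = TRUE),
    n_unclassified = sum(is.na(r$score)),
    threshold = x$params$threshold,
    min_guides = x$params$min_guides,
    method = x$params$method
  )
}

#' @rdname score_essentiality
#' @param object An `"essentiality"` object.
#' @export
autoplot.essentiality <- function(object, ...) {
  r <- filter(object$results, !is.na(.data$score)) %>%
    mutate(rank = rank(-.data$score, ties.method = "first"))
  ggplot(r, aes(.data$rank, .data$score, colour = .data$essential_call)) +
    geom_point(size = 1) +
    geom_hline(yintercept = object$params$threshold, linetype = 2) +
    scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "#7f8c8d"),
                        name = "essential call") +
    labs(x = "gene rank", y = "essentiality score (1 - p)") +
    theme_minimal()
}

#' Partition genes by essentiality call
#'
#' Strictly-greater comparison against the threshold: `score > threshold`
#' is essential, `score <= threshold` non-essential, missing scores
#' unclassified (a score of exactly 0.5 is non-essential).
#'
#' @param results An `"essentiality"` object or its `results` tibble.
#' @param threshold Score threshold (default 0.5).
#' @return A tibble with `gene_id`, `score`, `essential_class` (factor:
#'   `essential`, `non_essential`, `unclassified`).
#' @export
classify_essential <- function(results, threshold = 0.5) {
  if (inherits(results, "essentiality")) results <- results$results
  check_fraction(threshold, "threshold")
  results %>%
    transmute(
      gene_id = .data$gene_id,
      score = .data$score,
      essential_class = factor(
        dplyr::case_when(
          is.na(.data$score) ~ "unclassified",
          .data$score > threshold ~ "essential",
          TRUE ~ "non_essential"
        ),
        levels = c("essential", "non_essential", "unclassified")
      )
    )
}

#' Write essentiality results to TSV
#' @param fit An `"essentiality"` object or results tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(fit, path) {
  if (inherits(fit, "essentiality")) fit <- fit$results
  readr::write_tsv(fit, path)
  invisible(path)
}
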