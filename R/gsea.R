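#' Read gene sets from a GMT file
#'
#' @param path GMT path (one set per line: name, description, member ids).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Weighted running-sum gene-set enrichment on essentiality scores
#'
#' Ranks all genes by score (descending, ties broken by gene id for
#' determinism) and walks the list with a running sum: hitting a set
#' member adds `|score|^exponent / sum(|score_hits|^exponent)`, missing
#' subtracts `1 / (N - n_set)`. The enrichment score (ES) is the signed
#' maximal deviation of that walk. The null distribution comes from
#' permuting gene labels (re-drawing the set's positions in the fixed
#' ranking); NES divides ES by the mean |null ES| of the same sign, the
#' permutation p-value uses the same-sign null with a +1 correction (so
#' `p >= 1/(n_perm + 1)`), and q-values are Benjamini-Hochberg across
#' sets.
#'
#' @param scores A tibble with `gene_id` and `score`, or an
#'   `"essentiality"` object.
#' @param gene_sets Named list of character vectors (e.g. [read_gmt()]).
#' @param weight_exponent Hit-weight exponent (0 recovers the classic
#'   unweighted KS running sum; default 1).
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed Integer RNG seed for the permutation null (mandatory).
#' @param min_set_size Sets with fewer members in the scored universe are
#'   dropped (default 5).
#' @return An object of class `"gsea"` with a `results` tibble (`set`,
#'   `size`, `es`, `nes`, `p_perm`, `fdr`), the ranking used, the
#'   filtered sets, and parameters. Use [tidy()], [glance()],
#'   [autoplot()].
#' @export
weighted_gsea <- function(scores, gene_sets, weight_exponent = 1,
                          n_perm = 1000, seed, min_set_size = 5) {
  if (inherits(scores, "essentiality")) scores <- scores$results
  stopifnot(all(c("gene_id", "score") %in% names(scores)))
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for the permutation null.",
          class = "secrescreen_config_error")
  }
  check_count(n_perm, "n_perm", min = 1)
  check_count(min_set_size, "min_set_size", min = 1)

  ranking <- scores %>%
    filter(!is.na(.data$score)) %>%
    arrange(desc(.data$score), .data$gene_id)
  universe <- ranking$gene_id
  N <- length(universe)
  if (N == 0) {
    abort("empty scored universe.", class = "secrescreen_data_error")
  }
  sets <- lapply(gene_sets, function(s) intersect(s, universe))
  sets <- sets[lengths(sets) >= min_set_size]
  if (length(sets) == 0) {
    abort(sprintf("no gene set with >= %d members in the scored universe.",
                  min_set_size),
          class = "secrescreen_data_error")
  }

  w <- abs(ranking$score)^weight_exponent

  res <- with_seed(seed, {
    purrr::map_dfr(names(sets), function(nm) {
      hit_pos <- which(universe %in% sets[[nm]])
      es <- running_sum_es(hit_pos, w, N)
      null_es <- vapply(seq_len(n_perm), function(i) {
        running_sum_es(sample.int(N, length(hit_pos)), w, N)
      }, numeric(1))
      same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
      p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
      tibble(set = nm, size = length(hit_pos), es = es, nes = nes, p_perm = p)
    })
  })
  res$fdr <- p.adjust(res$p_perm, method = "BH")
  res <- arrange(res, desc(.data$nes))

  structure(
    list(results = res, ranking = ranking, gene_sets = sets,
         params = list(weight_exponent = weight_exponent, n_perm = n_perm,
                       seed = seed, min_set_size = min_set_size)),
    class = "gsea"
  )
}

# signed maximal deviation of the weighted running sum; hit_pos are the
# ranks of set members in the fixed ranking, w the |score|^exponent weights
running_sum_es <- function(hit_pos, w, N) {
  nh <- length(hit_pos)
  hit <- logical(N)
  hit[hit_pos] <- TRUE
  wr <- sum(w[hit])
  inc <- if (wr > 0) w / wr else rep(1 / nh, N)
  miss_dec <- if (N > nh) 1 / (N - nh) else 0
  steps <- ifelse(hit, inc, -miss_dec)
  cs <- cumsum(steps)
  pos <- max(cs, 0)
  neg <- min(cs, 0)
  # the positive branch wins (near-)exact |deviation| ties; the tolerance
  # absorbs cumsum rounding so the tie-break is stable
  if (pos >= -neg - 1e-12) pos else neg
}

#' @export
print.gsea <- function(x, ...) {
  cat(sprintf("<gsea> %d sets, %d-gene universe, %d permutations\n",
              nrow(x$results), nrow(x$ranking), x$params$n_perm))
  print(x$results, n = 10)
  invisible(x)
}

#' @rdname weighted_gsea
#' @param x,object A `"gsea"` object.
#' @param ... Unused.
#' @export
tidy.gsea <- function(x, ...) {
  x$results
}

#' @rdname weighted_gsea
#' @export
glance.gsea <- function(x, ...) {
  tibble(
    n_sets = nrow(x$results),
    n_genes = nrow(x$ranking),
    n_perm = x$params$n_perm,
    weight_exponent = x$params$weight_exponent,
    n_sig_fdr05 = sum(x$results$fdr < 0.05)
  )
}

#' @rdname weighted_gsea
#' @param set Which set to draw the running-sum profile for (default: the
#'   top set by NES).
#' @export
autoplot.gsea <- function(object, set = NULL, ...) {
  set <- set %||% object$results$set[1]
  if (!set %in% names(object$gene_sets)) {
    abort(sprintf("unknown set `%s`.", set),
          class = "secrescreen_config_error")
  }
  universe <- object$ranking$gene_id
  N <- length(universe)
  w <- abs(object$ranking$score)^object$params$weight_exponent
  hit_pos <- which(universe %in% object$gene_sets[[set]])
  hit <- logical(N); hit[hit_pos] <- TRUE
  wr <- sum(w[hit])
  inc <- if (wr > 0) w / wr else rep(1 / length(hit_pos), N)
  miss_dec <- if (N > length(hit_pos)) 1 / (N - length(hit_pos)) else 0
  cs <- cumsum(ifelse(hit, inc, -miss_dec))
  df <- tibble(rank = seq_len(N), running_sum = cs)
  ggplot(df, aes(.data$rank, .data$running_sum)) +
    geom_line(colour = "#2c7fb8") +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_rug(data = tibble(rank = hit_pos), aes(x = .data$rank),
             inherit.aes = FALSE, sides = "b", length = grid::unit(0.03, "npc")) +
    labs(title = set, x = "gene rank (by essentiality score)",
         y = "running enrichment") +
    theme_minimal()
}

#' Write enrichment results to TSV
#' @param fit A `"gsea"` object or results tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(fit, path) {
  if (inherits(fit, "gsea")) fit <- fit$results
  readr::write_tsv(fit, path)
  invisible(path)
}
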