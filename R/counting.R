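#' Count guides in amplicon FASTQ reads
#'
#' For each read, locates the first occurrence of the constant `anchor`
#' sequence (the cassette flank immediately 5' of the spacer), extracts the
#' following `spacer_len` nucleotides, and matches them against the library
#' spacers - exactly, or through a precomputed 1-mismatch neighbourhood
#' when `max_mismatches = 1`. Reads without the anchor, reads too short to
#' contain a full spacer after it, and unmatched (or ambiguous) spacers are
#' counted as unmapped. Per sample, mapped + unmapped always equals the
#' number of reads processed.
#'
#' @param fastq Character vector of FASTQ(.gz) paths, one per sample;
#'   names become sample names (file stems otherwise).
#' @param library Guide table with `guide_id`, `gene_id`, `spacer`
#'   (spacers must be unique and of equal length).
#' @param anchor Non-empty constant sequence 5' of the spacer.
#' @param max_mismatches 0 (exact, default) or 1 (neighbourhood lookup;
#'   slower to build, same matching speed).
#' @return A tibble with `guide_id`, `gene_id` and one integer count column
#'   per sample, carrying a `"totals"` attribute (see [count_totals()]).
#' @export
count_guides <- function(fastq, library, anchor, max_mismatches = 0) {
  stopifnot(is.character(anchor), length(anchor) == 1, nchar(anchor) > 0)
  if (!max_mismatches %in% c(0, 1)) {
    abort("`max_mismatches` must be 0 or 1.",
          class = "secrescreen_config_error")
  }
  spacers <- toupper(library$spacer)
  if (anyDuplicated(spacers)) {
    abort("duplicate spacers in library: guide assignment would be ambiguous.",
          class = "secrescreen_data_error")
  }
  sl <- unique(nchar(spacers))
  if (length(sl) != 1) {
    abort("library spacers must all have the same length.",
          class = "secrescreen_data_error")
  }

  lut <- if (max_mismatches == 1) mismatch_lut(spacers) else
    list(variant = spacers, gidx = seq_along(spacers))

  samples <- names(fastq) %||% tools::file_path_sans_ext(basename(fastq),
                                                         compression = TRUE)
  samples[samples == ""] <- tools::file_path_sans_ext(
    basename(fastq[samples == ""]), compression = TRUE)

  out <- tibble(guide_id = library$guide_id, gene_id = library$gene_id)
  totals <- tibble(sample = character(0), reads = integer(0),
                   mapped = integer(0), unmapped = integer(0))
  for (i in seq_along(fastq)) {
    reads <- read_fastq_seqs(fastq[[i]])
    n_reads <- length(reads)
    counts <- integer(nrow(library))
    if (n_reads > 0) {
      pos <- regexpr(anchor, reads, fixed = TRUE)
      start <- as.integer(pos) + nchar(anchor)
      ok <- pos > 0 & (start + sl - 1) <= nchar(reads)
      sp <- substr(reads[ok], start[ok], start[ok] + sl - 1)
      idx <- lut$gidx[match(sp, lut$variant)]
      counts <- tabulate(idx, nbins = nrow(library))
    }
    out[[samples[i]]] <- counts
    totals <- bind_rows(totals, tibble(
      sample = samples[i], reads = n_reads,
      mapped = sum(counts), unmapped = n_reads - sum(counts)
    ))
  }
  attr(out, "totals") <- totals
  class(out) <- c("guide_counts", class(out))
  out
}

# all 1-mismatch variants of each spacer; variants reachable from more than
# one guide are dropped as ambiguous (exact spacers always win)
mismatch_lut <- function(spacers) {
  sl <- nchar(spacers[1])
  bases <- c("A", "C", "G", "T")
  var_list <- lapply(seq_along(spacers), function(g) {
    s <- spacers[g]
    vars <- character(sl * 3)
    k <- 0
    for (p in seq_len(sl)) {
      orig <- substr(s, p, p)
      for (b in setdiff(bases, orig)) {
        k <- k + 1
        v <- s
        substr(v, p, p) <- b
        vars[k] <- v
      }
    }
    vars[seq_len(k)]
  })
  variant <- c(spacers, unlist(var_list))
  gidx <- c(seq_along(spacers),
            rep(seq_along(spacers), lengths(var_list)))
  exact <- seq_along(spacers)
  dup <- variant %in% variant[duplicated(variant)]
  keep <- !dup
  keep[exact] <- TRUE  # an exact spacer always assigns to its own guide
  list(variant = variant[keep], gidx = gidx[keep])
}

read_fastq_seqs <- function(path) {
  info <- file.size(path)
  if (is.na(info)) {
    abort(paste0("FASTQ file not found: ", path),
          class = "secrescreen_data_error")
  }
  if (info == 0) return(character(0))
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Per-sample read totals of a count table
#'
#' @param counts A `"guide_counts"` tibble from [count_guides()].
#' @return A tibble with `sample`, `reads`, `mapped`, `unmapped`.
#' @export
count_totals <- function(counts) {
  attr(counts, "totals")
}

#' Normalize guide counts to pseudocounted counts-per-million
#'
#' `norm = (count + pseudocount) / (mapped_total + pseudocount * n_guides)
#' * 1e6`, so each sample's normalized column sums to exactly 1e6 and zero
#' counts stay finite downstream. CPM is used instead of median-ratio
#' scaling because a depletion screen violates the mostly-unchanged
#' assumption when many genes drop out.
#'
#' @param counts A count tibble (`guide_id`, `gene_id`, sample columns).
#' @param pseudocount Added to every count (default 0.5).
#' @return A tibble of the same shape with normalized sample columns.
#' @export
normalize_counts <- function(counts, pseudocount = 0.5) {
  check_positive(pseudocount, "pseudocount")
  out <- as_tibble(counts)
  sample_cols <- setdiff(names(out), c("guide_id", "gene_id"))
  n <- nrow(out)
  for (s in sample_cols) {
    tot <- sum(out[[s]])
    if (tot <= 0) {
      abort(sprintf("sample `%s` has zero mapped reads.", s),
            class = "secrescreen_data_error")
    }
    out[[s]] <- (out[[s]] + pseudocount) / (tot + pseudocount * n) * 1e6
  }
  out
}

#' Guide-level log2 fold changes between two samples
#'
#' `lfc = log2(post_norm) - log2(pre_norm)` on normalized counts; the
#' pseudocount in [normalize_counts()] guarantees finite values, and a
#' guide at zero counts in both samples of equal depth has lfc 0 exactly.
#' Swapping `pre` and `post` negates every lfc.
#'
#' @param normalized A normalized count tibble from [normalize_counts()].
#' @param pre,post Names of the pre- and post-selection sample columns.
#' @return A tibble with `guide_id`, `gene_id`, `pre_norm`, `post_norm`,
#'   `lfc`.
#' @export
compute_lfc <- function(normalized, pre = "pre", post = "post") {
  for (col in c(pre, post)) {
    if (!col %in% names(normalized)) {
      abort(sprintf("sample column `%s` not found.", col),
            class = "secrescreen_data_error")
    }
  }
  if (anyNA(normalized[[pre]]) || anyNA(normalized[[post]])) {
    abort("missing normalized counts: every guide must be present in both samples.",
          class = "secrescreen_data_error")
  }
  tibble(
    guide_id = normalized$guide_id,
    gene_id = normalized$gene_id,
    pre_norm = normalized[[pre]],
    post_norm = normalized[[post]],
    lfc = log2(normalized[[post]]) - log2(normalized[[pre]])
  )
}

#' Normalize and compute log2 fold changes in one step
#'
#' @inheritParams normalize_counts
#' @inheritParams compute_lfc
#' @param counts A raw count tibble.
#' @return See [compute_lfc()].
#' @export
guide_lfc <- function(counts, pre = "pre", post = "post", pseudocount = 0.5) {
  compute_lfc(normalize_counts(counts, pseudocount), pre, post)
}
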