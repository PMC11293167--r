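## internal helpers shared across modules

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# scalar checks -------------------------------------------------------------

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lo, hi),
          class = "secrescreen_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min),
          class = "secrescreen_config_error")
  }
  invisible(as.integer(x))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name),
          class = "secrescreen_config_error")
  }
  invisible(x)
}

# random DNA of given GC content, as a single string
random_dna <- function(n, gc_content) {
  if (n == 0) return("")
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

gc_fraction <- function(seq) {
  bases <- strsplit(toupper(seq), "")[[1]]
  mean(bases %in% c("G", "C"))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}
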