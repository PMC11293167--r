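#' sgRNA design parameters
#'
#' @param spacer_len Spacer length in nt (SpCas9 default, 20).
#' @param pam PAM as an IUPAC pattern 5'->3' on the protospacer strand
#'   (default `NGG`).
#' @param cds_window_frac Fraction of the 5' portion of each CDS searched
#'   for cut sites; early cuts favour frameshift knockouts (default 0.5).
#' @param gc_min,gc_max Allowed spacer GC fraction (inclusive bounds).
#' @param forbid_homopolymer Subsequence that disqualifies a spacer
#'   (default `TTTT`, a Pol III terminator).
#' @param guides_per_gene Maximum guides emitted per gene.
#' @return A validated list with class `"design_params"`.
#' @export
design_params <- function(spacer_len = 20, pam = "NGG", cds_window_frac = 0.5,
                          gc_min = 0.2, gc_max = 0.8,
                          forbid_homopolymer = "TTTT", guides_per_gene = 4) {
  check_count(spacer_len, "spacer_len", min = 10)
  stopifnot(is.character(pam), length(pam) == 1, nchar(pam) >= 2)
  if (!is.numeric(cds_window_frac) || cds_window_frac <= 0 ||
      cds_window_frac > 1) {
    abort("`cds_window_frac` must be in (0, 1].",
          class = "secrescreen_config_error")
  }
  check_fraction(gc_min, "gc_min")
  check_fraction(gc_max, "gc_max")
  if (gc_min >= gc_max) {
    abort("`gc_min` must be smaller than `gc_max`.",
          class = "secrescreen_config_error")
  }
  check_count(guides_per_gene, "guides_per_gene", min = 1)
  structure(
    list(spacer_len = as.integer(spacer_len), pam = toupper(pam),
         cds_window_frac = cds_window_frac, gc_min = gc_min, gc_max = gc_max,
         forbid_homopolymer = toupper(forbid_homopolymer),
         guides_per_gene = as.integer(guides_per_gene)),
    class = "design_params"
  )
}

#' Design sgRNA spacers against annotated coding sequences
#'
#' Scans the 5' window of each CDS (both strands) for PAM sites, extracts
#' the `spacer_len`-nt protospacer immediately 5' of each PAM, and filters
#' candidates by GC content, homopolymer content, and genome-wide
#' uniqueness of the full spacer+PAM sequence (exact occurrence count of 1
#' across both genome strands). Candidates are ranked by cut position
#' (5'-most first, sense strand before antisense at ties) and up to
#' `guides_per_gene` are kept per gene. The Cas9 blunt cut is placed 3 nt
#' 5' of the PAM, between spacer positions 17 and 18; `cut_offset` is that
#' position in 1-based CDS coordinates.
#'
#' Genes for which no candidate survives the filters are reported via a
#' message and the `"no_guide_genes"` attribute of the result.
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param genes A CDS annotation tibble (`gene_id`, `seqnames`, `start`,
#'   `end`, `strand`) or GFF3 path.
#' @param gene_ids Genes to design against (default: all annotated genes);
#'   ids absent from the annotation are an error.
#' @param params A [design_params()].
#' @return A tibble with `guide_id`, `gene_id`, `spacer`, `pam`, `strand`
#'   (`+`/`-` relative to the CDS), `cut_offset`.
#' @export
design_guides <- function(genome, genes = NULL, gene_ids = NULL,
                          params = design_params()) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genes)) genes <- read_cds_gff3(genes)
  if (inherits(genome, "sim_genome")) {
    genes <- genes %||% genome$genes
    genome <- genome$genome
  }
  if (is.null(genes)) {
    abort("`genes` is required unless `genome` is a sim_genome.",
          class = "secrescreen_config_error")
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  gene_ids <- gene_ids %||% genes$gene_id
  missing <- setdiff(gene_ids, genes$gene_id)
  if (length(missing) > 0) {
    abort(paste0("gene id(s) absent from annotation: ",
                 paste(missing, collapse = ", ")),
          class = "secrescreen_data_error")
  }

  # subject sequences for uniqueness counting: every contig plus its
  # reverse complement, searched once per candidate
  subjects <- c(genome, Biostrings::reverseComplement(genome))

  rows <- list()
  no_guides <- character(0)
  for (gid in gene_ids) {
    g <- genes[genes$gene_id == gid, ][1, ]
    contig <- genome[[g$seqnames]]
    cds <- Biostrings::subseq(contig, g$start, g$end)
    if (g$strand == "-") cds <- Biostrings::reverseComplement(cds)
    cand <- scan_cds_for_guides(cds, params)
    if (nrow(cand) > 0) {
      cand <- arrange(cand, .data$cut_offset, .data$strand)
      kept <- list()
      for (i in seq_len(nrow(cand))) {
        if (length(kept) >= params$guides_per_gene) break
        target <- paste0(cand$spacer[i], cand$pam[i])
        hits <- sum(Biostrings::vcountPattern(target, subjects))
        if (hits == 1) kept[[length(kept) + 1]] <- cand[i, ]
      }
      cand <- bind_rows(kept)
    }
    if (nrow(cand) == 0) {
      no_guides <- c(no_guides, gid)
    } else {
      cand$gene_id <- gid
      cand$guide_id <- sprintf("%s_g%d", gid, seq_len(nrow(cand)))
      rows[[gid]] <- cand
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(guide_id = character(0), gene_id = character(0),
                  spacer = character(0), pam = character(0),
                  strand = character(0), cut_offset = integer(0))
  } else {
    out <- select(out, "guide_id", "gene_id", "spacer", "pam", "strand",
                  "cut_offset")
  }
  if (length(no_guides) > 0) {
    inform(paste0("no passing guides for ", length(no_guides), " gene(s): ",
                  paste(head(no_guides, 10), collapse = ", ")))
  }
  attr(out, "no_guide_genes") <- no_guides
  out
}

# Enumerate PAM-adjacent spacer candidates within the 5' window of one
# CDS-oriented sequence. Returns spacer/pam/strand/cut_offset in 1-based
# CDS coordinates; strand is relative to the CDS.
scan_cds_for_guides <- function(cds, params) {
  L <- length(cds)
  window_len <- floor(params$cds_window_frac * L)
  sl <- params$spacer_len
  pl <- nchar(params$pam)
  pam_pat <- params$pam

  collect <- function(seq_obj, sense) {
    m <- Biostrings::matchPattern(pam_pat, seq_obj, fixed = FALSE)
    s <- Biostrings::start(m)
    s <- s[s >= sl + 1]
    if (length(s) == 0) return(NULL)
    if (sense) {
      cut <- s - 3L
    } else {
      cut <- L - s + 4L
    }
    keep <- cut >= 1 & cut <= window_len
    s <- s[keep]; cut <- cut[keep]
    if (length(s) == 0) return(NULL)
    seq_chr <- as.character(seq_obj)
    tibble(
      spacer = substring(seq_chr, s - sl, s - 1),
      pam = substring(seq_chr, s, s + pl - 1),
      strand = if (sense) "+" else "-",
      cut_offset = as.integer(cut)
    )
  }

  cand <- bind_rows(
    collect(cds, sense = TRUE),
    collect(Biostrings::reverseComplement(cds), sense = FALSE)
  )
  if (is.null(cand) || nrow(cand) == 0) {
    return(tibble(spacer = character(0), pam = character(0),
                  strand = character(0), cut_offset = integer(0)))
  }
  gc <- vapply(cand$spacer, gc_fraction, numeric(1), USE.NAMES = FALSE)
  cand <- cand[gc >= params$gc_min & gc <= params$gc_max &
                 !grepl(params$forbid_homopolymer, cand$spacer, fixed = TRUE), ]
  distinct(cand, .data$spacer, .data$pam, .keep_all = TRUE)
}

#' Expand guides into pooled-synthesis cassette oligos
#'
#' Substitutes each spacer into a cassette template containing the literal
#' placeholder `{SPACER}` exactly once, producing one synthesis oligo per
#' guide with stable ids (`gene_id.guide_id`).
#'
#' @param guides A guide table from [design_guides()].
#' @param template Cassette template with a single `{SPACER}` placeholder.
#'   The default carries generic Golden-Gate-style flanks; substitute your
#'   own cassette flanks for a real synthesis run.
#' @return A tibble with `oligo_id`, `gene_id`, `guide_id`, `oligo`.
#' @export
emit_oligos <- function(guides,
                        template = "CGTCTCACACC{SPACER}GTTTCGAGACG") {
  n_ph <- stringr::str_count(template, stringr::fixed("{SPACER}"))
  if (n_ph != 1) {
    abort(sprintf("template must contain the {SPACER} placeholder exactly once (found %d).",
                  n_ph),
          class = "secrescreen_config_error")
  }
  tibble(
    oligo_id = paste(guides$gene_id, guides$guide_id, sep = "."),
    gene_id = guides$gene_id,
    guide_id = guides$guide_id,
    oligo = stringr::str_replace(rep(template, nrow(guides)),
                                 stringr::fixed("{SPACER}"), guides$spacer)
  )
}

#' Write oligos as FASTA
#'
#' @param oligos A tibble from [emit_oligos()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(oligos, path) {
  seqs <- Biostrings::DNAStringSet(setNames(oligos$oligo, oligos$oligo_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a guide table to TSV
#' @param guides Guide tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides <- function(guides, path) {
  readr::write_tsv(guides, path)
  invisible(path)
}
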