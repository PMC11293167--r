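#' Simulate a small annotated genome
#'
#' Builds a single-contig genome of random sequence at the configured GC
#' content, with `n_genes` non-overlapping CDS features separated by random
#' intergenic spacers. CDS lengths are drawn from `cds_len_range`, rounded to
#' multiples of 3; strands are assigned at random. The result stands in for a
#' small fungal genome so guide design and screen quantification can be
#' exercised without external data. Fixing the seed makes the output
#' byte-identical across runs.
#'
#' CDS features are annotated as genomic spans only; no start/stop codon or
#' open-reading-frame realism is imposed (see the methods vignette).
#'
#' @param config A [sim_config()].
#' @return A list with class `"sim_genome"`:
#'   \describe{
#'     \item{genome}{A [Biostrings::DNAStringSet] with one contig, `chr1`.}
#'     \item{genes}{A tibble with `gene_id`, `seqnames`, `start`, `end`,
#'       `strand` (1-based inclusive coordinates, GFF3 convention).}
#'     \item{config}{The configuration used.}
#'   }
#' @examples
#' sim <- simulate_genome(sim_config(n_genes = 5, seed = 1))
#' sim$genes
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    cds_len <- if (n > 0) {
      len <- sample(seq(config$cds_len_range[1], config$cds_len_range[2]),
                    n, replace = TRUE)
      pmax(24L, as.integer(ceiling(len / 3) * 3))
    } else {
      integer(0)
    }
    inter_len <- sample(seq(config$intergenic_len_range[1],
                            config$intergenic_len_range[2]),
                        n + 1, replace = TRUE)
    strand <- if (n > 0) sample(c("+", "-"), n, replace = TRUE) else character(0)

    pieces <- character(2 * n + 1)
    starts <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      pieces[2 * i - 1] <- random_dna(inter_len[i], config$gc_content)
      pos <- pos + inter_len[i]
      starts[i] <- pos + 1L
      pieces[2 * i] <- random_dna(cds_len[i], config$gc_content)
      pos <- pos + cds_len[i]
    }
    pieces[2 * n + 1] <- random_dna(inter_len[n + 1], config$gc_content)

    contig <- paste(pieces, collapse = "")
    genes <- tibble(
      gene_id = sprintf("g%03d", seq_len(n)),
      seqnames = rep("chr1", n),
      start = starts,
      end = starts + cds_len - 1L,
      strand = strand
    )
    genome <- Biostrings::DNAStringSet(setNames(contig, "chr1"))
    structure(list(genome = genome, genes = genes, config = config),
              class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d contig(s), %s nt, %d CDS features\n",
              length(x$genome), sum(Biostrings::width(x$genome)),
              nrow(x$genes)))
  invisible(x)
}

#' Write a simulated (or any) genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet] or a `"sim_genome"`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (inherits(genome, "sim_genome")) genome <- genome$genome
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write CDS annotation to GFF3
#'
#' Emits one `CDS` feature per gene with the gene id in the `ID` attribute,
#' using 1-based inclusive coordinates.
#'
#' @param genes A tibble with `gene_id`, `seqnames`, `start`, `end`,
#'   `strand`, or a `"sim_genome"`.
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_cds_gff3 <- function(genes, path) {
  if (inherits(genes, "sim_genome")) genes <- genes$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seqnames,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$source <- "secrescreen"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read CDS features from a GFF3 file
#'
#' @param path GFF3 path. Only features of type `CDS` are kept; the gene id
#'   is taken from the `ID` attribute.
#' @return A tibble with `gene_id`, `seqnames`, `start`, `end`, `strand`.
#' @export
read_cds_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  tibble(
    gene_id = as.character(gr$ID),
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}
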