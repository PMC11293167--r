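#' Default configuration for the packaged end-to-end demo
#'
#' A small but complete run: a 40-gene genome, 4 guides per gene, 15%
#' essential genes depleted 8-fold, ~100 reads per guide emitted as real
#' FASTQ and counted back, essentiality scoring, enrichment against a
#' planted essential gene set plus random sets, target selection and
#' vector packing. Every stage seed derives from the single top-level
#' `seed` so a config fully determines the outputs.
#'
#' @param seed Integer master seed.
#' @return A nested list with class `"pipeline_config"`.
#' @export
demo_config <- function(seed = 17) {
  check_count(seed, "seed")
  structure(list(
    seed = as.integer(seed),
    sim = sim_config(n_genes = 40, cds_len_range = c(300, 900),
                     guides_per_gene = 4, frac_essential = 0.15,
                     nb_mean = 100, seed = seed),
    design = design_params(guides_per_gene = 4),
    screen = list(anchor = "GACGAAACACC", error_rate = 0),
    score = list(min_guides = 2, threshold = 0.5),
    enrich = list(n_perm = 250, weight_exponent = 1, min_set_size = 5,
                  n_random_sets = 4, random_set_size = 8),
    select = list(score_threshold = 0.5, exclusions = NULL),
    pack = list(capacity = 4)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; the `seed` key is mandatory (no hidden
#' randomness). Keys under `sim`, `design`, `screen`, `score`, `enrich`,
#' `select`, `pack` override the corresponding [demo_config()] defaults.
#'
#' @param path YAML path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "sim", "design", "screen", "score", "enrich", "select",
             "pack")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "secrescreen_config_error")
  }
  if (is.null(raw$seed)) {
    abort("config must set an explicit `seed`.",
          class = "secrescreen_config_error")
  }
  cfg <- demo_config(seed = raw$seed)
  cfg$sim <- do.call(sim_config,
                     utils::modifyList(unclass(cfg$sim), raw$sim %||% list()))
  cfg$design <- do.call(design_params,
                        utils::modifyList(unclass(cfg$design),
                                          raw$design %||% list()))
  for (block in c("screen", "score", "enrich", "select", "pack")) {
    cfg[[block]] <- utils::modifyList(cfg[[block]], raw[[block]] %||% list())
  }
  cfg
}

#' Run the full screen pipeline on simulated inputs
#'
#' Executes simulate -> secretome -> design -> count -> lfc -> score ->
#' enrich -> select -> pack in dependency order, writing every artifact
#' (FASTA, GFF3, TSVs, FASTQ, GMT) plus a JSON run manifest into
#' `outdir`. The manifest records package version, seeds, parameters,
#' per-stage row counts and MD5 digests of every output, and contains no
#' timestamps, so rerunning an identical config reproduces byte-identical
#' outputs. A stage failure aborts with the stage name; artifacts of
#' completed stages are left in place.
#'
#' @param config A `"pipeline_config"` from [demo_config()] or
#'   [read_pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the key result objects and the manifest.
#' @examples
#' \donttest{
#' res <- run_pipeline(demo_config(seed = 1), tempfile("demo"))
#' res$manifest$stages$score
#' }
#' @export
run_pipeline <- function(config = demo_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$seed)) {
    abort("config must set an explicit `seed`.",
          class = "secrescreen_config_error")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  stages <- list()
  log_stage <- function(name) message("[secrescreen] stage: ", name)
  run_stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "secrescreen_stage_error")
    })
  }

  # -- simulate -------------------------------------------------------------
  sim <- run_stage("simulate", {
    sim <- simulate_genome(config$sim)
    write_genome_fasta(sim, p("genome.fa"))
    write_cds_gff3(sim, p("annotation.gff3"))
    sim
  })
  truth <- run_stage("truth", {
    truth <- simulate_truth(sim$genes$gene_id, config$sim)
    readr::write_tsv(truth, p("truth.tsv"))
    emit_signalp_tsv(truth, p("signalp.tsv"), seed = config$seed + 3L)
    # detected proteins: secreted genes plus a few abundant intracellular ones
    detected <- with_seed(config$seed + 4L, {
      ids <- truth$gene_id[truth$secreted]
      extra <- truth$gene_id[!truth$secreted]
      union(sample(ids, ceiling(length(ids) * 0.6)),
            sample(extra, min(length(extra), 3)))
    })
    ab <- simulate_abundance(max(2L, length(detected)),
                             rho = config$sim$abundance_rho,
                             seed = config$seed + 5L)
    if (length(detected) >= 2) {
      ab$protein_id <- rep(sort(detected), 2)
    }
    write_abundance_tsv(ab, p("abundance.tsv"),
                        n_replicates = config$sim$n_replicates,
                        seed = config$seed + 6L)
    truth
  })

  # -- secretome ------------------------------------------------------------
  secretome <- run_stage("secretome", {
    preds <- parse_signalp(p("signalp.tsv"))
    ab <- load_abundance(p("abundance.tsv"))
    st <- build_secretome(preds, ab)
    write_secretome(st, p("secretome.tsv"))
    st
  })

  # -- design ---------------------------------------------------------------
  guides <- run_stage("design", {
    g <- design_guides(sim$genome, sim$genes, params = config$design)
    write_guides(g, p("guides.tsv"))
    write_oligo_fasta(emit_oligos(g), p("oligos.fa"))
    g
  })

  # -- screen counts + FASTQ round trip -------------------------------------
  counts <- run_stage("count", {
    true_counts <- simulate_screen_counts(guides, truth, config$sim)
    emit_screen_fastq(true_counts, guides, "pre", p("pre.fastq"),
                      anchor = config$screen$anchor,
                      error_rate = config$screen$error_rate,
                      seed = config$seed + 7L)
    emit_screen_fastq(true_counts, guides, "post", p("post.fastq"),
                      anchor = config$screen$anchor,
                      error_rate = config$screen$error_rate,
                      seed = config$seed + 8L)
    counts <- count_guides(c(pre = p("pre.fastq"), post = p("post.fastq")),
                           guides, anchor = config$screen$anchor)
    readr::write_tsv(counts, p("counts.tsv"))
    counts
  })

  # -- lfc + score ----------------------------------------------------------
  lfc <- run_stage("lfc", {
    lfc <- guide_lfc(counts, pre = "pre", post = "post")
    readr::write_tsv(lfc, p("lfc.tsv"))
    lfc
  })
  fit <- run_stage("score", {
    fit <- score_essentiality(lfc, min_guides = config$score$min_guides,
                              threshold = config$score$threshold)
    write_scores(fit, p("scores.tsv"))
    fit
  })

  # -- enrichment -----------------------------------------------------------
  enrich <- run_stage("enrich", {
    sets <- with_seed(config$seed + 9L, {
      universe <- sim$genes$gene_id
      planted <- truth$gene_id[truth$essential]
      sets <- list(planted_essential = planted)
      for (i in seq_len(config$enrich$n_random_sets)) {
        sets[[sprintf("random_set_%02d", i)]] <-
          sample(universe, config$enrich$random_set_size)
      }
      sets
    })
    write_gmt(sets, p("sets.gmt"))
    enr <- weighted_gsea(fit, sets,
                         weight_exponent = config$enrich$weight_exponent,
                         n_perm = config$enrich$n_perm,
                         seed = config$seed + 10L,
                         min_set_size = config$enrich$min_set_size)
    write_enrichment(enr, p("enrichment.tsv"))
    enr
  })

  # -- selection + packing --------------------------------------------------
  selection <- run_stage("select", {
    sel <- select_targets(secretome, fit,
                          exclusions = config$select$exclusions,
                          score_threshold = config$select$score_threshold)
    write_selection(sel, p("selection.tsv"))
    sel
  })
  vectors <- run_stage("pack", {
    v <- assign_multiplex_vectors(selection$targets, guides,
                                  capacity = config$pack$capacity)
    readr::write_tsv(v, p("vectors.tsv"))
    v
  })

  # -- manifest -------------------------------------------------------------
  outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "secrescreen",
    version = as.character(utils::packageVersion("secrescreen")),
    seed = config$seed,
    params = list(
      sim = unclass(config$sim), design = unclass(config$design),
      screen = config$screen, score = config$score,
      enrich = config$enrich,
      select = config$select[setdiff(names(config$select), "exclusions")],
      pack = config$pack
    ),
    stages = list(
      simulate = list(n_genes = nrow(sim$genes),
                      genome_nt = sum(Biostrings::width(sim$genome))),
      secretome = list(n_proteins = nrow(secretome)),
      design = list(n_guides = nrow(guides),
                    n_genes_without_guides =
                      length(attr(guides, "no_guide_genes"))),
      count = lapply(split(count_totals(counts),
                           count_totals(counts)$sample),
                     function(r) list(reads = r$reads, mapped = r$mapped,
                                      unmapped = r$unmapped)),
      lfc = list(n_guides = nrow(lfc)),
      score = as.list(glance(fit)[c("n_genes", "n_scored", "n_essential")]),
      enrich = list(n_sets = nrow(tidy(enrich))),
      select = as.list(glance(selection)[c("n_candidates", "n_excluded",
                                           "n_targets")]),
      pack = list(n_vectors = length(unique(vectors$vector_id)))
    ),
    md5 = as.list(tools::md5sum(file.path(outdir, outputs)) |>
                    setNames(outputs))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(sim = sim, truth = truth, secretome = secretome,
                 guides = guides, counts = counts, lfc = lfc, scores = fit,
                 enrichment = enrich, selection = selection,
                 vectors = vectors, manifest = manifest, outdir = outdir))
}
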