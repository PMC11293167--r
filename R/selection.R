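#' Select non-essential knockout targets from a scored secretome
#'
#' Applies the target-selection rule: a protein is a candidate when it was
#' experimentally detected in the culture supernatant (any phase) and its
#' gene's essentiality score is strictly below `score_threshold`; genes
#' with missing scores are never candidates. A curated exclusion list
#' (id -> reason, e.g. methanol-metabolism genes that must stay intact
#' during induction) is then subtracted to give the final target list.
#' Candidates are ordered by score ascending (safest knockouts first),
#' ties broken by id. Exclusion ids that are not candidates produce a
#' warning, not an error.
#'
#' @param secretome A secretome tibble with `protein_id` and either a
#'   logical `detected` column or per-phase `detected_*` columns (e.g.
#'   from [build_secretome()] or [secretome_fixture()]).
#' @param scores An `"essentiality"` object, or a tibble with `gene_id`
#'   (or `protein_id`) and `score`.
#' @param exclusions Optional tibble with `gene_id` and `reason`, or a
#'   TSV path with those columns.
#' @param score_threshold Strict upper bound on the score for candidacy
#'   (default 0.5).
#' @param aliases Optional tibble (`from`, `to`) remapping score gene ids
#'   onto secretome protein ids.
#' @return An object of class `"target_selection"` with tibbles
#'   `candidates`, `excluded` (with reasons) and `targets`
#'   (final list). [tidy()] stacks the three stages with a `stage`
#'   column.
#' @examples
#' fx <- secretome_fixture()
#' sel <- select_targets(fx, fx[c("protein_id", "score")],
#'                       exclusions = fixture_exclusions(fx))
#' nrow(sel$targets)
#' @export
select_targets <- function(secretome, scores, exclusions = NULL,
                           score_threshold = 0.5, aliases = NULL) {
  check_fraction(score_threshold, "score_threshold")
  if (inherits(scores, "essentiality")) scores <- scores$results
  scores <- as_tibble(scores)
  if (!"gene_id" %in% names(scores) && "protein_id" %in% names(scores)) {
    scores <- rename(scores, gene_id = "protein_id")
  }
  stopifnot(all(c("gene_id", "score") %in% names(scores)))
  if (!is.null(aliases)) {
    stopifnot(all(c("from", "to") %in% names(aliases)))
    hit <- match(scores$gene_id, aliases$from)
    scores$gene_id[!is.na(hit)] <- aliases$to[hit[!is.na(hit)]]
  }

  det_cols <- grep("^detected", names(secretome), value = TRUE)
  if (length(det_cols) == 0) {
    abort("secretome table has no `detected` column(s).",
          class = "secrescreen_format_error")
  }
  detected_any <- Reduce(`|`, lapply(det_cols, function(c) {
    isTRUE_v(secretome[[c]])
  }))

  joined <- tibble(
    protein_id = secretome$protein_id,
    detected_any = detected_any,
    score = scores$score[match(secretome$protein_id, scores$gene_id)]
  )

  candidates <- joined %>%
    filter(.data$detected_any, !is.na(.data$score),
           .data$score < score_threshold) %>%
    arrange(.data$score, .data$protein_id) %>%
    transmute(gene_id = .data$protein_id, score = .data$score)

  if (is.character(exclusions)) exclusions <- read_tsv_quiet(exclusions)
  if (is.null(exclusions)) {
    exclusions <- tibble(gene_id = character(0), reason = character(0))
  }
  stopifnot(all(c("gene_id", "reason") %in% names(exclusions)))
  stray <- setdiff(exclusions$gene_id, candidates$gene_id)
  if (length(stray) > 0) {
    warn(paste0("exclusion id(s) not among candidates (ignored): ",
                paste(stray, collapse = ", ")))
  }
  excluded <- candidates %>%
    inner_join(exclusions, by = "gene_id")
  targets <- candidates %>%
    filter(!.data$gene_id %in% excluded$gene_id)

  structure(
    list(candidates = candidates, excluded = excluded, targets = targets,
         params = list(score_threshold = score_threshold)),
    class = "target_selection"
  )
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' @export
print.target_selection <- function(x, ...) {
  cat(sprintf(
    "<target_selection> %d candidates (detected & score < %.2f), %d excluded, %d final targets\n",
    nrow(x$candidates), x$params$score_threshold, nrow(x$excluded),
    nrow(x$targets)))
  invisible(x)
}

#' @rdname select_targets
#' @param x A `"target_selection"` object.
#' @param ... Unused.
#' @export
tidy.target_selection <- function(x, ...) {
  bind_rows(
    mutate(x$candidates, stage = "candidate", reason = NA_character_),
    mutate(x$excluded, stage = "excluded"),
    mutate(x$targets, stage = "target", reason = NA_character_)
  ) %>%
    select("stage", "gene_id", "score", "reason")
}

#' @rdname select_targets
#' @export
glance.target_selection <- function(x, ...) {
  tibble(
    n_candidates = nrow(x$candidates),
    n_excluded = nrow(x$excluded),
    n_targets = nrow(x$targets),
    score_threshold = x$params$score_threshold
  )
}

#' Write a target selection to TSV (stage-labelled)
#' @param selection A `"target_selection"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  readr::write_tsv(tidy(selection), path)
  invisible(path)
}
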