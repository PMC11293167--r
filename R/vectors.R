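#' Pack knockout targets into multiplexed vectors
#'
#' Greedily fills delivery vectors with up to `capacity` targets each, in
#' the input order of `targets`, attaching each target's top-ranked guide.
#' Every target appears in exactly one vector, so the number of vectors is
#' always `ceiling(n_targets / capacity)` - the optimum for disjoint
#' single-target demands. Targets without a designed guide are an error.
#'
#' @param targets Character vector of gene ids (or a tibble with a
#'   `gene_id` column, e.g. from [select_targets()] output).
#' @param guides Guide table with `gene_id` and `guide_id`, ranked within
#'   gene (first row per gene = top guide).
#' @param capacity Maximum targets per vector (>= 1, default 4).
#' @return A tibble with `vector_id`, `gene_id`, `guide_id`.
#' @examples
#' g <- tibble::tibble(gene_id = letters[1:5],
#'                     guide_id = paste0(letters[1:5], "_g1"))
#' assign_multiplex_vectors(letters[1:5], g, capacity = 4)
#' @export
assign_multiplex_vectors <- function(targets, guides, capacity = 4) {
  if (is.data.frame(targets)) targets <- targets$gene_id
  targets <- as.character(targets)
  check_count(capacity, "capacity", min = 1)
  if (anyDuplicated(targets)) {
    abort("duplicate target gene ids.", class = "secrescreen_data_error")
  }
  uncovered <- setdiff(targets, guides$gene_id)
  if (length(uncovered) > 0) {
    abort(paste0("target(s) without any designed guide: ",
                 paste(uncovered, collapse = ", ")),
          class = "secrescreen_data_error")
  }
  if (length(targets) == 0) {
    return(tibble(vector_id = character(0), gene_id = character(0),
                  guide_id = character(0)))
  }
  top <- guides[!duplicated(guides$gene_id), c("gene_id", "guide_id")]
  vec <- ceiling(seq_along(targets) / capacity)
  tibble(
    vector_id = sprintf("V%02d", vec),
    gene_id = targets,
    guide_id = top$guide_id[match(targets, top$gene_id)]
  )
}
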