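#' Load a replicate-level abundance table
#'
#' Consumes a TSV (or in-memory data frame) with one row per protein and
#' cultivation phase and one column per replicate area-under-curve (AUC)
#' measurement. The relative abundance of a protein in a phase is defined as
#' the log10 of the total AUC summed over replicate cultivations. Rows whose
#' replicate sum is zero are dropped with a warning (the protein was not
#' detected in that phase); negative AUC values are a data error.
#'
#' @param x A file path or data frame with columns `protein_id`, `phase`,
#'   and one or more numeric AUC columns (any names; every numeric column
#'   other than the first two is treated as a replicate).
#' @return A tibble with `protein_id`, `phase`, `total_auc`,
#'   `rel_abundance` (log10 of the replicate sum).
#' @examples
#' tbl <- data.frame(protein_id = "p1", phase = "outgrowth",
#'                   auc_1 = 10, auc_2 = 10, auc_3 = 10, auc_4 = 10)
#' load_abundance(tbl)$rel_abundance  # log10(40)
#' @export
load_abundance <- function(x) {
  tbl <- if (is.character(x)) read_tsv_quiet(x) else as_tibble(x)
  required <- c("protein_id", "phase")
  if (!all(required %in% names(tbl))) {
    abort("abundance table must have `protein_id` and `phase` columns.",
          class = "secrescreen_format_error")
  }
  auc_cols <- setdiff(names(tbl)[vapply(tbl, is.numeric, logical(1))], required)
  if (length(auc_cols) == 0) {
    abort("abundance table needs at least one numeric AUC column.",
          class = "secrescreen_format_error")
  }
  auc <- as.matrix(tbl[auc_cols])
  if (any(auc < 0, na.rm = TRUE)) {
    abort("negative AUC values are not allowed.",
          class = "secrescreen_data_error")
  }
  total <- rowSums(auc, na.rm = TRUE)
  zero <- total <= 0
  if (any(zero)) {
    warn(sprintf("dropped %d row(s) with zero total AUC: %s",
                 sum(zero),
                 paste(head(tbl$protein_id[zero], 5), collapse = ", ")))
  }
  tibble(
    protein_id = tbl$protein_id[!zero],
    phase = tbl$phase[!zero],
    total_auc = total[!zero],
    rel_abundance = log10(total[!zero])
  )
}

#' Generic numeric row filter
#'
#' Convenience filter for applying quality cutoffs (e.g. a search-engine
#' score or isolation-interference ceiling) to an input table before it
#' enters the pipeline.
#'
#' @param tbl A data frame.
#' @param column Column name to filter on.
#' @param op One of `">"`, `">="`, `"<"`, `"<="`, `"=="`.
#' @param cutoff Numeric cutoff.
#' @return The filtered tibble.
#' @export
filter_rows <- function(tbl, column, op = c(">=", "<=", ">", "<", "=="),
                        cutoff) {
  op <- match.arg(op)
  if (!column %in% names(tbl)) {
    abort(sprintf("column `%s` not found.", column),
          class = "secrescreen_format_error")
  }
  keep <- do.call(op, list(tbl[[column]], cutoff))
  as_tibble(tbl)[!is.na(keep) & keep, ]
}

#' Cross-phase Pearson correlation of protein abundances
#'
#' Correlates the log10 relative abundances of proteins detected in both
#' phases; proteins detected in only one phase are excluded. At least two
#' shared proteins are required.
#'
#' @param records A tibble with `protein_id`, `phase`, `rel_abundance`
#'   (from [load_abundance()] or [simulate_abundance()]).
#' @param phase_a,phase_b The two phases to correlate.
#' @return The sample Pearson correlation coefficient (a single number).
#' @examples
#' ab <- simulate_abundance(50, rho = 0.9, seed = 2)
#' abundance_correlation(ab)
#' @export
abundance_correlation <- function(records, phase_a = "outgrowth",
                                  phase_b = "production") {
  wide <- records %>%
    filter(.data$phase %in% c(phase_a, phase_b)) %>%
    select("protein_id", "phase", "rel_abundance") %>%
    tidyr::pivot_wider(names_from = "phase",
                       values_from = "rel_abundance") %>%
    filter(!is.na(.data[[phase_a]]), !is.na(.data[[phase_b]]))
  if (nrow(wide) < 2) {
    abort("fewer than 2 proteins detected in both phases; correlation undefined.",
          class = "secrescreen_data_error")
  }
  cor(wide[[phase_a]], wide[[phase_b]], method = "pearson")
}
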