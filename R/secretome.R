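#' Proteins with a predicted signal peptide
#'
#' Returns the ids whose Sec/SPI probability is strictly greater than the
#' threshold; a probability exactly at the threshold is excluded. Raising
#' the threshold can only shrink the returned set.
#'
#' @param preds A tibble with `protein_id` and `sp_prob` (from
#'   [parse_signalp()]).
#' @param threshold Probability cutoff (default 0.5, the standard Sec/SPI
#'   filter).
#' @return A character vector of protein ids.
#' @export
predict_secreted <- function(preds, threshold = 0.5) {
  check_fraction(threshold, "threshold")
  stopifnot(all(c("protein_id", "sp_prob") %in% names(preds)))
  preds$protein_id[preds$sp_prob > threshold]
}

#' Define a secretome from predicted and detected protein sets
#'
#' The secretome is the union of the signal-peptide-predicted set and the
#' experimentally detected set. Each member is classified into exactly one
#' of three classes: `predicted_and_detected` (intersection),
#' `predicted_only`, or `detected_only`. The class counts always satisfy
#' `|predicted_only| = |P| - |P n D|` and `|detected_only| = |D| - |P n D|`.
#'
#' @param predicted Character vector of predicted protein ids.
#' @param detected Character vector of detected protein ids (detection in
#'   any cultivation phase counts).
#' @return A tibble with `protein_id`, `predicted`, `detected`,
#'   `secretome_class` (factor), one row per secretome member, ordered by
#'   id.
#' @examples
#' st <- define_secretome(c("a", "b", "c"), c("b", "d"))
#' table(st$secretome_class)
#' @export
define_secretome <- function(predicted, detected) {
  predicted <- unique(as.character(predicted))
  detected <- unique(as.character(detected))
  ids <- sort(union(predicted, detected))
  p <- ids %in% predicted
  d <- ids %in% detected
  cls <- dplyr::case_when(
    p & d ~ "predicted_and_detected",
    p ~ "predicted_only",
    TRUE ~ "detected_only"
  )
  tibble(
    protein_id = ids,
    predicted = p,
    detected = d,
    secretome_class = factor(cls, levels = c("predicted_and_detected",
                                             "predicted_only",
                                             "detected_only"))
  )
}

#' Assemble the full secretome table from predictions and abundances
#'
#' Merges a signal-peptide prediction table with a loaded abundance table
#' into the per-protein secretome record: prediction probability, detection
#' flag and relative abundance per phase, and the three-way secretome class.
#' An optional two-column alias map reconciles protein ids between the two
#' inputs (exact string match otherwise).
#'
#' @param preds A tibble from [parse_signalp()].
#' @param abundance A tibble from [load_abundance()] (or
#'   [simulate_abundance()]).
#' @param threshold Sec/SPI probability cutoff for the predicted set.
#' @param aliases Optional tibble with columns `from`, `to` remapping
#'   abundance protein ids onto prediction ids.
#' @param phases Character vector naming the two cultivation phases.
#' @return A tibble with `protein_id`, `sp_prob`,
#'   `detected_<phase>` and `rel_abundance_<phase>` per phase, and
#'   `secretome_class`.
#' @export
build_secretome <- function(preds, abundance, threshold = 0.5, aliases = NULL,
                            phases = c("outgrowth", "production")) {
  if (!is.null(aliases)) {
    stopifnot(all(c("from", "to") %in% names(aliases)))
    hit <- match(abundance$protein_id, aliases$from)
    abundance$protein_id[!is.na(hit)] <- aliases$to[hit[!is.na(hit)]]
  }
  predicted_ids <- predict_secreted(preds, threshold)
  detected_ids <- unique(abundance$protein_id[abundance$phase %in% phases])
  core <- define_secretome(predicted_ids, detected_ids)

  out <- core %>%
    mutate(sp_prob = preds$sp_prob[match(.data$protein_id, preds$protein_id)])
  for (ph in phases) {
    sub <- abundance[abundance$phase == ph, ]
    out[[paste0("detected_", ph)]] <- out$protein_id %in% sub$protein_id
    out[[paste0("rel_abundance_", ph)]] <-
      sub$rel_abundance[match(out$protein_id, sub$protein_id)]
  }
  out %>% select("protein_id", "sp_prob", starts_with("detected_"),
                 starts_with("rel_abundance_"), "secretome_class")
}

#' Write a secretome table to TSV
#'
#' @param secretome A tibble from [build_secretome()] or
#'   [define_secretome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_secretome <- function(secretome, path) {
  readr::write_tsv(secretome, path)
  invisible(path)
}

#' Scatter plot of cross-phase protein abundances
#'
#' @param records A tibble with `protein_id`, `phase`, `rel_abundance`.
#' @param phase_a,phase_b Phases to plot on x and y.
#' @return A ggplot object annotated with the Pearson R over proteins
#'   detected in both phases.
#' @export
plot_abundance <- function(records, phase_a = "outgrowth",
                           phase_b = "production") {
  r <- abundance_correlation(records, phase_a, phase_b)
  wide <- records %>%
    filter(.data$phase %in% c(phase_a, phase_b)) %>%
    select("protein_id", "phase", "rel_abundance") %>%
    tidyr::pivot_wider(names_from = "phase", values_from = "rel_abundance")
  ggplot(wide, aes(.data[[phase_a]], .data[[phase_b]])) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
             label = sprintf("R = %.2f", r)) +
    labs(x = sprintf("log10 abundance (%s)", phase_a),
         y = sprintf("log10 abundance (%s)", phase_b)) +
    theme_minimal()
}
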