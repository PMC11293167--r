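#' Deterministic 361-protein secretome selection fixture
#'
#' A fully synthetic, seed-free table wired to the marginal counts of the
#' study design this package supports: 361 proteins of which 257 carry a
#' predicted signal peptide (Sec/SPI probability above 0.5), 134 are
#' detected in culture supernatant, and 30 are both (so 227 are
#' predicted-only and 104 detected-only). Among the 134 detected proteins
#' exactly 61 have an essentiality score below 0.5 (knockout candidates),
#' and exactly 7 of those carry a methanol-metabolism exclusion flag,
#' leaving 54 final targets. All ids, probabilities, scores and abundances
#' are synthetic and deterministic; the file exists so selection arithmetic
#' and vector packing can be tested without running a screen.
#'
#' @return A tibble with one row per protein: `protein_id`, `sp_prob`,
#'   `detected_outgrowth`, `detected_production`,
#'   `rel_abundance_outgrowth`, `rel_abundance_production`,
#'   `secretome_class`, `score`, `methanol_pathway`.
#' @examples
#' fx <- secretome_fixture()
#' table(fx$secretome_class)
#' sum(with(fx, (detected_outgrowth | detected_production) & score < 0.5))
#' @export
secretome_fixture <- function() {
  n <- 361L
  ids <- sprintf("SP%03d", seq_len(n))

  # rows 1..30 predicted & detected; 31..257 predicted only; 258..361 detected only
  predicted <- seq_len(n) <= 257
  detected <- seq_len(n) <= 30 | seq_len(n) >= 258

  sp_prob <- numeric(n)
  sp_prob[predicted] <- round(seq(0.51, 0.99, length.out = sum(predicted)), 4)
  sp_prob[!predicted] <- round(seq(0.01, 0.49, length.out = sum(!predicted)), 4)

  # phase detection split among the 134 detected proteins: 100 both,
  # 20 outgrowth-only, 14 production-only
  det_idx <- which(detected)
  det_rank <- match(seq_len(n), det_idx)
  detected_outgrowth <- !is.na(det_rank) & det_rank <= 120
  detected_production <- !is.na(det_rank) & (det_rank <= 100 | det_rank > 120)

  rel_out <- ifelse(detected_outgrowth,
                    round(4 + (det_rank %% 50) * 0.05, 3), NA_real_)
  rel_prod <- ifelse(detected_production,
                     round(4.2 + (det_rank %% 50) * 0.05, 3), NA_real_)

  # essentiality scores: the first 61 detected proteins (in detection order)
  # score below 0.5; the remaining 73 detected proteins score above it
  score <- numeric(n)
  low <- !is.na(det_rank) & det_rank <= 61
  high <- !is.na(det_rank) & det_rank > 61
  score[low] <- round(seq(0.02, 0.48, length.out = sum(low)), 4)
  score[high] <- round(seq(0.52, 0.98, length.out = sum(high)), 4)
  score[!detected] <- round(seq(0.05, 0.95, length.out = sum(!detected)), 4)

  # 7 methanol-metabolism exclusions among the 61 candidates
  methanol <- !is.na(det_rank) & det_rank %in% c(5L, 13L, 21L, 34L, 42L, 50L, 58L)

  secretome_class <- dplyr::case_when(
    predicted & detected ~ "predicted_and_detected",
    predicted ~ "predicted_only",
    TRUE ~ "detected_only"
  )

  tibble(
    protein_id = ids,
    sp_prob = sp_prob,
    detected_outgrowth = detected_outgrowth,
    detected_production = detected_production,
    rel_abundance_outgrowth = rel_out,
    rel_abundance_production = rel_prod,
    secretome_class = factor(secretome_class,
                             levels = c("predicted_and_detected",
                                        "predicted_only", "detected_only")),
    score = score,
    methanol_pathway = methanol
  )
}

#' Exclusion list carried by the packaged fixture
#'
#' @param fixture A tibble from [secretome_fixture()].
#' @return A tibble with `gene_id` and `reason` for every protein flagged
#'   as methanol-metabolism, suitable for [select_targets()].
#' @export
fixture_exclusions <- function(fixture = secretome_fixture()) {
  fixture %>%
    filter(.data$methanol_pathway) %>%
    transmute(gene_id = .data$protein_id, reason = "methanol metabolism")
}
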