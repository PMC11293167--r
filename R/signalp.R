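#' Parse a short-format signal-peptide prediction table
#'
#' Reads the tab-separated "short" output dialect of SignalP 5: comment
#' lines start with `#`, the protein id is in column 1, and the Sec/SPI
#' signal-peptide probability sits in the column whose header (the last
#' comment line) contains `SP(Sec/SPI)`. A headerless two-column TSV
#' (`id<TAB>probability`) is accepted as a fallback. Malformed data rows
#' (wrong column count or non-numeric probability) are skipped with a
#' warning naming their line numbers.
#'
#' @param path Path to the prediction file.
#' @return A tibble with `protein_id` and `sp_prob` (one row per protein).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("# SignalP-5.0\tOrganism: Eukarya",
#'              "# ID\tPrediction\tSP(Sec/SPI)\tOTHER\tCS Position",
#'              "prot1\tSP(Sec/SPI)\t0.9631\t0.0369\tCS pos: 23-24",
#'              "prot2\tOTHER\t0.1200\t0.8800\t"), f)
#' parse_signalp(f)
#' @export
parse_signalp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "#")
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_idx) == 0) {
    return(tibble(protein_id = character(0), sp_prob = numeric(0)))
  }

  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)

  headers <- lines[is_comment]
  sp_col <- NA_integer_
  hdr <- headers[grepl("SP(Sec/SPI)", headers, fixed = TRUE)]
  if (length(hdr) > 0) {
    hdr_fields <- strsplit(sub("^#\\s*", "", tail(hdr, 1)), "\t", fixed = TRUE)[[1]]
    sp_col <- which(trimws(hdr_fields) == "SP(Sec/SPI)")[1]
  } else if (all(ncols == 2)) {
    sp_col <- 2L
  }
  if (is.na(sp_col)) {
    abort(paste0("cannot locate the signal-peptide probability column in ",
                 path, ": expected a header line containing 'SP(Sec/SPI)' ",
                 "or a two-column TSV."),
          class = "secrescreen_format_error")
  }

  id <- vapply(fields, function(f) f[1], character(1))
  prob_raw <- vapply(fields, function(f) {
    if (length(f) >= sp_col) f[sp_col] else NA_character_
  }, character(1))
  prob <- suppressWarnings(as.numeric(prob_raw))

  bad <- is.na(prob) | prob < 0 | prob > 1
  if (any(bad)) {
    warn(sprintf("skipped %d malformed prediction row(s) at line(s): %s",
                 sum(bad), paste(data_idx[bad], collapse = ", ")))
  }
  out <- tibble(protein_id = id[!bad], sp_prob = prob[!bad])
  if (anyDuplicated(out$protein_id)) {
    abort("duplicate protein ids in prediction table.",
          class = "secrescreen_format_error")
  }
  out
}

#' Write predictions in the short signal-peptide table dialect
#'
#' Inverse of [parse_signalp()]; probabilities are written with four
#' decimals, matching the upstream tool's precision.
#'
#' @param preds A tibble with `protein_id` and `sp_prob`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signalp <- function(preds, path) {
  lines <- c(
    "# secrescreen signal-peptide table\tshort format",
    "# ID\tPrediction\tSP(Sec/SPI)\tOTHER\tCS Position",
    sprintf("%s\t%s\t%.4f\t%.4f\t",
            preds$protein_id,
            ifelse(preds$sp_prob > 0.5, "SP(Sec/SPI)", "OTHER"),
            preds$sp_prob, 1 - preds$sp_prob)
  )
  writeLines(lines, path)
  invisible(path)
}
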