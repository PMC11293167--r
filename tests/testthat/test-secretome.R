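signalp_lines <- c(
  "# SignalP-5.0\tOrganism: Eukarya",
  "# ID\tPrediction\tSP(Sec/SPI)\tOTHER\tCS Position",
  "prot1\tSP(Sec/SPI)\t0.9000\t0.1000\tCS pos: 20-21",
  "prot2\tOTHER\t0.4000\t0.6000\t",
  "prot3\tOTHER\t0.5000\t0.5000\t"
)

test_that("short-format prediction tables parse, skipping comments", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(signalp_lines, f)
  preds <- parse_signalp(f)
  expect_equal(nrow(preds), 3)
  expect_equal(preds$protein_id, c("prot1", "prot2", "prot3"))
  expect_equal(preds$sp_prob, c(0.9, 0.4, 0.5))
})

test_that("malformed rows are skipped with their line numbers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(signalp_lines, "prot4\tOTHER\tnot_a_number\t0.5\t"), f)
  expect_warning(preds <- parse_signalp(f), "line")
  expect_equal(nrow(preds), 3)
})

test_that("a file without the probability column is a format error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# ID\tPrediction\tScore", "p1\tSP\t0.9\textra"), f)
  err <- expect_error(parse_signalp(f), class = "secrescreen_format_error")
  expect_match(conditionMessage(err), "SP(Sec/SPI)", fixed = TRUE)
})

test_that("two-column tables parse as a fallback and round-trip to 3 decimals", {
  f <- withr::local_tempfile(fileext = ".tsv")
  probs <- round(runif(25), 4)
  writeLines(sprintf("p%02d\t%.4f", 1:25, probs), f)
  preds <- parse_signalp(f)
  expect_equal(preds$sp_prob, probs)
  # write-then-parse round trip
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_signalp(preds, f2)
  back <- parse_signalp(f2)
  expect_equal(back$protein_id, preds$protein_id)
  expect_equal(round(back$sp_prob, 3), round(preds$sp_prob, 3))
})

test_that("prediction threshold is strict and matches a brute-force scan", {
  preds <- tibble::tibble(protein_id = c("a", "b", "c"),
                          sp_prob = c(0.5, 0.51, 0.49))
  expect_equal(predict_secreted(preds), "b")
  big <- tibble::tibble(protein_id = sprintf("p%04d", 1:1000),
                        sp_prob = round(runif(1000), 3))
  got <- predict_secreted(big, threshold = 0.5)
  want <- character(0)
  for (i in seq_len(nrow(big))) {
    if (big$sp_prob[i] > 0.5) want <- c(want, big$protein_id[i])
  }
  expect_identical(got, want)
  # monotone in the threshold
  for (thr in c(0.2, 0.5, 0.8)) {
    expect_true(all(predict_secreted(big, thr + 0.1) %in%
                      predict_secreted(big, thr)))
  }
})

test_that("relative abundance is the log10 of the replicate sum", {
  tbl <- data.frame(protein_id = c("p1", "p2"), phase = "outgrowth",
                    auc_1 = c(10, 0), auc_2 = c(10, 0),
                    auc_3 = c(10, 0), auc_4 = c(10, 0))
  expect_warning(ab <- load_abundance(tbl), "zero")
  expect_equal(nrow(ab), 1)
  expect_equal(ab$rel_abundance, log10(40))
  # random tables match an independent recomputation
  rtbl <- data.frame(protein_id = sprintf("p%02d", 1:40),
                     phase = rep(c("outgrowth", "production"), 20),
                     a = runif(40, 1, 100), b = runif(40, 1, 100),
                     c = runif(40, 1, 100), d = runif(40, 1, 100))
  ab2 <- load_abundance(rtbl)
  expect_equal(ab2$rel_abundance,
               log10(rtbl$a + rtbl$b + rtbl$c + rtbl$d))
  expect_error(load_abundance(transform(rtbl, a = -a)),
               class = "secrescreen_data_error")
})

test_that("secretome definition reproduces the printed set algebra", {
  P <- sprintf("P%03d", 1:257)
  D <- c(sprintf("P%03d", 1:30), sprintf("D%03d", 1:104))
  st <- define_secretome(P, D)
  expect_equal(nrow(st), 361)
  expect_equal(sum(st$secretome_class == "predicted_and_detected"), 30)
  expect_equal(sum(st$secretome_class == "predicted_only"), 227)
  expect_equal(sum(st$secretome_class == "detected_only"), 104)
})

test_that("secretome set algebra matches brute-force set operations", {
  expect_equal(nrow(define_secretome(character(0), character(0))), 0)
  for (i in 1:20) {
    P <- sample(sprintf("x%03d", 1:60), sample(0:40, 1))
    D <- sample(sprintf("x%03d", 1:60), sample(0:40, 1))
    st <- define_secretome(P, D)
    expect_setequal(st$protein_id, union(P, D))
    expect_setequal(st$protein_id[st$secretome_class == "predicted_and_detected"],
                    intersect(P, D))
    expect_setequal(st$protein_id[st$secretome_class == "predicted_only"],
                    setdiff(P, D))
    expect_setequal(st$protein_id[st$secretome_class == "detected_only"],
                    setdiff(D, P))
    # partition identity
    expect_equal(sum(st$secretome_class == "predicted_only"),
                 length(unique(P)) - length(intersect(P, D)))
    expect_equal(sum(st$secretome_class == "detected_only"),
                 length(unique(D)) - length(intersect(P, D)))
  }
})

test_that("abundance correlation handles degenerate inputs", {
  x <- tibble::tibble(
    protein_id = rep(c("a", "b", "c"), 2),
    phase = rep(c("outgrowth", "production"), each = 3),
    rel_abundance = c(1, 2, 3, 1, 2, 3)
  )
  expect_equal(abundance_correlation(x), 1)
  y <- x
  y$rel_abundance[4:6] <- -c(1, 2, 3)
  expect_equal(abundance_correlation(y), -1)
  z <- x[c(1, 4), ]  # one shared protein only
  expect_error(abundance_correlation(z), class = "secrescreen_data_error")
})

test_that("detection in either phase makes a protein detected in the union", {
  preds <- tibble::tibble(protein_id = c("a", "b"), sp_prob = c(0.9, 0.1))
  ab <- tibble::tibble(protein_id = c("c", "d"),
                       phase = c("outgrowth", "production"),
                       total_auc = c(10, 10), rel_abundance = c(1, 1))
  st <- build_secretome(preds, ab)
  expect_setequal(st$protein_id, c("a", "c", "d"))
  expect_true(st$detected_outgrowth[st$protein_id == "c"])
  expect_false(st$detected_production[st$protein_id == "c"])
  expect_equal(sum(st$secretome_class == "detected_only"), 2)
  # single-phase proteins carry a missing abundance in the other phase
  expect_true(is.na(st$rel_abundance_production[st$protein_id == "c"]))
})
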