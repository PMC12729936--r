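make_hits <- function(...) {
  rows <- list(...)
  data.frame(query_id = vapply(rows, `[[`, "", 1),
             subject_id = vapply(rows, `[[`, "", 2),
             evalue = as.numeric(vapply(rows, `[[`, "", 3)),
             query_coverage = as.numeric(vapply(rows, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

test_that("homology thresholds are inclusive and best hits deterministic", {
  cfg <- filter_config()
  hits <- make_hits(c("A", "s1", "0.05", "0.60"),   # both at boundary
                    c("B", "s1", "0.06", "0.90"),   # E too large
                    c("C", "s1", "0.01", "0.59"),   # coverage too small
                    c("D", "s2", "1e-9", "0.80"),
                    c("D", "s1", "1e-9", "0.80"),   # tie: subject id decides
                    c("D", "s3", "1e-3", "0.99"))
  out <- filter_homology(hits, cfg)
  expect_setequal(out$transcript_id, c("A", "D"))
  expect_equal(out$subject_id[out$transcript_id == "D"], "s1")
  expect_true(out$annotated[out$transcript_id == "D"])
  expect_false(out$annotated[out$transcript_id == "A"])

  expect_equal(nrow(filter_homology(hits[0, ], cfg)), 0)
  bad <- make_hits(c("A", "s1", "-1", "0.5"))
  expect_error(filter_homology(bad, cfg), "line 1")
  bad2 <- make_hits(c("A", "s1", "0.01", "1.5"))
  expect_error(filter_homology(bad2, cfg), "coverage")
})

test_that("secretion filter keeps flagged ids and rejects conflicts", {
  ann <- data.frame(transcript_id = c("A", "B"),
                    has_signal_peptide = c(TRUE, FALSE))
  expect_equal(filter_secretion(ann), "A")
  expect_equal(filter_secretion(data.frame(transcript_id = "A",
                                           has_signal_peptide = "yes")), "A")
  none <- data.frame(transcript_id = c("A", "B"),
                     has_signal_peptide = c(FALSE, FALSE))
  expect_length(filter_secretion(none), 0)
  dup <- data.frame(transcript_id = c("A", "A"),
                    has_signal_peptide = c(TRUE, FALSE))
  expect_error(filter_secretion(dup), "conflicting")
  expect_error(
    filter_secretion(data.frame(transcript_id = "A",
                                has_signal_peptide = "maybe")),
    "unrecognised")
})

test_that("expression gate is inclusive at the threshold", {
  cfg <- filter_config()
  expr <- data.frame(transcript_id = c("A", "B", "C"),
                     tpm = c(40.0, 39.99, 1000))
  expect_setequal(filter_expression(expr, cfg), c("A", "C"))
  expect_length(filter_expression(expr[0, ], cfg), 0)
  expect_error(filter_expression(data.frame(transcript_id = "A", tpm = -1),
                                 cfg), "invalid TPM")
})

test_that("candidate identification equals the three-filter intersection", {
  set.seed(99)
  cfg <- filter_config(tpm_min = 60)
  for (i in 1:200) {
    ev <- random_evidence(n_ids = 15)
    got <- suppressWarnings(
      identify_candidates(ev$hits, ev$secretion, ev$expression, cfg))
    want <- Reduce(intersect, list(
      unique(ev$hits$query_id[ev$hits$evalue <= cfg$evalue_max &
                                ev$hits$query_coverage >= cfg$coverage_min]),
      ev$secretion$transcript_id[ev$secretion$has_signal_peptide],
      ev$expression$transcript_id[ev$expression$tpm >= cfg$tpm_min]))
    expect_setequal(got$transcript_id, want)
    # sorted by descending TPM, ties by id
    expect_equal(got$transcript_id,
                 got$transcript_id[order(-got$tpm, got$transcript_id)])
  }
})

test_that("relaxing any threshold never shrinks the candidate set", {
  set.seed(123)
  for (i in 1:20) {
    ev <- random_evidence(n_ids = 25)
    strict <- suppressWarnings(identify_candidates(
      ev$hits, ev$secretion, ev$expression,
      filter_config(evalue_max = 0.01, coverage_min = 0.8, tpm_min = 80)))
    loose <- suppressWarnings(identify_candidates(
      ev$hits, ev$secretion, ev$expression,
      filter_config(evalue_max = 0.5, coverage_min = 0.3, tpm_min = 10)))
    expect_true(all(strict$transcript_id %in% loose$transcript_id))
  }
})

test_that("missing expression records fail conservatively with a warning", {
  hits <- make_hits(c("A", "s1", "1e-8", "0.9"))
  ann <- data.frame(transcript_id = "A", has_signal_peptide = TRUE)
  expr <- data.frame(transcript_id = character(), tpm = numeric())
  expect_warning(out <- identify_candidates(hits, ann, expr),
                 "failing the TPM gate")
  expect_equal(nrow(out), 0)
})

test_that("an infinite TPM gate empties the candidate set", {
  ev <- random_evidence(n_ids = 10)
  out <- suppressWarnings(identify_candidates(
    ev$hits, ev$secretion, ev$expression, filter_config(tpm_min = Inf)))
  expect_equal(nrow(out), 0)
})

test_that("the homology table reader enforces the 13-column dialect", {
  f <- tempfile(fileext = ".tsv")
  writeLines("A\tS\t90", f)
  expect_error(read_homology_hits(f), "13")
  row <- paste(c("A", "TOX_1", "88.2", "50", "5", "0", "1", "50", "1", "50",
                 "1e-10", "120.5", "0.75"), collapse = "\t")
  writeLines(row, f)
  hits <- read_homology_hits(f)
  expect_equal(hits$query_coverage, 0.75)
  expect_equal(hits$evalue, 1e-10)
})
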