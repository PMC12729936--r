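test_that("scenario validation catches impossible mixes", {
  expect_error(synthetic_scenario(), "seed")
  expect_error(synthetic_scenario(seed = 1, n_transcripts = 3,
                                  n_planted = 5), "more positives")
  expect_error(synthetic_scenario(seed = 1,
                                  decoy_mix = c(fail_homology = 1)),
               "decoy_mix")
  expect_error(synthetic_scenario(seed = 1,
                                  decoy_mix = c(fail_homology = 0.5,
                                                fail_signal = 0.5,
                                                fail_expression = 0.25,
                                                non_helical = 0.25)),
               "sum to 1")
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  sc <- synthetic_scenario(seed = 42)
  set.seed(1); before <- runif(1)
  set.seed(1)
  p1 <- generate_proteome(sc)
  after <- runif(1)
  expect_identical(before, after)  # generator did not consume caller RNG

  p2 <- generate_proteome(sc)
  expect_identical(p1, p2)
  e1 <- generate_evidence_tables(p1, sc)
  e2 <- generate_evidence_tables(p2, sc)
  expect_identical(e1, e2)

  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_inputs(sc, d1)
  write_synthetic_inputs(sc, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = f)
})

test_that("planted positives satisfy every funnel criterion by construction", {
  sc <- synthetic_scenario(seed = 7)
  p <- generate_proteome(sc)
  ev <- generate_evidence_tables(p, sc)
  man <- p$manifest
  pos <- man[man$class == "positive", ]
  expect_equal(nrow(pos), 5)

  for (i in seq_len(nrow(pos))) {
    id <- pos$transcript_id[i]
    win <- substr(p$proteins[[id]], pos$window_start[i] + 1,
                  pos$window_start[i] + 18)
    expect_identical(win, pos$window_seq[i])
    # cationic under the shipped pKa table
    expect_gte(charge_at_ph(win, 7), 2)
    # inside an annotated helix segment
    seg <- annotate_helices(p$proteins[[id]])$segments
    expect_true(any(seg$start <= pos$window_start[i] &
                      seg$end >= pos$window_start[i] + 18))
  }

  hom <- filter_homology(ev$homology)
  expect_true(all(pos$transcript_id %in% hom$transcript_id))
  expect_true(all(pos$transcript_id %in% filter_secretion(ev$secretion)))
  expect_true(all(pos$transcript_id %in% filter_expression(ev$expression)))
})

test_that("each decoy class violates exactly its assigned criterion", {
  sc <- synthetic_scenario(seed = 8)
  p <- generate_proteome(sc)
  ev <- generate_evidence_tables(p, sc)
  man <- p$manifest
  hom_ids <- filter_homology(ev$homology)$transcript_id
  sec_ids <- filter_secretion(ev$secretion)
  exp_ids <- filter_expression(ev$expression)

  for (i in seq_len(nrow(man))) {
    id <- man$transcript_id[i]
    fails <- man$fails_criterion[i]
    expect_identical(id %in% hom_ids, fails != "homology", label = id)
    expect_identical(id %in% sec_ids, fails != "signal", label = id)
    expect_identical(id %in% exp_ids, fails != "expression", label = id)
    if (fails == "helix")
      expect_lt(helix_fraction(annotate_helices(p$proteins[[id]])), 0.5)
    if (fails %in% c("homology", "signal", "expression"))
      expect_gte(helix_fraction(annotate_helices(p$proteins[[id]])), 0)
  }
})

test_that("a zero-positive scenario lists no planted windows", {
  sc <- synthetic_scenario(seed = 3, n_planted = 0)
  p <- generate_proteome(sc)
  expect_equal(sum(p$manifest$class == "positive"), 0)
  expect_true(all(is.na(p$manifest$window_seq)))
})

test_that("predictor scores separate planted from decoy windows", {
  sc <- synthetic_scenario(seed = 12)
  p <- generate_proteome(sc)
  pos_ids <- p$manifest$transcript_id[p$manifest$class == "positive"]
  windows <- extract_windows_set(p$proteins[pos_ids])
  s1 <- generate_predictor_scores(windows, p$manifest, sc)
  s2 <- generate_predictor_scores(windows, p$manifest, sc)
  expect_identical(s1, s2)
  expect_equal(sum(s1$planted), length(pos_ids))
  expect_gt(mean(s1$pepnet[s1$planted]), mean(s1$pepnet[!s1$planted]))
  expect_true(all(s1$peptidebio[s1$planted] == "not_active"))
  expect_true(all(s1$pepnet >= 0 & s1$pepnet <= 1))
})

test_that("maximal score separation puts planted windows in the top block", {
  sc <- synthetic_scenario(seed = 19, positive_score_mean = 0.999,
                           decoy_score_mean = 0.001,
                           score_concentration = 2000,
                           hemolysis_decoy_frac = 0)
  p <- generate_proteome(sc)
  pos_ids <- p$manifest$transcript_id[p$manifest$class == "positive"]
  windows <- extract_windows_set(p$proteins[pos_ids])
  scores <- generate_predictor_scores(windows, p$manifest, sc)
  ranked <- rank_candidates(scores)
  n_planted <- sum(scores$planted)
  top_ids <- ranked$peptide_id[seq_len(n_planted)]
  expect_setequal(top_ids, scores$peptide_id[scores$planted])
})

test_that("generated files survive a read/write round trip unchanged", {
  sc <- synthetic_scenario(seed = 23)
  d <- tempfile()
  write_synthetic_inputs(sc, d)

  prot <- read_peptides(file.path(d, "proteome.fasta"))
  f2 <- tempfile(fileext = ".fasta")
  write_peptides(prot, f2)
  expect_identical(read_peptides(f2), prot)

  hits <- read_homology_hits(file.path(d, "homology.tsv"))
  expect_true(all(hits$query_coverage >= 0 & hits$query_coverage <= 1))
  expr <- read_tsv(file.path(d, "expression.tsv"))
  expect_true(all(expr$tpm >= 0))
  sec <- read_tsv(file.path(d, "secretion.tsv"))
  expect_setequal(names(prot), sec$transcript_id)
})
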