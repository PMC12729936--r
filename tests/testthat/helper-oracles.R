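# Shared fixtures and independent oracles.

# Printed physicochemistry/composition reference rows for the eight assay
# peptides (sequence-true; see the composition tests for the rows whose
# printed counts disagree with their own sequences).
table_peptides <- c(
  Pep1 = "VVSTTSYCKKMKKDCNDYTK",
  Pep2 = "VRKLTRYCKKMKKDCKRYWK",
  Pep3 = "GADCCVVSTTSYCKKMKKDC",
  Pep4 = "AAKRCVRSWTRYCKKMKKDC",
  Pep5 = "MMGHRCRAMKCMKKVHDK",
  Pep6 = "MMKHMCRAMKCMKKVMDK",
  Pep7 = "TCVNHCTRHRHSCCRSKM",
  NC_CV = "CVNHCTRHRHSCCRSKMK")

nc_cv <- table_peptides[["NC_CV"]]

random_peptide <- function(min_len = 5, max_len = 30) {
  n <- sample(min_len:max_len, 1)
  paste(sample(hdpminer::AA_STANDARD, n, replace = TRUE), collapse = "")
}

# Independent pI oracle: exhaustive grid search for the pH of minimum
# absolute charge, 0.001 steps across the full scale.
grid_pi <- function(seq, pkas = pka_table(), step = 0.001) {
  grid <- seq(step, 14 - step, by = step)
  z <- charge_at_ph(seq, grid, pkas)
  grid[which.min(abs(z))]
}

# Independent hydrophobic-moment oracle: literal complex sum, term by term.
direct_moment <- function(seq, scale = hydrophobicity_scale()) {
  chars <- strsplit(seq, "")[[1]]
  delta <- scale$angle_per_residue * pi / 180
  acc <- 0 + 0i
  for (k in seq_along(chars))
    acc <- acc + scale$values[[chars[k]]] * exp(1i * delta * (k - 1))
  Mod(acc) / length(chars)
}

# Brute-force window enumeration used against extract_windows.
count_windows_brute <- function(L, k, step) {
  n <- 0
  s <- 0
  while (s + k <= L) { n <- n + 1; s <- s + step }
  n
}

# Random evidence tables for the cascade intersection property.
random_evidence <- function(n_ids = 20) {
  ids <- sprintf("T%03d", seq_len(n_ids))
  hits <- data.frame(
    query_id = sample(ids, n_ids * 2, replace = TRUE),
    subject_id = sprintf("S%03d", sample.int(500, n_ids * 2, replace = TRUE)),
    evalue = 10^runif(n_ids * 2, -10, 1),
    query_coverage = runif(n_ids * 2),
    stringsAsFactors = FALSE)
  secretion <- data.frame(
    transcript_id = ids,
    has_signal_peptide = sample(c(TRUE, FALSE), n_ids, replace = TRUE),
    stringsAsFactors = FALSE)
  expression <- data.frame(
    transcript_id = ids,
    tpm = runif(n_ids, 0, 120),
    stringsAsFactors = FALSE)
  list(hits = hits, secretion = secretion, expression = expression)
}
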