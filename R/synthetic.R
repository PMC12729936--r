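# Seeded generator of a venom-gland-like secretome with planted ground truth.
# A minority of transcripts are simultaneously toxin-homologous, signal-
# peptide-bearing, highly expressed and helix-rich, and carry a cationic
# Cys/His-rich 18-mer inside their helical block; every decoy violates
# exactly one of the four funnel criteria. All randomness is drawn under an
# explicit seed and the caller's RNG state is left untouched.

#' Synthetic secretome scenario
#'
#' Parameters of the generator. Defaults describe a compact but structured
#' secretome: 60 transcripts of which 5 are planted positives, the remaining
#' decoys split evenly across the four single-criterion failure classes,
#' log-normal expression shifted above the 40-TPM gate for passing classes,
#' and Beta-distributed predictor scores whose means separate planted windows
#' from decoy windows.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_transcripts total number of transcripts.
#' @param n_planted number of planted triple-positive, helix-rich transcripts.
#' @param decoy_mix named proportions (summing to 1) of decoy classes
#'   `fail_homology`, `fail_signal`, `fail_expression`, `non_helical`.
#' @param tpm_meanlog,tpm_sdlog log-scale parameters of the log-normal
#'   expression excess added above the TPM gate for passing transcripts.
#' @param helix_len_range length range (residues) of the helix-former block.
#' @param positive_score_mean,decoy_score_mean Beta means of predictor scores
#'   for planted vs decoy windows.
#' @param score_concentration Beta concentration (a+b); larger = tighter.
#' @param hemolysis_decoy_frac probability that a hemolysis predictor calls a
#'   decoy window active.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed,
                               n_transcripts = 60,
                               n_planted = 5,
                               decoy_mix = c(fail_homology = 0.25,
                                             fail_signal = 0.25,
                                             fail_expression = 0.25,
                                             non_helical = 0.25),
                               tpm_meanlog = 3, tpm_sdlog = 1,
                               helix_len_range = c(26, 40),
                               positive_score_mean = 0.80,
                               decoy_score_mean = 0.25,
                               score_concentration = 30,
                               hemolysis_decoy_frac = 0.20) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory")
  if (n_planted > n_transcripts)
    stop("cannot plant more positives than transcripts")
  need <- c("fail_homology", "fail_signal", "fail_expression", "non_helical")
  if (!setequal(names(decoy_mix), need))
    stop("decoy_mix must name exactly: ", paste(need, collapse = ", "))
  if (abs(sum(decoy_mix) - 1) > 1e-8)
    stop("decoy_mix proportions must sum to 1")
  if (any(decoy_mix < 0)) stop("decoy_mix proportions must be non-negative")
  if (helix_len_range[1] < 26)
    stop("helix blocks must be at least 26 residues to host an 18-mer window")
  structure(list(seed = as.integer(seed), n_transcripts = n_transcripts,
                 n_planted = n_planted, decoy_mix = decoy_mix[need],
                 tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog,
                 helix_len_range = helix_len_range,
                 positive_score_mean = positive_score_mean,
                 decoy_score_mean = decoy_score_mean,
                 score_concentration = score_concentration,
                 hemolysis_decoy_frac = hemolysis_decoy_frac),
            class = "synthetic_scenario")
}

rand_res <- function(n, pool, prob = NULL)
  paste(sample(pool, n, replace = TRUE, prob = prob), collapse = "")

signal_prefix <- function()
  paste0("M", rand_res(15, c("L", "A", "V", "I", "F"),
                       c(0.35, 0.25, 0.20, 0.10, 0.10)))

coil_seq <- function(n)
  rand_res(n, c("G", "S", "P", "N", "T", "D", "Q"))

helix_flank <- function(n)
  rand_res(n, c("A", "L", "E", "K", "M", "Q", "F"),
           c(0.22, 0.20, 0.18, 0.16, 0.10, 0.08, 0.06))

# Cationic, Cys/His-rich 18-mer built from helix-compatible residues: five
# basic residues (mostly Lys), two Cys, two His, the rest helix formers.
planted_window_seq <- function() {
  res <- c(sample(c("K", "R"), 5, replace = TRUE, prob = c(0.7, 0.3)),
           rep("C", 2), rep("H", 2),
           sample(c("A", "L", "M", "K", "Q", "F"), 9, replace = TRUE))
  paste(sample(res), collapse = "")
}

# Allocate decoy class counts from proportions, preserving the total.
allocate_counts <- function(n, prop) {
  cum <- round(cumsum(prop) * n)
  counts <- diff(c(0L, cum))
  names(counts) <- names(prop)
  counts
}

#' Generate a synthetic venom-gland proteome
#'
#' Emits one protein per transcript. Planted positives carry an N-terminal
#' signal-like prefix, a coil linker, a helix-former block hosting a cationic
#' Cys/His-rich 18-mer (verified to sit inside one annotated helix segment of
#' the full protein under the default annotation parameters), and a coil
#' tail. Helical decoys share the architecture without the planted window;
#' non-helical decoys have a coil body. Identical seeds give identical
#' output.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `proteins` (named character vector) and `manifest`
#'   (data.frame: `transcript_id`, `class`, `fails_criterion`, `helix_start`,
#'   `helix_end`, `window_start` — 0-based — and `window_seq`).
#' @export
generate_proteome <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed, {
    n <- scenario$n_transcripts
    n_decoys <- n - scenario$n_planted
    counts <- allocate_counts(n_decoys, scenario$decoy_mix)
    classes <- sample(c(rep("positive", scenario$n_planted),
                        rep(names(counts), counts)))
    ids <- sprintf("DN%03d", seq_len(n))
    lr <- scenario$helix_len_range

    build_helical <- function(planted) {
      L <- sample(lr[1]:lr[2], 1)
      sig <- signal_prefix()
      linker <- coil_seq(sample(8:14, 1))
      tail <- coil_seq(sample(6:12, 1))
      hstart <- nchar(sig) + nchar(linker)
      if (!planted) {
        block <- helix_flank(L)
        return(list(seq = paste0(sig, linker, block, tail),
                    helix_start = hstart, helix_end = hstart + L,
                    window_start = NA_integer_, window_seq = NA_character_))
      }
      f_max <- L - 18 - 4
      for (try in 1:100) {
        f <- sample(4:f_max, 1)
        win <- planted_window_seq()
        block <- paste0(helix_flank(f), win, helix_flank(L - 18 - f))
        prot <- paste0(sig, linker, block, tail)
        wstart <- hstart + f
        ann <- annotate_helices(prot)
        seg <- ann$segments
        ok <- nrow(seg) > 0 &&
          any(seg$start <= wstart & seg$end >= wstart + 18)
        if (ok)
          return(list(seq = prot, helix_start = hstart,
                      helix_end = hstart + L,
                      window_start = as.integer(wstart), window_seq = win))
      }
      stop("failed to embed a planted window inside a helix segment")
    }

    rows <- vector("list", n)
    proteins <- character(n)
    for (i in seq_len(n)) {
      cl <- classes[i]
      if (cl == "non_helical") {
        prot <- paste0(signal_prefix(), coil_seq(sample(50:70, 1)))
        info <- list(seq = prot, helix_start = NA_integer_,
                     helix_end = NA_integer_,
                     window_start = NA_integer_, window_seq = NA_character_)
      } else {
        info <- build_helical(planted = cl == "positive")
      }
      proteins[i] <- info$seq
      rows[[i]] <- data.frame(
        transcript_id = ids[i], class = cl,
        fails_criterion = switch(cl, positive = "none",
                                 fail_homology = "homology",
                                 fail_signal = "signal",
                                 fail_expression = "expression",
                                 non_helical = "helix"),
        helix_start = info$helix_start, helix_end = info$helix_end,
        window_start = info$window_start, window_seq = info$window_seq,
        stringsAsFactors = FALSE)
    }
    names(proteins) <- ids
    list(proteins = proteins, manifest = do.call(rbind, rows))
  })
}

#' Generate evidence tables for a synthetic proteome
#'
#' Produces the three tabular inputs of the candidate cascade, consistent
#' with the manifest: classes other than `fail_homology` receive at least one
#' qualifying toxin hit (E-value <= 0.05, coverage >= 0.60); classes other
#' than `fail_signal` are flagged secreted; classes other than
#' `fail_expression` draw TPM above the gate. Each failing class violates
#' only its own table.
#'
#' @param proteome result of [generate_proteome()].
#' @param scenario the same [synthetic_scenario()].
#' @return list with data.frames `homology` (13-column hit table),
#'   `secretion` and `expression`.
#' @export
generate_evidence_tables <- function(proteome, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  manifest <- proteome$manifest
  proteins <- proteome$proteins
  if (!setequal(names(proteins), manifest$transcript_id))
    stop("manifest and proteome transcript ids do not match")
  with_seed(scenario$seed + 1L, {
    hit_rows <- list()
    for (i in seq_len(nrow(manifest))) {
      id <- manifest$transcript_id[i]
      cl <- manifest$class[i]
      qlen <- nchar(proteins[[id]])
      n_hits <- sample(1:3, 1)
      for (h in seq_len(n_hits)) {
        if (cl == "fail_homology") {
          # violate E-value or coverage, never satisfy both gates
          if (stats::runif(1) < 0.5) {
            ev <- 10^stats::runif(1, log10(0.06), 1)
            cov <- stats::runif(1, 0.60, 0.95)
          } else {
            ev <- 10^stats::runif(1, -30, log10(0.05))
            cov <- stats::runif(1, 0.05, 0.55)
          }
        } else if (h == 1) {
          ev <- 10^stats::runif(1, -30, log10(0.05))
          cov <- stats::runif(1, 0.60, 0.98)
        } else {
          # secondary hits may be anything qualifying or not
          ev <- 10^stats::runif(1, -10, 0.5)
          cov <- stats::runif(1, 0.30, 0.98)
        }
        ev <- signif(ev, 4)
        cov <- round(cov, 4)
        alen <- max(1L, round(cov * qlen))
        pident <- round(stats::runif(1, 35, 95), 1)
        hit_rows[[length(hit_rows) + 1]] <- data.frame(
          query_id = id,
          subject_id = sprintf("TOX_%04d", sample.int(9999, 1)),
          percent_identity = pident, length = alen,
          mismatch = max(0L, round(alen * (100 - pident) / 100)),
          gapopen = sample(0:2, 1), qstart = 1L, qend = alen,
          sstart = 1L, send = alen, evalue = ev,
          bitscore = round(stats::runif(1, 50, 300), 1),
          query_coverage = cov, stringsAsFactors = FALSE)
      }
    }
    homology <- do.call(rbind, hit_rows)

    secretion <- data.frame(
      transcript_id = manifest$transcript_id,
      has_signal_peptide = ifelse(manifest$class == "fail_signal",
                                  "false", "true"),
      stringsAsFactors = FALSE)

    tpm <- ifelse(manifest$class == "fail_expression",
                  stats::runif(nrow(manifest), 0, 39.5),
                  40 + stats::rlnorm(nrow(manifest), scenario$tpm_meanlog,
                                     scenario$tpm_sdlog))
    expression <- data.frame(transcript_id = manifest$transcript_id,
                             tpm = round(tpm, 3), stringsAsFactors = FALSE)
    list(homology = homology, secretion = secretion,
         expression = expression)
  })
}

#' Generate synthetic predictor scores for peptide windows
#'
#' Planted windows (those matching a manifest `window_seq` at the recorded
#' parent and offset) draw all four numeric scores from the high-mean Beta
#' distribution and are never called hemolytic; every other window draws from
#' the low-mean Beta and each hemolysis predictor calls it active with
#' probability `hemolysis_decoy_frac`.
#'
#' @param windows data.frame from [extract_windows_set()] (needs
#'   `window_id`, `parent_id`, `start`, `sequence`).
#' @param manifest manifest data.frame from [generate_proteome()].
#' @param scenario the same [synthetic_scenario()].
#' @return score data.frame in the layout read by
#'   [read_predictor_scores()], plus a logical `planted` column.
#' @export
generate_predictor_scores <- function(windows, manifest, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed + 2L, {
    key <- paste(manifest$transcript_id, manifest$window_start)
    planted <- paste(windows$parent_id, windows$start) %in%
      key[!is.na(manifest$window_start)]
    n <- nrow(windows)
    m <- ifelse(planted, scenario$positive_score_mean,
                scenario$decoy_score_mean)
    cc <- scenario$score_concentration
    draw <- function() round(stats::rbeta(n, m * cc, (1 - m) * cc), 4)
    call_draw <- function()
      ifelse(!planted & stats::runif(n) < scenario$hemolysis_decoy_frac,
             "active", "not_active")
    data.frame(peptide_id = windows$window_id,
               sequence = windows$sequence,
               pepnet = draw(), preaip = draw(), aipid = draw(),
               anoxppred = draw(),
               peptidebio = call_draw(), dbaasp = call_draw(),
               planted = planted, stringsAsFactors = FALSE)
  })
}

#' Write synthetic inputs to disk
#'
#' Materialises a scenario as the pipeline's on-disk input formats: a FASTA
#' proteome, the headerless 13-column homology table, 2-column secretion and
#' expression TSVs, and the ground-truth manifest TSV.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prot <- generate_proteome(scenario)
  ev <- generate_evidence_tables(prot, scenario)
  paths <- c(proteome = file.path(dir, "proteome.fasta"),
             homology = file.path(dir, "homology.tsv"),
             secretion = file.path(dir, "secretion.tsv"),
             expression = file.path(dir, "expression.tsv"),
             manifest = file.path(dir, "manifest.tsv"))
  write_peptides(prot$proteins, paths["proteome"])
  hom <- ev$homology
  hom$evalue <- fmt_sci(hom$evalue)
  hom$query_coverage <- fmt_num(hom$query_coverage, 4)
  hom$percent_identity <- fmt_num(hom$percent_identity, 1)
  hom$bitscore <- fmt_num(hom$bitscore, 1)
  hom[] <- lapply(hom, as.character)
  con <- file(paths["homology"], open = "wb")
  writeLines(do.call(paste, c(unname(hom), list(sep = "\t"))), con,
             sep = "\n")
  close(con)
  write_tsv(ev$secretion, paths["secretion"])
  expr <- ev$expression
  expr$tpm <- fmt_num(expr$tpm, 3)
  write_tsv(expr, paths["expression"])
  write_tsv(prot$manifest, paths["manifest"])
  invisible(paths)
}
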