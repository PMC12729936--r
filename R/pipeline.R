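# End-to-end orchestration: filter cascade -> helix annotation and enrichment
# -> 18-mer window design -> physicochemistry / composition -> veto + ranking,
# with TSV/FASTA reports and a deterministic run log.

#' Pipeline configuration
#'
#' Collects every knob of the discovery pipeline. In `synthetic` mode the
#' inputs are generated from `scenario`; in `files` mode they are read from
#' the given paths (predictor scores must then be supplied as a table
#' covering the designed windows).
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param scenario a [synthetic_scenario()] (synthetic mode).
#' @param proteome,homology,secretion,expression,scores input file paths
#'   (files mode).
#' @param filter_cfg a [filter_config()].
#' @param rank_cfg a [ranking_config()].
#' @param helix_w,helix_threshold,helix_min_run parameters of
#'   [annotate_helices()].
#' @param enrich_min minimum helical fraction for a candidate to be carried
#'   into window design.
#' @param k,step window length and stride of [extract_windows()].
#' @param min_charge,min_moment thresholds of [hdp_physchem_filter()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            scenario = NULL,
                            proteome = NULL, homology = NULL,
                            secretion = NULL, expression = NULL,
                            scores = NULL,
                            filter_cfg = filter_config(),
                            rank_cfg = ranking_config(),
                            helix_w = 6, helix_threshold = 1.03,
                            helix_min_run = 8, enrich_min = 0.5,
                            k = 18, step = 1,
                            min_charge = 2, min_moment = 0) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (!inherits(scenario, "synthetic_scenario"))
      stop("synthetic mode requires a synthetic_scenario")
  } else {
    paths <- c(proteome = proteome, homology = homology,
               secretion = secretion, expression = expression,
               scores = scores)
    if (length(paths) < 5)
      stop("files mode requires proteome, homology, secretion, expression ",
           "and scores paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(mode = mode, scenario = scenario, proteome = proteome,
                 homology = homology, secretion = secretion,
                 expression = expression, scores = scores,
                 filter_cfg = filter_cfg, rank_cfg = rank_cfg,
                 helix_w = helix_w, helix_threshold = helix_threshold,
                 helix_min_run = helix_min_run, enrich_min = enrich_min,
                 k = k, step = step, min_charge = min_charge,
                 min_moment = min_moment),
            class = "pipeline_config")
}

empty_ranking <- function() {
  data.frame(peptide_id = character(), aip_consensus = numeric(),
             aop_score = numeric(), passes_aip = logical(),
             passes_aop = logical(), composite_score = numeric(),
             rank = integer(), stringsAsFactors = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the discovery pipeline in memory
#'
#' Executes every stage on already-loaded inputs and returns all intermediate
#' tables. [run_pipeline()] wraps this with input generation/reading and
#' report writing.
#'
#' @param proteins named character vector of protein sequences.
#' @param homology,secretion,expression evidence data.frames.
#' @param cfg a [pipeline_config()].
#' @param score_fun function(windows) returning a predictor score table for
#'   the designed windows.
#' @return list with `candidates`, `annotations`, `enriched_ids`, `windows`,
#'   `profiles`, `composition`, `scores`, `ranking`, `log` (character lines).
#' @export
run_discovery <- function(proteins, homology, secretion, expression,
                          cfg, score_fun) {
  log <- c(sprintf("filter: evalue_max=%g coverage_min=%g tpm_min=%g annotation_evalue_max=%g",
                   cfg$filter_cfg$evalue_max, cfg$filter_cfg$coverage_min,
                   cfg$filter_cfg$tpm_min,
                   cfg$filter_cfg$annotation_evalue_max),
           sprintf("helix: w=%g threshold=%g min_run=%g enrich_min=%g",
                   cfg$helix_w, cfg$helix_threshold, cfg$helix_min_run,
                   cfg$enrich_min),
           sprintf("windows: k=%g step=%g", cfg$k, cfg$step),
           sprintf("physchem gate: min_charge=%g min_moment=%g",
                   cfg$min_charge, cfg$min_moment),
           sprintf("ranking: aip_weight=%g aop_weight=%g veto=%s",
                   cfg$rank_cfg$aip_weight, cfg$rank_cfg$aop_weight,
                   cfg$rank_cfg$veto_policy))

  candidates <- run_stage("candidate_filter",
    identify_candidates(homology, secretion, expression, cfg$filter_cfg))
  log <- c(log, sprintf("candidate_filter: %d transcripts in, %d candidates",
                        length(proteins), nrow(candidates)))

  empty_windows <- data.frame(parent_id = character(), start = integer(),
                              sequence = character(),
                              window_id = character(),
                              stringsAsFactors = FALSE)
  if (nrow(candidates) == 0) {
    warning("no transcripts survive the candidate cascade; ",
            "downstream reports will be empty")
    return(list(candidates = candidates, annotations = list(),
                enriched_ids = character(), windows = empty_windows,
                profiles = physchem_profile(character()),
                composition = count_antiox_residues(character()),
                scores = NULL,
                ranking = empty_ranking(),
                log = c(log, "pipeline: empty candidate set")))
  }

  cand_seqs <- proteins[candidates$transcript_id]
  annotations <- run_stage("helix_annotation",
    lapply(names(cand_seqs), function(nm)
      annotate_helices(cand_seqs[[nm]], id = nm, w = cfg$helix_w,
                       threshold = cfg$helix_threshold,
                       min_run = cfg$helix_min_run)))
  names(annotations) <- names(cand_seqs)
  fractions <- vapply(annotations, helix_fraction, numeric(1))
  enriched_ids <- names(fractions)[fractions >= cfg$enrich_min]
  log <- c(log, sprintf("helix_enrichment: %d candidates in, %d helix-enriched",
                        length(annotations), length(enriched_ids)))

  windows <- run_stage("window_design",
    extract_windows_set(cand_seqs[enriched_ids],
                        annotations = annotations[enriched_ids],
                        k = cfg$k, step = cfg$step))
  log <- c(log, sprintf("window_design: %d windows from %d proteins",
                        nrow(windows), length(enriched_ids)))

  wseqs <- stats::setNames(windows$sequence, windows$window_id)
  profiles <- run_stage("physchem",
    hdp_physchem_filter(physchem_profile(wseqs),
                        min_charge = cfg$min_charge,
                        min_moment = cfg$min_moment))
  composition <- run_stage("composition", count_antiox_residues(wseqs))
  eligible <- windows[profiles$hdp_pass, , drop = FALSE]
  log <- c(log, sprintf("physchem_gate: %d windows in, %d pass",
                        nrow(windows), nrow(eligible)))

  if (nrow(eligible) == 0) {
    warning("no windows pass the physicochemical gate; ranking is empty")
    scores <- NULL
    ranking <- empty_ranking()
  } else {
    scores <- run_stage("predictor_scores", score_fun(eligible))
    ranking <- run_stage("ranking", rank_candidates(scores, cfg$rank_cfg))
  }
  log <- c(log, sprintf("ranking: %d scored, %d ranked",
                        if (is.null(scores)) 0L else nrow(scores),
                        nrow(ranking)))

  list(candidates = candidates, annotations = annotations,
       enriched_ids = enriched_ids, windows = windows, profiles = profiles,
       composition = composition, scores = scores, ranking = ranking,
       log = log)
}

#' Run the full discovery pipeline and write reports
#'
#' Executes the stage order candidate cascade -> helix annotation/enrichment
#' -> sliding-window design -> physicochemistry and antioxidative composition
#' -> hemolysis veto and composite ranking, then writes a report bundle to
#' `out_dir`: `candidates.tsv`, `helices.tsv`, `windows.fasta`,
#' `physchem.tsv`, `composition.tsv`, `ranking.tsv` and `run_log.txt` (in
#' synthetic mode also the generated inputs under `inputs/`). Reports use
#' fixed number formatting, so reruns at the same seed are byte-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisible list as returned by [run_discovery()], plus `manifest`
#'   in synthetic mode and `paths` of the written reports.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- NULL
  if (cfg$mode == "synthetic") {
    prot <- run_stage("synthetic_inputs", generate_proteome(cfg$scenario))
    ev <- run_stage("synthetic_inputs",
                    generate_evidence_tables(prot, cfg$scenario))
    proteins <- prot$proteins
    manifest <- prot$manifest
    homology <- ev$homology
    secretion <- ev$secretion
    expression <- ev$expression
    score_fun <- function(w)
      generate_predictor_scores(w, manifest, cfg$scenario)
    in_dir <- file.path(out_dir, "inputs")
    run_stage("synthetic_inputs",
              write_synthetic_inputs(cfg$scenario, in_dir))
  } else {
    proteins <- run_stage("read_inputs", read_peptides(cfg$proteome))
    homology <- run_stage("read_inputs", read_homology_hits(cfg$homology))
    secretion <- run_stage("read_inputs", read_tsv(cfg$secretion))
    expression <- run_stage("read_inputs", read_tsv(cfg$expression))
    score_tab <- run_stage("read_inputs",
                           read_predictor_scores(cfg$scores, cfg$rank_cfg))
    score_fun <- function(w) {
      s <- score_tab[score_tab$peptide_id %in% w$window_id, , drop = FALSE]
      if (nrow(s) == 0)
        stop("score table covers none of the designed windows")
      s
    }
  }

  res <- run_discovery(proteins, homology, secretion, expression, cfg,
                       score_fun)
  res$manifest <- manifest
  res$paths <- write_reports(res, cfg, out_dir)
  invisible(res)
}

write_reports <- function(res, cfg, out_dir) {
  paths <- c(candidates = file.path(out_dir, "candidates.tsv"),
             helices = file.path(out_dir, "helices.tsv"),
             windows = file.path(out_dir, "windows.fasta"),
             physchem = file.path(out_dir, "physchem.tsv"),
             composition = file.path(out_dir, "composition.tsv"),
             ranking = file.path(out_dir, "ranking.tsv"),
             log = file.path(out_dir, "run_log.txt"))

  cand <- res$candidates
  if (nrow(cand) > 0) {
    cand$evalue <- fmt_sci(cand$evalue)
    cand$query_coverage <- fmt_num(cand$query_coverage, 4)
    cand$tpm <- fmt_num(cand$tpm, 3)
  }
  write_tsv(cand, paths["candidates"])

  write_helix_tsv(res$annotations, paths["helices"])

  if (nrow(res$windows) > 0)
    write_peptides(stats::setNames(res$windows$sequence,
                                   res$windows$window_id),
                   paths["windows"])
  else
    writeLines(character(), paths["windows"])

  prof <- res$profiles
  if (nrow(prof) > 0) {
    for (col in c("mw_gmol", "net_charge_ph7", "pi", "hydrophobic_moment",
                  "mean_hydrophobicity"))
      prof[[col]] <- fmt_num(prof[[col]], 4)
  }
  write_tsv(prof, paths["physchem"])
  write_tsv(res$composition, paths["composition"])

  rk <- res$ranking
  if (nrow(rk) > 0) {
    for (col in intersect(c("pepnet", "preaip", "aipid", "anoxppred",
                            "aip_consensus", "aop_score", "composite_score"),
                          names(rk)))
      rk[[col]] <- fmt_num(rk[[col]], 4)
  }
  write_tsv(rk, paths["ranking"])

  con <- file(paths["log"], open = "wb")
  writeLines(res$log, con, sep = "\n")
  close(con)
  paths
}

#' Characterize peptides from a FASTA file
#'
#' Combined physicochemistry and antioxidative-composition report: one row
#' per peptide with molecular weight, pH-7 net charge (raw and display),
#' isoelectric point, hydrophobic moment, mean hydrophobicity, solubility
#' class, and the three antioxidative residue-category counts with their
#' total. Duplicate ids are an integrity error.
#'
#' @param x FASTA path or named character vector of sequences.
#' @param masses,pkas,scale descriptor tables (see [physchem_profile()]).
#' @return data.frame, one row per peptide.
#' @export
characterize_peptides <- function(x, masses = residue_masses(),
                                  pkas = pka_table(),
                                  scale = hydrophobicity_scale()) {
  seqs <- if (is.character(x) && length(x) == 1 && file.exists(x))
    read_peptides(x) else x
  if (anyDuplicated(names(seqs)))
    stop("duplicate peptide id(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  prof <- physchem_profile(seqs, masses, pkas, scale)
  comp <- count_antiox_residues(seqs)
  cbind(prof, comp[, c("yw_count", "cm_count", "hkr_count", "antiox_total"),
                   drop = FALSE])
}
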