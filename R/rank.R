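# Aggregation of external predictor outputs into a final ranked shortlist:
# hemolysis calls act as a hard veto, anti-inflammatory (AIP) scores are
# averaged into a consensus, and the composite is a weighted mean of the AIP
# consensus and the antioxidative (AOP) score.

#' Ranking configuration
#'
#' @param aip_weight,aop_weight non-negative weights of the AIP consensus and
#'   the AOP score in the composite (normalised internally; defaults equal).
#' @param veto_policy `"any"` (default): vetoed when any hemolysis predictor
#'   calls the peptide active; `"all"`: vetoed only when all do.
#' @param pass_threshold score at or above which a consensus counts as a
#'   positive AIP/AOP call (reported as metadata, not used for ranking).
#' @param aip_cols,aop_col,hemolysis_cols column names of the score table
#'   holding the AIP scores, the AOP score and the hemolysis calls.
#' @return object of class `ranking_config`.
#' @export
ranking_config <- function(aip_weight = 0.5, aop_weight = 0.5,
                           veto_policy = c("any", "all"),
                           pass_threshold = 0.5,
                           aip_cols = c("pepnet", "preaip", "aipid"),
                           aop_col = "anoxppred",
                           hemolysis_cols = c("peptidebio", "dbaasp")) {
  veto_policy <- match.arg(veto_policy)
  if (aip_weight < 0 || aop_weight < 0 || aip_weight + aop_weight <= 0)
    stop("weights must be non-negative with a positive sum")
  if (pass_threshold < 0 || pass_threshold > 1)
    stop("pass_threshold must lie in [0, 1]")
  structure(list(aip_weight = aip_weight, aop_weight = aop_weight,
                 veto_policy = veto_policy, pass_threshold = pass_threshold,
                 aip_cols = aip_cols, aop_col = aop_col,
                 hemolysis_cols = hemolysis_cols),
            class = "ranking_config")
}

normalize_call <- function(x) {
  v <- gsub("[ -]", "_", tolower(trimws(as.character(x))))
  bad <- setdiff(unique(v), c("active", "not_active"))
  if (length(bad) > 0)
    stop("unknown hemolysis call label: '", bad[1],
         "' (expected 'active' or 'not_active')")
  v
}

#' Read a predictor score table
#'
#' Tab-separated with a header row: `peptide_id`, one numeric column per
#' AIP/AOP predictor (scores in [0, 1]) and one character column per
#' hemolysis predictor with calls `active` / `not_active` (case and
#' separator insensitive, so `Not active` parses too).
#'
#' @param path TSV path.
#' @param cfg a [ranking_config()] naming the expected columns.
#' @return validated data.frame.
#' @export
read_predictor_scores <- function(path, cfg = ranking_config()) {
  df <- read_tsv(path)
  validate_predictor_scores(df, cfg)
}

#' Validate a predictor score table
#'
#' @param scores data.frame of predictor outputs.
#' @param cfg a [ranking_config()].
#' @return the validated data.frame with normalised hemolysis calls.
#' @export
validate_predictor_scores <- function(scores, cfg = ranking_config()) {
  missing <- setdiff(c("peptide_id", cfg$aip_cols, cfg$aop_col),
                     names(scores))
  if (length(missing) > 0)
    stop("score table missing columns: ", paste(missing, collapse = ", "))
  if (length(cfg$aip_cols) < 1) stop("at least one AIP score column required")
  for (col in c(cfg$aip_cols, cfg$aop_col)) {
    v <- as.numeric(scores[[col]])
    if (any(!is.finite(v) | v < 0 | v > 1))
      stop("scores in column '", col, "' must lie in [0, 1]")
    scores[[col]] <- v
  }
  for (col in intersect(cfg$hemolysis_cols, names(scores)))
    scores[[col]] <- normalize_call(scores[[col]])
  scores
}

#' Apply hemolysis vetoes
#'
#' Under the default any-active policy a peptide is vetoed as soon as one
#' hemolysis predictor calls it active; under all-active, only when every
#' predictor does. An empty hemolysis map vetoes nothing but emits a warning.
#'
#' @param scores validated score data.frame.
#' @param cfg a [ranking_config()].
#' @return `scores` with logical column `vetoed` and character column
#'   `veto_reasons` (comma-separated flagging predictors, "" if none).
#' @export
apply_vetoes <- function(scores, cfg = ranking_config()) {
  cols <- intersect(cfg$hemolysis_cols, names(scores))
  if (length(cols) == 0) {
    warning("no hemolysis predictions available; no candidates vetoed")
    scores$vetoed <- rep(FALSE, nrow(scores))
    scores$veto_reasons <- rep("", nrow(scores))
    return(scores)
  }
  calls <- vapply(cols, function(col)
    normalize_call(scores[[col]]) == "active", logical(nrow(scores)))
  calls <- matrix(calls, nrow = nrow(scores),
                  dimnames = list(NULL, cols))
  scores$vetoed <- if (cfg$veto_policy == "any") rowSums(calls) > 0
  else rowSums(calls) == length(cols)
  scores$veto_reasons <- apply(calls, 1, function(r)
    paste(cols[r], collapse = ","))
  scores$veto_reasons[!scores$vetoed] <- ""
  scores
}

#' Composite predictor score
#'
#' Weighted mean of the AIP consensus (arithmetic mean of all AIP predictor
#' scores) and the AOP score; monotone non-decreasing in every input and
#' bounded in [0, 1].
#'
#' @param scores validated score data.frame.
#' @param cfg a [ranking_config()].
#' @return numeric vector of composite scores, one per row.
#' @export
composite_score <- function(scores, cfg = ranking_config()) {
  scores <- validate_predictor_scores(scores, cfg)
  aip <- rowMeans(as.matrix(scores[, cfg$aip_cols, drop = FALSE]))
  aop <- scores[[cfg$aop_col]]
  (cfg$aip_weight * aip + cfg$aop_weight * aop) /
    (cfg$aip_weight + cfg$aop_weight)
}

#' Rank candidate peptides
#'
#' Applies the hemolysis veto, computes composite scores for the survivors
#' and ranks them by descending composite, ties broken lexicographically by
#' peptide id. Vetoed candidates are excluded and receive no rank.
#'
#' @param scores score data.frame (one row per peptide).
#' @param cfg a [ranking_config()].
#' @return data.frame of non-vetoed candidates ordered by rank, with columns
#'   `peptide_id`, `aip_consensus`, `aop_score`, `passes_aip`, `passes_aop`,
#'   `composite_score`, `rank`, plus the original per-tool columns.
#' @export
rank_candidates <- function(scores, cfg = ranking_config()) {
  scores <- validate_predictor_scores(scores, cfg)
  scores <- apply_vetoes(scores, cfg)
  kept <- scores[!scores$vetoed, , drop = FALSE]
  if (nrow(kept) == 0) {
    out <- kept
    out$aip_consensus <- numeric(0)
    out$aop_score <- numeric(0)
    out$passes_aip <- logical(0)
    out$passes_aop <- logical(0)
    out$composite_score <- numeric(0)
    out$rank <- integer(0)
    return(out)
  }
  kept$aip_consensus <- rowMeans(as.matrix(kept[, cfg$aip_cols,
                                                drop = FALSE]))
  kept$aop_score <- kept[[cfg$aop_col]]
  kept$passes_aip <- kept$aip_consensus >= cfg$pass_threshold
  kept$passes_aop <- kept$aop_score >= cfg$pass_threshold
  kept$composite_score <- (cfg$aip_weight * kept$aip_consensus +
                             cfg$aop_weight * kept$aop_score) /
    (cfg$aip_weight + cfg$aop_weight)
  kept <- kept[order(-kept$composite_score, kept$peptide_id), , drop = FALSE]
  kept$rank <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  kept
}
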