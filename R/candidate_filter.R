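# The three-criterion toxin/venom candidate cascade: homology to known toxins
# (E-value and query-coverage gate), predicted secretion (signal peptide), and
# expression (TPM gate). Candidates are the intersection of the three filters.

#' Filter cascade thresholds
#'
#' Thresholds of the candidate cascade. Candidacy uses `evalue_max` together
#' with `coverage_min`; `annotation_evalue_max` is the stricter cutoff at
#' which a hit is additionally labelled a confident annotation (reported as
#' metadata, not used for candidacy). All thresholds are inclusive.
#'
#' @param evalue_max maximum E-value for a qualifying homology hit.
#' @param coverage_min minimum query coverage (fraction of the query aligned).
#' @param tpm_min minimum expression in transcripts per million.
#' @param annotation_evalue_max E-value below which a hit counts as a
#'   confident functional annotation.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(evalue_max = 0.05, coverage_min = 0.60,
                          tpm_min = 40, annotation_evalue_max = 1e-5) {
  if (evalue_max < 0 || annotation_evalue_max < 0)
    stop("E-value thresholds must be non-negative")
  if (coverage_min < 0 || coverage_min > 1)
    stop("coverage_min must lie in [0, 1]")
  if (tpm_min < 0) stop("tpm_min must be non-negative")
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 tpm_min = tpm_min,
                 annotation_evalue_max = annotation_evalue_max),
            class = "filter_config")
}

.hit_columns <- c("query_id", "subject_id", "percent_identity", "length",
                  "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore", "query_coverage")

#' Read a homology hit table
#'
#' Reads a headerless 13-column tab-separated hit table: the 12 standard
#' tabular alignment columns (query id, subject id, percent identity,
#' alignment length, mismatches, gap opens, query/subject start/end, E-value,
#' bit score) plus an appended query-coverage column expressed as a fraction
#' in [0, 1] (alignment length over query length, precomputed by the hit
#' generator). Malformed rows are rejected with their line number.
#'
#' @param path tab-separated file path.
#' @return validated data.frame with the 13 named columns.
#' @export
read_homology_hits <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 13)
    stop("homology table must have 13 tab-separated columns, found ",
         ncol(df))
  names(df) <- .hit_columns
  validate_homology_hits(df)
}

#' Validate a homology hit table
#'
#' @param hits data.frame carrying at least `query_id`, `subject_id`,
#'   `evalue`, `query_coverage`.
#' @return the validated data.frame.
#' @export
validate_homology_hits <- function(hits) {
  needed <- c("query_id", "subject_id", "evalue", "query_coverage")
  missing <- setdiff(needed, names(hits))
  if (length(missing) > 0)
    stop("homology table missing columns: ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(hits$evalue) | hits$evalue < 0)
  if (length(bad) > 0)
    stop("invalid E-value at line ", bad[1], ": ", hits$evalue[bad[1]])
  bad <- which(!is.finite(hits$query_coverage) | hits$query_coverage < 0 |
                 hits$query_coverage > 1)
  if (length(bad) > 0)
    stop("query coverage outside [0, 1] at line ", bad[1], ": ",
         hits$query_coverage[bad[1]])
  hits
}

#' Homology filter
#'
#' Retains every transcript with at least one hit passing both the E-value
#' and the query-coverage gate (inclusive), and reports the best hit per
#' retained transcript: lowest E-value, ties broken by highest coverage, then
#' lexicographic subject id.
#'
#' @param hits validated hit data.frame (see [read_homology_hits()]).
#' @param cfg a [filter_config()].
#' @return data.frame with one row per retained transcript: `transcript_id`,
#'   `subject_id`, `evalue`, `query_coverage`, `annotated` (TRUE when the
#'   best hit clears `annotation_evalue_max`).
#' @export
filter_homology <- function(hits, cfg = filter_config()) {
  hits <- validate_homology_hits(hits)
  keep <- hits[hits$evalue <= cfg$evalue_max &
                 hits$query_coverage >= cfg$coverage_min, , drop = FALSE]
  if (nrow(keep) == 0)
    return(data.frame(transcript_id = character(), subject_id = character(),
                      evalue = numeric(), query_coverage = numeric(),
                      annotated = logical(), stringsAsFactors = FALSE))
  ord <- order(keep$query_id, keep$evalue, -keep$query_coverage,
               keep$subject_id)
  keep <- keep[ord, , drop = FALSE]
  best <- keep[!duplicated(keep$query_id), , drop = FALSE]
  data.frame(transcript_id = best$query_id, subject_id = best$subject_id,
             evalue = best$evalue, query_coverage = best$query_coverage,
             annotated = best$evalue <= cfg$annotation_evalue_max,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Secretion filter
#'
#' Returns the transcripts whose annotation flags an N-terminal signal
#' peptide. Duplicate records are tolerated only when they agree; conflicting
#' duplicates are an error.
#'
#' @param annotations data.frame with columns `transcript_id` and
#'   `has_signal_peptide` (logical, or "true"/"false"/"yes"/"no"/1/0).
#' @return character vector of transcript ids with a signal peptide.
#' @export
filter_secretion <- function(annotations) {
  stopifnot(all(c("transcript_id", "has_signal_peptide") %in%
                  names(annotations)))
  flag <- parse_flag(annotations$has_signal_peptide)
  agg <- tapply(flag, annotations$transcript_id,
                function(v) length(unique(v)))
  conflicted <- names(agg)[agg > 1]
  if (length(conflicted) > 0)
    stop("conflicting signal-peptide flags for transcript(s): ",
         paste(conflicted, collapse = ", "))
  ids <- annotations$transcript_id[flag]
  sort(unique(ids))
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "yes", "1", "t", "y")] <- TRUE
  out[v %in% c("false", "no", "0", "f", "n")] <- FALSE
  if (any(is.na(out)))
    stop("unrecognised boolean flag value: '",
         x[which(is.na(out))[1]], "'")
  out
}

#' Expression filter
#'
#' Retains transcripts whose abundance reaches `tpm_min` (inclusive).
#'
#' @param records data.frame with columns `transcript_id` and `tpm`.
#' @param cfg a [filter_config()].
#' @return character vector of transcript ids passing the TPM gate.
#' @export
filter_expression <- function(records, cfg = filter_config()) {
  stopifnot(all(c("transcript_id", "tpm") %in% names(records)))
  bad <- which(!is.finite(records$tpm) | records$tpm < 0)
  if (length(bad) > 0)
    stop("invalid TPM at line ", bad[1], ": ", records$tpm[bad[1]])
  sort(unique(records$transcript_id[records$tpm >= cfg$tpm_min]))
}

#' Identify toxin/venom candidates
#'
#' Full three-criterion cascade: a transcript is a candidate when it has a
#' qualifying toxin-homology hit, a predicted signal peptide, and expression
#' at or above the TPM gate. The result equals the intersection of the three
#' single filters; the cascade order never matters. Transcripts with homology
#' evidence but no expression record are warned about and treated as failing
#' the expression criterion (missing evidence is a failure, not a pass).
#'
#' @param hits homology hit data.frame.
#' @param annotations secretion annotation data.frame.
#' @param expression expression data.frame.
#' @param cfg a [filter_config()].
#' @return data.frame of candidates sorted by descending TPM (ties by id):
#'   `transcript_id`, `subject_id`, `evalue`, `query_coverage`, `tpm`,
#'   `annotated`.
#' @export
identify_candidates <- function(hits, annotations, expression,
                                cfg = filter_config()) {
  hom <- filter_homology(hits, cfg)
  sec <- filter_secretion(annotations)
  expr_ids <- filter_expression(expression, cfg)
  unmeasured <- setdiff(hom$transcript_id, expression$transcript_id)
  if (length(unmeasured) > 0)
    warning("transcript(s) with homology evidence but no expression record ",
            "(treated as failing the TPM gate): ",
            paste(unmeasured, collapse = ", "))
  ids <- intersect(intersect(hom$transcript_id, sec), expr_ids)
  out <- hom[match(ids, hom$transcript_id), , drop = FALSE]
  out$tpm <- expression$tpm[match(ids, expression$transcript_id)]
  out <- out[order(-out$tpm, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("transcript_id", "subject_id", "evalue", "query_coverage", "tpm",
          "annotated")]
}
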