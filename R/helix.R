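# Helix annotation and sliding-window peptide design. Helicity is scored with
# smoothed Chou-Fasman propensities — a transparent, fully tabulated surrogate
# for black-box structure predictors — and helical regions are segmented into
# overlapping fixed-length (default 18-mer) candidate peptides.

#' Annotate alpha-helical regions
#'
#' Per-residue Chou-Fasman helix propensities are smoothed with a centred
#' moving average of width `w` (truncated at the chain ends); maximal runs of
#' residues whose smoothed propensity reaches `threshold` become helix
#' segments, and runs shorter than `min_run` residues are discarded.
#' Sequences shorter than the smoothing window yield an empty annotation
#' flagged degenerate.
#'
#' @param seq peptide/protein sequence.
#' @param id label recorded in the annotation.
#' @param w smoothing window width in residues.
#' @param threshold smoothed propensity needed to call a residue helical
#'   (1.0 = indifferent on the Chou-Fasman scale).
#' @param min_run minimum segment length in residues.
#' @param propensities a [helix_propensities()] table.
#' @return object of class `helix_annotation`: list with `id`, `length`,
#'   `segments` (data.frame `start`, `end` in 0-based half-open coordinates),
#'   `helix_fraction` and `degenerate`.
#' @export
annotate_helices <- function(seq, id = "protein", w = 6, threshold = 1.03,
                             min_run = 8,
                             propensities = helix_propensities()) {
  chars <- pep_chars(seq, id)
  n <- length(chars)
  empty <- data.frame(start = integer(), end = integer())
  if (n < w) {
    return(structure(list(id = id, length = n, segments = empty,
                          helix_fraction = 0, degenerate = TRUE),
                     class = "helix_annotation"))
  }
  p <- unname(propensities[chars])
  left <- floor((w - 1) / 2)
  right <- floor(w / 2)
  cs <- cumsum(c(0, p))
  i <- seq_len(n)
  lo <- pmax(1L, i - left)
  hi <- pmin(n, i + right)
  smoothed <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  helical <- smoothed >= threshold
  r <- rle(helical)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  segments <- data.frame(start = starts[keep] - 1L, end = ends[keep])
  structure(list(id = id, length = n, segments = segments,
                 helix_fraction = sum(segments$end - segments$start) / n,
                 degenerate = FALSE),
            class = "helix_annotation")
}

#' Helical fraction of a protein
#'
#' Total annotated helix length divided by sequence length; the quantity used
#' to call a protein helix-enriched (default enrichment threshold 0.5 in the
#' pipeline).
#'
#' @param annotation a [annotate_helices()] result.
#' @return fraction in [0, 1].
#' @export
helix_fraction <- function(annotation) {
  stopifnot(inherits(annotation, "helix_annotation"))
  annotation$helix_fraction
}

#' Extract sliding peptide windows from helical segments
#'
#' Slides a window of `k` residues with stride `step` across each helical
#' segment; a segment of length `L >= k` yields `floor((L - k) / step) + 1`
#' windows, shorter segments none. Windows are ordered by (parent id, start)
#' and duplicate sequences are removed keeping the first occurrence.
#'
#' @param seq parent sequence.
#' @param segments data.frame of helix segments (`start`, `end`, 0-based
#'   half-open), e.g. from [annotate_helices()].
#' @param k window length in residues.
#' @param step stride in residues.
#' @param id parent protein id recorded in the output.
#' @return data.frame with columns `parent_id`, `start` (0-based offset in
#'   the parent), `sequence`.
#' @export
extract_windows <- function(seq, segments, k = 18, step = 1,
                            id = "protein") {
  if (!is.numeric(k) || k < 1) stop("window length k must be >= 1")
  if (!is.numeric(step) || step < 1) stop("step must be >= 1")
  chars <- pep_chars(seq, id)
  n <- length(chars)
  out <- list()
  if (nrow(segments) > 0) {
    if (any(segments$start < 0 | segments$end > n |
              segments$start >= segments$end))
      stop("segment coordinates out of bounds for '", id, "'")
    for (j in seq_len(nrow(segments))) {
      s0 <- segments$start[j]; e0 <- segments$end[j]
      L <- e0 - s0
      if (L < k) next
      starts <- seq(s0, e0 - k, by = step)
      out[[length(out) + 1]] <- data.frame(
        parent_id = id, start = as.integer(starts),
        sequence = substring(seq, starts + 1, starts + k),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(parent_id = character(), start = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$parent_id, df$start), , drop = FALSE]
  df <- df[!duplicated(df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Extract windows across several proteins
#'
#' Applies [annotate_helices()] and [extract_windows()] to each sequence and
#' binds the results; duplicate window sequences are deduplicated globally,
#' keeping the first occurrence in (parent id, start) order.
#'
#' @param seqs named character vector of protein sequences.
#' @param annotations optional named list of `helix_annotation` objects to
#'   use instead of de novo annotation.
#' @param k,step window length and stride.
#' @param ... further arguments to [annotate_helices()].
#' @return data.frame as in [extract_windows()], plus a `window_id` column
#'   formatted `parent|start|k`.
#' @export
extract_windows_set <- function(seqs, annotations = NULL, k = 18, step = 1,
                                ...) {
  pieces <- lapply(names(seqs), function(nm) {
    ann <- if (is.null(annotations)) annotate_helices(seqs[[nm]], id = nm, ...)
    else annotations[[nm]]
    extract_windows(seqs[[nm]], ann$segments, k = k, step = step, id = nm)
  })
  df <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(df) || nrow(df) == 0)
    df <- data.frame(parent_id = character(), start = integer(),
                     sequence = character(), stringsAsFactors = FALSE)
  df <- df[order(df$parent_id, df$start), , drop = FALSE]
  df <- df[!duplicated(df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df$window_id <- sprintf("%s|%d|%d", df$parent_id, df$start, k)
  df
}

#' Read / write helix annotations as TSV
#'
#' The interchange format is one row per segment with 1-based inclusive
#' coordinates (`protein_id`, `start`, `end`), converted to and from the
#' package's internal 0-based half-open convention.
#'
#' @param annotations named list of `helix_annotation` objects.
#' @param path TSV path.
#' @return `write_helix_tsv` returns `path` invisibly; `read_helix_tsv`
#'   returns a named list of segment data.frames (0-based half-open).
#' @export
write_helix_tsv <- function(annotations, path) {
  rows <- lapply(annotations, function(a) {
    if (nrow(a$segments) == 0) return(NULL)
    data.frame(protein_id = a$id, start = a$segments$start + 1L,
               end = a$segments$end, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(protein_id = character(), start = integer(),
                     end = integer())
  write_tsv(df, path)
}

#' @rdname write_helix_tsv
#' @export
read_helix_tsv <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("protein_id", "start", "end") %in% names(df)))
  split_df <- split(df, df$protein_id)
  lapply(split_df, function(d)
    data.frame(start = as.integer(d$start) - 1L, end = as.integer(d$end)))
}
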