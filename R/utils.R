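#' Round half away from zero
#'
#' Commercial ("round half up") rounding used for display of net charges, as
#' opposed to [base::round()]'s round-half-even. `round_half_up(4.95, 1)` is
#' 5.0, not 4.9.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a net charge for display
#'
#' Rounds half-up to one decimal; values that land on an integer are shown
#' without a decimal ("+5"), others with one ("+4.9"). Always carries an
#' explicit sign.
#'
#' @param x numeric vector of net charges.
#' @return character vector.
#' @export
format_charge <- function(x) {
  r <- round_half_up(x, 1)
  vapply(r, function(v) {
    if (isTRUE(all.equal(v, round(v)))) sprintf("%+d", as.integer(round(v)))
    else sprintf("%+.1f", v)
  }, character(1))
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
# Keeps generator functions free of global random-state side effects.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic TSV writer: all columns coerced to character by the caller or
# via as.character here; LF line endings, no quoting, header row.
write_tsv <- function(df, path) {
  df[] <- lapply(df, as.character)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df) > 0) {
    rows <- do.call(paste, c(unname(df), list(sep = "\t")))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Fixed-format numeric rendering so reports are byte-identical across reruns.
fmt_num <- function(x, digits = 4) sprintf(paste0("%.", digits, "f"), x)
fmt_sci <- function(x) sprintf("%.3e", x)
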