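#' The 20 standard amino acids
#'
#' One-letter codes of the standard proteinogenic alphabet, the only residues
#' accepted anywhere in the package. Non-standard codes (B, J, O, U, X, Z) and
#' lowercase letters are rejected, never silently skipped.
#'
#' @format character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate a peptide sequence
#'
#' Checks that `x` is a single non-empty string of uppercase one-letter codes
#' over the 20 standard amino acids. Any offending character is reported with
#' its position.
#'
#' @param x character scalar, the candidate sequence.
#' @param id label used in error messages.
#' @return the validated sequence, invisibly usable as-is.
#' @examples
#' validate_peptide("CVNHCTRHRHSCCRSKMK")
#' @export
validate_peptide <- function(x, id = "peptide") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence for '", id, "' must be a single character string")
  if (nchar(x) < 1L)
    stop("sequence for '", id, "' is empty")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_STANDARD))
  if (length(bad) > 0L)
    stop("invalid residue '", chars[bad[1]], "' at position ", bad[1],
         " in '", id, "' (only uppercase standard one-letter codes allowed)")
  x
}

# Split into residue characters after validation.
pep_chars <- function(x, id = "peptide") {
  strsplit(validate_peptide(x, id), "", fixed = TRUE)[[1]]
}

#' Read peptide sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that returns a named
#' character vector and validates every record against the standard alphabet.
#'
#' @param path FASTA file path.
#' @return named character vector of validated sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_peptides <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  for (i in seq_along(seqs)) validate_peptide(seqs[[i]], names(seqs)[i])
  seqs
}

#' Write peptide sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_peptides <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
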