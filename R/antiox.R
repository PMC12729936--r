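# Antioxidative amino-acid composition: the three residue categories
# classically linked to radical scavenging — aromatic (Y, W), sulfur-bearing
# (C, M) and nitrogen-rich basic (H, K, R).

#' Count antioxidative residues by category
#'
#' Tallies the aromatic (Y, W), sulfur-containing (C, M) and nitrogen-rich
#' basic (H, K, R) residues of each peptide, plus their total. Counts depend
#' only on composition, never on residue order.
#'
#' @param seqs named character vector of peptide sequences.
#' @return data.frame with columns `id`, `sequence`, `length`, `yw_count`,
#'   `cm_count`, `hkr_count`, `antiox_total`.
#' @examples
#' count_antiox_residues(c(NC_CV = "CVNHCTRHRHSCCRSKMK"))
#' @export
count_antiox_residues <- function(seqs) {
  if (is.null(names(seqs)) && length(seqs) > 0)
    names(seqs) <- paste0("peptide", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    chars <- pep_chars(seqs[[i]], names(seqs)[i])
    yw <- sum(chars %in% c("Y", "W"))
    cm <- sum(chars %in% c("C", "M"))
    hkr <- sum(chars %in% c("H", "K", "R"))
    data.frame(id = names(seqs)[i], sequence = seqs[[i]],
               length = length(chars),
               yw_count = yw, cm_count = cm, hkr_count = hkr,
               antiox_total = yw + cm + hkr, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), yw_count = integer(),
                      cm_count = integer(), hkr_count = integer(),
                      antiox_total = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
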