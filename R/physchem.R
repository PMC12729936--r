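# Sequence-derived physicochemical descriptors for host-defense peptide
# screening: average molecular weight, Henderson-Hasselbalch net charge and
# isoelectric point, Eisenberg hydrophobic moment, and a charge-based water
# solubility surrogate.

#' Average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water mass, so that concatenating
#' two peptides weighs the sum of the parts minus one water (a condensation).
#'
#' @param seq peptide sequence (uppercase one-letter codes).
#' @param masses a [residue_masses()] table.
#' @return molecular weight in g/mol.
#' @examples
#' molecular_weight("CVNHCTRHRHSCCRSKMK")  # ~2186.6
#' @export
molecular_weight <- function(seq, masses = residue_masses()) {
  chars <- pep_chars(seq)
  sum(masses$residue_mass[chars]) + masses$water_mass
}

# Expand a sequence into its basic / acidic group pKa vectors (side chains
# plus both termini).
ionizable_groups <- function(seq, pkas) {
  chars <- pep_chars(seq)
  side <- pkas$side_chain
  basic <- c(side[chars[chars %in% c("H", "K", "R")]], pkas$nterm)
  acidic <- c(side[chars[chars %in% c("D", "E", "C", "Y")]], pkas$cterm)
  list(basic = unname(basic), acidic = unname(acidic))
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch fractional ionization summed over basic groups (H, K,
#' R side chains and the N-terminus, each contributing
#' \eqn{1/(1+10^{pH-pK_a})}) minus acidic groups (D, E, C, Y side chains and
#' the C-terminus, each contributing \eqn{1/(1+10^{pK_a-pH})}). Strictly
#' decreasing in pH. Cysteines titrate as free thiols.
#'
#' @param seq peptide sequence.
#' @param pH numeric vector of pH values, each strictly inside (0, 14).
#' @param pkas a [pka_table()].
#' @return net charge in elementary charge units, one value per pH.
#' @examples
#' charge_at_ph("CVNHCTRHRHSCCRSKMK", 7)  # ~ +5
#' @export
charge_at_ph <- function(seq, pH = 7, pkas = pka_table()) {
  if (any(!is.finite(pH)) || any(pH <= 0) || any(pH >= 14))
    stop("pH must lie strictly inside (0, 14)")
  g <- ionizable_groups(seq, pkas)
  pos <- rowSums(1 / (1 + 10^outer(pH, g$basic, `-`)))
  neg <- rowSums(1 / (1 + 10^outer(pH, g$acidic, function(p, pk) pk - p)))
  pos - neg
}

#' Isoelectric point by bisection
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge is zero. The
#' charge curve is strictly decreasing, positive near pH 0 and negative near
#' pH 14 (the termini guarantee one group of each sign), so the root is unique
#' and plain bisection on [0, 14] converges unconditionally.
#'
#' @param seq peptide sequence.
#' @param pkas a [pka_table()].
#' @param tol stop once `|charge| < tol` at the midpoint.
#' @return the isoelectric pH.
#' @examples
#' isoelectric_point("CVNHCTRHRHSCCRSKMK")  # ~10
#' @export
isoelectric_point <- function(seq, pkas = pka_table(), tol = 1e-6) {
  g <- ionizable_groups(seq, pkas)
  f <- function(p) sum(1 / (1 + 10^(p - g$basic))) -
    sum(1 / (1 + 10^(g$acidic - p)))
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    z <- f(mid)
    if (abs(z) < tol) return(mid)
    if (z > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Eisenberg hydrophobic moment
#'
#' Modulus of the vector sum of residue hydrophobicities placed at successive
#' `angle_per_residue` steps around an ideal helix, divided by the sequence
#' length (mean moment per residue):
#' \eqn{\mu_H = |\sum_k h_k e^{i\delta k}| / n}. Measures amphipathicity:
#' large when hydrophobic and hydrophilic residues segregate onto opposite
#' helix faces.
#'
#' @param seq peptide sequence.
#' @param scale a [hydrophobicity_scale()].
#' @return non-negative moment in scale units.
#' @export
hydrophobic_moment <- function(seq, scale = hydrophobicity_scale()) {
  chars <- pep_chars(seq)
  h <- scale$values[chars]
  delta <- scale$angle_per_residue * pi / 180
  k <- seq_along(h) - 1
  Mod(sum(h * exp(1i * delta * k))) / length(h)
}

#' Mean hydrophobicity
#'
#' Arithmetic mean of the scale values over the sequence.
#'
#' @inheritParams hydrophobic_moment
#' @return mean hydrophobicity in scale units.
#' @export
mean_hydrophobicity <- function(seq, scale = hydrophobicity_scale()) {
  chars <- pep_chars(seq)
  mean(scale$values[chars])
}

#' Classify water solubility
#'
#' Charge-based surrogate rule: a peptide is called `Good` when the magnitude
#' of its pH-7 net charge reaches `threshold` (default 2 elementary charges),
#' `Poor` otherwise. Strongly charged short peptides are reliably
#' water-soluble; near-neutral ones often are not. This is a deliberately
#' simple, documented stand-in for black-box solubility servers.
#'
#' @param seq peptide sequence.
#' @param pkas a [pka_table()].
#' @param threshold absolute pH-7 charge needed for a `Good` call.
#' @return `"Good"` or `"Poor"`.
#' @export
classify_solubility <- function(seq, pkas = pka_table(), threshold = 2) {
  if (abs(charge_at_ph(seq, 7, pkas)) >= threshold) "Good" else "Poor"
}

#' Full physicochemical profile table
#'
#' One row per peptide with every descriptor used to characterize HDP
#' candidates: length, molecular weight, pH-7 net charge (raw and display
#' form), isoelectric point, hydrophobic moment, mean hydrophobicity and the
#' solubility class.
#'
#' @param seqs named character vector of peptide sequences.
#' @param masses a [residue_masses()] table.
#' @param pkas a [pka_table()].
#' @param scale a [hydrophobicity_scale()].
#' @return data.frame with columns `id`, `sequence`, `length`, `mw_gmol`,
#'   `net_charge_ph7`, `net_charge_display`, `pi`, `hydrophobic_moment`,
#'   `mean_hydrophobicity`, `solubility`.
#' @export
physchem_profile <- function(seqs, masses = residue_masses(),
                             pkas = pka_table(),
                             scale = hydrophobicity_scale()) {
  if (is.null(names(seqs)) && length(seqs) > 0)
    names(seqs) <- paste0("peptide", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    validate_peptide(s, names(seqs)[i])
    z <- charge_at_ph(s, 7, pkas)
    data.frame(
      id = names(seqs)[i], sequence = s, length = nchar(s),
      mw_gmol = molecular_weight(s, masses),
      net_charge_ph7 = z,
      net_charge_display = format_charge(z),
      pi = isoelectric_point(s, pkas),
      hydrophobic_moment = hydrophobic_moment(s, scale),
      mean_hydrophobicity = mean_hydrophobicity(s, scale),
      solubility = classify_solubility(s, pkas),
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), mw_gmol = numeric(),
                      net_charge_ph7 = numeric(),
                      net_charge_display = character(), pi = numeric(),
                      hydrophobic_moment = numeric(),
                      mean_hydrophobicity = numeric(),
                      solubility = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' HDP physicochemistry gate
#'
#' Pass/fail screen on a physicochemical profile: a candidate passes when its
#' pH-7 net charge reaches `min_charge` (default +2, the cationicity floor of
#' host-defense peptides) and its hydrophobic moment reaches `min_moment`
#' (default 0, i.e. the amphipathicity criterion is off unless requested).
#' Per-criterion flags are reported so a failure names its cause.
#'
#' @param profile data.frame from [physchem_profile()].
#' @param min_charge minimum pH-7 net charge.
#' @param min_moment minimum hydrophobic moment.
#' @return `profile` with added logical columns `charge_ok`, `moment_ok`,
#'   `hdp_pass`.
#' @export
hdp_physchem_filter <- function(profile, min_charge = 2, min_moment = 0) {
  stopifnot(is.data.frame(profile),
            all(c("net_charge_ph7", "hydrophobic_moment") %in% names(profile)))
  profile$charge_ok <- profile$net_charge_ph7 >= min_charge
  profile$moment_ok <- profile$hydrophobic_moment >= min_moment
  profile$hdp_pass <- profile$charge_ok & profile$moment_ok
  profile
}
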