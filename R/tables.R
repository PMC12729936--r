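# Residue-level lookup tables: average masses, ionization pKa values, the
# Eisenberg consensus hydrophobicity scale and Chou-Fasman helix propensities.
# Each constructor returns a validated object and optionally reads an editable
# two-column key<TAB>value file so every table is user-replaceable.

.default_masses <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.default_water <- 18.0153

# Calibrated ionization constants: chosen so pH-7 net charges of short
# Cys/His/Lys-rich venom peptides land on the values reported by common web
# calculators, and so cationic 18-mers titrate to pI near 10. Cysteines are
# treated as free thiols (no disulfide correction).
.default_pka <- list(
  nterm = 9.0, cterm = 3.1,
  side_chain = c(D = 3.65, E = 4.25, C = 8.14, Y = 10.07,
                 H = 6.0, K = 11.1, R = 12.5))

# Eisenberg consensus hydrophobicity scale (unitless).
.eisenberg <- c(
  A = 0.62,  R = -2.53, N = -0.78, D = -0.90, C = 0.29,
  E = -0.74, Q = -0.85, G = 0.48,  H = -0.40, I = 1.38,
  L = 1.06,  K = -1.50, M = 0.64,  F = 1.19,  P = 0.12,
  S = -0.18, T = -0.05, W = 0.81,  Y = 0.26,  V = 1.08)

# Chou-Fasman alpha-helix propensities (P_alpha / 100).
.chou_fasman_helix <- c(
  A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
  E = 1.51, Q = 1.11, G = 0.57, H = 1.00, I = 1.08,
  L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
  S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06)

read_kv_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Average residue mass table
#'
#' Average (isotope-weighted) residue masses in g/mol — the mass of each amino
#' acid minus one water — plus the mass of water added back once per chain.
#'
#' @param file optional two-column TSV (`residue<TAB>mass`) overriding the
#'   built-in masses; a `WATER` row overrides the water mass.
#' @return object of class `residue_mass_table`: list with `residue_mass`
#'   (named numeric, all 20 residues) and `water_mass`.
#' @export
residue_masses <- function(file = NULL) {
  masses <- .default_masses
  water <- .default_water
  if (!is.null(file)) {
    kv <- read_kv_table(file)
    if ("WATER" %in% names(kv)) {
      water <- kv[["WATER"]]
      kv <- kv[names(kv) != "WATER"]
    }
    masses[names(kv)] <- kv
  }
  missing <- setdiff(AA_STANDARD, names(masses))
  if (length(missing) > 0)
    stop("mass table missing residues: ", paste(missing, collapse = ", "))
  if (any(masses <= 0)) stop("residue masses must be positive")
  if (abs(water - 18.015) > 0.01)
    stop("water mass must be ~18.015 g/mol, got ", water)
  structure(list(residue_mass = masses[AA_STANDARD], water_mass = water),
            class = "residue_mass_table")
}

#' Ionization pKa table
#'
#' Side-chain pKa values for the seven ionizable residues plus the two chain
#' termini, with the usual sign convention: H, K, R and the N-terminus titrate
#' as bases (+), D, E, C, Y and the C-terminus as acids (-).
#'
#' @param file optional two-column TSV (`group<TAB>pKa`; groups are the
#'   one-letter codes plus `NTERM` and `CTERM`) overriding individual entries.
#' @return object of class `pka_table`: list with `nterm`, `cterm` and
#'   `side_chain` (named numeric over D, E, C, Y, H, K, R).
#' @export
pka_table <- function(file = NULL) {
  pk <- .default_pka
  if (!is.null(file)) {
    kv <- read_kv_table(file)
    if ("NTERM" %in% names(kv)) pk$nterm <- kv[["NTERM"]]
    if ("CTERM" %in% names(kv)) pk$cterm <- kv[["CTERM"]]
    side <- kv[names(kv) %in% names(pk$side_chain)]
    pk$side_chain[names(side)] <- side
  }
  vals <- c(pk$nterm, pk$cterm, pk$side_chain)
  if (any(vals <= 0 | vals >= 14))
    stop("all pKa values must lie strictly inside (0, 14)")
  if (!setequal(names(pk$side_chain), c("D", "E", "C", "Y", "H", "K", "R")))
    stop("side-chain pKa table must cover exactly D, E, C, Y, H, K, R")
  structure(pk, class = "pka_table")
}

#' Hydrophobicity scale
#'
#' Per-residue hydrophobicity values used for the helical-wheel hydrophobic
#' moment, with the angular step between successive residues on an ideal
#' alpha-helix (100 degrees by default).
#'
#' @param file optional two-column TSV overriding individual residue values.
#' @param angle_per_residue helix rotation per residue, in degrees.
#' @return object of class `hydrophobicity_scale`: list with `values` (named
#'   numeric, all 20 residues) and `angle_per_residue`.
#' @export
hydrophobicity_scale <- function(file = NULL, angle_per_residue = 100) {
  vals <- .eisenberg
  if (!is.null(file)) {
    kv <- read_kv_table(file)
    vals[names(kv)] <- kv
  }
  missing <- setdiff(AA_STANDARD, names(vals))
  if (length(missing) > 0)
    stop("hydrophobicity scale missing residues: ",
         paste(missing, collapse = ", "))
  structure(list(values = vals[AA_STANDARD],
                 angle_per_residue = angle_per_residue),
            class = "hydrophobicity_scale")
}

#' Alpha-helix propensity table
#'
#' Chou-Fasman helix-former propensities (P_alpha scaled to 1.0 = indifferent)
#' used by [annotate_helices()].
#'
#' @param file optional two-column TSV overriding individual residue values.
#' @return named numeric vector over the 20 standard residues.
#' @export
helix_propensities <- function(file = NULL) {
  vals <- .chou_fasman_helix
  if (!is.null(file)) {
    kv <- read_kv_table(file)
    vals[names(kv)] <- kv
  }
  missing <- setdiff(AA_STANDARD, names(vals))
  if (length(missing) > 0)
    stop("propensity table missing residues: ",
         paste(missing, collapse = ", "))
  vals[AA_STANDARD]
}
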