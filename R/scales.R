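#' Wimley-White interfacial hydrophobicity scale
#'
#' Per-residue free energies of transfer (kcal/mol) from water to the
#' POPC bilayer interface, in the convention where positive values are
#' interfacially unfavourable. Glu and Asp carry their charged (deprotonated)
#' values and Lys and Arg their protonated values, so at neutral pH the
#' charged residues of an amphipathic helix count as strongly polar.
#' Termini are not part of the scale: sequence-level means and moments are
#' computed over sidechain values only.
#'
#' @return A named numeric vector over the 20 one-letter amino-acid codes.
#' @examples
#' ww_interface()[["L"]] # Leu, interfacially favourable
#' @export
ww_interface <- function() {
  c(
    A = 0.17, R = 0.81, N = 0.42, D = 1.23, C = -0.24,
    Q = 0.58, E = 2.02, G = 0.01, H = 0.17, I = -0.31,
    L = -0.56, K = 0.99, M = -0.23, F = -1.13, P = 0.45,
    S = 0.13, T = 0.14, W = -1.85, Y = -0.94, V = 0.07
  )
}

#' Average residue masses
#'
#' Average (not monoisotopic) masses of amino-acid residues in Da, i.e. the
#' free amino-acid mass minus one water. A peptide with free termini weighs
#' the sum of its residue masses plus one water ([water_mass()]).
#'
#' @return A named numeric vector over the 20 one-letter codes.
#' @export
residue_masses <- function() {
  c(
    A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
  )
}

#' @rdname residue_masses
#' @export
water_mass <- function() 18.01528

#' Ionizable-group pKa table
#'
#' Default pKa values for the titratable sidechains and the free termini,
#' following the EMBOSS convention. Swappable wherever a pKa table is
#' accepted; printed isoelectric points of designed peptides depend on the
#' table choice by several tenths of a pH unit.
#'
#' @return A tibble with columns `group` (one-letter sidechain code or
#'   `"nterm"`/`"cterm"`), `pka`, and `sign` (+1 basic, -1 acidic).
#' @examples
#' pka_table()
#' @export
pka_table <- function() {
  tibble::tibble(
    group = c("C", "D", "E", "H", "K", "R", "Y", "nterm", "cterm"),
    pka   = c(8.5, 3.9, 4.1, 6.5, 10.8, 12.5, 10.1, 8.6, 3.6),
    sign  = c(-1, -1, -1, +1, +1, +1, -1, +1, -1)
  )
}

# Residue classes used on the helical wheel. Ala is borderline: it is
# aliphatic but too small to extend a Leu face, so it is outside the
# hydrophobic class unless explicitly requested.
.hydrophobic_residues <- c("L", "I", "V", "F", "M", "W", "C")
.charged_residues <- c("E", "D", "K", "R", "H")

#' Helical-wheel residue classes
#'
#' Classifies residues as `"hydrophobic"` (L, I, V, F, M, W, C, and A when
#' `ala_hydrophobic = TRUE`), `"charged"` (E, D, K, R, H) or
#' `"neutral-polar"` (everything else).
#'
#' @param residues Character vector of one-letter codes.
#' @param ala_hydrophobic Count Ala as part of the hydrophobic face?
#' @return Character vector of classes, same length as `residues`.
#' @export
residue_class <- function(residues, ala_hydrophobic = FALSE) {
  hydro <- .hydrophobic_residues
  if (ala_hydrophobic) hydro <- c(hydro, "A")
  dplyr::case_when(
    residues %in% hydro ~ "hydrophobic",
    residues %in% .charged_residues ~ "charged",
    .default = "neutral-polar"
  )
}
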