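#' Parse and validate peptide sequences
#'
#' Normalises raw sequence strings (whitespace stripped, case folded to upper)
#' and validates every character against the standard 20-letter amino-acid
#' alphabet. Termini are taken as free (unmodified amine and acid) throughout
#' the package.
#'
#' @param x Character vector of raw sequences.
#' @return Character vector of validated, upper-case sequences.
#' @examples
#' parse_peptide("ekl")
#' parse_peptide("EKLKELLEKLLEKLKELL")
#' @export
parse_peptide <- function(x) {
  x <- toupper(gsub("\\s+", "", x))
  if (any(!nzchar(x))) {
    stop("empty peptide sequence", call. = FALSE)
  }
  valid <- names(residue_masses())
  for (s in x) {
    res <- strsplit(s, "")[[1]]
    bad <- which(!res %in% valid)
    if (length(bad) > 0) {
      stop(sprintf(
        "invalid residue '%s' at position %d in sequence '%s'",
        res[bad[1]], bad[1], s
      ), call. = FALSE)
    }
  }
  x
}

#' Read peptides from a FASTA file
#'
#' Reads amino-acid FASTA via Biostrings and returns a validated tidy table.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` (FASTA header up to first space) and
#'   `sequence`. An empty FASTA yields a zero-row tibble with a warning.
#' @export
read_fasta_peptides <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    warning("no sequences found in ", path)
    return(tibble::tibble(name = character(), sequence = character()))
  }
  tibble::tibble(
    name = sub("\\s.*$", "", names(aa)),
    sequence = unname(parse_peptide(as.character(aa)))
  )
}

# residue vector from a single validated sequence
pep_residues <- function(sequence) {
  strsplit(parse_peptide(sequence), "")[[1]]
}

#' Peptide molecular weight
#'
#' Sum of average residue masses plus one water for the free termini.
#'
#' @param sequence Character vector of sequences.
#' @param masses Named residue-mass vector, Da ([residue_masses()]).
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mw("G") # 57.05 + 18.02
#' @export
peptide_mw <- function(sequence, masses = residue_masses()) {
  vapply(sequence, function(s) {
    sum(masses[pep_residues(s)]) + water_mass()
  }, numeric(1), USE.NAMES = FALSE)
}

#' Integer net charge at neutral pH
#'
#' The integer model used for design tables: +1 per Lys/Arg, -1 per Glu/Asp,
#' free termini cancelling (+1 N-terminal amine, -1 C-terminal acid).
#' Histidine is treated as neutral at pH 7.
#'
#' @param sequence Character vector of sequences.
#' @return Integer vector of net charges in elementary charge units.
#' @export
peptide_net_charge <- function(sequence) {
  vapply(sequence, function(s) {
    r <- pep_residues(s)
    as.integer(sum(r %in% c("K", "R")) - sum(r %in% c("E", "D")))
  }, integer(1), USE.NAMES = FALSE)
}

#' Fractional peptide charge at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable sidechains and both free termini:
#' each basic group contributes \eqn{+1/(1+10^{pH-pKa})}, each acidic group
#' \eqn{-1/(1+10^{pKa-pH})}.
#'
#' @param sequence Character vector of sequences.
#' @param pH pH value(s) in (0, 14); recycled against `sequence`.
#' @param pka pKa table ([pka_table()]).
#' @return Numeric vector of fractional charges in e.
#' @export
peptide_charge <- function(sequence, pH, pka = pka_table()) {
  stopifnot(all(pH > 0 & pH < 14))
  n <- max(length(sequence), length(pH))
  sequence <- rep_len(sequence, n)
  pH <- rep_len(pH, n)
  pk <- stats::setNames(pka$pka, pka$group)
  sg <- stats::setNames(pka$sign, pka$group)
  vapply(seq_len(n), function(i) {
    r <- pep_residues(sequence[i])
    groups <- c(r[r %in% pka$group], "nterm", "cterm")
    q <- ifelse(sg[groups] > 0,
      1 / (1 + 10^(pH[i] - pk[groups])),
      -1 / (1 + 10^(pk[groups] - pH[i]))
    )
    sum(q)
  }, numeric(1))
}

#' Isoelectric point
#'
#' pH at which the fractional charge ([peptide_charge()]) crosses zero, found
#' by bisection on (0, 14) to 1e-3 pH. Requires at least one acidic and one
#' basic group so a root exists; the charge curve is strictly decreasing in
#' pH, so the root is unique.
#'
#' @param sequence Character vector of sequences.
#' @param pka pKa table ([pka_table()]).
#' @param tol Bisection tolerance in pH units.
#' @return Numeric vector of pI values.
#' @export
peptide_pi <- function(sequence, pka = pka_table(), tol = 1e-3) {
  vapply(sequence, function(s) {
    # free termini always supply one acidic and one basic group, so a root
    # exists; the explicit sign-change check guards swapped custom tables
    lo <- 1e-6
    hi <- 14 - 1e-6
    f_lo <- peptide_charge(s, lo, pka)
    f_hi <- peptide_charge(s, hi, pka)
    if (f_lo <= 0 || f_hi >= 0) {
      stop("no sign change of charge on (0, 14); pI undefined", call. = FALSE)
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (peptide_charge(s, mid, pka) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mean interfacial hydrophobicity
#'
#' Arithmetic mean of per-residue Wimley-White interfacial transfer free
#' energies; termini excluded.
#'
#' @param sequence Character vector of sequences.
#' @param scale Named hydrophobicity vector ([ww_interface()]).
#' @return Numeric vector, kcal/mol per residue.
#' @export
mean_hydrophobicity <- function(sequence, scale = ww_interface()) {
  vapply(sequence, function(s) mean(scale[pep_residues(s)]),
    numeric(1),
    USE.NAMES = FALSE
  )
}

#' Helical hydrophobic moment
#'
#' Magnitude of the vector sum of per-residue hydrophobicity indices placed
#' around the helical wheel (residue i at angle (i-1)*delta), divided by the
#' number of residues:
#' \deqn{\mu_H = \frac{1}{N}\left|\sum_i h_i (\cos i\delta, \sin i\delta)\right|}
#' With the default 100 deg/residue twist this measures amphipathicity of an
#' ideal alpha-helix; it is invariant under cyclic shifts and reversal of the
#' sequence.
#'
#' @param sequence Character vector of sequences (length >= 2 residues each).
#' @param scale Named hydrophobicity vector ([ww_interface()]).
#' @param delta Helical twist per residue, degrees.
#' @return Numeric vector, kcal/mol.
#' @export
hydrophobic_moment <- function(sequence, scale = ww_interface(), delta = 100) {
  vapply(sequence, function(s) {
    h <- scale[pep_residues(s)]
    stopifnot(length(h) >= 2)
    ang <- (seq_along(h) - 1) * delta * pi / 180
    sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
  }, numeric(1), USE.NAMES = FALSE)
}
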