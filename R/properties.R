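#' Physicochemical property table for peptides
#'
#' One row per peptide with the standard design-table columns: molecular
#' weight, isoelectric point, mean interfacial hydrophobicity, hydrophobic
#' moment, integer net charge at pH 7, and the hydrophobic-face subtended
#' angle from the helical wheel.
#'
#' @param peptides A data frame with columns `name` and `sequence`, or a
#'   character vector of sequences (names taken from the vector names), or a
#'   path to a FASTA file.
#' @param scale Hydrophobicity scale ([ww_interface()]).
#' @param masses Residue-mass table ([residue_masses()]).
#' @param pka pKa table ([pka_table()]).
#' @param delta Helical twist per residue, degrees.
#' @param ala_hydrophobic Count Ala in the wheel's hydrophobic face?
#' @return A tibble with columns `name`, `sequence`, `mw`, `pi`,
#'   `mean_hydrophobicity`, `hydrophobic_moment`, `net_charge`, `face_angle`.
#' @examples
#' peptide_property_table(c(neu = "EKLKELLEKLLEKLKELL"))
#' @export
peptide_property_table <- function(peptides,
                                   scale = ww_interface(),
                                   masses = residue_masses(),
                                   pka = pka_table(),
                                   delta = 100,
                                   ala_hydrophobic = FALSE) {
  if (is.character(peptides) && length(peptides) == 1 &&
    file.exists(peptides) && !grepl("^[A-Za-z]+$", peptides)) {
    peptides <- read_fasta_peptides(peptides)
  }
  if (is.character(peptides)) {
    peptides <- tibble::tibble(
      name = if (is.null(names(peptides))) {
        paste0("peptide", seq_along(peptides))
      } else {
        names(peptides)
      },
      sequence = unname(peptides)
    )
  }
  stopifnot(all(c("name", "sequence") %in% names(peptides)))
  if (nrow(peptides) == 0) {
    return(tibble::tibble(
      name = character(), sequence = character(), mw = numeric(),
      pi = numeric(), mean_hydrophobicity = numeric(),
      hydrophobic_moment = numeric(), net_charge = integer(),
      face_angle = numeric()
    ))
  }
  dplyr::mutate(tibble::as_tibble(peptides),
    sequence = parse_peptide(.data$sequence),
    mw = peptide_mw(.data$sequence, masses),
    pi = peptide_pi(.data$sequence, pka),
    mean_hydrophobicity = mean_hydrophobicity(.data$sequence, scale),
    hydrophobic_moment = hydrophobic_moment(.data$sequence, scale, delta),
    net_charge = peptide_net_charge(.data$sequence),
    face_angle = unname(vapply(.data$sequence, face_angle,
      numeric(1),
      delta = delta, ala_hydrophobic = ala_hydrophobic
    ))
  )
}

#' The four ELK design peptides
#'
#' The 18-mer Glu/Leu/Lys(/Ala) sequences studied as apoA-I mimetics, named
#' by their dominant character: net-neutral (`neu`), extra-hydrophobic
#' (`hyd`), net-positive (`pos`) and net-negative (`neg`).
#'
#' @return A named character vector of four sequences.
#' @export
elk_peptides <- function() {
  c(
    neu = "EKLKELLEKLLEKLKELL",
    hyd = "EKLLELLKKLLELLKELL",
    pos = "EKLKALLEKLKAKLKELL",
    neg = "EELKEKLEELKEKLEEKL"
  )
}
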