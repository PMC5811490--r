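#' Canonical contact specifications
#'
#' The named atom-role pairs and distance cutoffs used for salt-bridge and
#' hydrophobic-contact counting, as obtained from radial distribution
#' functions of all-atom simulations of these systems: Lys amine N - Glu
#' carboxyl C 4.3; Lys amine N - C-terminal carboxyl C 4.6; Glu carboxyl C
#' - N-terminal amine N 4.1; Lys amine N - POPC phosphate P 4.6; Glu
#' carboxyl C - POPC choline N 5.8; Leu sidechain C - Leu sidechain C 7.9
#' (all Angstrom).
#'
#' @return A tibble with columns `name`, `role_a`, `role_b`, `cutoff`
#'   (Angstrom), `scope` (`"peptide-peptide"` or `"peptide-lipid"`) and
#'   `kind` (`"salt_bridge"` or `"hydrophobic"`).
#' @export
contact_specs <- function() {
  tibble::tibble(
    name = c(
      "lys_glu", "lys_cterm", "glu_nterm", "lys_phosphate",
      "glu_choline", "leu_leu"
    ),
    role_a = c(
      "LYS_NZ", "LYS_NZ", "GLU_CD", "LYS_NZ", "GLU_CD",
      "LEU_SIDECHAIN_C"
    ),
    role_b = c(
      "GLU_CD", "CTERM_C", "NTERM_N", "LIPID_P", "LIPID_CHOLINE_N",
      "LEU_SIDECHAIN_C"
    ),
    cutoff = c(4.3, 4.6, 4.1, 4.6, 5.8, 7.9),
    scope = c(
      "peptide-peptide", "peptide-peptide", "peptide-peptide",
      "peptide-lipid", "peptide-lipid", "peptide-peptide"
    ),
    kind = c(
      "salt_bridge", "salt_bridge", "salt_bridge", "salt_bridge",
      "salt_bridge", "hydrophobic"
    )
  )
}

# resolve a contact spec argument: a name into contact_specs(), a one-row
# data frame, or a list with role_a/role_b/cutoff
resolve_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1) {
    cs <- contact_specs()
    row <- cs[cs$name == spec, ]
    if (nrow(row) == 0) stop("unknown contact spec: ", spec, call. = FALSE)
    return(as.list(row))
  }
  if (is.data.frame(spec)) {
    stopifnot(nrow(spec) == 1)
    return(as.list(spec))
  }
  stopifnot(is.list(spec), all(c("role_a", "role_b", "cutoff") %in% names(spec)))
  spec
}

# pairwise distances between coordinate matrices a (n x 3) and b (m x 3)
# under the minimum-image convention on the flagged periodic axes
pair_distances <- function(a, b, box, periodic) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (periodic[k]) {
      if (is.na(box[k])) {
        stop("periodic axis without box length", call. = FALSE)
      }
      dk <- dk - box[k] * round(dk / box[k])
    }
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Count contacts in a frame
#'
#' Counts atom pairs of the spec's two roles whose minimum-image distance
#' (on the frame's periodic axes) is at or below the cutoff. Counting is
#' pair-based: an atom participating in two qualifying pairs contributes two
#' contacts, and every unordered pair counts once. Pairs within the same
#' residue of the same molecule are always excluded; `exclude_same_chain`
#' additionally drops intramolecular pairs (e.g. to count only
#' peptide-peptide bridges between different peptides).
#'
#' @param frame A `pep_frame`.
#' @param spec A contact spec: a name from [contact_specs()], a one-row data
#'   frame, or a list with `role_a`, `role_b`, `cutoff`.
#' @param exclude_same_chain Drop pairs within one molecule?
#' @return Integer contact count (0 when either role is absent).
#' @export
count_contacts <- function(frame, spec, exclude_same_chain = FALSE) {
  nrow(contact_pairs(frame, spec, exclude_same_chain))
}

#' @rdname count_contacts
#' @return `contact_pairs()`: a tibble of qualifying pairs with atom row
#'   indices `atom_a`, `atom_b` and the `distance` in Angstrom.
#' @export
contact_pairs <- function(frame, spec, exclude_same_chain = FALSE) {
  spec <- resolve_spec(spec)
  box <- frame_box(frame)
  periodic <- frame_periodic(frame)
  half <- box[periodic] / 2
  if (any(!is.na(half) & spec$cutoff >= half)) {
    stop("cutoff must be below half the periodic box length", call. = FALSE)
  }
  ia <- which(frame$role == spec$role_a)
  ib <- which(frame$role == spec$role_b)
  empty <- tibble::tibble(
    atom_a = integer(), atom_b = integer(), distance = numeric()
  )
  if (length(ia) == 0 || length(ib) == 0) {
    return(empty)
  }
  xyz <- as.matrix(frame[, c("x", "y", "z")])
  d <- pair_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE],
    box, periodic
  )
  hit <- which(d <= spec$cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(empty)
  }
  aa <- ia[hit[, 1]]
  bb <- ib[hit[, 2]]
  keep <- rep(TRUE, length(aa))
  # same-role specs: count each unordered pair once, never self-pairs
  if (spec$role_a == spec$role_b) keep <- aa < bb
  same_res <- frame$chain[aa] == frame$chain[bb] &
    frame$resid[aa] == frame$resid[bb]
  keep <- keep & !same_res
  if (exclude_same_chain) keep <- keep & frame$chain[aa] != frame$chain[bb]
  tibble::tibble(
    atom_a = aa[keep], atom_b = bb[keep],
    distance = d[hit][keep]
  )
}

#' Per-frame contact series over a trajectory
#'
#' Evaluates a contact spec in every frame and records both the per-frame
#' contact count and the presence matrix of every atom pair ever observed in
#' contact, for lifetime analysis.
#'
#' @inheritParams count_contacts
#' @param traj A `pep_traj`.
#' @return An object of class `contact_series`: list with `counts`
#'   (integer per frame), `presence` (frames x pairs logical matrix),
#'   `pairs` (tibble of atom index pairs) and `dt` (ps).
#' @export
contact_series <- function(traj, spec, exclude_same_chain = FALSE) {
  stopifnot(is_trajectory(traj))
  frames <- traj_frames(traj)
  per_frame <- lapply(frames, contact_pairs,
    spec = spec,
    exclude_same_chain = exclude_same_chain
  )
  keys <- unique(dplyr::bind_rows(per_frame)[c("atom_a", "atom_b")])
  presence <- matrix(FALSE, length(frames), nrow(keys))
  if (nrow(keys) > 0) {
    key_id <- paste(keys$atom_a, keys$atom_b)
    for (t in seq_along(per_frame)) {
      pf <- per_frame[[t]]
      presence[t, match(paste(pf$atom_a, pf$atom_b), key_id)] <- TRUE
    }
  }
  structure(
    list(
      counts = vapply(per_frame, nrow, integer(1)),
      presence = presence, pairs = keys, dt = traj_dt(traj)
    ),
    class = "contact_series"
  )
}

#' Mean contacts per peptide
#'
#' The per-frame contact count averaged over all frames and divided by the
#' number of peptides -- the normalisation used for per-peptide salt-bridge
#' tables.
#'
#' @inheritParams contact_series
#' @param n_peptides Number of peptides in the system (>= 1).
#' @return Mean contacts per peptide (unitless).
#' @export
mean_contacts_per_peptide <- function(traj, spec, n_peptides,
                                      exclude_same_chain = FALSE) {
  stopifnot(n_peptides >= 1)
  cs <- contact_series(traj, spec, exclude_same_chain)
  mean(cs$counts) / n_peptides
}

#' Mean contact lifetime
#'
#' For every atom pair, maximal runs of consecutive frames in contact are
#' converted to lifetimes (run length x frame spacing); the mean is taken
#' over all runs of all pairs. Runs touching either trajectory end are
#' counted without censoring correction. When the frame spacing exceeds the
#' resulting mean lifetime the estimate is resolution-limited and a warning
#' is issued (trajectories saved too sparsely cannot resolve short-lived
#' contacts).
#'
#' @param series A `contact_series`.
#' @return Mean lifetime in ps, or `NA_real_` if no contact was ever
#'   present.
#' @export
contact_lifetimes <- function(series) {
  stopifnot(inherits(series, "contact_series"))
  if (ncol(series$presence) == 0) {
    return(NA_real_)
  }
  runs <- unlist(lapply(seq_len(ncol(series$presence)), function(j) {
    r <- rle(series$presence[, j])
    r$lengths[r$values]
  }))
  if (length(runs) == 0) {
    return(NA_real_)
  }
  out <- mean(runs) * series$dt
  if (out <= series$dt) {
    warning(
      "mean lifetime does not exceed the frame spacing (", series$dt,
      " ps); lifetimes are resolution-limited",
      call. = FALSE
    )
  }
  out
}

#' Classify peptide dimers in a frame
#'
#' Every pair of peptides linked by at least one inter-peptide salt bridge
#' (Lys-Glu, Lys/C-terminus, Glu/N-terminus) or Leu-Leu hydrophobic contact
#' is a dimer. Orientation is read from the sign of the dot product of the
#' two helix-axis unit vectors (first-to-last C-alpha); the register is
#' `"matched"` when the offset of the two backbone centres along the first
#' peptide's principal axis (which, unlike the first-to-last vector, is
#' insensitive to the azimuthal offset of the terminal residues) is at most
#' `register_tol` (one helical rise by default), else `"mismatched"`.
#'
#' @param frame A `pep_frame` with at least two peptides.
#' @param specs Contact spec table (rows with scope `"peptide-peptide"` are
#'   used).
#' @param register_tol Axial-offset tolerance for a matched register,
#'   Angstrom.
#' @return A tibble with one row per dimer: `chain_a`, `chain_b`,
#'   `orientation`, `register`, `n_salt_bridges`, `n_hydrophobic`.
#' @export
classify_dimers <- function(frame, specs = contact_specs(),
                            register_tol = 1.5) {
  stopifnot(is_frame(frame))
  chains <- unique(frame$chain[substr(frame$chain, 1, 1) == "P"])
  if (length(chains) < 2) stop("need at least two peptides", call. = FALSE)
  pp <- specs[specs$scope == "peptide-peptide", ]
  # evidence pairs per spec, restricted to different peptides
  evidence <- purrr::map(seq_len(nrow(pp)), function(k) {
    pr <- contact_pairs(frame, pp[k, ], exclude_same_chain = TRUE)
    pr$kind <- pp$kind[k]
    pr
  })
  evidence <- dplyr::bind_rows(evidence)
  axes <- lapply(chains, function(ch) helix_axis(frame[frame$chain == ch, ]))
  paxes <- lapply(chains, function(ch) {
    helix_principal_axis(frame[frame$chain == ch, ])
  })
  centres <- lapply(chains, function(ch) {
    backbone_centre(frame[frame$chain == ch, ])
  })
  names(axes) <- names(paxes) <- names(centres) <- chains
  out <- list()
  for (i in seq_along(chains)) {
    for (j in seq_along(chains)) {
      if (j <= i) next
      a <- chains[i]
      b <- chains[j]
      inpair <- (frame$chain[evidence$atom_a] == a &
        frame$chain[evidence$atom_b] == b) |
        (frame$chain[evidence$atom_a] == b &
          frame$chain[evidence$atom_b] == a)
      if (!any(inpair)) next
      n_sb <- sum(inpair & evidence$kind == "salt_bridge")
      n_hp <- sum(inpair & evidence$kind == "hydrophobic")
      dot <- sum(axes[[a]] * axes[[b]])
      offset <- abs(sum((centres[[b]] - centres[[a]]) * paxes[[a]]))
      out[[length(out) + 1]] <- tibble::tibble(
        chain_a = a, chain_b = b,
        orientation = if (dot >= 0) "parallel" else "antiparallel",
        register = if (offset <= register_tol) "matched" else "mismatched",
        n_salt_bridges = n_sb, n_hydrophobic = n_hp
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      chain_a = character(), chain_b = character(),
      orientation = character(), register = character(),
      n_salt_bridges = integer(), n_hydrophobic = integer()
    ))
  }
  dplyr::bind_rows(out)
}
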