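#' Atom roles
#'
#' The closed set of atom roles carried by configurations. Roles name the
#' atoms that the contact and height metrics reference: peptide backbone
#' C-alpha, the Lys sidechain amine nitrogen, the Glu sidechain carboxyl
#' carbon, the free-termini groups, Leu sidechain carbons, and the lipid
#' phosphate phosphorus, choline nitrogen and oleoyl C2 atoms.
#'
#' @return Character vector of valid role names.
#' @export
atom_roles <- function() {
  c(
    "BACKBONE_CA", "LYS_NZ", "GLU_CD", "NTERM_N", "CTERM_C",
    "LEU_SIDECHAIN_C", "LIPID_P", "LIPID_CHOLINE_N", "LIPID_C2_OLEOYL",
    "LIPID_OTHER", "CHOL_C"
  )
}

#' Construct a frame of atom records
#'
#' A frame is a tibble of role-tagged atom records plus box metadata:
#' one row per atom, columns `role`, `chain` (molecule id such as `"P1"`,
#' `"L12"`, `"C3"`), `resid` (1-based residue index within the molecule),
#' `resname`, and coordinates `x`, `y`, `z` in Angstrom. The z axis is the
#' bilayer / disc normal and the box origin is the bilayer centre.
#'
#' @param atoms A data frame with the columns above.
#' @param box Numeric length-3 box edge lengths in Angstrom (NA if open).
#' @param periodic Logical length-3, per-axis periodicity flags.
#' @param time Frame time in ps.
#' @return A tibble of class `pep_frame`.
#' @export
new_frame <- function(atoms, box = c(NA_real_, NA_real_, NA_real_),
                      periodic = c(FALSE, FALSE, FALSE), time = 0) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("role", "chain", "resid", "resname", "x", "y", "z")
  stopifnot(all(required %in% names(atoms)))
  bad <- setdiff(unique(atoms$role), atom_roles())
  if (length(bad) > 0) {
    stop("unknown atom role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(
    all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)),
    length(box) == 3, length(periodic) == 3
  )
  structure(atoms[required],
    box = as.numeric(box), periodic = as.logical(periodic),
    time = as.numeric(time),
    class = c("pep_frame", class(atoms))
  )
}

#' @rdname new_frame
#' @param x Object to test.
#' @export
is_frame <- function(x) inherits(x, "pep_frame")

#' Frame metadata accessors
#'
#' @param frame A `pep_frame` or `pep_traj`.
#' @return `frame_box()` the box lengths, `frame_periodic()` the per-axis
#'   periodicity flags, `frame_time()` the frame time in ps.
#' @export
frame_box <- function(frame) attr(frame, "box")

#' @rdname frame_box
#' @export
frame_periodic <- function(frame) attr(frame, "periodic")

#' @rdname frame_box
#' @export
frame_time <- function(frame) attr(frame, "time")

#' Construct a trajectory
#'
#' A trajectory is an ordered sequence of frames sharing atom count and
#' ordering, at uniform time spacing. Stored as a single tibble with `frame`
#' and `time` columns prepended to the atom columns; metadata (`box`,
#' `periodic`, `dt`) as attributes.
#'
#' @param frames A list of `pep_frame` objects with identical atom ordering.
#' @param dt Frame spacing in ps (> 0).
#' @return A tibble of class `pep_traj`.
#' @export
new_trajectory <- function(frames, dt) {
  stopifnot(length(frames) >= 1, dt > 0)
  n <- nrow(frames[[1]])
  ok <- vapply(frames, function(f) {
    nrow(f) == n && identical(f$role, frames[[1]]$role) &&
      identical(f$chain, frames[[1]]$chain)
  }, logical(1))
  if (!all(ok)) stop("frames differ in atom count or ordering", call. = FALSE)
  out <- purrr::imap(frames, function(f, i) {
    dplyr::mutate(tibble::as_tibble(f),
      frame = as.integer(i), time = (i - 1) * dt, .before = 1
    )
  })
  structure(dplyr::bind_rows(out),
    box = frame_box(frames[[1]]), periodic = frame_periodic(frames[[1]]),
    dt = as.numeric(dt),
    class = c("pep_traj", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname new_trajectory
#' @param x Object to test.
#' @export
is_trajectory <- function(x) inherits(x, "pep_traj")

#' @rdname new_trajectory
#' @param traj A `pep_traj`.
#' @export
traj_dt <- function(traj) attr(traj, "dt")

#' @rdname new_trajectory
#' @export
n_frames <- function(traj) {
  if (is_trajectory(traj)) length(unique(traj$frame)) else 1L
}

#' Split a trajectory into frames
#'
#' @param traj A `pep_traj`.
#' @return A list of `pep_frame` objects in time order.
#' @export
traj_frames <- function(traj) {
  stopifnot(is_trajectory(traj))
  idx <- sort(unique(traj$frame))
  lapply(idx, function(i) {
    f <- traj[traj$frame == i, , drop = FALSE]
    new_frame(f[setdiff(names(f), c("frame", "time"))],
      box = attr(traj, "box"), periodic = attr(traj, "periodic"),
      time = f$time[1]
    )
  })
}

# three-letter residue names for PDB output
.aa3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Ideal alpha-helix pseudo-atom model of a peptide
#'
#' Places backbone C-alpha atoms on a canonical alpha-helix (default rise
#' 1.5 Angstrom/residue, twist 100 deg/residue, C-alpha radius 2.3 Angstrom)
#' with the helix axis along +z starting at the origin, and one pseudo
#' sidechain atom per Lys (`LYS_NZ`), Glu (`GLU_CD`) and Leu
#' (`LEU_SIDECHAIN_C`) placed radially outward at the residue's azimuth, so
#' sidechain directions reproduce the helical-wheel layout. Free-termini
#' roles (`NTERM_N`, `CTERM_C`) are added just beyond the terminal
#' C-alphas.
#'
#' @param sequence A single peptide sequence.
#' @param rise Rise per residue, Angstrom.
#' @param twist Twist per residue, degrees.
#' @param ca_radius C-alpha helix radius, Angstrom.
#' @param chain Chain id for the atoms.
#' @return An atom tibble (frame columns, no box metadata).
#' @export
build_ideal_helix <- function(sequence, rise = 1.5, twist = 100,
                              ca_radius = 2.3, chain = "P1") {
  res <- pep_residues(sequence)
  n <- length(res)
  th <- (seq_len(n) - 1) * twist * pi / 180
  z <- (seq_len(n) - 1) * rise
  ca <- tibble::tibble(
    role = "BACKBONE_CA", chain = chain, resid = seq_len(n),
    resname = unname(.aa3[res]),
    x = ca_radius * cos(th), y = ca_radius * sin(th), z = z
  )
  # radial extension of the pseudo-sidechain atom beyond the C-alpha radius,
  # roughly the sidechain reach: Lys amine ~6.4, Glu carboxyl ~3.7,
  # Leu sidechain centre ~2.6
  ext <- c(LYS_NZ = 6.4, GLU_CD = 3.7, LEU_SIDECHAIN_C = 2.6)
  side_role <- c(K = "LYS_NZ", E = "GLU_CD", L = "LEU_SIDECHAIN_C")[res]
  keep <- !is.na(side_role)
  side <- tibble::tibble(
    role = unname(side_role[keep]), chain = chain,
    resid = which(keep), resname = unname(.aa3[res[keep]]),
    x = (ca_radius + ext[side_role[keep]]) * cos(th[keep]),
    y = (ca_radius + ext[side_role[keep]]) * sin(th[keep]),
    z = z[keep]
  )
  termini <- tibble::tibble(
    role = c("NTERM_N", "CTERM_C"), chain = chain,
    resid = c(1L, n), resname = unname(.aa3[res[c(1, n)]]),
    x = ca_radius * cos(th[c(1, n)]), y = ca_radius * sin(th[c(1, n)]),
    z = c(z[1] - 1.5, z[n] + 1.5)
  )
  dplyr::bind_rows(ca, side, termini)
}

#' Azimuth of the hydrophobic face
#'
#' Circular mean (degrees) of the wheel angles of the hydrophobic residues;
#' the direction the hydrophobic face points when the helix is built by
#' [build_ideal_helix()].
#'
#' @inheritParams wheel_layout
#' @return Angle in degrees in [0, 360).
#' @export
face_azimuth <- function(sequence, delta = 100, ala_hydrophobic = FALSE) {
  wl <- wheel_layout(sequence, delta, ala_hydrophobic)
  a <- wl$angle[wl$class == "hydrophobic"] * pi / 180
  if (length(a) == 0) stop("no hydrophobic residue", call. = FALSE)
  (atan2(mean(sin(a)), mean(cos(a))) * 180 / pi) %% 360
}

# --- rigid-body helpers on atom tibbles ---------------------------------

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

transform_atoms <- function(atoms, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rotation)
  atoms$x <- xyz[, 1] + translation[1]
  atoms$y <- xyz[, 2] + translation[2]
  atoms$z <- xyz[, 3] + translation[3]
  atoms
}

# centre of geometry of backbone C-alphas
backbone_centre <- function(atoms) {
  ca <- atoms[atoms$role == "BACKBONE_CA", ]
  c(mean(ca$x), mean(ca$y), mean(ca$z))
}

# principal axis of the backbone C-alphas, sign-aligned with the
# first-to-last direction; insensitive to the azimuthal offset between the
# terminal residues, so suited to measuring axial offsets
helix_principal_axis <- function(atoms) {
  ca <- atoms[atoms$role == "BACKBONE_CA", ]
  xyz <- sweep(as.matrix(ca[, c("x", "y", "z")]), 2, c(
    mean(ca$x), mean(ca$y), mean(ca$z)
  ))
  v <- eigen(crossprod(xyz), symmetric = TRUE)$vectors[, 1]
  if (sum(v * helix_axis(atoms)) < 0) v <- -v
  v
}

# helix axis unit vector, first-to-last C-alpha
helix_axis <- function(atoms) {
  ca <- atoms[atoms$role == "BACKBONE_CA", ]
  ca <- ca[order(ca$resid), ]
  v <- c(
    ca$x[nrow(ca)] - ca$x[1], ca$y[nrow(ca)] - ca$y[1],
    ca$z[nrow(ca)] - ca$z[1]
  )
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) stop("degenerate helix axis (coincident termini)", call. = FALSE)
  v / nv
}
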