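# Role <-> PDB name mapping. Molecule identity travels in the segid field
# (chain ids are a single character in PDB, too few for 24 peptides plus
# hundreds of lipids): segid "P<i>" peptide, "L<i>" lipid, "C<i>"
# cholesterol. Roles are inferred from (molecule class, residue name, atom
# name); unknown atoms fall back to LIPID_OTHER with a warning.
.role_to_elety <- c(
  BACKBONE_CA = "CA", LYS_NZ = "NZ", GLU_CD = "CD", NTERM_N = "N",
  CTERM_C = "C", LEU_SIDECHAIN_C = "CD1", LIPID_P = "P",
  LIPID_CHOLINE_N = "N", LIPID_C2_OLEOYL = "C2", LIPID_OTHER = "C1",
  CHOL_C = "C3"
)

.pep_elety_to_role <- c(
  CA = "BACKBONE_CA", NZ = "LYS_NZ", CD = "GLU_CD", N = "NTERM_N",
  C = "CTERM_C", CD1 = "LEU_SIDECHAIN_C"
)

.lipid_elety_to_role <- c(
  P = "LIPID_P", N = "LIPID_CHOLINE_N", C2 = "LIPID_C2_OLEOYL",
  C1 = "LIPID_OTHER"
)

infer_roles <- function(segid, resname, elety) {
  segid[is.na(segid)] <- ""
  cls <- substr(segid, 1, 1)
  role <- rep(NA_character_, length(segid))
  pep <- cls == "P"
  role[pep] <- .pep_elety_to_role[elety[pep]]
  lip <- cls == "L"
  role[lip] <- .lipid_elety_to_role[elety[lip]]
  role[cls == "C" | resname == "CHL"] <- "CHOL_C"
  unknown <- is.na(role)
  if (any(unknown)) {
    warning(
      sum(unknown), " atom(s) with unmapped names assigned role LIPID_OTHER",
      call. = FALSE
    )
    role[unknown] <- "LIPID_OTHER"
  }
  role
}

#' Write a configuration or trajectory as (multi-model) PDB
#'
#' Frames are written as standard PDB via bio3d, trajectories as multi-model
#' PDB (one MODEL per frame). Atom roles are encoded in atom/residue names
#' and molecule ids in the segid field; box lengths, periodicity flags and
#' frame times travel in a CRYST1 record and a REMARK 250 header line so a
#' round trip restores the full frame metadata.
#'
#' @param x A `pep_frame` or `pep_traj`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (is_trajectory(x)) {
    frames <- traj_frames(x)
    atoms <- frames[[1]]
    xyz <- do.call(rbind, lapply(frames, function(f) {
      as.numeric(t(as.matrix(f[, c("x", "y", "z")])))
    }))
    dt <- traj_dt(x)
    t0 <- frame_time(frames[[1]])
  } else {
    stopifnot(is_frame(x))
    atoms <- x
    xyz <- matrix(as.numeric(t(as.matrix(x[, c("x", "y", "z")]))), nrow = 1)
    dt <- 0
    t0 <- frame_time(x)
  }
  unmapped <- setdiff(unique(atoms$role), names(.role_to_elety))
  if (length(unmapped) > 0) {
    stop("role(s) with no PDB name mapping: ", paste(unmapped, collapse = ", "),
      call. = FALSE
    )
  }
  # global residue numbering so (segid, resno) is unique
  key <- paste(atoms$chain, atoms$resid)
  resno <- match(key, unique(key))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    eleno = seq_len(nrow(atoms)),
    elety = unname(.role_to_elety[atoms$role]),
    resid = atoms$resname,
    chain = substr(atoms$chain, 1, 1),
    resno = resno
  )
  # inject molecule ids into the segid columns (73-76); bio3d's writer
  # drops them, but its reader recovers them
  lines <- readLines(path)
  n_at <- nrow(atoms)
  j <- 0
  lines <- vapply(lines, function(l) {
    if (startsWith(l, "ATOM")) {
      j <<- j + 1
      l <- formatC(l, width = -80)
      substr(l, 73, 76) <- formatC(atoms$chain[(j - 1) %% n_at + 1], width = -4)
    }
    l
  }, character(1), USE.NAMES = FALSE)
  writeLines(lines, path)
  box <- frame_box(if (is_trajectory(x)) frames[[1]] else x)
  per <- frame_periodic(if (is_trajectory(x)) frames[[1]] else x)
  lines <- readLines(path)
  header <- c(
    sprintf(
      "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
      ifelse(is.na(box[1]), 0, box[1]), ifelse(is.na(box[2]), 0, box[2]),
      ifelse(is.na(box[3]), 0, box[3])
    ),
    sprintf(
      "REMARK 250 PEPDISC PERIODIC %d %d %d TIME %.6g DT %.6g RESID %s",
      per[1], per[2], per[3], t0, dt,
      paste(atoms$resid, collapse = ",")
    )
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a configuration or trajectory from (multi-model) PDB
#'
#' Inverse of [write_structure()]: single-model files yield a `pep_frame`,
#' multi-model files a `pep_traj`. Roles are inferred from the documented
#' name mapping; atoms with unknown names become `LIPID_OTHER` with a
#' warning. ATOM records with unparseable coordinates raise an error naming
#' the line number.
#'
#' @param path Path to a PDB or multi-model PDB file.
#' @return A `pep_frame` or `pep_traj`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  atom_lines <- grep("^ATOM|^HETATM", lines)
  for (i in atom_lines) {
    coords <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46),
      substr(lines[i], 47, 54)
    )))
    if (anyNA(coords)) {
      stop("malformed ATOM record at line ", i, " of ", path, call. = FALSE)
    }
  }
  box <- c(NA_real_, NA_real_, NA_real_)
  periodic <- c(FALSE, FALSE, FALSE)
  t0 <- 0
  dt <- 0
  resid_field <- NULL
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry) > 0) {
    b <- as.numeric(c(
      substr(cry[1], 7, 15), substr(cry[1], 16, 24), substr(cry[1], 25, 33)
    ))
    box <- ifelse(b == 0, NA_real_, b)
  }
  rem <- grep("^REMARK 250 PEPDISC", lines, value = TRUE)
  if (length(rem) > 0) {
    tok <- strsplit(trimws(rem[1]), "\\s+")[[1]]
    periodic <- as.logical(as.integer(tok[5:7]))
    t0 <- as.numeric(tok[9])
    dt <- as.numeric(tok[11])
    resid_field <- as.integer(strsplit(tok[13], ",")[[1]])
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  role <- infer_roles(at$segid, at$resid, at$elety)
  resid <- if (!is.null(resid_field) && length(resid_field) == nrow(at)) {
    resid_field
  } else {
    # rebuild per-molecule indices from the global numbering
    stats::ave(at$resno, at$segid, FUN = function(v) {
      match(v, sort(unique(v)))
    })
  }
  atoms <- tibble::tibble(
    role = role, chain = at$segid, resid = as.integer(resid),
    resname = at$resid, x = 0, y = 0, z = 0
  )
  nm <- nrow(pdb$xyz)
  frames <- lapply(seq_len(nm), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    f <- atoms
    f$x <- xyz[, 1]
    f$y <- xyz[, 2]
    f$z <- xyz[, 3]
    new_frame(f,
      box = box, periodic = periodic,
      time = t0 + (m - 1) * max(dt, 0)
    )
  })
  if (nm == 1) frames[[1]] else new_trajectory(frames, dt = if (dt > 0) dt else 1)
}

# --- atom selection ------------------------------------------------------

# short aliases accepted by the selection mini-language
.role_aliases <- c(
  CA = "BACKBONE_CA", NZ = "LYS_NZ", CD = "GLU_CD", P = "LIPID_P",
  CHOLINE = "LIPID_CHOLINE_N", C2 = "LIPID_C2_OLEOYL"
)

#' Select atoms by role, residue, chain or molecule class
#'
#' Evaluates a selection expression against a frame and returns the matching
#' row indices. The expression is either a predicate string in a small
#' selection language -- terms `role:<ROLE>` (full role names or the
#' aliases CA, NZ, CD, P, CHOLINE, C2), `resid:<n>` (1-based residue index
#' within its molecule), `chain:<id>`, `resname:<name>`, and the molecule
#' classes `peptide` / `lipid` / `chol`, combined with `not` (binds
#' tightest), `and`, then `or` -- or a function taking the frame and
#' returning a logical vector.
#'
#' @param frame A `pep_frame` (a single frame of a trajectory works too).
#' @param selection Selection string or predicate function.
#' @return Integer vector of matching atom row indices.
#' @examples
#' fr <- build_membrane_patch()
#' length(select_atoms(fr, "role:P"))            # 90 phosphates
#' select_atoms(fr, "role:CA and resid:9")       # 9th-residue C-alphas
#' @export
select_atoms <- function(frame, selection) {
  if (is.function(selection)) {
    return(which(selection(frame)))
  }
  stopifnot(is.character(selection), length(selection) == 1)
  tokens <- strsplit(trimws(selection), "\\s+")[[1]]
  eval_term <- function(tok) {
    if (tok == "peptide") {
      return(substr(frame$chain, 1, 1) == "P")
    }
    if (tok == "lipid") {
      return(substr(frame$chain, 1, 1) == "L")
    }
    if (tok == "chol") {
      return(substr(frame$chain, 1, 1) == "C")
    }
    kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad selection term: ", tok, call. = FALSE)
    key <- kv[1]
    val <- kv[2]
    switch(key,
      role = {
        role <- if (val %in% names(.role_aliases)) .role_aliases[[val]] else val
        if (!role %in% atom_roles()) {
          stop("unknown role in selection: ", val, call. = FALSE)
        }
        frame$role == role
      },
      resid = frame$resid == as.integer(val),
      chain = frame$chain == val,
      resname = frame$resname == val,
      stop("bad selection key: ", key, call. = FALSE)
    )
  }
  # parse: or-separated groups of and-separated (possibly negated) terms
  i <- 1
  parse_factor <- function() {
    neg <- FALSE
    while (i <= length(tokens) && tokens[i] == "not") {
      neg <- !neg
      i <<- i + 1
    }
    if (i > length(tokens)) stop("dangling operator in selection", call. = FALSE)
    v <- eval_term(tokens[i])
    i <<- i + 1
    if (neg) !v else v
  }
  parse_and <- function() {
    v <- parse_factor()
    while (i <= length(tokens) && tokens[i] == "and") {
      i <<- i + 1
      v <- v & parse_factor()
    }
    v
  }
  parse_or <- function() {
    v <- parse_and()
    while (i <= length(tokens) && tokens[i] == "or") {
      i <<- i + 1
      v <- v | parse_and()
    }
    v
  }
  out <- parse_or()
  if (i <= length(tokens)) {
    stop("trailing tokens in selection: ", paste(tokens[i:length(tokens)],
      collapse = " "
    ), call. = FALSE)
  }
  which(out)
}
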