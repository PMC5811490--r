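# Pseudo-lipid geometry. Reduced POPC carries only the atoms the metrics
# reference: choline N, phosphate P, two oleoyl-equivalent C2 atoms and two
# generic chain carbons. Depths are typical distances from the bilayer
# centre: phosphate ~19, C2/carbonyl ~14.5, choline ~21 Angstrom.
.z_choline <- 21
.z_p <- 19
.z_c2 <- 14.5

# one reduced POPC at head position (x, y) in leaflet s (+1 upper, -1 lower)
pseudo_popc <- function(x, y, s, chain) {
  tibble::tibble(
    role = c(
      "LIPID_CHOLINE_N", "LIPID_P", "LIPID_C2_OLEOYL", "LIPID_C2_OLEOYL",
      "LIPID_OTHER", "LIPID_OTHER"
    ),
    chain = chain, resid = 1L, resname = "POP",
    x = x + c(0.5, 0, -0.8, 0.8, 0, 0),
    y = y + c(0, 0, 0, 0, 0.5, -0.5),
    z = s * c(.z_choline, .z_p, .z_c2, .z_c2, .z_c2 - 4, .z_c2 - 8)
  )
}

# reduced cholesterol: a short CHOL_C chain; participates in no metric
pseudo_chol <- function(x, y, s, chain) {
  tibble::tibble(
    role = "CHOL_C", chain = chain, resid = 1L, resname = "CHL",
    x = x, y = y, z = s * c(12, 8, 4)
  )
}

# square-lattice head positions for one leaflet over an Lx x Ly patch
leaflet_grid <- function(n, lx, ly) {
  m <- ceiling(sqrt(n * lx / ly))
  k <- ceiling(n / m)
  g <- expand.grid(
    x = (seq_len(m) - 0.5) * lx / m - lx / 2,
    y = (seq_len(k) - 0.5) * ly / k - ly / 2
  )
  g[seq_len(n), ]
}

# lipids for one leaflet: n_popc POPC and n_chol cholesterol on a grid,
# cholesterol interleaved at evenly spaced sites
build_leaflet <- function(n_popc, n_chol, s, lx, ly, chain_offset_popc,
                          chain_offset_chol) {
  n <- n_popc + n_chol
  g <- leaflet_grid(n, lx, ly)
  chol_sites <- if (n_chol > 0) {
    unique(round(seq(1, n, length.out = n_chol)))
  } else {
    integer(0)
  }
  popc_sites <- setdiff(seq_len(n), chol_sites)[seq_len(n_popc)]
  lipids <- purrr::imap(popc_sites, function(site, i) {
    pseudo_popc(g$x[site], g$y[site], s, paste0("L", chain_offset_popc + i))
  })
  chols <- purrr::imap(chol_sites, function(site, i) {
    pseudo_chol(g$x[site], g$y[site], s, paste0("C", chain_offset_chol + i))
  })
  dplyr::bind_rows(lipids, chols)
}

# orient a helix built by build_ideal_helix(): optionally flip the axis
# (about x), then rotate about z so the hydrophobic face points at
# `face_to` degrees, then tilt the axis into the membrane plane if `flat`
orient_helix <- function(atoms, sequence, face_to, flip = FALSE,
                         flat = FALSE, ala_hydrophobic = FALSE) {
  centre <- backbone_centre(atoms)
  atoms <- transform_atoms(atoms, translation = -centre)
  az <- face_azimuth(sequence, ala_hydrophobic = ala_hydrophobic)
  if (flip) {
    atoms <- transform_atoms(atoms, rot_x(180))
    az <- (-az) %% 360
  }
  atoms <- transform_atoms(atoms, rot_z(face_to - az))
  if (flat) {
    # axis z -> x; an azimuth-0 face ends up pointing along -z
    atoms <- transform_atoms(atoms, rot_y(90))
  }
  atoms
}

#' Build a surface-bound membrane patch
#'
#' Emulates the surface-binding geometry: a flat pseudo-lipid bilayer with
#' one peptide per leaflet lying flat (helix axis in the bilayer plane) at a
#' configurable height above the oleoyl C2 plane, hydrophobic face toward
#' the bilayer interior. Default composition 90 POPC : 10 cholesterol : 2
#' peptides.
#'
#' @param sequence Peptide sequence (the same peptide on both leaflets).
#' @param n_popc,n_chol Lipid counts, split evenly between leaflets.
#' @param n_peptides Number of peptides (1 or 2; one per leaflet).
#' @param height Initial height of the backbone centre above the C2 plane,
#'   Angstrom.
#' @param apl Area per lipid, Angstrom^2 (sets the patch size).
#' @return A `pep_frame`, periodic in the bilayer plane.
#' @export
build_membrane_patch <- function(sequence = elk_peptides()[["neu"]],
                                 n_popc = 90, n_chol = 10, n_peptides = 2,
                                 height = 5, apl = 65) {
  if (n_popc + n_chol <= 0) stop("zero lipids", call. = FALSE)
  stopifnot(n_peptides %in% c(1L, 2L))
  n_leaf <- (n_popc + n_chol) / 2
  l <- sqrt(n_leaf * apl)
  upper <- build_leaflet(floor(n_popc / 2), floor(n_chol / 2), +1, l, l, 0, 0)
  lower <- build_leaflet(
    n_popc - floor(n_popc / 2), n_chol - floor(n_chol / 2), -1, l, l,
    floor(n_popc / 2), floor(n_chol / 2)
  )
  peps <- purrr::map(seq_len(n_peptides), function(i) {
    s <- if (i == 1) +1 else -1
    h <- build_ideal_helix(sequence, chain = paste0("P", i))
    # flat helix with the hydrophobic face toward the bilayer interior
    h <- orient_helix(h, sequence,
      face_to = if (s > 0) 0 else 180, flat = TRUE
    )
    transform_atoms(h, translation = c(0, 0, s * (.z_c2 + height)))
  })
  new_frame(dplyr::bind_rows(upper, lower, peps),
    box = c(l, l, 2 * (.z_choline + 15)),
    periodic = c(TRUE, TRUE, FALSE)
  )
}

#' Build an edge-exposed bilayer slab
#'
#' Emulates the nanodisc-patch geometry: a bilayer slab periodic along one
#' in-plane axis (y) with its two acyl-chain edges exposed along x, and
#' upright peptides (helix axis along the bilayer normal) covering the
#' edges, hydrophobic faces toward the acyl chains. Consecutive peptides on
#' an edge point the same way (`"parallel"`, head-to-head) or alternate
#' (`"antiparallel"`, head-to-tail); `"mixed"` puts a parallel arrangement
#' on one edge and an antiparallel one on the other.
#'
#' @param sequence Peptide sequence.
#' @param n_popc,n_chol Lipid counts.
#' @param n_peptides Total peptides, split evenly between the two edges.
#' @param arrangement `"mixed"`, `"parallel"` or `"antiparallel"`.
#' @param edge_length Slab length along the periodic axis, Angstrom.
#' @param apl Area per lipid, Angstrom^2.
#' @return A `pep_frame`, periodic along y only.
#' @export
build_edge_slab <- function(sequence = elk_peptides()[["neu"]],
                            n_popc = 80, n_chol = 8, n_peptides = 8,
                            arrangement = c("mixed", "parallel", "antiparallel"),
                            edge_length = 70, apl = 65) {
  arrangement <- match.arg(arrangement)
  if (n_popc + n_chol <= 0) stop("zero lipids", call. = FALSE)
  stopifnot(n_peptides >= 2, n_peptides %% 2 == 0)
  n_edge <- n_peptides / 2
  # ~12 Angstrom footprint per upright helix along the edge
  if (n_edge * 12 > edge_length) {
    stop("more peptides than the edge length accommodates", call. = FALSE)
  }
  n_leaf <- (n_popc + n_chol) / 2
  wx <- n_leaf * apl / edge_length
  upper <- build_leaflet(floor(n_popc / 2), floor(n_chol / 2), +1, wx,
    edge_length, 0, 0
  )
  lower <- build_leaflet(
    n_popc - floor(n_popc / 2), n_chol - floor(n_chol / 2), -1, wx,
    edge_length, floor(n_popc / 2), floor(n_chol / 2)
  )
  flips <- switch(arrangement,
    parallel = rep(FALSE, n_peptides),
    antiparallel = rep(c(FALSE, TRUE), length.out = n_peptides),
    mixed = c(
      rep(FALSE, n_edge),
      rep(c(FALSE, TRUE), length.out = n_edge)
    )
  )
  x_edge <- wx / 2 + 6
  peps <- purrr::map(seq_len(n_peptides), function(i) {
    edge <- if (i <= n_edge) +1 else -1
    j <- if (i <= n_edge) i else i - n_edge
    y <- (j - 0.5) * edge_length / n_edge - edge_length / 2
    h <- build_ideal_helix(sequence, chain = paste0("P", i))
    h <- orient_helix(h, sequence,
      face_to = if (edge > 0) 180 else 0, flip = flips[i]
    )
    transform_atoms(h, translation = c(edge * x_edge, y, 0))
  })
  new_frame(dplyr::bind_rows(upper, lower, peps),
    box = c(2 * (x_edge + 12), edge_length, 60),
    periodic = c(FALSE, TRUE, FALSE)
  )
}

#' Build a peptide-stabilised nanodisc
#'
#' Emulates the nanodisc geometry: a circular pseudo-lipid bilayer disc
#' (sunflower packing per leaflet) with peptides either upright around the
#' rim in a picket-fence arrangement (antiparallel neighbours, hydrophobic
#' faces toward the acyl chains) or lying flat at random positions on the
#' two disc surfaces. Default composition 150 POPC : 15 cholesterol : 24
#' peptides.
#'
#' @param sequence Peptide sequence.
#' @param n_popc,n_chol Lipid counts.
#' @param n_peptides Peptide count (split across surfaces for random
#'   placement).
#' @param placement `"picket_fence"` or `"random_surface"`.
#' @param radius Disc radius, Angstrom; defaults to the radius implied by
#'   the leaflet lipid count at `apl`.
#' @param apl Area per lipid, Angstrom^2.
#' @param seed Integer seed; required for `"random_surface"`.
#' @return A `pep_frame` with no periodicity.
#' @export
build_nanodisc <- function(sequence = elk_peptides()[["neu"]],
                           n_popc = 150, n_chol = 15, n_peptides = 24,
                           placement = c("picket_fence", "random_surface"),
                           radius = NULL, apl = 65, seed = NULL) {
  placement <- match.arg(placement)
  if (placement == "random_surface" && is.null(seed)) {
    stop("random surface placement requires a seed", call. = FALSE)
  }
  n_leaf_popc <- c(floor(n_popc / 2), n_popc - floor(n_popc / 2))
  n_leaf_chol <- c(floor(n_chol / 2), n_chol - floor(n_chol / 2))
  if (is.null(radius)) {
    radius <- sqrt(max(n_leaf_popc + n_leaf_chol) * apl / pi)
  }
  golden <- pi * (3 - sqrt(5))
  disc_leaflet <- function(n_p, n_c, s, off_p, off_c) {
    n <- n_p + n_c
    k <- seq_len(n)
    r <- radius * sqrt((k - 0.5) / n)
    th <- k * golden
    chol_sites <- if (n_c > 0) unique(round(seq(1, n, length.out = n_c))) else integer(0)
    popc_sites <- setdiff(k, chol_sites)[seq_len(n_p)]
    dplyr::bind_rows(
      purrr::imap(popc_sites, function(site, i) {
        pseudo_popc(r[site] * cos(th[site]), r[site] * sin(th[site]), s,
          paste0("L", off_p + i)
        )
      }),
      purrr::imap(chol_sites, function(site, i) {
        pseudo_chol(r[site] * cos(th[site]), r[site] * sin(th[site]), s,
          paste0("C", off_c + i)
        )
      })
    )
  }
  upper <- disc_leaflet(n_leaf_popc[1], n_leaf_chol[1], +1, 0, 0)
  lower <- disc_leaflet(n_leaf_popc[2], n_leaf_chol[2], -1, n_leaf_popc[1],
    n_leaf_chol[1]
  )
  peps <- if (placement == "picket_fence") {
    purrr::map(seq_len(n_peptides), function(i) {
      phi <- (i - 1) * 360 / n_peptides
      h <- build_ideal_helix(sequence, chain = paste0("P", i))
      # upright on the rim, hydrophobic face pointing inward
      h <- orient_helix(h, sequence,
        face_to = (phi + 180) %% 360,
        flip = i %% 2 == 0
      )
      transform_atoms(h, translation = (radius + 4) *
        c(cos(phi * pi / 180), sin(phi * pi / 180), 0))
    })
  } else {
    with_seed(seed, {
      purrr::map(seq_len(n_peptides), function(i) {
        s <- if (i <= ceiling(n_peptides / 2)) +1 else -1
        rr <- 0.8 * radius * sqrt(stats::runif(1))
        ph <- stats::runif(1, 0, 2 * pi)
        spin <- stats::runif(1, 0, 360)
        h <- build_ideal_helix(sequence, chain = paste0("P", i))
        h <- orient_helix(h, sequence,
          face_to = if (s > 0) 0 else 180, flat = TRUE
        )
        h <- transform_atoms(h, rot_z(spin))
        transform_atoms(h, translation = c(
          rr * cos(ph), rr * sin(ph), s * (.z_c2 + 6)
        ))
      })
    })
  }
  new_frame(dplyr::bind_rows(upper, lower, peps),
    box = c(4 * radius, 4 * radius, 120),
    periodic = c(FALSE, FALSE, FALSE)
  )
}

# evaluate code with a private, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Synthesize a noisy trajectory from a configuration
#'
#' Produces a test trajectory by adding i.i.d. Gaussian displacements to
#' every atom in every frame (no dynamics). An optional contact script pins
#' designated atom pairs inside (80% of cutoff) or outside (150% of cutoff)
#' their contact cutoff per frame, giving exact-lifetime ground truth.
#'
#' @param frame A `pep_frame` starting configuration.
#' @param sigma Per-axis Gaussian displacement SD, Angstrom (>= 0).
#' @param n_frames Number of frames (>= 1).
#' @param dt Frame spacing, ps.
#' @param seed Integer seed (required when `sigma > 0`).
#' @param contact_script Optional tibble with columns `atom_a`, `atom_b`
#'   (row indices into `frame`), `cutoff` (Angstrom) and `schedule` (a
#'   list-column of logical vectors of length `n_frames`; TRUE = in
#'   contact).
#' @return A `pep_traj`.
#' @export
synthesize_trajectory <- function(frame, sigma, n_frames, dt = 10,
                                  seed = NULL, contact_script = NULL) {
  stopifnot(is_frame(frame), n_frames >= 1, sigma >= 0, dt > 0)
  if (sigma > 0 && is.null(seed)) stop("noise requires a seed", call. = FALSE)
  base <- as.matrix(frame[, c("x", "y", "z")])
  n_atoms <- nrow(base)
  make_frames <- function() {
    purrr::map(seq_len(n_frames), function(t) {
      xyz <- base
      if (sigma > 0) {
        xyz <- xyz + matrix(stats::rnorm(3 * n_atoms, sd = sigma), n_atoms, 3)
      }
      if (!is.null(contact_script)) {
        for (k in seq_len(nrow(contact_script))) {
          a <- contact_script$atom_a[k]
          b <- contact_script$atom_b[k]
          on <- contact_script$schedule[[k]][t]
          u <- base[b, ] - base[a, ]
          nu <- sqrt(sum(u^2))
          u <- if (nu < 1e-8) c(1, 0, 0) else u / nu
          d <- if (isTRUE(on)) 0.8 else 1.5
          xyz[b, ] <- xyz[a, ] + u * d * contact_script$cutoff[k]
        }
      }
      f <- frame
      f$x <- xyz[, 1]
      f$y <- xyz[, 2]
      f$z <- xyz[, 3]
      f
    })
  }
  frames <- if (is.null(seed)) make_frames() else with_seed(seed, make_frames())
  new_trajectory(frames, dt = dt)
}
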