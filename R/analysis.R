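#' Block-averaged mean and standard error
#'
#' Splits a (correlated) time series into `n_blocks` equal-length contiguous
#' blocks (any trailing remainder is dropped), takes the mean of block
#' means, and reports the standard error as the standard deviation of block
#' means divided by sqrt(n_blocks).
#'
#' @param x Numeric time series of length >= `n_blocks`.
#' @param n_blocks Number of blocks (default 10).
#' @return An object of class `block_estimate`: list with `mean`, `stderr`,
#'   `n_blocks`, `block_means` and `n_used` (samples actually used).
#' @examples
#' glance(block_statistics(rnorm(1000)))
#' @export
block_statistics <- function(x, n_blocks = 10) {
  stopifnot(n_blocks >= 2)
  if (length(x) < n_blocks) {
    stop("series shorter than the number of blocks", call. = FALSE)
  }
  len <- floor(length(x) / n_blocks)
  used <- x[seq_len(len * n_blocks)]
  bm <- colMeans(matrix(used, nrow = len))
  structure(
    list(
      mean = mean(bm), stderr = stats::sd(bm) / sqrt(n_blocks),
      n_blocks = n_blocks, block_means = bm, n_used = len * n_blocks
    ),
    class = "block_estimate"
  )
}

#' @export
print.block_estimate <- function(x, ...) {
  cat(sprintf(
    "block estimate: %.4g +/- %.3g (%d blocks)\n",
    x$mean, x$stderr, x$n_blocks
  ))
  invisible(x)
}

#' Peptide insertion height above the C2 plane
#'
#' Per-frame signed vertical distance between the centre of geometry of a
#' peptide's backbone C-alphas and the mean z of the oleoyl C2 atoms of the
#' peptide's leaflet, block-averaged over the trajectory. The sign is
#' positive toward the aqueous phase of that leaflet, so a peptide buried
#' below the C2 plane has negative height.
#'
#' @param traj A `pep_traj`.
#' @param chain Peptide chain id (e.g. `"P1"`).
#' @param leaflet `"auto"` (from the sign of the peptide's mean z in the
#'   first frame), `"upper"` or `"lower"`.
#' @param n_blocks Blocks for the error estimate.
#' @return A `block_estimate` in Angstrom.
#' @export
peptide_height <- function(traj, chain, leaflet = c("auto", "upper", "lower"),
                           n_blocks = 10) {
  leaflet <- match.arg(leaflet)
  series <- peptide_height_series(traj, chain, leaflet)
  block_statistics(series, n_blocks)
}

#' @rdname peptide_height
#' @return `peptide_height_series()`: the raw per-frame heights in
#'   Angstrom.
#' @export
peptide_height_series <- function(traj, chain,
                                  leaflet = c("auto", "upper", "lower")) {
  leaflet <- match.arg(leaflet)
  stopifnot(is_trajectory(traj))
  frames <- traj_frames(traj)
  ca1 <- frames[[1]]$role == "BACKBONE_CA" & frames[[1]]$chain == chain
  if (!any(ca1)) stop("no backbone C-alphas for chain ", chain, call. = FALSE)
  if (!any(frames[[1]]$role == "LIPID_C2_OLEOYL")) {
    stop("no oleoyl C2 atoms in frame", call. = FALSE)
  }
  s <- switch(leaflet,
    upper = 1,
    lower = -1,
    auto = sign(mean(frames[[1]]$z[ca1]))
  )
  if (s == 0) stop("cannot infer leaflet: peptide centred at z = 0", call. = FALSE)
  vapply(frames, function(f) {
    zp <- mean(f$z[f$role == "BACKBONE_CA" & f$chain == chain])
    c2 <- f$z[f$role == "LIPID_C2_OLEOYL" & sign(f$z) == s]
    if (length(c2) == 0) stop("no C2 atoms in the peptide's leaflet", call. = FALSE)
    s * (zp - mean(c2))
  }, numeric(1))
}

#' Time-averaged 2D number-density map
#'
#' Histograms the positions of selected atoms on a coordinate plane in
#' every frame and averages over frames. Cell values are number densities
#' (atoms per Angstrom^2), so the map integrates to the mean selected-atom
#' count per frame: `sum(density) * bin^2 == mean count`.
#'
#' @param traj A `pep_traj` (a single `pep_frame` is treated as one frame).
#' @param selection Selection for [select_atoms()].
#' @param axes Two of `"x"`, `"y"`, `"z"` naming the map plane.
#' @param bin Bin width, Angstrom (> 0).
#' @return A tibble of class `pep_density` with cell-centre columns named
#'   after `axes` and a `density` column; bin size, axes and frame count as
#'   attributes.
#' @export
density_map <- function(traj, selection, axes = c("x", "z"), bin = 1) {
  stopifnot(bin > 0, length(axes) == 2, all(axes %in% c("x", "y", "z")))
  frames <- if (is_trajectory(traj)) traj_frames(traj) else list(traj)
  idx <- select_atoms(frames[[1]], selection)
  if (length(idx) == 0) {
    warning("empty selection; density map is all zero", call. = FALSE)
    out <- tibble::tibble(u = numeric(), v = numeric(), density = numeric())
    names(out)[1:2] <- axes
    return(structure(out,
      bin = bin, axes = axes, n_frames = length(frames),
      class = c("pep_density", class(out))
    ))
  }
  u <- unlist(lapply(frames, function(f) f[[axes[1]]][idx]))
  v <- unlist(lapply(frames, function(f) f[[axes[2]]][idx]))
  iu <- floor(u / bin)
  iv <- floor(v / bin)
  counts <- dplyr::count(tibble::tibble(iu = iu, iv = iv), .data$iu, .data$iv)
  out <- tibble::tibble(
    u = (counts$iu + 0.5) * bin,
    v = (counts$iv + 0.5) * bin,
    density = counts$n / (bin^2 * length(frames))
  )
  names(out)[1:2] <- axes
  structure(out,
    bin = bin, axes = axes, n_frames = length(frames),
    class = c("pep_density", class(out))
  )
}

#' Plot a number-density map
#'
#' @param object A `pep_density` map.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pep_density <- function(object, ...) {
  axes <- attr(object, "axes")
  ggplot2::ggplot(object, ggplot2::aes(
    .data[[axes[1]]], .data[[axes[2]]],
    fill = .data$density
  )) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = paste(axes[1], "(Å)"), y = paste(axes[2], "(Å)"),
      fill = "atoms/Å²"
    )
}

#' Disc diameter from the z moment of inertia
#'
#' Estimates the diameter of a discoidal assembly by comparing the
#' out-of-plane moment of inertia of the selected atoms (unit masses) with
#' that of a homogeneous disc, I_z = N R^2 / 2. The atoms are centred on
#' their centroid and aligned on their principal axes (the axis of least
#' positional spread becomes the disc normal z); then
#' \deqn{I_z = \sum_i (x_i^2 + y_i^2), \quad D = 2\sqrt{2 I_z / N}.}
#' The estimator is exact for homogeneous discs and biased high for mass
#' concentrated at the rim (a thin ring gives 2 sqrt(2) R).
#'
#' @param frame A `pep_frame`.
#' @param selection Selection for [select_atoms()]; by default the lipid
#'   atoms only (peptides excluded, includable by selecting them).
#' @return An object of class `disc_geometry`: list with `diameter`
#'   (Angstrom), `i_z`, `n` and the disc `normal` unit vector in the
#'   original frame coordinates.
#' @export
disc_diameter <- function(frame, selection = "lipid or chol") {
  idx <- select_atoms(frame, selection)
  if (length(idx) < 3) stop("need at least 3 selected atoms", call. = FALSE)
  xyz <- as.matrix(frame[idx, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(xyz))
  gyr <- crossprod(xyz) / nrow(xyz)
  if (qr(gyr)$rank < 2) stop("degenerate (collinear) atom set", call. = FALSE)
  eig <- eigen(gyr, symmetric = TRUE)
  # smallest positional spread = disc normal
  normal <- eig$vectors[, 3]
  rot <- xyz %*% eig$vectors
  i_z <- sum(rot[, 1]^2 + rot[, 2]^2)
  n <- nrow(xyz)
  structure(
    list(
      diameter = 2 * sqrt(2 * i_z / n), i_z = i_z, n = n,
      normal = normal
    ),
    class = "disc_geometry"
  )
}

#' @export
print.disc_geometry <- function(x, ...) {
  cat(sprintf(
    "disc diameter %.2f Angstrom (N = %d atoms, I_z = %.4g)\n",
    x$diameter, x$n, x$i_z
  ))
  invisible(x)
}
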