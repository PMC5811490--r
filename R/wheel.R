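#' Helical-wheel layout
#'
#' Projects a helix onto the plane perpendicular to its axis: residue i sits
#' at angle ((i-1) * delta) mod 360. For an 18-mer at the ideal alpha-helical
#' twist of 100 deg/residue the 18 positions are exactly the multiples of
#' 20 deg, each occupied once, and each residue owns a 20 deg sector.
#'
#' @param sequence A single peptide sequence.
#' @param delta Helical twist per residue, degrees.
#' @param ala_hydrophobic Count Ala in the hydrophobic class?
#' @return A tibble of class `pep_wheel` with columns `position` (1-based),
#'   `residue`, `angle` (degrees in [0, 360)) and `class`; the residue sector
#'   width (the angular grid spacing generated by `delta`, 20 deg at the
#'   default twist) is carried as attribute `width`.
#' @examples
#' wheel_layout("EKLLELLKKLLELLKELL")
#' @export
wheel_layout <- function(sequence, delta = 100, ala_hydrophobic = FALSE) {
  res <- pep_residues(sequence)
  out <- tibble::tibble(
    position = seq_along(res),
    residue = res,
    angle = ((seq_along(res) - 1) * delta) %% 360,
    class = residue_class(res, ala_hydrophobic = ala_hydrophobic)
  )
  # grid spacing of wheel positions; 20 deg for the ideal 100 deg twist
  width <- .wheel_width(delta)
  structure(out, width = width, class = c("pep_wheel", class(out)))
}

# angular grid generated by delta on the circle: gcd(delta, 360)
.wheel_width <- function(delta) {
  g <- function(a, b) if (b < 1e-9) a else g(b, a %% b)
  g(360, delta %% 360)
}

#' Hydrophobic-face subtended angle
#'
#' The angle subtended by the maximal contiguous arc of wheel positions
#' occupied by hydrophobic-class residues, computed circularly (the arc may
#' cross 0 deg) on the quantized wheel and reported as the span between the
#' arc's extreme members plus one residue sector width (20 deg at the
#' default twist). A single hydrophobic residue therefore subtends 20 deg;
#' a fully hydrophobic wheel subtends 360 deg.
#'
#' @param x A `pep_wheel` layout or a sequence string (which is laid out with
#'   the given `delta` and `ala_hydrophobic`).
#' @param delta,ala_hydrophobic Passed to [wheel_layout()] when `x` is a
#'   sequence.
#' @return Subtended angle in degrees.
#' @examples
#' face_angle("EKLLELLKKLLELLKELL") # 200
#' @export
face_angle <- function(x, delta = 100, ala_hydrophobic = FALSE) {
  if (is.character(x)) x <- wheel_layout(x, delta, ala_hydrophobic)
  stopifnot(inherits(x, "pep_wheel"))
  width <- attr(x, "width")
  occupied <- sort(unique(x$angle[x$class == "hydrophobic"]))
  if (length(occupied) == 0) {
    stop("no hydrophobic residue on the wheel; face angle undefined",
      call. = FALSE
    )
  }
  slots <- sort(unique(x$angle))
  occ <- slots %in% occupied
  if (all(occ)) {
    return(360)
  }
  # longest circular run of occupied slots; runs measured on the slot grid
  occ2 <- c(occ, occ)
  best <- 0
  run <- 0
  for (v in occ2) {
    run <- if (v) run + 1 else 0
    best <- max(best, min(run, length(slots)))
  }
  # span between extreme members plus one residue width
  (best - 1) * width + width
}

#' @rdname face_angle
#' @export
hydrophobic_face_angle <- face_angle

#' Plot a helical wheel
#'
#' Draws the wheel projection with residues coloured by class and labelled
#' with one-letter code and position.
#'
#' @param object A `pep_wheel` layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pep_wheel <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
    theta = .data$angle * pi / 180,
    x = cos(.data$theta), y = sin(.data$theta),
    label = paste0(.data$residue, .data$position)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::coord_equal(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25)) +
    ggplot2::scale_colour_manual(values = c(
      hydrophobic = "#e6c200", charged = "#d62728", `neutral-polar` = "grey70"
    )) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

#' @rdname autoplot.pep_wheel
#' @param x A `pep_wheel` layout.
#' @param y Unused.
#' @export
plot.pep_wheel <- function(x, y, ...) print(autoplot.pep_wheel(x, ...))
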