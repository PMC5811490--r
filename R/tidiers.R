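#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidiers for block estimates
#'
#' `tidy()` returns one row per block with its mean; `glance()` returns a
#' one-row summary with the block-averaged mean, its standard error and the
#' block count.
#'
#' @param x A `block_estimate`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.block_estimate <- function(x, ...) {
  tibble::tibble(block = seq_along(x$block_means), mean = x$block_means)
}

#' @rdname tidy.block_estimate
#' @exportS3Method generics::glance
glance.block_estimate <- function(x, ...) {
  tibble::tibble(
    mean = x$mean, stderr = x$stderr, n_blocks = x$n_blocks,
    n_used = x$n_used
  )
}

#' Tidiers for disc geometry estimates
#'
#' @param x A `disc_geometry`.
#' @param ... Unused.
#' @return A one-row tibble with `diameter` (Angstrom), `i_z` and `n`.
#' @exportS3Method generics::tidy
tidy.disc_geometry <- function(x, ...) {
  tibble::tibble(diameter = x$diameter, i_z = x$i_z, n = x$n)
}

#' @rdname tidy.disc_geometry
#' @exportS3Method generics::glance
glance.disc_geometry <- tidy.disc_geometry

#' Tidier for contact series
#'
#' @param x A `contact_series`.
#' @param ... Unused.
#' @return A tibble with one row per frame: `frame`, `time` (ps), `count`.
#' @exportS3Method generics::tidy
tidy.contact_series <- function(x, ...) {
  tibble::tibble(
    frame = seq_along(x$counts),
    time = (seq_along(x$counts) - 1) * x$dt,
    count = x$counts
  )
}
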