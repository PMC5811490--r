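#' Mean residue ellipticity
#'
#' Normalises an observed circular-dichroism signal per residue:
#' \deqn{[\theta] = \theta_{obs} \cdot MRW / (10 \cdot l \cdot c)}
#' with the observed ellipticity in millidegrees, path length in cm,
#' concentration in mg/mL and a mean residue weight in Da (121 by default,
#' appropriate for short Glu/Leu/Lys/Ala peptides).
#'
#' @param theta_obs Observed ellipticity, millidegrees.
#' @param conc Peptide concentration, mg/mL (> 0).
#' @param path Cuvette path length, cm (> 0).
#' @param mrw Mean residue weight, Da.
#' @return Mean residue ellipticity, deg cm^2 dmol^-1.
#' @examples
#' mean_residue_ellipticity(1, conc = 1, path = 0.2) # 60.5
#' @export
mean_residue_ellipticity <- function(theta_obs, conc, path, mrw = 121) {
  if (any(conc <= 0)) stop("concentration must be positive", call. = FALSE)
  if (any(path <= 0)) stop("path length must be positive", call. = FALSE)
  theta_obs * mrw / (10 * path * conc)
}

#' Percent helicity from the 222 nm ellipticity
#'
#' Single-wavelength linear estimator: the mean residue ellipticity at
#' 222 nm is mapped linearly between a 0%-helix reference and a 100%-helix
#' reference and clipped to [0, 100]. The default references (-3000 for
#' random coil, -39500 for a fully formed helix, deg cm^2 dmol^-1) are the
#' classic single-wavelength values; both are exposed because published
#' helicity numbers depend on the chosen pair.
#'
#' @param mre222 Mean residue ellipticity at 222 nm, deg cm^2 dmol^-1.
#' @param ref0 MRE222 corresponding to 0% helix.
#' @param ref100 MRE222 corresponding to 100% helix.
#' @return Percent helicity in [0, 100].
#' @examples
#' helicity_from_mre222(-21250) # midway between defaults -> 50
#' @export
helicity_from_mre222 <- function(mre222, ref0 = -3000, ref100 = -39500) {
  stopifnot(ref100 != ref0)
  pmin(100, pmax(0, 100 * (mre222 - ref0) / (ref100 - ref0)))
}
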