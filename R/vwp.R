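#' Vortex wave plate model
#'
#' A vortex wave plate (VWP) is a half-wave retarder whose fast axis
#' rotates with azimuth (fast-axis angle \eqn{q\phi}, with \eqn{q = 1/2}
#' for the geometry that maps radial polarization to horizontal). At the
#' design wavelength the retardance is exactly \eqn{\pi} and the VWP
#' converts radially/azimuthally polarized light into horizontal/vertical
#' polarization with 100% efficiency; away from it a fraction
#' \eqn{\cos^2(\delta/2)} of the light is left unconverted.
#'
#' The chromatic model follows a nematic liquid-crystal retarder: the
#' retardance is \eqn{\delta(\lambda) = 2\pi\,\Delta n(\lambda)\,t /
#' \lambda} with a two-term Cauchy birefringence
#' \eqn{\Delta n(\lambda) = a + b/\lambda^2}, and the thickness \eqn{t}
#' is calibrated so that \eqn{\delta(\lambda_\mathrm{design}) = \pi}.
#' The Cauchy term makes the retardance error grow faster towards the
#' blue edge of a detection band, as is typical of nematic LCs. The
#' default coefficients (`a = 0.18`, `b = 1.5e4` nm^2, giving
#' \eqn{\Delta n \approx 0.21} at 680 nm) describe a generic
#' visible-range nematic LC.
#'
#' @param design_wavelength Wavelength (nm) at which \eqn{\delta = \pi}.
#' @param cauchy_a,cauchy_b Cauchy coefficients of the birefringence
#'   \eqn{\Delta n(\lambda) = a + b/\lambda^2} (\eqn{b} in nm^2).
#' @param q Fast-axis order (fast-axis angle is \eqn{q\phi}).
#' @param ideal If `TRUE`, the VWP is perfectly achromatic: the
#'   retardance is \eqn{\pi} at every wavelength.
#' @return An object of class `vwp_model`.
#' @examples
#' v <- vwp_model(design_wavelength = 680, ideal = FALSE)
#' lc_retardance(v, 680) / pi   # exactly 1 at the design wavelength
#' @export
vwp_model <- function(design_wavelength = 680, cauchy_a = 0.18,
                      cauchy_b = 1.5e4, q = 0.5, ideal = TRUE) {
  stopifnot(design_wavelength > 0, cauchy_a > 0, cauchy_b >= 0)
  dn_design <- cauchy_a + cauchy_b / design_wavelength^2
  thickness <- design_wavelength / (2 * dn_design)   # delta(design) = pi
  structure(list(design_wavelength = design_wavelength,
                 cauchy_a = cauchy_a, cauchy_b = cauchy_b,
                 thickness = thickness, q = q, ideal = ideal),
            class = "vwp_model")
}

#' @export
print.vwp_model <- function(x, ...) {
  cat(sprintf("<vwp_model: %s, design %g nm, q = %g>\n",
              if (x$ideal) "ideal (achromatic)" else "chromatic LC",
              x$design_wavelength, x$q))
  invisible(x)
}

#' Retardance of the liquid-crystal vortex wave plate
#'
#' \eqn{\delta(\lambda) = 2\pi\,\Delta n(\lambda)\, t/\lambda}, with the
#' Cauchy birefringence of [vwp_model()]. Strictly decreasing in
#' \eqn{\lambda} and equal to \eqn{\pi} at the design wavelength. For an
#' ideal VWP the retardance is \eqn{\pi} everywhere.
#'
#' @param vwp A [vwp_model()].
#' @param wavelength Wavelength(s) in nm.
#' @return Retardance in radians.
#' @export
lc_retardance <- function(vwp, wavelength) {
  stopifnot(inherits(vwp, "vwp_model"))
  if (any(wavelength <= 0)) stop("wavelength must be positive", call. = FALSE)
  if (vwp$ideal) return(rep(pi, length(wavelength)))
  dn <- vwp$cauchy_a + vwp$cauchy_b / wavelength^2
  2 * pi * dn * vwp$thickness / wavelength
}

#' Jones transformation of the vortex wave plate
#'
#' Applies the VWP retarder (retardance \eqn{\delta(\lambda)}, fast axis
#' at \eqn{q\phi}) to a field given by its radial and azimuthal
#' components on the pupil, and returns the Cartesian (H, V) output
#' components that a polarizing beam splitter separates. At
#' \eqn{\delta = \pi} the map is exactly R to H and A to V (up to a
#' global phase); at other retardances the unconverted fraction
#' \eqn{\cos^2(\delta/2)} keeps its original polarization structure and
#' splits between both output ports, degrading the parity of the
#' interferometer arm.
#'
#' The retarder Jones matrix is unitary, so
#' \eqn{|E_H|^2 + |E_V|^2 = |E_R|^2 + |E_A|^2} pointwise.
#'
#' @param ER,EA Complex matrices: radial and azimuthal field components.
#' @param phi Matrix of pupil azimuth angles (radians), same shape.
#' @param vwp A [vwp_model()].
#' @param wavelength Wavelength in nm.
#' @return List with complex matrices `H` and `V`.
#' @export
vwp_transform <- function(ER, EA, phi, vwp, wavelength) {
  delta <- lc_retardance(vwp, wavelength)
  EH <- ER * cos(phi) - EA * sin(phi)
  EV <- ER * sin(phi) + EA * cos(phi)
  if (vwp$ideal || abs(delta - pi) < 1e-14) {
    # delta = pi: exact R -> H, A -> V (phases -i and +i dropped per port)
    return(list(H = ER, V = EA))
  }
  c2 <- cos(delta / 2)
  s2 <- sin(delta / 2)
  ax <- 2 * vwp$q * phi   # polarization rotation axis angle doubled
  H <- c2 * EH - 1i * s2 * (cos(ax) * EH + sin(ax) * EV)
  V <- c2 * EV - 1i * s2 * (sin(ax) * EH - cos(ax) * EV)
  list(H = H, V = V)
}

#' Interferometer imperfection parameters
#'
#' Describes the image-inversion (SLIVER) interferometer: the intensity
#' fraction `split_ratio` sent into the inverting arm (ideal 1/2) and a
#' residual phase offset `phase` (radians) between the arms at the
#' recombining beam splitter. The symmetric/antisymmetric outputs are
#' \deqn{E_\pm = \tfrac{1}{\sqrt 2}\left(\sqrt{1-r}\,E(x,y) \pm
#'   \sqrt{r}\,e^{i\Delta\phi} E(-x,-y)\right),}
#' which for \eqn{r = 1/2, \Delta\phi = 0} reduces to the ideal
#' half/half split and conserves energy for any \eqn{r, \Delta\phi}.
#' A split ratio of 1:0.95 corresponds to
#' `split_ratio = 0.95 / 1.95`.
#'
#' @param split_ratio Intensity fraction in the inverting arm.
#' @param phase Arm phase offset in radians.
#' @return An object of class `interferometer`.
#' @export
interferometer <- function(split_ratio = 0.5, phase = 0) {
  stopifnot(split_ratio > 0, split_ratio < 1)
  structure(list(split_ratio = split_ratio, phase = phase),
            class = "interferometer")
}

#' @export
print.interferometer <- function(x, ...) {
  cat(sprintf("<interferometer: split %.4f, phase %.4f rad>\n",
              x$split_ratio, x$phase))
  invisible(x)
}
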