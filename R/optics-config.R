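#' Optical configuration for the dipole imaging model
#'
#' Defines the optical system used throughout the package: emission
#' wavelength (optionally a finite detection band), objective numerical
#' aperture, the refractive-index stack of sample medium / coverslip /
#' immersion, and the pupil and camera sampling grids. The configuration
#' is the coordinate authority for every downstream computation: pupil
#' fields, point spread functions, Fisher information and quantum bounds
#' all derive their grids from it.
#'
#' The camera pixel size defaults to \eqn{\lambda/(8\,\mathrm{NA})}, well
#' below the Nyquist rate, so that all features of the vectorial PSF are
#' resolved; each pixel is integrated over
#' `subpixel_oversampling^2` sub-samples. The pupil is sampled on an
#' odd-sized square grid spanning the NA disc symmetrically about
#' \eqn{k = 0}, so that point inversion of the pupil (and of the image
#' plane) is an exact index reversal with no interpolation; this matters
#' for the interferometric (SLIVER) channels whose null depths are probed
#' down to machine precision.
#'
#' @param emission_wavelength Emission wavelength \eqn{\lambda} in nm.
#' @param numerical_aperture Objective numerical aperture; must not
#'   exceed `n_immersion`.
#' @param bandwidth Detection bandwidth \eqn{\Delta\lambda} in nm (full
#'   width of the emission filter). `0` means monochromatic. When
#'   positive, computations average over `n_wavelengths` equally spaced,
#'   equally weighted wavelengths across the band.
#' @param n_medium,n_coverslip,n_immersion Refractive indices of the
#'   sample medium, coverslip and immersion oil. The defaults
#'   (1.33/1.516/1.516) describe a watery sample under an oil-immersion
#'   objective; the index step at the medium/coverslip interface produces
#'   supercritical-angle fluorescence (SAF) rings in the pupil.
#' @param pupil_grid_n Number of pupil samples per axis (odd, so that the
#'   grid contains \eqn{k = 0} and is inversion symmetric).
#' @param image_size Camera pixels per axis per channel.
#' @param pixel_size Camera pixel size in nm; default
#'   \eqn{\lambda/(8\,\mathrm{NA})}.
#' @param subpixel_oversampling Sub-samples per pixel per axis used for
#'   pixel integration.
#' @param emitter_depth Distance (nm) of the emitter from the
#'   medium/coverslip interface. The default 0 places the emitter at the
#'   interface, in focus, where SAF is strongest.
#' @param n_wavelengths Number of spectral samples across the band when
#'   `bandwidth > 0`.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(emission_wavelength = 680, numerical_aperture = 1.45)
#' cfg
#' @export
optical_config <- function(emission_wavelength = 680,
                           numerical_aperture = 1.45,
                           bandwidth = 0,
                           n_medium = 1.33,
                           n_coverslip = 1.516,
                           n_immersion = 1.516,
                           pupil_grid_n = 129,
                           image_size = 150,
                           pixel_size = NULL,
                           subpixel_oversampling = 2,
                           emitter_depth = 0,
                           n_wavelengths = 11) {
  if (is.null(pixel_size)) {
    pixel_size <- emission_wavelength / (8 * numerical_aperture)
  }
  cfg <- structure(list(
    emission_wavelength = emission_wavelength,
    numerical_aperture = numerical_aperture,
    bandwidth = bandwidth,
    n_medium = n_medium,
    n_coverslip = n_coverslip,
    n_immersion = n_immersion,
    pupil_grid_n = as.integer(pupil_grid_n),
    image_size = as.integer(image_size),
    pixel_size = pixel_size,
    subpixel_oversampling = as.integer(subpixel_oversampling),
    emitter_depth = emitter_depth,
    n_wavelengths = as.integer(n_wavelengths),
    model = "dipole"
  ), class = "optical_config")
  validate_optical_config(cfg)
  cfg
}

validate_optical_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$model == "dipole") {
    if (cfg$numerical_aperture > cfg$n_immersion) {
      stop("numerical_aperture must not exceed n_immersion", call. = FALSE)
    }
    if (cfg$emission_wavelength <= 0) stop("wavelength must be positive")
  }
  if (cfg$pupil_grid_n < 3 || cfg$image_size < 2) {
    stop("grid sizes must be positive (pupil_grid_n >= 3, image_size >= 2)",
         call. = FALSE)
  }
  if (cfg$pupil_grid_n %% 2 == 0) {
    stop("pupil_grid_n must be odd so the pupil grid contains k = 0",
         call. = FALSE)
  }
  if (cfg$bandwidth < 0) stop("bandwidth must be >= 0", call. = FALSE)
  if (cfg$subpixel_oversampling < 1) {
    stop("subpixel_oversampling must be >= 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Scalar Gaussian reference model
#'
#' A drop-in replacement for the vectorial dipole pupil in which the
#' emitter has a scalar Gaussian amplitude PSF of intensity width
#' `sigma`. This is the textbook model for which the quantum bound on
#' two-emitter separation is known in closed form (the QCRB variance at
#' one expected photon equals \eqn{4\sigma_\mathrm{psf}^2},
#' independently of the separation), so it serves as the primary
#' cross-check of the numerical quantum-Fisher-information machinery.
#'
#' The pupil-plane amplitude is \eqn{\exp(-k^2\sigma^2)}, sampled out to
#' `kmax_factor / sigma` where it has decayed to
#' \eqn{e^{-\mathrm{kmax\_factor}^2}}; both pupil and image supports are
#' then effectively unbounded, so truncation effects are negligible.
#'
#' @param sigma Intensity PSF width in nm (standard deviation of
#'   \eqn{|\psi|^2}).
#' @param pixel_size Camera pixel size in nm; default `sigma / 4`.
#' @param image_size,pupil_grid_n,subpixel_oversampling As in
#'   [optical_config()].
#' @param kmax_factor Pupil support half-width in units of `1 / sigma`.
#' @return An object of class `optical_config` with `model = "gaussian"`.
#' @examples
#' gcfg <- gaussian_config(sigma = 100)
#' @export
gaussian_config <- function(sigma = 100,
                            pixel_size = sigma / 4,
                            image_size = 150,
                            pupil_grid_n = 129,
                            subpixel_oversampling = 2,
                            kmax_factor = 4) {
  cfg <- structure(list(
    sigma = sigma,
    emission_wavelength = NA_real_,
    numerical_aperture = NA_real_,
    bandwidth = 0,
    pupil_grid_n = as.integer(pupil_grid_n),
    image_size = as.integer(image_size),
    pixel_size = pixel_size,
    subpixel_oversampling = as.integer(subpixel_oversampling),
    kmax_factor = kmax_factor,
    n_wavelengths = 1L,
    model = "gaussian"
  ), class = "optical_config")
  validate_optical_config(cfg)
  cfg
}

#' @export
print.optical_config <- function(x, ...) {
  if (x$model == "gaussian") {
    cat(sprintf("<optical_config: scalar Gaussian model, sigma = %g nm>\n",
                x$sigma))
  } else {
    cat(sprintf(
      "<optical_config: lambda = %g nm%s, NA = %g, n = %g/%g/%g>\n",
      x$emission_wavelength,
      if (x$bandwidth > 0) sprintf(" (band %g nm)", x$bandwidth) else "",
      x$numerical_aperture, x$n_medium, x$n_coverslip, x$n_immersion))
  }
  cat(sprintf("  pupil %d x %d; image %d px of %.2f nm, %dx oversampled\n",
              x$pupil_grid_n, x$pupil_grid_n, x$image_size, x$pixel_size,
              x$subpixel_oversampling))
  invisible(x)
}

#' Wavelengths sampled by a configuration
#'
#' For a monochromatic configuration this is the emission wavelength; for
#' `bandwidth > 0` it is `n_wavelengths` equally spaced samples spanning
#' the band, weighted uniformly (flat emission spectrum).
#'
#' @param cfg An [optical_config()].
#' @return Numeric vector of wavelengths in nm.
#' @export
config_wavelengths <- function(cfg) {
  if (cfg$model == "gaussian" || cfg$bandwidth <= 0) {
    return(if (cfg$model == "gaussian") NA_real_ else cfg$emission_wavelength)
  }
  seq(cfg$emission_wavelength - cfg$bandwidth / 2,
      cfg$emission_wavelength + cfg$bandwidth / 2,
      length.out = cfg$n_wavelengths)
}

#' Read or write a configuration as a flat YAML file
#'
#' @param cfg An [optical_config()].
#' @param path File path.
#' @return `read_config()` returns an [optical_config()];
#'   `write_config()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' write_config(optical_config(), p)
#' read_config(p)
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  model <- x$model %||% "dipole"
  if (model == "gaussian") {
    do.call(gaussian_config, x[intersect(names(x), names(formals(gaussian_config)))])
  } else {
    do.call(optical_config, x[intersect(names(x), names(formals(optical_config)))])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
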