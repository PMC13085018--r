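#' @keywords internal
#' @name pupil-internal
#' @noRd
NULL

# Stratified-medium Fresnel transmission amplitudes for the
# medium -> coverslip -> immersion stack, evaluated at the immersion-side
# sine grid. Angles beyond the medium critical angle become complex with
# the Im >= 0 branch, which carries the supercritical-angle fluorescence.
fresnel_stack <- function(sin_i, cos_i, n_med, n_cov, n_imm) {
  sin_m <- n_imm * sin_i / n_med
  cos_m <- sqrt(as.complex(1 - sin_m^2))     # principal sqrt: Im >= 0
  sin_g <- n_imm * sin_i / n_cov
  cos_g <- sqrt(as.complex(1 - sin_g^2))
  ts1 <- 2 * n_med * cos_m / (n_med * cos_m + n_cov * cos_g)
  tp1 <- 2 * n_med * cos_m / (n_cov * cos_m + n_med * cos_g)
  ts2 <- 2 * n_cov * cos_g / (n_cov * cos_g + n_imm * cos_i)
  tp2 <- 2 * n_cov * cos_g / (n_imm * cos_g + n_cov * cos_i)
  list(ts = ts1 * ts2, tp = tp1 * tp2, sin_m = sin_m, cos_m = cos_m)
}

# Vectorial pupil basis of a dipole emitter at one wavelength: the six
# polarized far fields (orientations x,y,z in each of the R/A and H/V
# polarization bases) on the odd-symmetric pupil grid, jointly normalized
# so the total detected intensity per photon is 1.
#
# The radial/azimuthal components follow the far field of a dipole below
# a planar index step, collected by an aplanatic (sine-condition)
# objective:
#   E_R ∝ tp (mu_x cosθ_m cosφ + mu_y cosθ_m sinφ - mu_z sinθ_m) / sqrt(cosθ_i)
#   E_A ∝ ts (-mu_x sinφ + mu_y cosφ) / sqrt(cosθ_i)
# with θ_m the medium-side polar angle (complex beyond the critical
# angle) and θ_i the immersion-side angle. H/V are the Cartesian
# components, E_H = E_R cosφ - E_A sinφ, E_V = E_R sinφ + E_A cosφ.
#
# At the singular pupil origin (φ undefined) the Cartesian fields take
# their physical on-axis values while the stored R/A components are set
# to their azimuthal principal value 0, so the exact parity of the
# azimuthal basis (odd for x/y dipoles, zero for z) holds on the grid.
pupil_basis <- function(cfg, wavelength = NULL) {
  if (cfg$model == "gaussian") return(gaussian_pupil_basis(cfg))
  lambda <- wavelength %||% cfg$emission_wavelength
  na <- cfg$numerical_aperture
  N <- cfg$pupil_grid_n
  kmax <- 2 * pi * na / lambda
  k <- seq(-kmax, kmax, length.out = N)
  dk <- k[2] - k[1]
  KX <- matrix(k, N, N)
  KY <- matrix(k, N, N, byrow = TRUE)
  KR <- sqrt(KX^2 + KY^2)
  mask <- KR <= kmax * (1 + 1e-12)
  k0 <- 2 * pi / lambda
  sin_i <- KR / (k0 * cfg$n_immersion)
  sin_i[!mask] <- 0
  cos_i <- sqrt(pmax(0, 1 - sin_i^2))
  fr <- fresnel_stack(sin_i, cos_i, cfg$n_medium, cfg$n_coverslip,
                      cfg$n_immersion)
  phi <- atan2(KY, KX)
  apod <- 1 / sqrt(pmax(cos_i, 1e-12))
  depth_phase <- if (cfg$emitter_depth != 0) {
    exp(1i * cfg$emitter_depth * k0 * cfg$n_medium * fr$cos_m)
  } else 1
  mk <- function(v) {
    v <- v * apod * depth_phase
    v[!mask] <- 0 + 0i
    v
  }
  zero <- matrix(0 + 0i, N, N)
  R <- list(x = mk(fr$tp * fr$cos_m * cos(phi)),
            y = mk(fr$tp * fr$cos_m * sin(phi)),
            z = mk(-fr$tp * fr$sin_m))
  A <- list(x = mk(-fr$ts * sin(phi)),
            y = mk(fr$ts * cos(phi)),
            z = zero)
  H <- lapply(c(x = "x", y = "y", z = "z"),
              function(j) R[[j]] * cos(phi) - A[[j]] * sin(phi))
  V <- lapply(c(x = "x", y = "y", z = "z"),
              function(j) R[[j]] * sin(phi) + A[[j]] * cos(phi))
  # azimuthal principal value at the singular origin sample
  c0 <- (N + 1L) / 2L
  for (j in c("x", "y", "z")) {
    R[[j]][c0, c0] <- 0 + 0i
    A[[j]][c0, c0] <- 0 + 0i
  }
  f <- list(R = R, A = A, H = H, V = V)
  S <- sum(vapply(f$H, function(m) sum(Mod(m)^2), 0)) +
       sum(vapply(f$V, function(m) sum(Mod(m)^2), 0))
  S <- S * dk^2 / (2 * pi)^2
  sc <- 1 / sqrt(S)
  f <- lapply(f, function(l) lapply(l, function(m) m * sc))
  list(fields = f, k = k, dk = dk, KX = KX, KY = KY, phi = phi, mask = mask,
       wavelength = lambda, orientations = c("x", "y", "z"))
}

gaussian_pupil_basis <- function(cfg) {
  N <- cfg$pupil_grid_n
  kmax <- cfg$kmax_factor / cfg$sigma
  k <- seq(-kmax, kmax, length.out = N)
  dk <- k[2] - k[1]
  KX <- matrix(k, N, N)
  KY <- matrix(k, N, N, byrow = TRUE)
  E <- exp(-(KX^2 + KY^2) * cfg$sigma^2) + 0i
  S <- sum(Mod(E)^2) * dk^2 / (2 * pi)^2
  E <- E / sqrt(S)
  zero <- matrix(0 + 0i, N, N)
  f <- list(R = list(s = E), A = list(s = zero),
            H = list(s = E), V = list(s = zero))
  list(fields = f, k = k, dk = dk, KX = KX, KY = KY,
       phi = atan2(KY, KX), mask = matrix(TRUE, N, N),
       wavelength = NA_real_, orientations = "s")
}

#' Vectorial pupil field of a dipole emitter
#'
#' Computes the complex far-field amplitude, after the objective, of a
#' dipole oscillating along `orientation`, expressed in the requested
#' polarization basis component: `"R"`/`"A"` (radial/azimuthal) or
#' `"H"`/`"V"` (horizontal/vertical Cartesian). The field lives on a
#' square \eqn{(k_x, k_y)} grid spanning the NA disc and is exactly zero
#' outside the aperture. The six fields of one emitter (three
#' orientations in two polarizations) are jointly normalized so the
#' emitter's total detected intensity is 1 per photon.
#'
#' Key symmetries realized exactly on the grid: the azimuthal field of a
#' z-oriented dipole is identically zero; the azimuthal fields of x/y
#' dipoles are odd under pupil point inversion; the Cartesian H/V fields
#' of x/y dipoles are even and those of the z dipole odd. The oddness of
#' the azimuthal basis at every dipole orientation is what gives the
#' polarization-sorted interferometric scheme its unit visibility.
#'
#' @param cfg An [optical_config()].
#' @param orientation Dipole orientation, one of `"x"`, `"y"`, `"z"`
#'   (or `"s"` for the scalar Gaussian model).
#' @param polarization One of `"H"`, `"V"`, `"R"`, `"A"`.
#' @param wavelength Wavelength in nm; defaults to the configuration's
#'   emission wavelength.
#' @return An object of class `pupil_field`: a list with the complex
#'   `values` matrix, the `k` axis (rad/nm), and metadata.
#' @examples
#' cfg <- optical_config(pupil_grid_n = 65)
#' f <- dipole_pupil(cfg, "x", "A")
#' max(Mod(f$values + f$values[rev(seq_len(65)), rev(seq_len(65))]))  # odd
#' @export
dipole_pupil <- function(cfg, orientation, polarization = c("H", "V", "R", "A"),
                         wavelength = NULL) {
  polarization <- match.arg(polarization)
  pb <- pupil_basis(cfg, wavelength)
  orientation <- match.arg(orientation, pb$orientations)
  structure(list(
    values = pb$fields[[polarization]][[orientation]],
    k = pb$k, dk = pb$dk, KX = pb$KX, KY = pb$KY,
    orientation = orientation, polarization = polarization,
    wavelength = pb$wavelength
  ), class = "pupil_field")
}

#' @export
print.pupil_field <- function(x, ...) {
  cat(sprintf(
    "<pupil_field: dipole %s, polarization %s, %d x %d, lambda %g nm>\n",
    x$orientation, x$polarization, length(x$k), length(x$k), x$wavelength))
  invisible(x)
}

#' Tip-tilt phase for a laterally displaced emitter
#'
#' Multiplies a pupil field by \eqn{\exp(-i k_x x_e - i k_y y_e)}, the
#' phase acquired when the emitter sits at \eqn{(x_e, y_e)} instead of
#' the optical axis. For an even or odd pupil field this phase breaks the
#' field's parity, which is what routes photons into the interferometer's
#' null channel and makes SLIVER sensitive to small displacements.
#'
#' @param field A `pupil_field` from [dipole_pupil()].
#' @param xe,ye Emitter displacement in nm.
#' @return A `pupil_field` with the phase applied.
#' @export
apply_tip_tilt <- function(field, xe, ye) {
  stopifnot(inherits(field, "pupil_field"))
  field$values <- field$values * exp(-1i * (field$KX * xe + field$KY * ye))
  field
}

# exact point inversion (k -> -k or x -> -x) on a symmetric grid
invert_grid <- function(m) {
  m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
}

#' Export a complex pupil field as paired magnitude/phase TIFF planes
#'
#' Writes a two-plane 32-bit float TIFF (magnitude scaled to `[0, 1]`,
#' phase mapped from \eqn{[-\pi, \pi]} to `[0, 1]`) plus a JSON sidecar
#' with the grid and scaling metadata.
#'
#' @param field A `pupil_field` from [dipole_pupil()].
#' @param path Output TIFF path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_pupil_tiff <- function(field, path) {
  stopifnot(inherits(field, "pupil_field"))
  mag <- Mod(field$values)
  mag_max <- max(mag, 1e-300)
  ph <- (Arg(field$values) + pi) / (2 * pi)
  tiff::writeTIFF(list(mag / mag_max, ph), path, bits.per.sample = 32L)
  jsonlite::write_json(list(
    orientation = field$orientation, polarization = field$polarization,
    wavelength_nm = field$wavelength, magnitude_scale = mag_max,
    phase_encoding = "plane2 * 2*pi - pi",
    k_axis = field$k), sub("\\.tiff?$", ".json", path),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
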