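METHODS <- c("DD", "SLIVER", "SLIVER+DD", "DDA+DDR", "PolarSLIVER")

#' Detection model engine
#'
#' Precomputes everything a detection method needs to produce its
#' channel PSFs: the vectorial pupil basis at each sampled wavelength,
#' the VWP-sorted port fields where the method uses one, and the
#' Fourier kernels mapping the pupil to the oversampled camera grid.
#' The engine is the object all bound computations operate on.
#'
#' The five methods and their output channels:
#' \describe{
#'   \item{DD}{direct detection; one channel, the incoherent sum of the
#'     six polarized dipole fields.}
#'   \item{SLIVER}{image-inversion interferometry of the full field;
#'     symmetric and antisymmetric channels.}
#'   \item{SLIVER+DD}{a 50/50 split between a DD arm and a SLIVER stage;
#'     three channels with weights 1/2, 1/4, 1/4 of the photons.}
#'   \item{DDA+DDR}{a vortex wave plate plus polarizing beam splitter
#'     sort the radial and azimuthal components; each is directly
#'     detected.}
#'   \item{PolarSLIVER}{the polarization-sorted interferometric scheme:
#'     the radial component is directly detected while the azimuthal
#'     component, which is odd for every dipole orientation, enters
#'     SLIVER. Its symmetric channel is ideally a perfect null.}
#' }
#'
#' @param cfg An [optical_config()].
#' @param method One of `"DD"`, `"SLIVER"`, `"SLIVER+DD"`, `"DDA+DDR"`,
#'   `"PolarSLIVER"`.
#' @param vwp A [vwp_model()]; used by the VWP methods. Defaults to an
#'   ideal VWP designed at the emission wavelength.
#' @param ifm An [interferometer()]; defaults to ideal.
#' @return An object of class `detection_model`.
#' @examples
#' cfg <- optical_config(pupil_grid_n = 65, image_size = 64)
#' mod <- detection_model(cfg, "PolarSLIVER")
#' psf <- method_psf(mod)
#' sum(unlist(lapply(psf$channels, sum)))   # close to 1
#' @export
detection_model <- function(cfg, method = METHODS, vwp = NULL, ifm = NULL) {
  method <- match.arg(method)
  validate_optical_config(cfg)
  if (cfg$model == "gaussian" && method %in% c("DDA+DDR", "PolarSLIVER")) {
    stop("polarization-sorted methods are undefined for the scalar model",
         call. = FALSE)
  }
  if (is.null(vwp)) {
    vwp <- vwp_model(design_wavelength =
                       if (cfg$model == "gaussian") 680 else
                         cfg$emission_wavelength)
  }
  if (is.null(ifm)) ifm <- interferometer()
  lambdas <- config_wavelengths(cfg)
  os <- cfg$subpixel_oversampling
  M <- cfg$image_size * os
  x <- (seq_len(M) - (M + 1) / 2) * (cfg$pixel_size / os)
  per_lambda <- lapply(lambdas, function(lam) {
    pb <- pupil_basis(cfg, if (is.na(lam)) NULL else lam)
    ports <- build_ports(pb, method, vwp, lam)
    A <- exp(1i * outer(x, pb$k)) * pb$dk / (2 * pi)
    list(pb = pb, ports = ports, A = A)
  })
  structure(list(
    config = cfg, method = method, vwp = vwp, ifm = ifm,
    lambdas = lambdas, per_lambda = per_lambda,
    x = x, os = os,
    pixmat = pixel_matrix(cfg$image_size, os),
    dxs2 = (cfg$pixel_size / os)^2,
    cache = new.env(parent = emptyenv())
  ), class = "detection_model")
}

# Port = a set of pupil fields sharing one detection stage.
# type "dd": channel intensity sum |FT field|^2; type "sliver": the
# interferometer produces sym/asym channels. `weight` multiplies the
# full-input port intensity (beam-splitter power fractions of
# the method definitions).
build_ports <- function(pb, method, vwp, lambda) {
  f <- pb$fields
  hv <- c(f$H, f$V)
  if (method == "DD") {
    return(list(list(type = "dd", fields = hv, labels = "DD", weight = 1)))
  }
  if (method == "SLIVER") {
    return(list(list(type = "sliver", fields = hv,
                     labels = c("Sym", "Asym"), weight = 1)))
  }
  if (method == "SLIVER+DD") {
    return(list(
      list(type = "dd", fields = hv, labels = "DD", weight = 0.5),
      list(type = "sliver", fields = hv, labels = c("Sym", "Asym"),
           weight = 0.5)))
  }
  # VWP methods: sort R/A into the two PBS ports
  Hp <- list(); Vp <- list()
  for (j in pb$orientations) {
    out <- vwp_transform(f$R[[j]], f$A[[j]], pb$phi, vwp, lambda)
    Hp[[j]] <- out$H
    Vp[[j]] <- out$V
  }
  if (method == "DDA+DDR") {
    return(list(
      list(type = "dd", fields = Hp, labels = "DD-R", weight = 1),
      list(type = "dd", fields = Vp, labels = "DD-A", weight = 1)))
  }
  # PolarSLIVER
  list(
    list(type = "dd", fields = Hp, labels = "DD-R", weight = 1),
    list(type = "sliver", fields = Vp, labels = c("Sym-A", "Asym-A"),
         weight = 1))
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("<detection_model: %s, %d wavelength%s>\n", x$method,
              length(x$lambdas), if (length(x$lambdas) > 1) "s" else ""))
  print(x$config)
  invisible(x)
}

# aggregation matrix summing os x os subpixel blocks into pixels
pixel_matrix <- function(npix, os) {
  P <- matrix(0, npix, npix * os)
  P[cbind(rep(seq_len(npix), each = os), seq_len(npix * os))] <- 1
  P
}

#' Image-plane amplitude of a pupil field
#'
#' Propagates a pupil field to the oversampled camera grid by a direct
#' (matrix-product) discrete Fourier transform, optionally displacing
#' the emitter by `offset` through the tip-tilt pupil phase. The
#' matrix-product transform decouples the pupil sampling from the image
#' sampling, so the pupil can be finely resolved (supercritical-angle
#' ring included) while the image grid stays at the camera geometry.
#'
#' @param model A [detection_model()] (supplies the grids), or an
#'   [optical_config()].
#' @param field A `pupil_field` from [dipole_pupil()].
#' @param offset Emitter displacement `c(xe, ye)` in nm; must lie within
#'   the camera field of view.
#' @return An object of class `amplitude_psf`: complex matrix `values`
#'   on the oversampled image grid plus the axis `x` (nm).
#' @export
amplitude_psf <- function(model, field, offset = c(0, 0)) {
  if (inherits(model, "optical_config")) {
    model <- detection_model(model, "DD")
  }
  check_offset(model, offset)
  pl <- model$per_lambda[[1]]
  tt <- exp(-1i * (pl$pb$KX * offset[1] + pl$pb$KY * offset[2]))
  W <- pl$A %*% (field$values * tt) %*% t(pl$A)
  structure(list(values = W, x = model$x, offset = offset,
                 wavelength = field$wavelength),
            class = "amplitude_psf")
}

check_offset <- function(model, offset) {
  half_fov <- model$config$image_size * model$config$pixel_size / 2
  if (any(abs(offset) > half_fov * 0.98)) {
    stop("emitter offset lies outside the camera field of view",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Split an image-plane amplitude into interferometer outputs
#'
#' Combines an image-plane amplitude with its point-inverted copy into
#' the symmetric and antisymmetric output intensities of the
#' image-inversion interferometer. The inversion is an exact index
#' reversal on the symmetric grid (no interpolation), so parity nulls
#' are exact to machine precision. Imperfections (arm split ratio,
#' residual phase) are taken from the [interferometer()] object.
#'
#' @param amp An `amplitude_psf` (or bare complex matrix on a symmetric
#'   grid).
#' @param ifm An [interferometer()].
#' @return List with nonnegative intensity matrices `sym` and `asym`
#'   (same normalization as `Mod(amp)^2`; their total equals the input
#'   total for any split ratio and phase).
#' @export
sliver_split <- function(amp, ifm = interferometer()) {
  W <- if (inherits(amp, "amplitude_psf")) amp$values else amp
  if (nrow(W) != ncol(W)) stop("inversion requires a square symmetric grid",
                               call. = FALSE)
  Wi <- invert_grid(W)
  a <- sqrt(1 - ifm$split_ratio)
  b <- sqrt(ifm$split_ratio) * exp(1i * ifm$phase)
  list(sym  = Mod((a * W + b * Wi) / sqrt(2))^2,
       asym = Mod((b * Wi - a * W) / sqrt(2))^2)
}

#' Integrate an oversampled intensity onto camera pixels
#'
#' Each pixel value is the sum of its `os^2` subpixel sample weights
#' (the samples already carry the subpixel area), so total intensity is
#' conserved exactly.
#'
#' @param intensity Real matrix on the oversampled grid.
#' @param os Integer subpixel oversampling per axis.
#' @return Matrix of pixel values.
#' @export
pixelate <- function(intensity, os) {
  n <- nrow(intensity)
  if (os != round(os) || n %% os != 0 || ncol(intensity) %% os != 0) {
    stop("oversampled grid must be an integer refinement of the pixel grid",
         call. = FALSE)
  }
  if (os == 1) return(intensity)
  P <- pixel_matrix(n / os, os)
  P %*% intensity %*% t(P)
}

#' Channel PSFs of a detection method
#'
#' Produces the ordered per-channel point spread functions of the
#' model's detection method for an emitter displaced by `offset`: pupil
#' fields are tip-tilted, Fourier transformed to the oversampled image
#' grid, passed through the method's detection stages (direct detection
#' or interferometer), integrated onto camera pixels, and (for a finite
#' detection bandwidth) averaged uniformly over the sampled wavelengths.
#' Channel values are photon probabilities per pixel; over all channels
#' they sum to the fraction of the emitter's photons that lands inside
#' the camera field of view (slightly below 1 because the dipole PSF has
#' a long-tailed halo).
#'
#' @param model A [detection_model()].
#' @param offset Emitter displacement `c(xe, ye)` in nm.
#' @return An object of class `detection_psf`: list with `channels`
#'   (named list of `image_size` x `image_size` matrices), `weights`,
#'   `method`, `offset`.
#' @export
method_psf <- function(model, offset = c(0, 0)) {
  stopifnot(inherits(model, "detection_model"))
  check_offset(model, offset)
  nl <- length(model$per_lambda)
  acc <- NULL
  for (pl in model$per_lambda) {
    ch <- channels_one_lambda(model, pl, offset)
    acc <- if (is.null(acc)) ch else Map(`+`, acc, ch)
  }
  channels <- lapply(acc, function(m) m / nl)
  weights <- channel_weights(model$method)
  structure(list(channels = channels, weights = weights,
                 method = model$method, offset = offset,
                 config = model$config),
            class = "detection_psf")
}

channels_one_lambda <- function(model, pl, offset) {
  tt <- exp(-1i * (pl$pb$KX * offset[1] + pl$pb$KY * offset[2]))
  A <- pl$A
  P <- model$pixmat
  out <- list()
  for (port in pl$ports) {
    if (port$type == "dd") {
      I <- 0
      for (E in port$fields) I <- I + Mod(A %*% (E * tt) %*% t(A))^2
      out[[port$labels]] <- (out[[port$labels]] %||% 0) +
        port$weight * (P %*% I %*% t(P)) * model$dxs2
    } else {
      S <- 0; As <- 0
      for (E in port$fields) {
        W <- A %*% (E * tt) %*% t(A)
        sp <- sliver_split(W, model$ifm)
        S <- S + sp$sym
        As <- As + sp$asym
      }
      out[[port$labels[1]]] <- (out[[port$labels[1]]] %||% 0) +
        port$weight * (P %*% S %*% t(P)) * model$dxs2
      out[[port$labels[2]]] <- (out[[port$labels[2]]] %||% 0) +
        port$weight * (P %*% As %*% t(P)) * model$dxs2
    }
  }
  out[channel_order(model$method)]
}

channel_order <- function(method) {
  switch(method,
         DD = "DD",
         SLIVER = c("Sym", "Asym"),
         "SLIVER+DD" = c("DD", "Sym", "Asym"),
         "DDA+DDR" = c("DD-R", "DD-A"),
         PolarSLIVER = c("DD-R", "Sym-A", "Asym-A"))
}

# channel multipliers of the method definitions (exact rationals), in the
# convention where the interferometer intensities are |(w + w_inv)/sqrt(2)|^2
channel_weights <- function(method) {
  switch(method,
         DD = c(DD = 1),
         SLIVER = c(Sym = 1 / 2, Asym = 1 / 2),
         "SLIVER+DD" = c(DD = 1 / 2, Sym = 1 / 4, Asym = 1 / 4),
         "DDA+DDR" = c("DD-R" = 1, "DD-A" = 1),
         PolarSLIVER = c("DD-R" = 1, "Sym-A" = 1 / 2, "Asym-A" = 1 / 2))
}

#' @export
print.detection_psf <- function(x, ...) {
  tot <- vapply(x$channels, sum, 0)
  cat(sprintf("<detection_psf: %s, offset (%g, %g) nm>\n", x$method,
              x$offset[1], x$offset[2]))
  for (nm in names(x$channels)) {
    cat(sprintf("  %-8s %3d x %3d px, total %.4f\n", nm,
                nrow(x$channels[[nm]]), ncol(x$channels[[nm]]), tot[[nm]]))
  }
  invisible(x)
}

#' Export channel PSFs as a multi-plane TIFF with a JSON sidecar
#'
#' Writes the channel images as a 32-bit float multi-plane TIFF
#' (one plane per channel) and a JSON sidecar recording channel labels,
#' nominal weights, method and configuration.
#'
#' @param psf A `detection_psf` from [method_psf()].
#' @param path Output TIFF path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_psf_tiff <- function(psf, path) {
  planes <- lapply(psf$channels, function(m) {
    m <- m / max(m, 1e-300)          # TIFF float planes scaled to [0, 1]
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(method = psf$method,
               channels = names(psf$channels),
               weights = as.list(psf$weights),
               channel_totals = lapply(psf$channels, sum),
               offset_nm = psf$offset,
               config = unclass(psf$config))
  jsonlite::write_json(side, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
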