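#' Two-emitter parameter vector
#'
#' The six parameters of the two-emitter model: separation `d` and angle
#' `alpha` of the emitter pair, centroid `(x0, y0)`, total expected
#' signal photons `s`, and background `b`. The two emitters are
#' identical and sit at the centroid plus/minus half the separation
#' vector \eqn{(\Delta x, \Delta y) = d(\cos\alpha, \sin\alpha)}.
#'
#' Background is specified in photons per \eqn{\sigma_\mathrm{psf}^2}
#' (photons per pixel if the pixel were \eqn{\sigma_\mathrm{psf}}
#' sized), the natural unit for comparing configurations with different
#' pixel sizes; it is converted internally to photons per camera pixel
#' and added uniformly to every pixel of every channel.
#'
#' @param d Separation in nm (>= 0).
#' @param alpha Angle (radians) between the x axis and the emitter line.
#' @param x0,y0 Centroid position in nm (nonzero `x0`/`y0` model
#'   misalignment between the pair and the interferometer inversion
#'   axis).
#' @param s Expected total signal photons from both emitters (> 0).
#' @param b Expected background photons per \eqn{\sigma_\mathrm{psf}^2}
#'   (>= 0).
#' @return An object of class `emitter_pair`.
#' @examples
#' emitter_pair(d = 50, s = 1000, b = 2)
#' @export
emitter_pair <- function(d = 0, alpha = 0, x0 = 0, y0 = 0, s = 1, b = 0) {
  stopifnot(d >= 0, s > 0, b >= 0)
  structure(list(d = d, alpha = alpha, x0 = x0, y0 = y0, s = s, b = b),
            class = "emitter_pair")
}

#' @export
print.emitter_pair <- function(x, ...) {
  cat(sprintf(
    "<emitter_pair: d = %g nm, alpha = %g rad, centroid (%g, %g) nm, s = %g, b = %g /sigma_psf^2>\n",
    x$d, x$alpha, x$x0, x$y0, x$s, x$b))
  invisible(x)
}

#' Expected pixel counts of the two-emitter model
#'
#' Builds the per-channel expected camera images
#' \deqn{I_\mathrm{2em} = \tfrac{s}{2} I(\cdot - r_0 - \Delta/2) +
#'   \tfrac{s}{2} I(\cdot - r_0 + \Delta/2) + b_\mathrm{px},}
#' the incoherent sum of two identical single-emitter channel PSFs at
#' the two emitter positions plus a uniform background per pixel per
#' channel.
#'
#' @param model A [detection_model()].
#' @param theta An [emitter_pair()].
#' @param sigma_psf \eqn{\sigma_\mathrm{psf}} in nm, needed to convert
#'   the background unit when `theta$b > 0`; computed from the
#'   configuration (and cached on the model) when omitted.
#' @return Named list of expected-count matrices, one per channel.
#' @export
two_emitter_image <- function(model, theta, sigma_psf = NULL) {
  stopifnot(inherits(model, "detection_model"),
            inherits(theta, "emitter_pair"))
  G <- two_emitter_shape(model, theta)
  bpx <- background_per_pixel(model, theta, sigma_psf)
  lapply(G, function(g) theta$s * g + bpx)
}

# mean per-photon shape (signal part / s); separated out so the Fisher
# matrix can use exact derivatives for the linear parameters s and b
two_emitter_shape <- function(model, theta) {
  dx <- theta$d * cos(theta$alpha) / 2
  dy <- theta$d * sin(theta$alpha) / 2
  p1 <- method_psf(model, c(theta$x0 + dx, theta$y0 + dy))
  p2 <- method_psf(model, c(theta$x0 - dx, theta$y0 - dy))
  Map(function(a, b) (a + b) / 2, p1$channels, p2$channels)
}

background_per_pixel <- function(model, theta, sigma_psf = NULL) {
  if (theta$b <= 0) return(0)
  if (is.null(sigma_psf)) sigma_psf <- sigma_psf(model$config)
  theta$b * (model$config$pixel_size / sigma_psf)^2
}

#' Fisher information matrix and Cramer-Rao bounds
#'
#' Computes the classical Fisher information matrix of the Poisson pixel
#' model over a chosen subset of the two-emitter parameters,
#' \deqn{F_{ij} = \sum_q \frac{1}{I_q}
#'   \frac{\partial I_q}{\partial\theta_i}
#'   \frac{\partial I_q}{\partial\theta_j},}
#' summing over all pixels of all channels. Geometry derivatives
#' (`d`, `alpha`, `x0`, `y0`) use central finite differences with steps
#' of \eqn{10^{-3}\sigma_\mathrm{psf}} (lengths) and \eqn{10^{-3}} rad;
#' the model is linear in `s` and `b`, so those derivatives are exact.
#' For a background-free model a floor of `eps` is added to the expected
#' counts in the \eqn{1/I_q} factor only, which regularizes empty pixels
#' without materially changing any reported bound.
#'
#' @param model A [detection_model()].
#' @param theta An [emitter_pair()].
#' @param params Character vector, subset of
#'   `c("d", "alpha", "x0", "y0", "s", "b")`.
#' @param sigma_psf \eqn{\sigma_\mathrm{psf}} in nm; computed (and
#'   cached) from the configuration when omitted. Used for the
#'   finite-difference steps and the background unit.
#' @param eps Floor added to expected counts in the denominator.
#' @return An object of class `fisher_result` with elements `fim`
#'   (the matrix), `crb` (per-parameter standard deviations from the
#'   full matrix inverse; `Inf` for directions the data do not
#'   constrain), `per_channel_fi` (the additive FI contribution of each
#'   channel), `params`, `theta`, `sigma_psf`.
#' @examples
#' cfg <- optical_config(pupil_grid_n = 65, image_size = 64)
#' mod <- detection_model(cfg, "DD")
#' fr <- fisher_matrix(mod, emitter_pair(d = 400), params = "d",
#'                     sigma_psf = 150)
#' crb(fr)
#' @export
fisher_matrix <- function(model, theta,
                          params = c("d", "alpha", "x0", "y0", "s", "b"),
                          sigma_psf = NULL, eps = 1e-12) {
  stopifnot(inherits(model, "detection_model"),
            inherits(theta, "emitter_pair"))
  params <- match.arg(params, c("d", "alpha", "x0", "y0", "s", "b"),
                      several.ok = TRUE)
  if (is.null(sigma_psf)) sigma_psf <- sigma_psf(model$config)
  G0 <- two_emitter_shape(model, theta)
  bpx <- background_per_pixel(model, theta, sigma_psf)
  I0 <- lapply(G0, function(g) theta$s * g + bpx)
  bunit <- (model$config$pixel_size / sigma_psf)^2
  steps <- list(d = 1e-3 * sigma_psf, alpha = 1e-3,
                x0 = 1e-3 * sigma_psf, y0 = 1e-3 * sigma_psf)
  derivs <- vector("list", length(params))
  names(derivs) <- params
  for (p in params) {
    if (p == "s") {
      derivs[[p]] <- G0
    } else if (p == "b") {
      derivs[[p]] <- lapply(G0, function(g) array(bunit, dim(g)))
    } else {
      h <- steps[[p]]
      tp <- theta; tp[[p]] <- tp[[p]] + h
      tm <- theta; tm[[p]] <- tm[[p]] - h
      Gp <- two_emitter_shape(model, tp)
      Gm <- two_emitter_shape(model, tm)
      derivs[[p]] <- Map(function(a, b) theta$s * (a - b) / (2 * h), Gp, Gm)
    }
  }
  np <- length(params)
  per_channel <- lapply(seq_along(I0), function(ci) {
    Fc <- matrix(0, np, np, dimnames = list(params, params))
    denom <- I0[[ci]] + eps
    for (i in seq_len(np)) for (j in i:np) {
      v <- sum(derivs[[i]][[ci]] * derivs[[j]][[ci]] / denom)
      Fc[i, j] <- v
      Fc[j, i] <- v
    }
    Fc
  })
  names(per_channel) <- names(I0)
  fim <- Reduce(`+`, per_channel)
  structure(list(fim = fim, crb = crb_from_fim(fim),
                 per_channel_fi = per_channel, params = params,
                 theta = theta, sigma_psf = sigma_psf,
                 method = model$method),
            class = "fisher_result")
}

# standard deviations from the full-matrix inverse, with diagonal
# prescaling for numerical stability; unconstrained directions give Inf
crb_from_fim <- function(fim) {
  d <- diag(fim)
  out <- rep(Inf, length(d))
  names(out) <- colnames(fim)
  ok <- d > 0
  if (!any(ok)) return(out)
  Dm <- sqrt(d[ok])
  C <- fim[ok, ok, drop = FALSE] / outer(Dm, Dm)
  Ci <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Ci)) return(out)
  v <- diag(Ci) / d[ok]
  out[ok] <- sqrt(pmax(v, 0))
  out
}

#' @rdname fisher_matrix
#' @param fr A `fisher_result`.
#' @export
crb <- function(fr) {
  stopifnot(inherits(fr, "fisher_result"))
  fr$crb
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("<fisher_result: %s, parameters %s>\n", x$method,
              paste(x$params, collapse = ", ")))
  cat("  CRB standard deviations:\n")
  print(signif(x$crb, 5))
  invisible(x)
}

#' Single-emitter localization precision sigma_psf
#'
#' \eqn{\sigma_\mathrm{psf} = \sqrt{\sigma_{x_0}\sigma_{y_0}}}, the
#' geometric-mean centroid Cramer-Rao bound of a single freely rotating
#' dipole under direct detection at one expected signal photon and zero
#' background. It is the natural length unit of all separation results:
#' separations are quoted in units of \eqn{\sigma_\mathrm{psf}} and
#' precisions normalized by it. The DD PSF of a freely rotating dipole
#' is circularly symmetric, so \eqn{\sigma_{x_0} = \sigma_{y_0}} (the
#' function checks agreement to 0.5%).
#'
#' Results are cached on the configuration within a session.
#'
#' @param cfg An [optical_config()] (or a [detection_model()], whose
#'   configuration is used).
#' @return \eqn{\sigma_\mathrm{psf}} in nm.
#' @export
sigma_psf <- function(cfg) {
  if (inherits(cfg, "detection_model")) cfg <- cfg$config
  key <- paste(deparse(unclass(cfg)), collapse = "")
  hit <- sigma_psf_cache[[key]]
  if (!is.null(hit)) return(hit)
  mod <- detection_model(cfg, "DD")
  theta <- emitter_pair(d = 0, s = 1, b = 0)
  # rough length scale for the finite-difference step
  scale0 <- if (cfg$model == "gaussian") cfg$sigma else
    0.2 * cfg$emission_wavelength / cfg$numerical_aperture
  fx <- fisher_matrix(mod, theta, "x0", sigma_psf = scale0)
  fy <- fisher_matrix(mod, theta, "y0", sigma_psf = scale0)
  sx <- 1 / sqrt(fx$fim[1, 1])
  sy <- 1 / sqrt(fy$fim[1, 1])
  if (abs(sx / sy - 1) > 0.005) {
    warning(sprintf("sigma_x0 and sigma_y0 differ by %.2f%%",
                    100 * abs(sx / sy - 1)))
  }
  val <- sqrt(sx * sy)
  sigma_psf_cache[[key]] <- val
  val
}

sigma_psf_cache <- new.env(parent = emptyenv())

#' Signal-to-background ratio
#'
#' \eqn{\mathrm{SBR} = s / (A\, b)} with the reference area `A` in units
#' of \eqn{\sigma_\mathrm{psf}^2} (default 10, covering the bulk of the
#' PSF) and `b` in photons per \eqn{\sigma_\mathrm{psf}^2}. Because both
#' `b` and `A` are expressed in PSF units, the SBR is independent of the
#' camera pixel size.
#'
#' @param theta An [emitter_pair()] (or a list with `s` and `b`).
#' @param area Reference area in units of \eqn{\sigma_\mathrm{psf}^2}.
#' @return Dimensionless SBR; `Inf` when `b = 0`.
#' @examples
#' sbr(emitter_pair(d = 0, s = 10000, b = 10))   # 100
#' @export
sbr <- function(theta, area = 10) {
  if (theta$b <= 0) return(Inf)
  theta$s / (area * theta$b)
}
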