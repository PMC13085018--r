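# Shared fixtures: small grids for unit tests, full study settings for
# the acceptance checks. Expensive objects are cached for the run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# small grids: fast, adequate for structural/property checks
tiny_cfg <- function(...) {
  args <- utils::modifyList(list(pupil_grid_n = 65, image_size = 64),
                            list(...))
  do.call(optical_config, args)
}

# full study settings: emission 680 nm, NA 1.45, watery sample under oil
study_cfg <- function(...) {
  args <- utils::modifyList(list(emission_wavelength = 680,
                                 numerical_aperture = 1.45,
                                 n_medium = 1.33), list(...))
  do.call(optical_config, args)
}

grid_inv <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]

# brute-force QFI on the full discretized pupil (no subspace): builds the
# six generating states as dense vectors, assembles rho and drho as full
# matrices and evaluates the eigenpair sum directly. Independent oracle
# for the reduced-subspace computation.
dense_qfi <- function(cfg, d, alpha = 0) {
  pb <- dipolesep:::pupil_basis(cfg)
  gs <- dipolesep:::qfi_generators(pb, d, alpha)
  w <- sqrt(gs$dk2)
  vec <- function(g) c(as.vector(g[[1]]), as.vector(g[[2]])) * w
  rho <- 0; drho <- 0
  for (j in pb$orientations) {
    v1 <- vec(gs$gens[[paste0("p1", j)]]); v2 <- vec(gs$gens[[paste0("p2", j)]])
    w1 <- vec(gs$gens[[paste0("d1", j)]]); w2 <- vec(gs$gens[[paste0("d2", j)]])
    rho <- rho + 0.5 * (v1 %*% Conj(t(v1)) + v2 %*% Conj(t(v2)))
    drho <- drho + 0.5 * (w1 %*% Conj(t(v1)) + v1 %*% Conj(t(w1)) +
                          w2 %*% Conj(t(v2)) + v2 %*% Conj(t(w2)))
  }
  rho <- (rho + Conj(t(rho))) / 2
  drho <- (drho + Conj(t(drho))) / 2
  er <- eigen(rho, symmetric = TRUE)
  lam <- Re(er$values)
  M <- Conj(t(er$vectors)) %*% drho %*% er$vectors
  K <- 0
  cutoff <- 1e-12 * max(lam)
  for (i in seq_along(lam)) for (j in seq_along(lam)) {
    den <- lam[i] + lam[j]
    if (den > cutoff) K <- K + 2 * Mod(M[i, j])^2 / den
  }
  Re(K)
}
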