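# Fisher/CRB machinery on small grids. sigma_psf for the tiny
# configuration is computed once and shared.

tiny_sp <- function() cached("tiny_sp", sigma_psf(tiny_cfg()))

test_that("two-emitter model reduces correctly at coincidence and swaps", {
  mod <- cached("tiny_dd", detection_model(tiny_cfg(), "DD"))
  sp <- tiny_sp()
  one <- method_psf(mod)$channels$DD
  img0 <- two_emitter_image(mod, emitter_pair(d = 0, s = 7), sigma_psf = sp)
  expect_equal(img0$DD, 7 * one, tolerance = 1e-12)
  # emitter swap (alpha -> alpha + pi) leaves the image unchanged
  a <- two_emitter_image(mod, emitter_pair(d = 300, alpha = 0.4, s = 2),
                         sigma_psf = sp)
  b <- two_emitter_image(mod, emitter_pair(d = 300, alpha = 0.4 + pi, s = 2),
                         sigma_psf = sp)
  expect_equal(a$DD, b$DD, tolerance = 1e-10)
})

test_that("expected counts decompose into signal and uniform background", {
  mod <- cached("tiny_dd", detection_model(tiny_cfg(), "DD"))
  sp <- tiny_sp()
  th <- emitter_pair(d = 200, s = 1000, b = 5)
  img <- two_emitter_image(mod, th, sigma_psf = sp)
  bpx <- 5 * (mod$config$pixel_size / sp)^2
  sig <- two_emitter_image(mod, emitter_pair(d = 200, s = 1000), sigma_psf = sp)
  expect_equal(img$DD, sig$DD + bpx, tolerance = 1e-12)
  npx <- mod$config$image_size^2
  expect_equal(sum(img$DD), sum(sig$DD) + bpx * npx, tolerance = 1e-9)
})

test_that("Fisher information is additive over channels and scales with s", {
  mod <- cached("tiny_ps", detection_model(tiny_cfg(), "PolarSLIVER"))
  sp <- tiny_sp()
  th <- emitter_pair(d = 0.5 * sp, s = 1)
  fr <- fisher_matrix(mod, th, c("d", "x0"), sigma_psf = sp)
  expect_equal(Reduce(`+`, fr$per_channel_fi), fr$fim, tolerance = 1e-12)
  expect_true(all(diag(fr$fim) >= 0))
  expect_equal(fr$fim, t(fr$fim))
  # Poisson FI is linear in the photon budget: sigma ~ 1/sqrt(s)
  fr1 <- fisher_matrix(mod, th, "d", sigma_psf = sp)
  fr100 <- fisher_matrix(mod, emitter_pair(d = 0.5 * sp, s = 100), "d",
                         sigma_psf = sp)
  expect_equal(fr100$fim[1, 1], 100 * fr1$fim[1, 1], tolerance = 1e-6)
  expect_equal(crb(fr100)[["d"]], crb(fr1)[["d"]] / 10, tolerance = 1e-6)
})

test_that("one-parameter separation CRB never exceeds the full-parameter CRB", {
  mod <- cached("tiny_ps", detection_model(tiny_cfg(), "PolarSLIVER"))
  sp <- tiny_sp()
  for (du in c(0.05, 0.7, 4)) {
    th <- emitter_pair(d = du * sp, s = 1, b = 0)
    f1 <- fisher_matrix(mod, th, "d", sigma_psf = sp)
    f6 <- fisher_matrix(mod, th, c("d", "alpha", "x0", "y0", "s", "b"),
                        sigma_psf = sp)
    expect_lte(crb(f1)[["d"]], crb(f6)[["d"]] * (1 + 1e-9))
  }
})

test_that("Fisher matrix matches the Monte-Carlo likelihood-curvature oracle", {
  # small Gaussian toy model: 8 x 8 pixels, background regularized
  gcfg <- gaussian_config(sigma = 100, pixel_size = 100, image_size = 8,
                          pupil_grid_n = 65, subpixel_oversampling = 2)
  mod <- detection_model(gcfg, "DD")
  th <- emitter_pair(d = 150, s = 60, b = 1)
  fr <- fisher_matrix(mod, th, c("d", "s"), sigma_psf = 100)
  mu <- two_emitter_image(mod, th, sigma_psf = 100)$DD
  # derivative of the expected image for the score, via the same steps
  h <- 0.1
  mup <- two_emitter_image(mod, emitter_pair(d = 150 + h, s = 60, b = 1),
                           sigma_psf = 100)$DD
  mum <- two_emitter_image(mod, emitter_pair(d = 150 - h, s = 60, b = 1),
                           sigma_psf = 100)$DD
  dmu <- (mup - mum) / (2 * h)
  set.seed(42)
  nrep <- 1e5
  counts <- matrix(rpois(64 * nrep, rep(as.vector(mu), nrep)), 64, nrep)
  scores <- crossprod(counts / as.vector(mu) - 1, as.vector(dmu))
  expect_equal(var(as.vector(scores)), fr$fim["d", "d"], tolerance = 0.03)
})

test_that("sigma_psf is isotropic and shrinks with NA", {
  cfg <- tiny_cfg()
  mod <- detection_model(cfg, "DD")
  th <- emitter_pair(d = 0, s = 1, b = 0)
  sx <- 1 / sqrt(fisher_matrix(mod, th, "x0", sigma_psf = 150)$fim[1, 1])
  sy <- 1 / sqrt(fisher_matrix(mod, th, "y0", sigma_psf = 150)$fim[1, 1])
  expect_equal(sx / sy, 1, tolerance = 0.005)
  # with a matched index stack sigma_psf shrinks monotonically with NA;
  # under index mismatch the supercritical halo beyond NA = n_medium
  # broadens the DD PSF and costs localization precision
  sps <- vapply(c(0.7, 1.1, 1.45), function(na)
    sigma_psf(tiny_cfg(numerical_aperture = na, n_medium = 1.516)), 0)
  expect_true(all(diff(sps) < 0))
  expect_gt(sigma_psf(tiny_cfg(numerical_aperture = 1.45)), sps[3])
  # sigma scales as 1/sqrt(s)
  s25 <- 1 / sqrt(fisher_matrix(mod, emitter_pair(d = 0, s = 25), "x0",
                                sigma_psf = 150)$fim[1, 1])
  expect_equal(s25, sx / 5, tolerance = 1e-6)
})

test_that("the empty-pixel floor does not move any reported bound", {
  mod <- cached("tiny_ps", detection_model(tiny_cfg(), "PolarSLIVER"))
  sp <- tiny_sp()
  th <- emitter_pair(d = 0.05 * sp, s = 1, b = 0)
  a <- crb(fisher_matrix(mod, th, "d", sigma_psf = sp, eps = 1e-12))[["d"]]
  b <- crb(fisher_matrix(mod, th, "d", sigma_psf = sp, eps = 1e-15))[["d"]]
  expect_lt(abs(a / b - 1), 1e-3)
})

test_that("misalignment degrades Polar-SLIVER but not direct detection", {
  sp <- tiny_sp()
  dd <- cached("tiny_dd", detection_model(tiny_cfg(), "DD"))
  ps <- cached("tiny_ps", detection_model(tiny_cfg(), "PolarSLIVER"))
  d0 <- 0.02 * sp
  sd_dd0 <- crb(fisher_matrix(dd, emitter_pair(d = d0), "d", sigma_psf = sp))[["d"]]
  sd_dd1 <- crb(fisher_matrix(dd, emitter_pair(d = d0, x0 = 0.1 * sp), "d",
                              sigma_psf = sp))[["d"]]
  expect_equal(sd_dd1 / sd_dd0, 1, tolerance = 1e-3)
  sd_ps0 <- crb(fisher_matrix(ps, emitter_pair(d = d0), "d", sigma_psf = sp))[["d"]]
  sd_ps1 <- crb(fisher_matrix(ps, emitter_pair(d = d0, x0 = 0.1 * sp), "d",
                              sigma_psf = sp))[["d"]]
  expect_gt(sd_ps1 / sd_ps0, 2)
})

test_that("signal-to-background ratio follows s/(A b)", {
  expect_equal(sbr(emitter_pair(d = 0, s = 10000, b = 10)), 100)
  expect_equal(sbr(emitter_pair(d = 0, s = 10000, b = 20)), 50)
  expect_identical(sbr(emitter_pair(d = 0, s = 100, b = 0)), Inf)
  expect_equal(sbr(emitter_pair(d = 0, s = 500, b = 1), area = 5), 100)
})
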