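test_that("dilute uncorrelated limit reduces to independent scattering", {
  asm <- assembly_spec(anisotropic_sphere(305, 1.96), 1e-4,
                       sq = "none", host = "medium")
  mf <- mean_free_paths(asm, 550)
  or <- oracle_mie(size_parameter(305, 550, 1.33), 1.96 / 1.33)
  sigma <- or$Q_sca * pi * (305 / 2)^2
  rho <- 1e-4 / (pi / 6 * 305^3)
  expect_equal(mf$l_s, 1 / (rho * sigma), tolerance = 1e-6)
  expect_gt(mf$l_t, mf$l_s)        # forward-peaked scattering
})

test_that("mean free paths scale inversely with density at fixed S(q)", {
  sq1 <- function(q) rep(1, length(q))
  a1 <- assembly_spec(anisotropic_sphere(305, 1.96), 0.10,
                      sq = sq1, host = "medium")
  a2 <- assembly_spec(anisotropic_sphere(305, 1.96), 0.05,
                      sq = sq1, host = "medium")
  m1 <- mean_free_paths(a1, 550); m2 <- mean_free_paths(a2, 550)
  expect_equal(m2$l_s / m1$l_s, 2, tolerance = 1e-10)
  expect_equal(m2$l_t / m1$l_t, 2, tolerance = 1e-10)
})

test_that("angular quadrature agrees with a brute-force fine grid", {
  asm <- assembly_spec(anisotropic_sphere(305, 1.96), 0.50)
  mf <- mean_free_paths(asm, 550)
  ## brute force: trapezoid over 20,001 angles, same physics
  nh <- spherulite:::effective_host_index(anisotropic_sphere(305, 1.96),
                                          0.50, 1.33)
  k <- 2 * pi * nh / 550
  th <- seq(0, pi, length.out = 20001)
  am <- scattering_amplitudes(anisotropic_sphere(305, 1.96),
                              optical_context(550, nh), th)
  dsig <- (Mod(am$S1)^2 + Mod(am$S2)^2) / (2 * k^2)
  S <- py_structure_factor(0.50, 305, 2 * k * sin(th / 2))$S
  rho <- 0.50 / (pi / 6 * 305^3)
  f <- dsig * S * sin(th)
  inv_ls <- rho * 2 * pi * sum((f[-1] + f[-length(f)]) / 2 * diff(th))
  f2 <- f * (1 - cos(th))
  inv_lt <- rho * 2 * pi * sum((f2[-1] + f2[-length(f2)]) / 2 * diff(th))
  expect_equal(mf$l_s, 1 / inv_ls, tolerance = 1e-4)
  expect_equal(mf$l_t, 1 / inv_lt, tolerance = 1e-4)
  ## quadrature self-convergence
  mf2 <- mean_free_paths(asm, 550, n_theta = 256L)
  expect_equal(mf$l_t, mf2$l_t, tolerance = 1e-6)
})

test_that("diffusion slab reflectance has its closed-form anchors", {
  expect_equal(slab_reflectance(1000, 1000), 2 / 7)   # L = l_t
  L <- 5000
  lts <- c(100, 500, 2000)
  R <- slab_reflectance(lts, L)
  expect_true(all(R >= 0 & R <= 1))
  expect_true(all(diff(R) < 0))            # weaker scattering, less R
  Ls <- c(1000, 5000, 2e4, 1e6)
  RL <- vapply(Ls, function(LL) slab_reflectance(500, LL), numeric(1))
  expect_true(all(diff(RL) > 0))           # monotone in thickness
  expect_gt(RL[4], 0.999)                  # thick non-absorbing: R -> 1
  expect_equal(slab_reflectance(Inf, 5000), 0)  # no scattering at all
  expect_error(slab_reflectance(500, -1), "positive")
})

test_that("zero-contrast assemblies reflect nothing", {
  asm <- assembly_spec(anisotropic_sphere(305, 1.33, 1.33), 0.5,
                       host = "medium")
  tr <- reflectance_spectrum(asm, wavelengths = seq(400, 700, 100))
  expect_true(all(tr$R == 0))
})

test_that("structural correlations shape the reflectance spectrum", {
  ## isotropic n = 1.96 at phi = 0.5 with the coordinate S(q): the
  ## near-monodisperse packing imprints a visible-band structural
  ## feature which 10% polydispersity dampens.  In the saturating
  ## diffusion observable the ~500 nm structural peak appears as a
  ## plateau (slope through zero) on the declining R(lambda) background.
  lam <- seq(400, 700, 5)
  curves <- lapply(c(1, 31), function(cv) {
    cfg <- if (cv == 1) glass_cv03_050() else glass_cv10_050()
    sk <- structure_factor_from_config(cfg, q_max = 0.08)
    sq_fun <- approxfun(sk$q, sk$S, yleft = sk$S[1], yright = 1, rule = 2)
    asm <- assembly_spec(anisotropic_sphere(305, 1.96),
                         measure_filling_fraction(cfg),
                         sigma1 = ifelse(cv == 1, 0, 31), sq = sq_fun)
    reflectance_spectrum(asm, wavelengths = lam)$R
  })
  for (R in curves) {
    expect_true(all(R >= 0 & R <= 1))
    expect_true(all(is.finite(R)))
  }
  ## structural plateau of the low-polydispersity assembly in 450-550 nm
  mid <- lam >= 430 & lam <= 670
  slope03 <- diff(curves[[1]]) / diff(lam)
  lam_mid <- lam[-1][mid[-1]]
  flat_at <- lam_mid[which.min(abs(slope03[mid[-1]]))]
  expect_gte(flat_at, 450); expect_lte(flat_at, 550)
  ## dampening: residual structure (departure from a smooth quadratic
  ## baseline) shrinks when polydispersity rises to 10%
  rough <- vapply(curves, function(R) {
    fit <- lm(R ~ poly(lam, 2))
    sd(residuals(fit))
  }, numeric(1))
  expect_lt(rough[2], rough[1])
})

test_that("birefringence outperforms both isotropic variants at high fill", {
  parts <- list(biref = anisotropic_sphere(305, 1.96, 1.40),
                iso96 = anisotropic_sphere(305, 1.96),
                iso74 = anisotropic_sphere(305, 1.74))
  for (phi in c(0.50, 0.60)) {
    rv <- vapply(parts, function(p)
      reflectance_spectrum(assembly_spec(p, phi, sigma1 = 31),
                           wavelengths = seq(400, 700, 20))$R_vis,
      numeric(1))
    expect_gt(rv[["biref"]], rv[["iso96"]])
    expect_gt(rv[["iso96"]], rv[["iso74"]])
  }
})

test_that("single-point sweep grid returns that point as the argmax", {
  sw <- fill_fraction_sweep(list(iso = anisotropic_sphere(305, 1.96)),
                            phi_grid = 0.30,
                            wavelengths = seq(450, 650, 50))
  expect_equal(sw$summary$argmax_phi, 0.30)
  expect_equal(sw$summary$phi_within_10pct, 0.30)
  expect_error(fill_fraction_sweep(list(a = anisotropic_sphere(305, 1.9)),
                                   phi_grid = 0.75), "0.70")
})
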