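test_that("zero-contrast sphere scatters nothing", {
  ctx <- optical_context(500, 1.33)
  co <- mie_coefficients(anisotropic_sphere(305, 1.33, 1.33), ctx)
  expect_true(all(Mod(co$a) == 0) && all(Mod(co$b) == 0))
  sp <- scattering_efficiency(anisotropic_sphere(305, 1.33, 1.33),
                              seq(400, 900, 50))
  expect_true(all(sp$Q_sca == 0))
})

test_that("isotropic limit matches the independent Mie oracle", {
  for (d in c(100, 305, 600)) for (lam in c(400, 650, 900))
    for (n_iso in c(1.40, 1.96)) {
      ctx <- optical_context(lam, 1.33)
      co <- mie_coefficients(anisotropic_sphere(d, n_iso, n_iso), ctx)
      or <- oracle_mie(co$x, n_iso / 1.33, co$l_max)
      nn <- seq_len(co$l_max)
      q_pkg <- sum(2 / co$x^2 * (2 * nn + 1) * (Mod(co$a)^2 + Mod(co$b)^2))
      expect_lt(abs(q_pkg - or$Q_sca) / or$Q_sca, 1e-8)
      ## coefficient-level agreement where the coefficients carry weight
      big <- Mod(or$a) > 1e-4 * max(Mod(or$a))
      expect_lt(max(Mod(co$a - or$a)[big] / Mod(or$a)[big]), 1e-8)
      big <- Mod(or$b) > 1e-4 * max(Mod(or$b))
      expect_lt(max(Mod(co$b - or$b)[big] / Mod(or$b)[big]), 1e-8)
    }
})

test_that("effective fractional order follows the anisotropy formula", {
  co <- mie_coefficients(anisotropic_sphere(305, 1.96, 1.40),
                         optical_context(500))
  expect_equal(co$nu[2], -0.5 + sqrt(0.25 + 6 * (1.96 / 1.40)^2),
               tolerance = 1e-12)
  ## reduces to the integer orders when isotropic
  co_iso <- mie_coefficients(anisotropic_sphere(305, 1.96, 1.96),
                             optical_context(500))
  expect_equal(co_iso$nu, as.numeric(seq_len(co_iso$l_max)))
})

test_that("anisotropic dipole term reproduces the exact static limit", {
  ## a_1 -> -(2i/3) x^3 (nu1 eps_r - eps_m) / (nu1 eps_r + 2 eps_m)
  for (nr in c(1.40, 1.52, 1.60)) {
    co <- mie_coefficients(anisotropic_sphere(2, 1.87, nr),
                           optical_context(5e4, 1.33), 2)
    s <- -0.5 + sqrt(0.25 + 2 * (1.87 / nr)^2)
    pred <- (s * nr^2 - 1.33^2) / (s * nr^2 + 2 * 1.33^2)
    expect_equal(Im(co$a[1]) * (-3 / (2 * co$x^3)), pred, tolerance = 1e-5)
  }
})

test_that("per-multipole channels sum exactly to the total", {
  sp <- scattering_efficiency(anisotropic_sphere(305, 1.96, 1.40),
                              seq(400, 900, 10), per_multipole = TRUE)
  expect_lt(max(abs(rowSums(sp$per_multipole) - sp$Q_sca) / sp$Q_sca), 1e-10)
  expect_true(all(sp$Q_sca >= 0))
})

test_that("amplitudes integrate back to Q_sca and obey the optical theorem", {
  sph <- anisotropic_sphere(305, 1.96, 1.40)
  ctx <- optical_context(500)
  co <- mie_coefficients(sph, ctx)
  nn <- seq_len(co$l_max)
  q_direct <- sum(2 / co$x^2 * (2 * nn + 1) * (Mod(co$a)^2 + Mod(co$b)^2))
  gl <- pracma::gaussLegendre(200, -1, 1)
  th <- sort(acos(gl$x)); w <- gl$w[order(acos(gl$x))]
  am <- scattering_amplitudes(sph, ctx, th)
  q_int <- sum(w * (Mod(am$S1)^2 + Mod(am$S2)^2)) / co$x^2
  expect_lt(abs(q_int - q_direct) / q_direct, 1e-4)
  ## non-absorbing: extinction from the forward amplitude equals Q_sca
  fwd <- scattering_amplitudes(sph, ctx, 0)
  q_ext <- 4 / co$x^2 * Re(fwd$S1)
  expect_lt(abs(q_ext - q_direct) / q_direct, 1e-4)
  ## endpoint angles are finite and S1 = S2 at 0 and pi up to sign
  ends <- scattering_amplitudes(sph, ctx, c(0, pi))
  expect_true(all(is.finite(c(Mod(ends$S1), Mod(ends$S2)))))
  ## isotropic amplitudes match the oracle at a generic angle
  iso <- anisotropic_sphere(305, 1.96)
  am2 <- scattering_amplitudes(iso, ctx, 0.6458)
  oa <- oracle_amplitudes(size_parameter(305, 500, 1.33), 1.96 / 1.33, 0.6458)
  expect_lt(Mod(am2$S1 - oa$S1) / Mod(oa$S1), 1e-8)
  expect_lt(Mod(am2$S2 - oa$S2) / Mod(oa$S2), 1e-8)
})

test_that("default truncation order is adequate and monotone", {
  x <- c(0.01, 0.5, 2, 5, 20)
  lm <- default_l_max(x)
  expect_true(all(lm >= 3))
  expect_true(all(diff(lm) >= 0))
  ## doubling l_max does not change Q_sca
  sph <- anisotropic_sphere(305, 1.96, 1.96)
  x0 <- size_parameter(305, 400, 1.33)
  q1 <- scattering_efficiency(sph, 400, l_max = default_l_max(x0))$Q_sca
  q2 <- scattering_efficiency(sph, 400, l_max = 2L * default_l_max(x0))$Q_sca
  expect_lt(abs(q1 - q2) / q1, 1e-8)
})

test_that("Q_sca is continuous across the isotropic point", {
  lam <- seq(400, 700, 20)
  q0 <- scattering_efficiency(anisotropic_sphere(305, 1.8, 1.8), lam)$Q_sca
  for (eps in c(1e-4, 1e-6)) {
    qp <- scattering_efficiency(anisotropic_sphere(305, 1.8, 1.8 + eps), lam)$Q_sca
    expect_lt(max(abs(qp - q0) / q0), 50 * eps)
  }
})

test_that("TE2+TE3 dominate the visible band for the measured particle", {
  ## the single-particle study size (430 nm), whose TE2/TE3 are both in
  ## the visible window
  sp <- scattering_efficiency(anisotropic_sphere(430, 1.96, 1.40),
                              seq(400, 700, 5), per_multipole = TRUE)
  band <- colSums(sp$per_multipole)
  te23 <- band["TE2"] + band["TE3"]
  others <- band[!names(band) %in% c("TE2", "TE3")]
  expect_true(all(te23 > others))
})

test_that("invalid optical inputs are rejected", {
  expect_error(anisotropic_sphere(-1, 1.9), "positive")
  expect_error(anisotropic_sphere(300, 0.9), ">= 1")
  expect_error(optical_context(-5), "positive")
  expect_error(scattering_efficiency(anisotropic_sphere(305, 1.9),
                                     numeric(0)), "empty")
  expect_error(scattering_efficiency(anisotropic_sphere(305, 1.9),
                                     c(500, 450)), "increasing")
  expect_error(scattering_amplitudes(anisotropic_sphere(305, 1.9),
                                     optical_context(500), -0.1), "angle")
})
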