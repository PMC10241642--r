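test_that("log-normal parameter map matches the closed forms", {
  lp <- lognormal_params(305, 0)
  expect_equal(lp$mu2, log(305))
  expect_equal(lp$sigma2_sq, 0)
  lp31 <- lognormal_params(305, 31)
  expect_equal(lp31$mu2, 5.71517305, tolerance = 1e-8)
  expect_equal(lp31$sigma2_sq, 0.0102775608, tolerance = 1e-7)
  ## independent re-evaluation at sigma1 = 50
  lp50 <- lognormal_params(305, 50)
  expect_equal(lp50$mu2, log(305^2 / sqrt(305^2 + 50^2)), tolerance = 1e-12)
  expect_equal(lp50$sigma2_sq, log(1 + 50^2 / 305^2), tolerance = 1e-12)
  ## the resulting distribution reproduces the arithmetic moments
  expect_equal(exp(lp50$mu2 + lp50$sigma2_sq / 2), 305, tolerance = 1e-10)
})

test_that("diameter sampling is clipped, seeded and has the right spread", {
  r <- glass_recipe(seed = 5)
  expect_identical(sample_diameters(r, 100), sample_diameters(r, 100))
  r0 <- glass_recipe(sigma1 = 0)
  expect_true(all(sample_diameters(r0, 50) == 305))
  d <- sample_diameters(glass_recipe(sigma1 = 31, seed = 2), 1e5)
  cv <- 100 * sd(d) / mean(d)
  expect_lt(abs(cv - 10.2), 0.3)
  expect_true(all(d >= 100 & d <= 600))
  ## with sigma1 = 50 the pre-clip tail mass is tiny and clipping keeps
  ## every draw inside the bounds
  lp <- lognormal_params(305, 50)
  tail_mass <- plnorm(100, lp$mu2, sqrt(lp$sigma2_sq)) +
    plnorm(600, lp$mu2, sqrt(lp$sigma2_sq), lower.tail = FALSE)
  expect_lt(tail_mass, 2e-5)   # direct plnorm evaluation: ~1.04e-5
  d50 <- sample_diameters(glass_recipe(sigma1 = 50, seed = 3), 1e4)
  expect_true(all(d50 >= 100 & d50 <= 600))
})

test_that("smoothed 12-0 potential vanishes smoothly at the cutoff", {
  pp <- pair_potential_params()
  ## independent check of the C_k: the linear conditions themselves
  xc <- 1.5
  v_at <- function(x) (x^-12 - 1) + pp$C[1] + pp$C[2] * x^2 + pp$C[3] * x^4
  expect_equal(v_at(xc), 0, tolerance = 1e-12)
  h <- 1e-5
  expect_equal((v_at(xc + 0) - v_at(xc - h)) / h, 0, tolerance = 1e-3)
  expect_equal((v_at(xc - 2 * h) - 2 * v_at(xc - h) + v_at(xc)) / h^2, 0,
               tolerance = 1e-2)
  ## energy at contact r = sigma_ij is exactly sum(C_k)
  pe <- pair_energy(305, 305, 305, pp)
  expect_equal(pe$energy, sum(pp$C), tolerance = 1e-12)
  expect_equal(pe$sigma_ij, 305)         # equal diameters: no nonadditivity
  ## zero beyond the cutoff, repulsive inside, singular at r = 0
  far <- pair_energy(1.6 * 305, 305, 305, pp)
  expect_equal(far$energy, 0)
  expect_equal(far$force, 0)
  inside <- pair_energy(seq(250, 450, 10), 305, 305, pp)
  expect_true(all(inside$energy >= 0) && all(inside$force >= 0))
  expect_error(pair_energy(0, 305, 305, pp), "positive")
})

test_that("nonadditive cross diameter shrinks mixed pairs", {
  pp <- pair_potential_params()
  pe <- pair_energy(300, 200, 400, pp, eps_nonadd = 0.01, mu1 = 305)
  expect_equal(pe$sigma_ij, 0.5 * 600 * (1 - 0.01 * 200 / 305))
  expect_lt(pe$sigma_ij, 300)
})

test_that("two distant particles relax to zero energy", {
  r <- glass_recipe(n_particles = 2, sigma1 = 0, target_fill = 1e-4,
                    quench_steps = 2000, seed = 1)
  cfg <- generate_packing(r)
  expect_equal(tail(cfg$energy_trace$pe_per_particle, 1), 0)
})

test_that("desk-scale quench hits the target fill without deep overlaps", {
  cfg <- glass_cv10_050()
  expect_equal(measure_filling_fraction(cfg), 0.50, tolerance = 0.005 / 0.5)
  pos <- cfg$positions; L <- cfg$box; n <- nrow(pos)
  worst <- Inf
  for (i in seq_len(n - 1)) {
    dx <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    dx <- dx - L * round(dx / L)
    rr <- sqrt(rowSums(dx^2))
    sij <- 0.5 * (cfg$diameters[(i + 1):n] + cfg$diameters[i]) *
      (1 - 0.01 * abs(cfg$diameters[(i + 1):n] - cfg$diameters[i]) / 305)
    worst <- min(worst, min(rr / sij))
  }
  expect_gt(worst, 0.8)
  ## energy decreases over the final fixed-box cooling stage
  tr <- cfg$energy_trace
  cool <- tr[tr$step > 0.9 * max(tr$step), ]
  expect_lt(tail(cool$pe_per_particle, 1), head(cool$pe_per_particle, 1))
  ## same recipe, same seed: bit-identical diameters and positions
  cfg2 <- generate_packing(glass_recipe(n_particles = 500, sigma1 = 31,
                                        target_fill = 0.50,
                                        quench_steps = 15000, seed = 42))
  expect_identical(cfg$diameters, cfg2$diameters)
  expect_identical(cfg$positions, cfg2$positions)
})

test_that("output diameters follow the clipped log-normal", {
  cfg <- glass_cv10_050()
  r <- glass_recipe(sigma1 = 31, seed = 999)
  ref <- sample_diameters(r, 1e4, seed = 999)
  ks <- suppressWarnings(ks.test(cfg$diameters, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("q6 separates crystals from the quenched glasses", {
  expect_equal(bond_order_q6(fcc_config()), 0.5745, tolerance = 1e-3)
  expect_equal(bond_order_q6(sc_config(), r_cut = 400), 0.3536,
               tolerance = 1e-3)
  expect_lt(bond_order_q6(glass_cv10_050()), 0.48)
})

test_that("infeasible recipes are refused", {
  expect_error(glass_recipe(target_fill = 0.73), "0.72|0.74")
  expect_error(glass_recipe(d_min = 400), "d_min")
})
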