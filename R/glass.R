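## Generation of polydisperse photonic-glass packings by a Langevin
## quench with a smoothed 12-0 soft-core pair potential:
##
##   v(r) = v0 [ (sigma_ij/r)^12 - 1 ] + sum_{k=0}^{2} C_k (r/sigma_ij)^{2k}
##   for r/sigma_ij <= x_c, zero beyond;
##   sigma_ij = (sigma_i + sigma_j)/2 * (1 - eps |sigma_i - sigma_j|),
##
## with the C_k fixed so that v, v' and v'' vanish at the cutoff (the
## potential is then purely repulsive and C2-continuous).  The
## nonadditivity term eps |sigma_i - sigma_j| is evaluated with diameters
## in units of the mean diameter, keeping the correction O(1e-3) and
## sigma_ij positive.  All internal dynamics run in reduced units
## (length = mean diameter mu1, energy = v0, unit mass).

#' Parameters of the log-normal diameter distribution
#'
#' Maps the arithmetic mean `mu1` and standard deviation `sigma1` of the
#' particle diameter to the parameters of the underlying normal:
#' `mu2 = log(mu1^2 / sqrt(mu1^2 + sigma1^2))`,
#' `sigma2^2 = log(1 + sigma1^2 / mu1^2)`.
#'
#' @param mu1 Mean diameter (nm), positive.
#' @param sigma1 Diameter standard deviation (nm), non-negative.
#' @return List with `mu2` (meanlog) and `sigma2_sq` (variance of the log).
#' @export
lognormal_params <- function(mu1, sigma1) {
  if (mu1 <= 0 || sigma1 < 0) stop("need mu1 > 0 and sigma1 >= 0")
  list(mu2 = log(mu1^2 / sqrt(mu1^2 + sigma1^2)),
       sigma2_sq = log(1 + sigma1^2 / mu1^2))
}

#' Recipe for a photonic-glass packing
#'
#' Full parameterization of the Langevin quench.  Defaults follow the
#' reference protocol (mean diameter 305 nm, clip bounds 100-600 nm,
#' kT = 0.05, v0 = 1, nonadditivity 0.01, dimensionless cutoff 1.5, box
#' squeezed by a factor 4 in edge length), at a desk scale of ~1,000
#' particles and 5e4 time steps; the recipe scales up unchanged.
#'
#' @param n_particles Number of particles.
#' @param mu1,sigma1 Mean and s.d. of the diameter distribution (nm).
#' @param d_min,d_max Clip bounds for sampled diameters (nm).
#' @param target_fill Target volume filling fraction in (0, 0.72).
#' @param quench_steps Total Langevin steps (squeeze + final cool).
#' @param kT Reduced temperature of the Langevin thermostat.
#' @param v0 Energy scale of the pair potential.
#' @param eps_nonadd Nonadditivity parameter of `sigma_ij`.
#' @param cutoff_x Dimensionless cutoff `x_c` applied to `r / sigma_ij`.
#' @param dt Reduced time step.
#' @param gamma Langevin friction (reduced units).
#' @param box_ratio Initial box edge over final box edge.
#' @param cool_frac Final fraction of steps run at fixed box with the
#'   thermostat ramped to zero (quench of the residual overlaps).
#' @param seed Integer seed controlling diameters, lattice and noise.
#' @return Object of class `glass_recipe`.
#' @export
glass_recipe <- function(n_particles = 1000, mu1 = 305, sigma1 = 31,
                         d_min = 100, d_max = 600, target_fill = 0.50,
                         quench_steps = 50000L, kT = 0.05, v0 = 1,
                         eps_nonadd = 0.01, cutoff_x = 1.5, dt = 0.005,
                         gamma = 1, box_ratio = 4, cool_frac = 0.1,
                         seed = 1L) {
  if (!(d_min > 0 && d_min < mu1 && mu1 < d_max))
    stop("need 0 < d_min < mu1 < d_max")
  if (target_fill <= 0 || target_fill >= 0.74)
    stop("'target_fill' must lie in (0, 0.74)")
  if (target_fill > 0.72)
    stop("target_fill > 0.72 is beyond random-packing feasibility")
  structure(list(n_particles = as.integer(n_particles), mu1 = mu1,
                 sigma1 = sigma1, d_min = d_min, d_max = d_max,
                 target_fill = target_fill,
                 quench_steps = as.integer(quench_steps), kT = kT, v0 = v0,
                 eps_nonadd = eps_nonadd, cutoff_x = cutoff_x, dt = dt,
                 gamma = gamma, box_ratio = box_ratio,
                 cool_frac = cool_frac, seed = as.integer(seed)),
            class = "glass_recipe")
}

#' Sample clipped log-normal particle diameters
#'
#' I.i.d. log-normal draws with the moments of the recipe, values outside
#' `[d_min, d_max]` rounded to the nearest boundary (clipped, not
#' resampled).
#'
#' @param recipe A [glass_recipe()].
#' @param n Number of draws (default `recipe$n_particles`).
#' @param seed Seed (default `recipe$seed`).
#' @return Numeric vector of diameters in nm.
#' @export
sample_diameters <- function(recipe, n = recipe$n_particles,
                             seed = recipe$seed) {
  lp <- lognormal_params(recipe$mu1, recipe$sigma1)
  set.seed(seed)
  if (lp$sigma2_sq == 0) return(rep(recipe$mu1, n))
  d <- stats::rlnorm(n, meanlog = lp$mu2, sdlog = sqrt(lp$sigma2_sq))
  pmin(pmax(d, recipe$d_min), recipe$d_max)
}

#' Smoothing coefficients and evaluation of the 12-0 pair potential
#'
#' `pair_potential_params()` solves the three linear conditions
#' `v(x_c) = v'(x_c) = v''(x_c) = 0` for `C_0, C_1, C_2`.
#'
#' @param v0 Energy scale.
#' @param cutoff_x Dimensionless cutoff.
#' @return List with `C` (length-3 coefficients), `v0`, `cutoff_x`.
#' @export
pair_potential_params <- function(v0 = 1, cutoff_x = 1.5) {
  xc <- cutoff_x
  ## p(x) = C0 + C1 x^2 + C2 x^4 must cancel f(x) = v0 (x^-12 - 1)
  ## and its first two derivatives at xc.
  A <- rbind(c(1, xc^2, xc^4),
             c(0, 2 * xc, 4 * xc^3),
             c(0, 2, 12 * xc^2))
  b <- c(-v0 * (xc^-12 - 1),
         12 * v0 * xc^-13,
         -156 * v0 * xc^-14)
  C <- solve(A, b)
  list(C = as.numeric(C), v0 = v0, cutoff_x = cutoff_x)
}

#' @rdname pair_potential_params
#' @param r Center-to-center distance (same units as the diameters).
#' @param sigma_i,sigma_j Diameters of the pair.
#' @param params Output of `pair_potential_params()`.
#' @param eps_nonadd Nonadditivity parameter.
#' @param mu1 Reference diameter in which the nonadditive size difference
#'   is expressed.
#' @return `pair_energy()`: list with `energy` and `force` (magnitude of
#'   the radial force, positive = repulsive), vectorized over `r`.
#' @export
pair_energy <- function(r, sigma_i, sigma_j,
                        params = pair_potential_params(),
                        eps_nonadd = 0.01, mu1 = 305) {
  if (any(r <= 0)) stop("pair distance must be positive")
  sij <- 0.5 * (sigma_i + sigma_j) *
    (1 - eps_nonadd * abs(sigma_i - sigma_j) / mu1)
  x <- r / sij
  C <- params$C
  inside <- x <= params$cutoff_x
  e <- f <- numeric(length(x))
  xi <- x[inside]
  e[inside] <- params$v0 * (xi^-12 - 1) + C[1] + C[2] * xi^2 + C[3] * xi^4
  dvdx <- -12 * params$v0 * xi^-13 + 2 * C[2] * xi + 4 * C[3] * xi^3
  f[inside] <- -dvdx / sij
  list(energy = e, force = f, sigma_ij = sij)
}

#' Generate a disordered packing by Langevin quench
#'
#' Starts from a simple cubic lattice in a large box, squeezes the box
#' linearly in edge length to the final volume under Langevin dynamics at
#' `kT`, then holds the box fixed for the last `cool_frac` of the steps
#' while ramping the thermostat to zero to relax residual overlaps.  The
#' final box edge is set from the sampled diameters so the filling
#' fraction equals `target_fill` exactly.
#'
#' @param recipe A [glass_recipe()].
#' @return Object of class `particle_configuration`: `box` (edge, nm),
#'   `positions` (N x 3, nm, wrapped), `diameters` (nm), `energy_trace`
#'   (data.frame of step, box edge, kT, potential energy per particle)
#'   and `provenance`.
#' @export
generate_packing <- function(recipe) {
  stopifnot(inherits(recipe, "glass_recipe"))
  d_nm <- sample_diameters(recipe)          # seeds the RNG stream
  final_box <- (sum(pi / 6 * d_nm^3) / recipe$target_fill)^(1 / 3)
  box1 <- final_box / recipe$mu1            # reduced units from here on
  box0 <- box1 * recipe$box_ratio
  n <- recipe$n_particles
  n_side <- ceiling(n^(1 / 3))
  g <- (expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                    z = seq_len(n_side)) - 0.5) / n_side
  pos0 <- as.matrix(g[seq_len(n), ]) * box0
  pp <- pair_potential_params(recipe$v0, recipe$cutoff_x)
  res <- md_quench_cpp(pos0, d_nm / recipe$mu1, box0, box1,
                       recipe$quench_steps, recipe$dt, recipe$kT,
                       recipe$gamma, recipe$v0, recipe$eps_nonadd,
                       recipe$cutoff_x, pp$C, recipe$cool_frac, 100L)
  if (!all(is.finite(res$positions)))
    stop("Langevin quench diverged (non-finite coordinates); ",
         "inspect the energy trace")
  structure(list(
    box = final_box,
    positions = res$positions * recipe$mu1,
    diameters = d_nm,
    energy_trace = data.frame(step = res$trace_step,
                              box = res$trace_box * recipe$mu1,
                              kT = res$trace_kT,
                              pe_per_particle = res$trace_pe / n),
    provenance = list(recipe = unclass(recipe), steps = recipe$quench_steps)),
    class = "particle_configuration")
}

#' @export
print.particle_configuration <- function(x, ...) {
  cat(sprintf("<particle_configuration> N = %d, box = %.1f nm, fill = %.3f\n",
              nrow(x$positions), x$box, measure_filling_fraction(x)))
  invisible(x)
}

#' Volume filling fraction of a configuration
#'
#' `phi = sum (pi/6) d_i^3 / V`; sphere overlaps are not deducted.
#'
#' @param config A `particle_configuration`.
#' @return Filling fraction (0 for an empty configuration).
#' @export
measure_filling_fraction <- function(config) {
  if (!length(config$diameters)) return(0)
  sum(pi / 6 * config$diameters^3) / config$box^3
}

#' Mean Steinhardt q6 bond-orientational order parameter
#'
#' Per-particle `q6` from the spherical-harmonic moments of the bond
#' directions to neighbours within `r_cut`, averaged over particles.
#' With a first-shell cutoff, close-packed crystals give ~0.57 (fcc;
#' 0.511 bcc, 0.354 sc) while the rapidly quenched soft-sphere glasses
#' produced here sit near 0.40-0.43; the package treats mean q6 < 0.48
#' as non-crystalline.
#'
#' @param config A `particle_configuration`.
#' @param r_cut Neighbour cutoff in nm; default 1.4 times the mean
#'   diameter, a bond-length scale for these soft packings.
#' @return Mean q6 over particles with at least one neighbour.
#' @export
bond_order_q6 <- function(config, r_cut = NULL) {
  if (is.null(r_cut)) r_cut <- 1.4 * mean(config$diameters)
  pos <- config$positions; L <- config$box; n <- nrow(pos)
  q6 <- rep(NA_real_, n)
  ## pairwise minimum-image displacements
  for (i in seq_len(n)) {
    dx <- sweep(pos, 2L, pos[i, ])
    dx <- dx - L * round(dx / L)
    r <- sqrt(rowSums(dx^2))
    nb <- which(r > 1e-9 & r <= r_cut)
    if (!length(nb)) next
    u <- dx[nb, , drop = FALSE] / r[nb]
    ct <- pmin(1, pmax(-1, u[, 3]))
    phi <- atan2(u[, 2], u[, 1])
    P <- pracma::legendre(6, ct)      # rows m = 0..6
    acc <- 0
    for (m in 0:6) {
      nf <- sqrt((2 * 6 + 1) / (4 * pi) *
                 factorial(6 - m) / factorial(6 + m))
      ylm <- nf * P[m + 1, ] * exp(1i * m * phi)
      qlm <- mean(ylm)
      acc <- acc + (if (m == 0) 1 else 2) * Mod(qlm)^2
    }
    q6[i] <- sqrt(4 * pi / 13 * acc)
  }
  mean(q6, na.rm = TRUE)
}
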