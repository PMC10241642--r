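## Mie scattering for a sphere with radially oriented uniaxial anisotropy.
##
## The TE (magnetic-type, b_n) partial waves only probe the tangential
## index and are the ordinary Mie coefficients evaluated with relative
## index m_t.  The TM (electric-type, a_n) partial waves see both indices:
## the internal radial dependence is a Riccati-Bessel function of
## fractional effective order
##   nu_n = -1/2 + sqrt(1/4 + n (n+1) (n_t/n_r)^2),
## which collapses to nu_n = n in the isotropic limit.  Bohren-Huffman
## sign conventions throughout; the isotropic limit is pinned against an
## independent Mie implementation in the test-suite.

## Riccati-Bessel psi_nu(z) = sqrt(pi z / 2) J_{nu + 1/2}(z), fractional
## order allowed.  Derivative via the upward identity
## psi'_nu(z) = (nu + 1)/z psi_nu(z) - psi_{nu+1}(z), which avoids
## negative orders.
ricbes_psi <- function(nu, z) {
  k <- max(length(nu), length(z))
  sqrt(pi * z / 2) * besselJ(rep_len(z, k), rep_len(nu, k) + 0.5)
}

ricbes_chi <- function(nu, z) {
  k <- max(length(nu), length(z))
  -sqrt(pi * z / 2) * besselY(rep_len(z, k), rep_len(nu, k) + 0.5)
}

ricbes_xi <- function(nu, z) {
  complex(real = ricbes_psi(nu, z), imaginary = -ricbes_chi(nu, z))
}

ricbes_psi_d <- function(nu, z) {
  (nu + 1) / z * ricbes_psi(nu, z) - ricbes_psi(nu + 1, z)
}

ricbes_xi_d <- function(nu, z) {
  (nu + 1) / z * ricbes_xi(nu, z) - ricbes_xi(nu + 1, z)
}

#' Truncation order for the Mie partial-wave series
#'
#' Wiscombe-style heuristic `ceil(x + 4.05 x^{1/3} + 2)`, floored at 3 so
#' that the quadrupole and octupole channels (TE2, TE3) are always
#' represented.
#'
#' @param x Size parameter (positive).
#' @return Integer truncation order, monotone non-decreasing in `x`.
#' @export
default_l_max <- function(x) {
  if (any(x <= 0)) stop("'x' must be positive")
  pmax(3L, as.integer(ceiling(x + 4.05 * x^(1/3) + 2)))
}

#' Mie coefficients of a radially anisotropic sphere
#'
#' Partial-wave coefficients `a_n` (TM/electric) and `b_n` (TE/magnetic)
#' for a non-absorbing sphere whose tangential and radial refractive
#' indices differ.  The isotropic case `n_t == n_r` reproduces ordinary
#' Mie theory.
#'
#' @param sphere An [anisotropic_sphere()].
#' @param ctx An [optical_context()] with a single wavelength.
#' @param l_max Truncation order; default from [default_l_max()].
#' @return A list of class `multipole_coefficients` with elements `a`, `b`
#'   (complex vectors indexed 1..l_max), `x` (size parameter), `m_t`,
#'   `m_r` (relative indices) and `nu` (effective fractional orders).
#' @export
mie_coefficients <- function(sphere, ctx, l_max = NULL) {
  stopifnot(inherits(sphere, "anisotropic_sphere"),
            inherits(ctx, "optical_context"))
  if (length(ctx$wavelength) != 1L)
    stop("mie_coefficients() needs a single-wavelength context")
  x <- size_parameter(sphere$diameter, ctx$wavelength, ctx$n_medium)
  if (is.null(l_max)) l_max <- default_l_max(x)
  if (l_max < 1) stop("'l_max' must be >= 1")
  n <- seq_len(l_max)
  m_t <- sphere$n_t / ctx$n_medium
  m_r <- sphere$n_r / ctx$n_medium
  nu <- -0.5 + sqrt(0.25 + n * (n + 1) * (sphere$n_t / sphere$n_r)^2)

  mx <- m_t * x
  psi_x   <- ricbes_psi(n, x)
  psi_x_d <- ricbes_psi_d(n, x)
  xi_x    <- ricbes_xi(n, x)
  xi_x_d  <- ricbes_xi_d(n, x)
  ## internal radial functions: fractional order for TM, integer for TE
  psi_nu   <- ricbes_psi(nu, mx)
  psi_nu_d <- ricbes_psi_d(nu, mx)
  psi_m    <- ricbes_psi(n, mx)
  psi_m_d  <- ricbes_psi_d(n, mx)

  vals <- c(psi_x, psi_x_d, psi_nu, psi_nu_d, psi_m, psi_m_d,
            Re(xi_x), Im(xi_x), Re(xi_x_d), Im(xi_x_d))
  if (any(!is.finite(vals)))
    stop(sprintf(paste0("non-finite Bessel evaluation at x = %.6g ",
                        "(l_max = %d); outside the numerical domain"),
                 x, l_max))

  a <- (m_t * psi_nu * psi_x_d - psi_x * psi_nu_d) /
       (m_t * psi_nu * xi_x_d  - xi_x  * psi_nu_d)
  b <- (psi_m * psi_x_d - m_t * psi_x * psi_m_d) /
       (psi_m * xi_x_d  - m_t * xi_x  * psi_m_d)

  structure(list(a = a, b = b, x = x, m_t = m_t, m_r = m_r, nu = nu,
                 l_max = l_max),
            class = "multipole_coefficients")
}

## Q_sca channel contributions from a coefficient set:
## (2/x^2) (2n+1) |c_n|^2 per channel.
channel_efficiencies <- function(coef) {
  n <- seq_len(coef$l_max)
  pref <- 2 / coef$x^2 * (2 * n + 1)
  list(TM = pref * Mod(coef$a)^2, TE = pref * Mod(coef$b)^2)
}

#' Scattering efficiency spectrum of an anisotropic sphere
#'
#' `Q_sca(lambda)` (scattering cross-section over geometric cross-section)
#' on a strictly increasing wavelength grid, optionally decomposed into
#' per-multipole channels (TE1, TM1, TE2, ...).
#'
#' @param sphere An [anisotropic_sphere()].
#' @param wavelengths Strictly increasing vacuum wavelengths in nm.
#' @param n_medium Host medium index (default 1.33).
#' @param l_max Optional fixed truncation order; default adapts per
#'   wavelength.
#' @param per_multipole Populate the per-channel decomposition?
#' @return An object of class `scattering_spectrum`: list with
#'   `wavelengths`, `Q_sca` and (optionally) `per_multipole`, a matrix
#'   with one column per channel whose rows sum to `Q_sca` exactly.
#' @export
scattering_efficiency <- function(sphere, wavelengths, n_medium = 1.33,
                                  l_max = NULL, per_multipole = FALSE) {
  if (length(wavelengths) == 0L) stop("empty wavelength grid")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  x_max <- size_parameter(sphere$diameter, min(wavelengths), n_medium)
  lm <- if (is.null(l_max)) default_l_max(x_max) else l_max
  q_tot <- numeric(length(wavelengths))
  chan <- if (per_multipole)
    matrix(0, length(wavelengths), 2L * lm) else NULL
  for (i in seq_along(wavelengths)) {
    co <- mie_coefficients(sphere, optical_context(wavelengths[i], n_medium),
                           l_max = lm)
    ce <- channel_efficiencies(co)
    if (per_multipole) chan[i, ] <- c(rbind(ce$TE, ce$TM))
    q_tot[i] <- sum(ce$TE) + sum(ce$TM)
  }
  out <- list(wavelengths = wavelengths, Q_sca = q_tot)
  if (per_multipole) {
    colnames(chan) <- paste0(rep(c("TE", "TM"), lm),
                             rep(seq_len(lm), each = 2))
    out$per_multipole <- chan
  }
  structure(out, class = "scattering_spectrum")
}

#' @export
print.scattering_spectrum <- function(x, ...) {
  cat(sprintf("<scattering_spectrum> %d wavelengths (%g-%g nm), peak Q_sca = %.3f\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              max(x$Q_sca)))
  invisible(x)
}

## Angular functions pi_n(mu), tau_n(mu) by the standard recurrence.
## Returns l_max-row matrices over the angle vector.
angular_functions <- function(mu, l_max) {
  p <- matrix(0, l_max, length(mu))
  t <- matrix(0, l_max, length(mu))
  p_prev <- 0        # pi_0
  p[1, ] <- 1        # pi_1
  t[1, ] <- mu
  if (l_max >= 2) {
    for (n in 2:l_max) {
      p[n, ] <- ((2 * n - 1) / (n - 1)) * mu * p[n - 1, ] -
        (n / (n - 1)) * (if (n == 2) p_prev else p[n - 2, ])
      t[n, ] <- n * mu * p[n, ] - (n + 1) * p[n - 1, ]
    }
  }
  list(pi = p, tau = t)
}

#' Scattering amplitudes S1, S2 at given angles
#'
#' Complex amplitudes of the two linear polarizations for scattering angle
#' theta; the unpolarized differential cross-section is
#' `(|S1|^2 + |S2|^2) / (2 k^2)` per steradian.
#'
#' @param sphere An [anisotropic_sphere()].
#' @param ctx Single-wavelength [optical_context()].
#' @param angle Scattering angles in radians, within `[0, pi]`.
#' @param coef Optional precomputed [mie_coefficients()].
#' @return List with complex vectors `S1`, `S2` and the coefficients used.
#' @export
scattering_amplitudes <- function(sphere, ctx, angle, coef = NULL) {
  if (any(angle < 0 | angle > pi)) stop("'angle' must lie in [0, pi]")
  if (is.null(coef)) coef <- mie_coefficients(sphere, ctx)
  mu <- cos(angle)
  ang <- angular_functions(mu, coef$l_max)
  n <- seq_len(coef$l_max)
  w <- (2 * n + 1) / (n * (n + 1))
  S1 <- as.vector(t(ang$pi) %*% (w * coef$a) + t(ang$tau) %*% (w * coef$b))
  S2 <- as.vector(t(ang$tau) %*% (w * coef$a) + t(ang$pi) %*% (w * coef$b))
  list(S1 = S1, S2 = S2, coef = coef)
}
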