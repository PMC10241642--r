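## Independent isotropic Mie implementation used as an oracle.
## Classic BHMIE scheme: logarithmic derivative by downward recurrence,
## Riccati-Bessel functions by upward recurrence.  Deliberately a
## different algorithm from the package's direct fractional-order Bessel
## evaluation.
oracle_mie <- function(x, m, nmax = NULL) {
  if (is.null(nmax)) nmax <- max(3L, as.integer(ceiling(x + 4.05 * x^(1/3) + 2)))
  mx <- m * x
  nstart <- max(nmax, ceiling(abs(mx))) + 16L
  D <- numeric(nstart + 1L)        # D[k] = D_{k}, D_{nstart} = 0
  for (k in nstart:1) D[k] <- (k + 1) / mx - 1 / (D[k + 1L] + (k + 1) / mx)
  psi_m1 <- cos(x); psi_0 <- sin(x)
  chi_m1 <- -sin(x); chi_0 <- cos(x)
  a <- complex(nmax); b <- complex(nmax)
  psi_prev <- psi_0; psi_pp <- psi_m1
  chi_prev <- chi_0; chi_pp <- chi_m1
  for (n in seq_len(nmax)) {
    psi_n <- (2 * n - 1) / x * psi_prev - psi_pp
    chi_n <- (2 * n - 1) / x * chi_prev - chi_pp
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_prev <- complex(real = psi_prev, imaginary = -chi_prev)
    fa <- D[n] / m + n / x
    fb <- D[n] * m + n / x
    a[n] <- (fa * psi_n - psi_prev) / (fa * xi_n - xi_prev)
    b[n] <- (fb * psi_n - psi_prev) / (fb * xi_n - xi_prev)
    psi_pp <- psi_prev; psi_prev <- psi_n
    chi_pp <- chi_prev; chi_prev <- chi_n
  }
  n <- seq_len(nmax)
  list(a = a, b = b,
       Q_sca = sum(2 / x^2 * (2 * n + 1) * (Mod(a)^2 + Mod(b)^2)))
}

## Oracle amplitudes at angle theta from oracle coefficients.
oracle_amplitudes <- function(x, m, theta, nmax = NULL) {
  co <- oracle_mie(x, m, nmax)
  nmax <- length(co$a)
  mu <- cos(theta)
  p <- numeric(nmax); tau <- numeric(nmax)
  p[1] <- 1; tau[1] <- mu
  if (nmax >= 2) for (n in 2:nmax) {
    pm2 <- if (n == 2) 0 else p[n - 2]
    p[n] <- ((2 * n - 1) / (n - 1)) * mu * p[n - 1] - (n / (n - 1)) * pm2
    tau[n] <- n * mu * p[n] - (n + 1) * p[n - 1]
  }
  n <- seq_len(nmax)
  w <- (2 * n + 1) / (n * (n + 1))
  list(S1 = sum(w * (co$a * p + co$b * tau)),
       S2 = sum(w * (co$a * tau + co$b * p)))
}
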