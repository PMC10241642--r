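## Near-field coupling between two nanospheres, computed with a
## coupled-dipole (discrete-dipole) solver.  Each sphere is discretized
## on a cubic voxel lattice; a voxel at radial unit vector r-hat from its
## sphere's centre carries the permittivity tensor
## eps = n_r^2 r r^T + n_t^2 (I - r r^T) (relative to the medium), turned
## into a polarizability tensor by the Clausius-Mossotti relation with
## radiative correction per principal axis.  A point dipole source sits
## in sphere 1; the magnitude of the time-averaged Poynting vector is
## monitored at the far edge of sphere 2.

#' Two-sphere near-field coupling setup
#'
#' @param material An [anisotropic_sphere()]; its diameter sets the
#'   sphere size.
#' @param l_over_d Centre-to-centre distance in units of the diameter
#'   (1 = touching).
#' @param n_medium Host index (default 1.33).
#' @param wavelength Source wavelength in nm (default 500).
#' @param pitch Voxel pitch in nm; must not exceed `diameter / 12`.
#' @param source_position `"centre"` of sphere 1 or `"edge"` (on the
#'   surface facing sphere 2).
#' @param source_theta Source dipole orientation in degrees with respect
#'   to the inter-sphere axis (0 = parallel, 90 = orthogonal).
#' @return Object of class `coupling_setup`.
#' @export
coupling_setup <- function(material, l_over_d, n_medium = 1.33,
                           wavelength = 500, pitch = material$diameter / 12,
                           source_position = c("centre", "edge"),
                           source_theta = 0) {
  stopifnot(inherits(material, "anisotropic_sphere"))
  if (l_over_d < 1) stop("'l_over_d' must be >= 1 (spheres touch at 1)")
  if (pitch > material$diameter / 12 + 1e-9)
    stop("voxel pitch must not exceed diameter / 12")
  source_position <- match.arg(source_position)
  if (!source_theta %in% c(0, 90))
    stop("'source_theta' must be 0 or 90 degrees")
  structure(list(material = material, l_over_d = l_over_d,
                 n_medium = n_medium, wavelength = wavelength,
                 pitch = pitch, source_position = source_position,
                 source_theta = source_theta),
            class = "coupling_setup")
}

#' Discretize the two spheres into a polarizable dipole lattice
#'
#' @param setup A [coupling_setup()].
#' @return List with `positions` (M x 3, nm), `alpha` (M x 9 complex,
#'   row-wise 3x3 polarizability tensors in nm^3), `k` (wavenumber in the
#'   medium, 1/nm), and the geometry (`centres`, `monitor`, `source_pos`,
#'   `source_moment`).
#' @export
discretize_spheres <- function(setup) {
  stopifnot(inherits(setup, "coupling_setup"))
  d <- setup$material$diameter
  h <- setup$pitch
  l <- setup$l_over_d * d
  k <- 2 * pi * setup$n_medium / setup$wavelength
  centres <- rbind(c(0, 0, 0), c(l, 0, 0))

  ## half-offset cubic lattice: cell centres at (i + 1/2) h, so no voxel
  ## sits exactly at a sphere centre, on the surface, or on a lattice
  ## plane shared with the other sphere when the spheres touch
  half <- ceiling(d / 2 / h) + 1L
  gr <- h * (seq(-half, half - 1L) + 0.5)
  gcell <- as.matrix(expand.grid(x = gr, y = gr, z = gr))
  inside <- sqrt(rowSums(gcell^2)) <= d / 2
  cell <- gcell[inside, , drop = FALSE]
  positions <- rbind(sweep(cell, 2L, centres[1, ], "+"),
                     sweep(cell, 2L, centres[2, ], "+"))
  m_each <- nrow(cell)

  nm <- setup$n_medium
  et <- (setup$material$n_t / nm)^2
  er <- (setup$material$n_r / nm)^2
  cm <- function(eps) 3 * h^3 / (4 * pi) * (eps - 1) / (eps + 2)
  rad <- function(a0) a0 / (1 - (2 / 3) * 1i * k^3 * a0)
  a_t <- rad(cm(et)); a_r <- rad(cm(er))
  e_iso <- (2 * et + er) / 3
  a_iso <- rad(cm(e_iso))

  rvec <- rbind(cell, cell)                     # voxel - own centre
  rn <- sqrt(rowSums(rvec^2))
  M <- nrow(positions)
  alpha <- matrix(0 + 0i, M, 9L)
  eye <- diag(3)
  for (i in seq_len(M)) {
    if (rn[i] < h / 4 || er == et) {
      A <- (if (rn[i] < h / 4 && er != et) a_iso else a_t) * eye
    } else {
      u <- rvec[i, ] / rn[i]
      P <- tcrossprod(u)
      A <- a_r * P + a_t * (eye - P)
    }
    alpha[i, ] <- as.vector(A)
  }

  src <- if (setup$source_position == "centre") c(0, 0, 0) else c(d / 2, 0, 0)
  mom <- if (setup$source_theta == 0) c(1, 0, 0) else c(0, 0, 1)
  list(positions = positions, alpha = alpha, k = k, pitch = h,
       m_each = m_each, centres = centres,
       monitor = c(l + d / 2, 0, 0), source_pos = src, source_moment = mom,
       setup = setup)
}

## Field of a point dipole (moment p at origin) at displacement r, in the
## medium with wavenumber k.  Returns complex E (and H) rows per point.
dipole_E <- function(rmat, p, k) {
  rn <- sqrt(rowSums(rmat^2))
  u <- rmat / rn
  udp <- as.vector(u %*% p)
  ph <- exp(1i * k * rn)
  term1 <- k^2 / rn * (matrix(p, nrow(rmat), 3, byrow = TRUE) - u * udp)
  term2 <- (1 / rn^3 - 1i * k / rn^2) * (3 * u * udp -
             matrix(p, nrow(rmat), 3, byrow = TRUE))
  ph * (term1 + term2)
}

dipole_H <- function(rmat, p, k) {
  rn <- sqrt(rowSums(rmat^2))
  u <- rmat / rn
  cx <- cbind(u[, 2] * p[3] - u[, 3] * p[2],
              u[, 3] * p[1] - u[, 1] * p[3],
              u[, 1] * p[2] - u[, 2] * p[1])
  (k^2 * exp(1i * k * rn) / rn) * (1 - 1 / (1i * k * rn)) * cx
}

#' Solve the coupled-dipole equations
#'
#' Solves `alpha_i^{-1} p_i - sum_{j != i} G_ij p_j = E_inc,i` by
#' Jacobi-preconditioned BiCGSTAB (relative residual < `tol`).
#'
#' @param lattice Output of [discretize_spheres()].
#' @param e_inc Complex incident field, length `3 M` (or matrix with one
#'   column per right-hand side), ordered x1,y1,z1,x2,...
#' @param tol Relative residual tolerance.
#' @param max_iter Iteration cap.
#' @return List with `p` (complex matrix, columns matching `e_inc`),
#'   `iterations`, `residual`.
#' @export
solve_coupled_dipoles <- function(lattice, e_inc, tol = 1e-6,
                                  max_iter = 400L) {
  e_inc <- as.matrix(e_inc)
  if (nrow(e_inc) != 3L * nrow(lattice$positions))
    stop("'e_inc' must have 3 rows per voxel")
  if (max(Mod(lattice$alpha)) == 0)
    return(list(p = matrix(0 + 0i, nrow(e_inc), ncol(e_inc)),
                iterations = 0L, residual = 0))
  res <- dda_solve_cpp(lattice$positions, lattice$alpha, lattice$k,
                       e_inc, tol, as.integer(max_iter))
  if (any(res$residual > tol))
    stop(sprintf("coupled-dipole solver did not converge (residual %.3g)",
                 max(res$residual)))
  res
}

## Incident field of the source dipole on every voxel, as a 3M vector.
source_field <- function(lattice, source_pos, moment) {
  rmat <- sweep(lattice$positions, 2L, source_pos)
  as.vector(t(dipole_E(rmat, moment, lattice$k)))
}

## E and H at a single point from many dipoles with individual complex
## moments (pm: M x 3).  Returns complex length-3 vectors.
fields_at_point <- function(point, positions, pm, k) {
  rvec <- matrix(point, nrow(positions), 3, byrow = TRUE) - positions
  rn <- sqrt(rowSums(rvec^2))
  u <- rvec / rn
  udp <- rowSums(u * pm)                         # complex
  ph <- exp(1i * k * rn)
  near <- (1 / rn^3 - 1i * k / rn^2)
  E <- ph * (k^2 / rn * (pm - u * udp) + near * (3 * u * udp - pm))
  cx <- cbind(u[, 2] * pm[, 3] - u[, 3] * pm[, 2],
              u[, 3] * pm[, 1] - u[, 1] * pm[, 3],
              u[, 1] * pm[, 2] - u[, 2] * pm[, 1])
  H <- (k^2 * ph / rn) * (1 - 1 / (1i * k * rn)) * cx
  list(E = colSums(E), H = colSums(H))
}

#' Poynting-vector magnitude at the monitor point
#'
#' Total field = source dipole + all induced voxel dipoles;
#' `S = |Re(E x H*)| / 2` in the model's arbitrary units (unit source
#' moment).
#'
#' @param lattice Output of [discretize_spheres()].
#' @param p Complex dipole moments (length 3M; use zeros for the free
#'   source field).
#' @param point Monitor position (default the lattice's far-edge monitor).
#' @return Scalar Poynting magnitude.
#' @export
poynting_magnitude <- function(lattice, p, point = lattice$monitor) {
  pm <- matrix(p, ncol = 3L, byrow = TRUE)
  all_pos <- rbind(lattice$positions, lattice$source_pos)
  all_pm <- rbind(pm, lattice$source_moment + 0i)
  f <- fields_at_point(point, all_pos, all_pm, lattice$k)
  S <- 0.5 * Re(c(f$E[2] * Conj(f$H[3]) - f$E[3] * Conj(f$H[2]),
                  f$E[3] * Conj(f$H[1]) - f$E[1] * Conj(f$H[3]),
                  f$E[1] * Conj(f$H[2]) - f$E[2] * Conj(f$H[1])))
  sqrt(sum(S^2))
}

#' Near-field coupling versus inter-sphere distance
#'
#' For each centre-to-centre distance, solves the coupled-dipole system
#' for both source orientations (0 and 90 degrees to the axis) and
#' records the Poynting magnitude at the far edge of the second sphere;
#' the orientation mean is the coupling measure.
#'
#' @param material An [anisotropic_sphere()].
#' @param distances Centre-to-centre distances in units of the diameter.
#' @param source_position `"centre"` or `"edge"` of sphere 1.
#' @param wavelength Source wavelength (nm).
#' @param pitch Voxel pitch (nm).
#' @param n_medium Host index.
#' @param tol,max_iter Solver controls.
#' @return Object of class `coupling_result`: data.frame `per_run`
#'   (l_over_d, orientation, poynting) and `curve` (l_over_d,
#'   mean poynting).
#' @export
coupling_curve <- function(material, distances = c(1, 2, 3, 4),
                           source_position = "centre", wavelength = 500,
                           pitch = material$diameter / 12, n_medium = 1.33,
                           tol = 1e-6, max_iter = 400L) {
  runs <- data.frame()
  for (l in distances) {
    base <- coupling_setup(material, l, n_medium, wavelength, pitch,
                           source_position, source_theta = 0)
    lat <- discretize_spheres(base)
    rhs <- sapply(c(0, 90), function(th) {
      mom <- if (th == 0) c(1, 0, 0) else c(0, 0, 1)
      rmat <- sweep(lat$positions, 2L, lat$source_pos)
      as.vector(t(dipole_E(rmat, mom, lat$k)))
    })
    sol <- solve_coupled_dipoles(lat, rhs, tol, max_iter)
    for (ith in 1:2) {
      lat_th <- lat
      lat_th$source_moment <- if (ith == 1) c(1, 0, 0) else c(0, 0, 1)
      runs <- rbind(runs, data.frame(
        l_over_d = l, orientation = c(0, 90)[ith],
        poynting = poynting_magnitude(lat_th, sol$p[, ith])))
    }
  }
  curve <- stats::aggregate(poynting ~ l_over_d, runs, mean)
  structure(list(per_run = runs, curve = curve, material = material,
                 source_position = source_position,
                 wavelength = wavelength, pitch = pitch),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result> %s source, lambda = %g nm\n",
              x$source_position, x$wavelength))
  print(x$curve, row.names = FALSE)
  invisible(x)
}
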