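#' Radially anisotropic (spherulitic) nanosphere
#'
#' A sphere built from radially oriented molecular stacks presents one
#' refractive index tangential to its surface (`n_t`) and another along the
#' radius (`n_r`). Isotropic spheres are the degenerate case `n_t == n_r`.
#'
#' @param diameter Particle diameter in nm.
#' @param n_t Tangential refractive index (dimensionless, >= 1).
#' @param n_r Radial refractive index; defaults to `n_t` (isotropic).
#' @return An object of class `anisotropic_sphere`.
#' @examples
#' anisotropic_sphere(305, n_t = 1.96, n_r = 1.40)
#' anisotropic_sphere(305, 1.74) # isotropic comparator
#' @export
anisotropic_sphere <- function(diameter, n_t, n_r = n_t) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("'diameter' must be a single positive number (nm)")
  if (n_t < 1 || n_r < 1)
    stop("refractive indices must be >= 1")
  structure(
    list(diameter = diameter, n_t = n_t, n_r = n_r),
    class = "anisotropic_sphere"
  )
}

#' @export
print.anisotropic_sphere <- function(x, ...) {
  kind <- if (is_isotropic(x)) "isotropic" else "birefringent"
  cat(sprintf("<anisotropic_sphere> d = %g nm, n_t = %g, n_r = %g (%s)\n",
              x$diameter, x$n_t, x$n_r, kind))
  invisible(x)
}

is_isotropic <- function(sphere) sphere$n_t == sphere$n_r

#' Optical context: host medium and vacuum wavelength
#'
#' @param wavelength Vacuum wavelength in nm (may be a vector).
#' @param n_medium Refractive index of the host medium (default 1.33,
#'   cytoplasm/water).
#' @return An object of class `optical_context`.
#' @export
optical_context <- function(wavelength, n_medium = 1.33) {
  if (any(wavelength <= 0)) stop("'wavelength' must be positive (nm)")
  if (n_medium < 1) stop("'n_medium' must be >= 1")
  structure(list(wavelength = wavelength, n_medium = n_medium),
            class = "optical_context")
}

#' Size parameter of a sphere in a medium
#'
#' `x = pi * d * n_medium / lambda` with the vacuum wavelength in nm.
#'
#' @param diameter Diameter in nm.
#' @param wavelength Vacuum wavelength in nm.
#' @param n_medium Host medium index.
#' @return Dimensionless size parameter.
#' @export
size_parameter <- function(diameter, wavelength, n_medium = 1.33) {
  pi * diameter * n_medium / wavelength
}
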