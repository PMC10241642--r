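## Inference of the tangential refractive index from the positions of the
## TE2/TE3 Mie resonances, mirroring the single-particle peak-matching
## procedure: compute Q_sca peak positions on a grid of n_t (n_r held
## fixed; TE peak positions are exactly independent of n_r in this
## model), then invert the monotone peak-wavelength curve at the observed
## peak wavelengths.

#' Locate resonance peaks in a scattering spectrum
#'
#' Finds local maxima of the total `Q_sca`, refines each position by
#' quadratic interpolation over the three surrounding grid points, and
#' labels each peak by the multipole channel that dominates there (ties
#' broken toward lower order, TE before TM at equal order).
#'
#' @param spectrum A `scattering_spectrum` (see [scattering_efficiency()]),
#'   with per-multipole channels if labels are wanted.
#' @param min_prominence Discard peaks whose prominence (height above the
#'   higher of the two flanking valleys) is below this value.
#' @param on `"total"`: maxima of the total `Q_sca`, labeled by the
#'   dominant channel.  `"channels"`: maxima of each per-multipole
#'   channel curve itself — the observable plotted in resonance
#'   calibration curves, robust even when a resonance only forms a
#'   shoulder of the smooth total.
#' @return A data.frame with columns `label`, `wavelength`, `height`,
#'   `prominence`; zero rows if the spectrum has no interior local maximum.
#' @export
find_peaks <- function(spectrum, min_prominence = 0,
                       on = c("total", "channels")) {
  on <- match.arg(on)
  if (on == "channels") {
    if (is.null(spectrum$per_multipole))
      stop("channel peak search needs a per-multipole decomposition")
    out <- lapply(colnames(spectrum$per_multipole), function(ch) {
      sub <- structure(list(wavelengths = spectrum$wavelengths,
                            Q_sca = spectrum$per_multipole[, ch]),
                       class = "scattering_spectrum")
      pk <- find_peaks(sub, min_prominence, on = "total")
      if (nrow(pk)) pk$label <- ch
      pk
    })
    return(do.call(rbind, out))
  }
  y <- spectrum$Q_sca
  lam <- spectrum$wavelengths
  m <- length(y)
  empty <- data.frame(label = character(), wavelength = numeric(),
                      height = numeric(), prominence = numeric(),
                      stringsAsFactors = FALSE)
  if (m < 3) return(empty)
  idx <- which(diff(sign(diff(y))) < 0) + 1L   # strict rise then fall/flat
  idx <- idx[y[idx] > y[idx - 1L] & y[idx] >= y[idx + 1L]]
  if (!length(idx)) return(empty)

  ## prominence: walk out each side until a higher point or the edge,
  ## take the minimum en route; height above the higher of the two
  ## side-minima.
  prominence <- vapply(idx, function(i) {
    h <- y[i]
    left <- h; j <- i
    while (j > 1L && y[j - 1L] <= h) { j <- j - 1L; left <- min(left, y[j]) }
    right <- h; j <- i
    while (j < m && y[j + 1L] <= h) { j <- j + 1L; right <- min(right, y[j]) }
    h - max(left, right)
  }, numeric(1))

  keep <- prominence >= min_prominence
  idx <- idx[keep]; prominence <- prominence[keep]
  if (!length(idx)) return(empty)

  refine <- vapply(idx, function(i) {
    xs <- lam[(i - 1L):(i + 1L)]; ys <- y[(i - 1L):(i + 1L)]
    co <- stats::coef(stats::lm.fit(cbind(1, xs, xs^2), ys))
    if (!is.finite(co[3]) || co[3] >= 0) return(lam[i])
    v <- -co[2] / (2 * co[3])
    if (v < xs[1] || v > xs[3]) lam[i] else v
  }, numeric(1))

  labels <- rep(NA_character_, length(idx))
  if (!is.null(spectrum$per_multipole)) {
    ch <- spectrum$per_multipole
    ord <- order(as.integer(sub("^T[EM]", "", colnames(ch))),
                 match(substr(colnames(ch), 1, 2), c("TE", "TM")))
    ch <- ch[, ord, drop = FALSE]
    labels <- colnames(ch)[apply(ch[idx, , drop = FALSE], 1L, which.max)]
  }
  data.frame(label = labels, wavelength = refine, height = y[idx],
             prominence = prominence, stringsAsFactors = FALSE)
}

## Peak-wavelength estimator for one resonance channel: global maximum
## in the window, refined by a least-squares parabola over +/- fit_half
## nm around it.  Robust to noise on broad peaks; used identically for
## the noiseless calibration and for observed spectra, so any estimator
## bias from peak asymmetry cancels in the inversion.  Returns NA when
## the maximum sits at the grid edge (resonance outside the window).
channel_peak_wavelength <- function(lam, y, fit_half = 50) {
  i0 <- which.max(y)
  ## maxima too close to the grid edge cannot support the fit window:
  ## the resonance is (partly) outside the analysis window
  if (lam[i0] < lam[1] + fit_half / 2 ||
      lam[i0] > lam[length(lam)] - fit_half / 2) return(NA_real_)
  w <- which(abs(lam - lam[i0]) <= fit_half)
  if (length(w) < 5L) w <- max(1L, i0 - 2L):min(length(y), i0 + 2L)
  co <- stats::coef(stats::lm.fit(cbind(1, lam[w], lam[w]^2), y[w]))
  if (!is.finite(co[3]) || co[3] >= 0) return(lam[i0])
  v <- -co[2] / (2 * co[3])
  if (v < min(lam[w]) || v > max(lam[w])) lam[i0] else v
}

#' Calibration curve: resonance peak wavelength versus n_t
#'
#' Sweeps the tangential index with the radial index held fixed and
#' records the wavelength of the labeled resonance peak of `Q_sca`,
#' reproducing the model side of the peak-matching index measurement.
#' Peak wavelengths red-shift monotonically with `n_t`.
#'
#' @param diameter Particle diameter in nm (the single-particle study
#'   default is 430 nm, the size consistent with visible-band TE2/TE3).
#' @param n_r_fixed Radial index held constant (default 1.50).
#' @param n_t_grid Increasing grid of tangential indices.
#' @param labels Resonance labels to track (default TE2 and TE3).
#' @param wavelengths Analysis grid in nm.
#' @param n_medium Host index.
#' @return Object of class `calibration_curve`: list with `n_t`, a matrix
#'   `peak_wavelength` (one column per label; `NA` where the resonance has
#'   left the window), plus the fixed parameters.
#' @export
calibration_curve <- function(diameter = 430, n_r_fixed = 1.50,
                              n_t_grid = seq(1.5, 2.1, by = 0.005),
                              labels = c("TE2", "TE3"),
                              wavelengths = seq(340, 950, by = 2),
                              n_medium = 1.33) {
  if (is.unsorted(n_t_grid, strictly = TRUE))
    stop("'n_t_grid' must be strictly increasing")
  pw <- matrix(NA_real_, length(n_t_grid), length(labels),
               dimnames = list(NULL, labels))
  for (i in seq_along(n_t_grid)) {
    sp <- scattering_efficiency(
      anisotropic_sphere(diameter, n_t_grid[i], n_r_fixed),
      wavelengths, n_medium, per_multipole = TRUE)
    for (lb in labels)
      pw[i, lb] <- channel_peak_wavelength(wavelengths,
                                           sp$per_multipole[, lb])
  }
  structure(list(n_t = n_t_grid, peak_wavelength = pw,
                 diameter = diameter, n_r_fixed = n_r_fixed,
                 n_medium = n_medium, wavelengths = wavelengths),
            class = "calibration_curve")
}

#' Infer the tangential index from observed resonance peak wavelengths
#'
#' Inverts the monotone calibration curve for each labeled observed peak
#' (monotone interpolation, bisection root-finding) and averages the
#' per-resonance estimates.
#'
#' @param observed_peaks Named numeric vector of peak wavelengths in nm,
#'   names being resonance labels, e.g. `c(TE2 = 600, TE3 = 480)`.
#' @param diameter,n_r_fixed,n_medium Particle/medium parameters, used to
#'   build the calibration when `calibration` is not supplied.
#' @param calibration Optional precomputed [calibration_curve()].
#' @return Object of class `index_estimate`: per-resonance `n_t`, their
#'   arithmetic mean, and interpolation diagnostics.
#' @export
infer_tangential_index <- function(observed_peaks, diameter = 430,
                                   n_r_fixed = 1.50, n_medium = 1.33,
                                   calibration = NULL) {
  if (!length(observed_peaks) || is.null(names(observed_peaks)))
    stop("'observed_peaks' must be a named vector of wavelengths")
  if (is.null(calibration))
    calibration <- calibration_curve(diameter, n_r_fixed,
                                     n_medium = n_medium)
  if (any(is.na(observed_peaks))) {
    warning(sprintf("dropping unobserved resonance(s): %s",
                    paste(names(observed_peaks)[is.na(observed_peaks)],
                          collapse = ", ")))
    observed_peaks <- observed_peaks[!is.na(observed_peaks)]
    if (!length(observed_peaks)) stop("no observed resonance peaks left")
  }
  per <- numeric(0); resid <- numeric(0)
  for (lb in names(observed_peaks)) {
    if (!lb %in% colnames(calibration$peak_wavelength))
      stop(sprintf("no calibration for resonance label '%s'", lb))
    ok <- !is.na(calibration$peak_wavelength[, lb])
    nt <- calibration$n_t[ok]
    lamc <- calibration$peak_wavelength[ok, lb]
    if (any(diff(lamc) <= 0))
      stop(sprintf("calibration for '%s' is not strictly increasing", lb))
    target <- unname(observed_peaks[[lb]])
    if (target < min(lamc) || target > max(lamc))
      stop(sprintf(
        "observed %s peak at %.1f nm is outside the calibration range [%.1f, %.1f] nm",
        lb, target, min(lamc), max(lamc)))
    if (target == min(lamc) || target == max(lamc)) {
      warning(sprintf("observed %s peak sits at a calibration endpoint", lb))
      est <- nt[which(lamc == target)[1]]
    } else {
      f <- stats::splinefun(nt, lamc, method = "hyman")
      est <- stats::uniroot(function(v) f(v) - target,
                            range(nt), tol = 1e-10)$root
    }
    per[lb] <- est
    resid[lb] <- abs(stats::approx(nt, lamc, xout = est)$y - target)
  }
  structure(list(per_resonance = per, average = mean(per),
                 residual = resid, calibration = calibration),
            class = "index_estimate")
}

#' @export
print.index_estimate <- function(x, ...) {
  cat("<index_estimate>\n")
  for (lb in names(x$per_resonance))
    cat(sprintf("  %s: n_t = %.3f\n", lb, x$per_resonance[lb]))
  cat(sprintf("  average n_t = %.3f\n", x$average))
  invisible(x)
}

#' Synthetic noisy single-particle scattering spectrum
#'
#' Model `Q_sca` spectrum of an anisotropic sphere plus independent
#' Gaussian noise — a stand-in for a measured dark-field spectrum with a
#' known ground-truth index, used for parameter-recovery studies.
#'
#' @param n_t_true,n_r_true,diameter Ground-truth particle.
#' @param noise_sd Noise standard deviation in `Q_sca` units (0 = exact
#'   model spectrum).  Noise is drawn independently per wavelength and
#'   per multipole channel; the total is the sum of the noisy channels.
#' @param seed Integer seed; the same seed reproduces the same spectrum.
#' @param wavelengths,n_medium Analysis grid and host index.
#' @return A `scattering_spectrum` with per-multipole channels.
#' @export
synth_particle_spectrum <- function(n_t_true, n_r_true, diameter,
                                    noise_sd = 0, seed = 1L,
                                    wavelengths = seq(340, 950, by = 2),
                                    n_medium = 1.33) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  sp <- scattering_efficiency(anisotropic_sphere(diameter, n_t_true, n_r_true),
                              wavelengths, n_medium, per_multipole = TRUE)
  if (noise_sd > 0) {
    set.seed(seed)
    sp$per_multipole <- sp$per_multipole +
      matrix(stats::rnorm(length(sp$per_multipole), 0, noise_sd),
             nrow(sp$per_multipole))
    sp$Q_sca <- rowSums(sp$per_multipole)
  }
  sp
}

#' Read TE2/TE3 peak wavelengths off a (possibly noisy) spectrum
#'
#' Extracts the wavelength of the most prominent local maximum of each
#' requested resonance channel, after optional Savitzky-Golay smoothing
#' (order 3, window 11) — the standard pre-processing for noisy spectra.
#'
#' @param spectrum A `scattering_spectrum` with per-multipole channels
#'   (e.g. from [synth_particle_spectrum()]).
#' @param labels Channels to read (default TE2 and TE3).
#' @param smooth Apply Savitzky-Golay smoothing to each channel first?
#'   The default window (21 points, i.e. ~40 nm on a 2-nm grid) stays
#'   well under half the ~150 nm resonance width, so it suppresses noise
#'   without biasing the peak position.
#' @param window Odd Savitzky-Golay window length in grid points.
#' @return Named vector of peak wavelengths (NA if a channel shows no
#'   local maximum in the window).
#' @export
observed_channel_peaks <- function(spectrum, labels = c("TE2", "TE3"),
                                   smooth = FALSE, window = 21L) {
  if (is.null(spectrum$per_multipole))
    stop("spectrum lacks per-multipole channels")
  sp <- spectrum
  if (smooth) {
    n <- nrow(sp$per_multipole)
    win <- min(window, if (n %% 2L) n else n - 1L)
    sp$per_multipole <- apply(sp$per_multipole, 2L, function(v)
      as.numeric(signal::sgolayfilt(v, p = 3, n = win)))
  }
  vapply(labels, function(lb)
    channel_peak_wavelength(sp$wavelengths, sp$per_multipole[, lb]),
    numeric(1))
}
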