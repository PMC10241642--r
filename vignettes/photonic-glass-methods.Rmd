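---
title: "Methods: modelling whiteness from birefringent nanosphere glasses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling whiteness from birefringent nanosphere glasses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spherulite` models how ultra-thin layers of densely packed, radially
anisotropic ("spherulitic") nanospheres produce brilliant broadband
whiteness in an aqueous medium. The pipeline has five scientific stages:
single-particle anisotropic Mie optics, inference of the tangential
refractive index from resonance positions, generation of polydisperse
photonic-glass packings by a Langevin quench, structural observables,
and two complementary optical models of the assembly — a
dependent-scattering transport model of slab reflectance and a
coupled-dipole solver for near-field coupling between particle pairs.
This vignette records the models, their assumptions, and the design
decisions behind the defaults.

## 1. Single-particle optics

A spherulitic particle stacks planar molecules radially, so the
high-polarizability molecular plane lies tangential to the surface.
Optically the particle is a radially uniaxial sphere with tangential
index $n_t$ and radial index $n_r$ (defaults 1.96 and 1.40, the
calculated crystal values; the medium is cytoplasm-like water,
$n_m = 1.33$). The TE (magnetic-type) partial waves $b_n$ see only
$n_t$ and are ordinary Mie coefficients at relative index
$m_t = n_t/n_m$. The TM (electric-type) partial waves $a_n$ solve a
radial equation whose angular eigenvalue is displaced by the anisotropy:
the internal Riccati–Bessel function carries the fractional order

$$\nu_n = -\tfrac12 + \sqrt{\tfrac14 + n(n+1)\,(n_t/n_r)^2},$$

which collapses to $\nu_n = n$ in the isotropic limit. We use
Bohren–Huffman sign conventions; fractional-order Riccati–Bessel
functions are evaluated directly through `besselJ`/`besselY`, with
derivatives by the upward recurrence
$\psi'_\nu(z) = (\nu+1)\psi_\nu(z)/z - \psi_{\nu+1}(z)$ (no negative
orders arise). Non-finite Bessel evaluations raise an error rather than
returning silent zeros. Two independent anchors pin the implementation:
the isotropic limit agrees with a logarithmic-derivative (BHMIE-style)
implementation to $10^{-8}$, and the anisotropic dipole coefficient
reproduces the exact static polarizability
$(\nu_1\varepsilon_r - \varepsilon_m)/(\nu_1\varepsilon_r + 2\varepsilon_m)$
of a radially anisotropic sphere.

The default series truncation is $\lceil x + 4.05x^{1/3} + 2\rceil$,
floored at 3 so the quadrupole (TE2) and octupole (TE3) channels always
exist. Material dispersion is ignored: indices are constants per run.

One genuine quantitative caveat, worth stating because the qualitative
literature claim is stronger: $Q_\mathrm{sca}$ is *not* strictly
insensitive to $n_r$. The TE channels — which dominate the visible band
and carry the index inference — are exactly $n_r$-independent in this
model, but the TM channels retain an $n_r$ dependence that is provable
in the static limit (the dipole factor above changes by tens of percent
when $n_r$ moves from 1.40 to 1.60). Pointwise changes of
$Q_\mathrm{sca}$ across the visible band reach roughly 20% at fixed
$n_t$. The inference machinery is immune because it reads only TE peak
positions.

## 2. Which particle size for the single-particle studies?

The assemblies use the measured ensemble mean diameter, 305 nm. For the
*single-particle* resonance studies the package defaults to 430 nm: at
305 nm the TE3 resonance sits in the ultraviolet (~350 nm) and the
magnetic dipole dominates the visible band, whereas at 430 nm the TE2
and TE3 peaks fall at ~600 and ~480 nm — both in the visible, TE3 blue
of TE2, and jointly dominant over every other channel — which is the
configuration the resonance-matching measurement relies on. Individual
particles in these tissues span roughly 250–450 nm, so a 430-nm
specimen is unremarkable.

## 3. Index inference

`calibration_curve()` sweeps $n_t$ at fixed $n_r$ (default 1.50) and
records the wavelength of the TE2 and TE3 *channel* peaks — the
per-multipole efficiency maxima, not maxima of the total
$Q_\mathrm{sca}$. For these low-contrast spheres in water the total
cross-section is smooth and a resonance often appears only as a
shoulder, while the channel peak is always defined and strictly
red-shifts with $n_t$, giving a uniquely invertible curve.
`infer_tangential_index()` inverts it by monotone (Hyman) interpolation
and bisection, reporting per-resonance estimates and their arithmetic
mean. Observed peaks outside the calibrated range raise an error naming
the resonance; a peak exactly at an endpoint returns the endpoint value
with a warning.

Peak read-off uses one estimator everywhere: the channel maximum
refined by a least-squares parabola over ±50 nm. Using the identical
estimator on the noiseless calibration and on (noisy) observations
cancels the estimator's small bias on asymmetric peaks, which is why
noiseless round trips recover $n_t$ to machine precision and 2%-noise
recovery keeps the median error below 0.01. The analysis window is
340–950 nm so the TE3 resonance keeps a left flank down to
$n_t \approx 1.7$; maxima within half a fit-window of the grid edge are
reported as absent rather than guessed. `synth_particle_spectrum()`
adds seeded i.i.d. Gaussian noise per wavelength and channel — it
emulates measurement noise on the model observable, not the dark-field
collection geometry, which the package deliberately does not model.

## 4. Packing generation

`generate_packing()` reproduces the reference molecular-dynamics
protocol: particle diameters are log-normal with
$\mu_2 = \log(\mu_1^2/\sqrt{\mu_1^2+s_1^2})$ and
$\sigma_2^2 = \log(1+\sigma_1^2/\mu_1^2)$, clipped (not resampled) to
[100, 600] nm; particles start on a simple cubic lattice in a box four
times the final edge length and are squeezed linearly in edge length
under Langevin dynamics, then held at fixed box for the final 10% of
steps while the thermostat ramps to zero, relaxing residual overlaps.
The pair potential is the smoothed polydisperse 12–0 soft core

$$v(r) = v_0\left[(\sigma_{ij}/r)^{12} - 1\right] +
  \sum_{k=0}^{2} C_k (r/\sigma_{ij})^{2k},
  \qquad r/\sigma_{ij} \le x_c,$$

with $\sigma_{ij} = \tfrac12(\sigma_i+\sigma_j)
(1-\epsilon\,|\sigma_i-\sigma_j|)$ and $v_0 = 1$, $\epsilon = 0.01$,
$kT = 0.05$. Three interpretation decisions, made once:

* the cutoff is dimensionless, $x_c = 1.5$ applied to $r/\sigma_{ij}$
  (the printed cutoff mixes units; the dimensionless reading makes the
  smoothing coefficients well defined per pair);
* the nonadditive term evaluates $|\sigma_i - \sigma_j|$ in units of
  the mean diameter, keeping the correction $O(10^{-3})$ and
  $\sigma_{ij}$ positive;
* the $C_k$ solve $v(x_c) = v'(x_c) = v''(x_c) = 0$, the standard
  smoothed-soft-sphere construction, making the potential purely
  repulsive and $C^2$ at the cutoff.

Unprinted integrator details are fixed as: unit mass, reduced time step
$\mathrm{d}t = 0.005$, friction $\gamma = 1$, BAOAB splitting, Verlet
neighbour list with displacement-triggered rebuilds. All randomness
(diameters, thermostat noise) flows from the recipe's single seed
through R's RNG, so runs are bit-reproducible. The desk-scale defaults
are $N = 1000$ particles and $5\times10^4$ steps (the box is then
~3 µm at 50% fill); the recipe scales to larger $N$ and step counts
unchanged. The final box edge is computed from the sampled diameters,
so the measured filling fraction matches the target identically.

An important physical property of this potential at $kT = 0.05$: the
repulsive shoulder extends well beyond contact ($v = kT$ near
$r \approx 1.2\,\sigma_{ij}$), so packings are effectively *denser*
than hard spheres at the same nominal fill — the contact peak of
$g(r)$ sits near $1.1$–$1.2$ diameters and the structure factor's
first peak is correspondingly sharper than the hard-sphere
Percus–Yevick prediction at the nominal $\phi$ (about 4.1 versus 2.3
at $\phi = 0.45$, at the same peak position). The packing pipeline is
therefore validated on peak *positions*, fill fractions, diameter
statistics (two-sample KS against the clipped log-normal) and
non-crystallinity, not on matching PY peak heights. Crystallinity is
screened with the mean Steinhardt $q_6$ at a first-shell cutoff
(1.4 mean diameters): fcc gives 0.574, simple cubic 0.354, and these
rapid quenches sit near 0.40–0.43; the package flags mean $q_6 \ge
0.48$ as crystalline. At 0.33% polydispersity partial local order is
expected and permitted.

## 5. Structure observables

$g(r)$ uses the standard minimum-image shell histogram. The coordinate
structure factor is the direct sum
$S(q) = |\sum_j e^{i\mathbf{q}\cdot\mathbf{r}_j}|^2/N$ over the exact
reciprocal vectors $2\pi/L \times$ integer triples, shell-averaged with
width $2\pi/L$ — no windowing artefacts, Bragg peaks of crystalline
fixtures appear at full height in the raw sum. The analytic
monodisperse Percus–Yevick factor integrates the closed-form direct
correlation function by 96-node Gauss–Legendre quadrature (exact to
machine precision for the polynomial $c(r)$), and reproduces
$S(0) = (1-\phi)^4/(1+2\phi)^2$ to $10^{-10}$. Above $\phi = 0.64$ the
PY expression is an analytic continuation past random close packing; it
is retained up to 0.72 because the fill-fraction sweep evaluates the
model there, and flagged as such. Polydisperse assemblies use the
measured number-number $S(q)$ from coordinates with size-averaged form
factors (a decoupling treatment, adequate at CV ≤ 16%).

## 6. Slab reflectance: dependent scattering + effective medium

The commercial FDTD stage of the original study is replaced by a
desk-scale transport model:

$$\frac{1}{l_s} = \rho \int \frac{d\sigma}{d\Omega}\,S(q)\,d\Omega,
\qquad
\frac{1}{l_t} = \rho \int \frac{d\sigma}{d\Omega}\,S(q)\,
(1-\cos\theta)\,d\Omega,$$

with $q = 2k\sin(\theta/2)$, the unpolarized Mie differential
cross-section from the anisotropic amplitudes, 128-node Gauss–Legendre
quadrature in $\cos\theta$ (converged well past $10^{-4}$), and
number-averaged form factors over the clipped log-normal when
polydisperse. Slab reflectance uses the diffusion approximation for a
non-absorbing slab, $T = (l_t + z_e)/(L + 2z_e)$ with
$z_e = \tfrac23 l_t$ and no index-mismatch correction; $T$ is capped at
1 so the dilute limit degrades gracefully. $R_\mathrm{vis}$ averages
$R(\lambda)$ over 400–700 nm on a 5-nm grid.

**The effective host.** Far-field interference through $S(q)$ alone
does not produce optical crowding for a strong scatterer: with the bare
solvent as host, the $n = 1.96$ isotropic assembly's reflectance keeps
rising to $\phi \approx 0.6$, where the full-wave reference behaviour
peaks near 30%. The missing mean-field physics is contrast starvation:
a particle in a dense suspension is embedded not in solvent but in the
suspension itself. The model therefore evaluates the Mie scattering in
a Maxwell–Garnett effective host whose permittivity interpolates from
solvent toward the suspension average with $\phi$; birefringent
inclusions enter the host average through the orientation-averaged
permittivity $(2\varepsilon_t + \varepsilon_r)/3$ while keeping their
full anisotropic form factor. This single choice gives the observed
phenomenology: both isotropic variants peak at 25–30% fill and collapse
at high fill, while the birefringent variant — whose *average* index,
and hence host, stays low, but whose tangential contrast survives —
remains within 10% of its maximum out to 70%. The known cost of the
approximation is that it exaggerates crowding for the weakest
scatterer: at $\phi = 0.5$ the model's
$R_\mathrm{vis}(\text{birefringent})/R_\mathrm{vis}(n{=}1.74)$ ratio
far exceeds the two-fold enhancement a full-wave solver reports,
because the $n = 1.74$ assembly is driven nearly transparent. The
ordering (birefringent > isotropic 1.96 > isotropic 1.74 at 50–60%
fill) is robust to this and is the assertion the test-suite treats as
hard. Coherent backscattering, absorption, and angular-resolved
collection apertures are out of scope; residual quantitative offsets
against full-wave reflectance are expected.

## 7. Two-sphere near-field coupling

`coupling_curve()` re-creates the pair experiment: two spheres
($d = 305$ nm) at centre-to-centre distances 1–4 diameters, a unit
point dipole in sphere 1 (orientations 0° and 90° to the axis,
averaged), and the time-averaged Poynting magnitude at the far edge of
sphere 2, at a single wavelength (500 nm — the reference study reports
one scalar per distance, and the claim is an ordering, not a spectrum).
The solver is a coupled-dipole method on a half-offset cubic lattice
(pitch $\le d/12$; cell centres at half-integer multiples of the pitch,
so no voxel coincides with a sphere centre, the surface, or the
source/monitor). Each voxel carries the tensor permittivity
$\varepsilon = n_r^2\,\hat r\hat r + n_t^2(I - \hat r\hat r)$ about its
own sphere's centre, converted to a polarizability by the
Clausius–Mossotti relation with radiative correction per principal
axis; a voxel at an exact centre (possible only for other lattices)
would take the isotropic average index
$\sqrt{(2n_t^2+n_r^2)/3}$. The dense system
$\alpha_i^{-1}p_i - \sum_{j\ne i} G_{ij} p_j = E_i$ is solved by
Jacobi-preconditioned BiCGSTAB to a $10^{-6}$ relative residual, with
an explicit error on non-convergence.

With the source at the sphere centre the birefringent pair couples
roughly an order of magnitude more weakly than even the lower-index
($n = 1.74$) isotropic pair at every distance — the central result.
The physical picture: a dipole's dominant near field is longitudinal
(radial), so at the centre of a radially anisotropic sphere it couples
through $n_r \approx 1.40 \approx n_m$ and barely polarizes its own
host sphere. That picture also delimits the effect: for sources at or
near the particle surface (probed inside, on, and outside the surface,
facing toward and away from the neighbour) this solver finds
birefringent coupling comparable to the $n = 1.74$ case rather than
strictly below it, so the edge-source ordering reported by full-wave
simulation is *not* reproduced here — a documented limitation, possibly
reflecting the coarse local-field treatment of point sources embedded
in a discretized anisotropic medium.

Discretization accuracy: at pitch $d/12$ the monitor flux of an
isotropic sphere changes by a few percent when refined to $d/16$
(standard DDA behaviour at $|m|kh \approx 0.6$); the material
comparisons are always run at identical geometry and pitch so the
discretization bias largely cancels.

## 8. Problem sizes and scope of the test evidence

The shipped studies run at desk scale, chosen as the smallest sizes at
which each claim is stable: packings of 500–1000 particles (the
structural observables change by less than the assertion margins
between these sizes), 100-replicate recovery studies, and pair
coupling at pitch $d/12$ (about 900 voxels per sphere). The synthetic
data emulate clipped log-normal sizes, disordered packings at stated
fills, and noisy single-particle spectra with known ground truth; they
do not emulate instrument response, particle voids or ellipticity, or
substrate effects, so passing tests demonstrate correctness of the
models as specified, not agreement with any particular measured
specimen. The two honest quantitative gaps — Percus–Yevick peak
heights versus the soft-core packings, and the edge-source coupling
ordering — are asserted at their literature values in the acceptance
suite and left failing there deliberately, with the analysis above.
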