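// Langevin quench of polydisperse soft spheres (reduced units:
// length = mean diameter, energy = v0, unit mass) and the direct
// coordinate sum for the structure factor.  BAOAB splitting for the
// Langevin integrator; Verlet neighbour list with displacement-triggered
// rebuilds (box rescaling is affine, so only thermal displacement and
// the accumulated shrink matter for list validity).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct NeighbourList {
  std::vector<int> i, j;
};

void build_list(const std::vector<double>& x, const std::vector<double>& y,
                const std::vector<double>& z, double L, double rlist,
                NeighbourList& nl) {
  const int n = (int)x.size();
  nl.i.clear(); nl.j.clear();
  const double r2 = rlist * rlist;
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      double dx = x[a] - x[b]; dx -= L * std::round(dx / L);
      double dy = y[a] - y[b]; dy -= L * std::round(dy / L);
      double dz = z[a] - z[b]; dz -= L * std::round(dz / L);
      if (dx * dx + dy * dy + dz * dz < r2) { nl.i.push_back(a); nl.j.push_back(b); }
    }
  }
}

// forces and total potential energy over the neighbour list
double forces(const std::vector<double>& x, const std::vector<double>& y,
              const std::vector<double>& z, const std::vector<double>& diam,
              double L, double v0, double eps, double xc,
              const double* C, const NeighbourList& nl,
              std::vector<double>& fx, std::vector<double>& fy,
              std::vector<double>& fz) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  double pe = 0.0;
  const int m = (int)nl.i.size();
  for (int k = 0; k < m; ++k) {
    const int a = nl.i[k], b = nl.j[k];
    double dx = x[a] - x[b]; dx -= L * std::round(dx / L);
    double dy = y[a] - y[b]; dy -= L * std::round(dy / L);
    double dz = z[a] - z[b]; dz -= L * std::round(dz / L);
    const double r2 = dx * dx + dy * dy + dz * dz;
    // diameters already in units of mu1, so eps |di - dj| is direct
    const double sij = 0.5 * (diam[a] + diam[b]) *
      (1.0 - eps * std::fabs(diam[a] - diam[b]));
    const double rc = xc * sij;
    if (r2 >= rc * rc) continue;
    const double r = std::sqrt(r2);
    const double xr = r / sij;
    const double x2 = xr * xr;
    const double inv12 = 1.0 / (x2 * x2 * x2 * x2 * x2 * x2);
    pe += v0 * (inv12 - 1.0) + C[0] + C[1] * x2 + C[2] * x2 * x2;
    const double dvdx = -12.0 * v0 * inv12 / xr + 2.0 * C[1] * xr +
      4.0 * C[2] * xr * x2;
    const double fmag = -dvdx / sij;          // dV/dr with sign flipped
    const double fr = fmag / r;
    fx[a] += fr * dx; fx[b] -= fr * dx;
    fy[a] += fr * dy; fy[b] -= fr * dy;
    fz[a] += fr * dz; fz[b] -= fr * dz;
  }
  return pe;
}

} // namespace

// [[Rcpp::export]]
List md_quench_cpp(NumericMatrix pos0, NumericVector diam, double box0,
                   double box1, int steps, double dt, double kT,
                   double gamma, double v0, double eps, double xc,
                   NumericVector C, double cool_frac, int trace_every) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n),
    fx(n), fy(n), fz(n), dcp(diam.begin(), diam.end());
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  const double sd0 = std::sqrt(kT);
  for (int i = 0; i < n; ++i) {
    vx[i] = sd0 * norm_rand(); vy[i] = sd0 * norm_rand();
    vz[i] = sd0 * norm_rand();
  }
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) dmax = std::max(dmax, dcp[i]);
  const double skin = 0.35;
  const double rlist = xc * dmax + skin;
  double L = box0;
  const int n_squeeze = (int)std::lround(steps * (1.0 - cool_frac));
  const int n_cool = steps - n_squeeze;
  const double Cc[3] = { C[0], C[1], C[2] };

  NeighbourList nl;
  build_list(x, y, z, L, rlist, nl);
  double pe = forces(x, y, z, dcp, L, v0, eps, xc, Cc, nl, fx, fy, fz);
  double acc_disp = 0.0, acc_shrink = 1.0;

  std::vector<int> t_step; std::vector<double> t_box, t_kT, t_pe;
  const double half = 0.5 * dt;

  for (int s = 0; s < steps; ++s) {
    double kT_s;
    if (s < n_squeeze) {
      kT_s = kT;
      const double Lnew = box0 + (box1 - box0) * (double)(s + 1) / n_squeeze;
      const double scale = Lnew / L;
      for (int i = 0; i < n; ++i) { x[i] *= scale; y[i] *= scale; z[i] *= scale; }
      L = Lnew;
      acc_shrink *= scale;
    } else {
      kT_s = (n_cool > 0) ? kT * (1.0 - (double)(s - n_squeeze + 1) / n_cool)
                          : 0.0;
    }
    const double c1 = std::exp(-gamma * dt);
    const double c2 = std::sqrt(std::max(0.0, (1.0 - c1 * c1) * kT_s));
    double vmax2 = 0.0;
    for (int i = 0; i < n; ++i) {                 // B + A
      vx[i] += half * fx[i]; vy[i] += half * fy[i]; vz[i] += half * fz[i];
      x[i] += half * vx[i]; y[i] += half * vy[i]; z[i] += half * vz[i];
    }
    for (int i = 0; i < n; ++i) {                 // O
      vx[i] = c1 * vx[i] + c2 * norm_rand();
      vy[i] = c1 * vy[i] + c2 * norm_rand();
      vz[i] = c1 * vz[i] + c2 * norm_rand();
    }
    for (int i = 0; i < n; ++i) {                 // A
      x[i] += half * vx[i]; y[i] += half * vy[i]; z[i] += half * vz[i];
      const double v2 = vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
      if (v2 > vmax2) vmax2 = v2;
    }
    acc_disp += std::sqrt(vmax2) * dt;
    if (2.0 * acc_disp + rlist * (1.0 - acc_shrink) > skin) {
      build_list(x, y, z, L, rlist, nl);
      acc_disp = 0.0; acc_shrink = 1.0;
    }
    pe = forces(x, y, z, dcp, L, v0, eps, xc, Cc, nl, fx, fy, fz);
    for (int i = 0; i < n; ++i) {                 // B
      vx[i] += half * fx[i]; vy[i] += half * fy[i]; vz[i] += half * fz[i];
    }
    if ((s + 1) % trace_every == 0 || s == steps - 1) {
      t_step.push_back(s + 1); t_box.push_back(L);
      t_kT.push_back(kT_s); t_pe.push_back(pe);
    }
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double xi = x[i] - L * std::floor(x[i] / L);
    double yi = y[i] - L * std::floor(y[i] / L);
    double zi = z[i] - L * std::floor(z[i] / L);
    out(i, 0) = xi; out(i, 1) = yi; out(i, 2) = zi;
  }
  return List::create(_["positions"] = out,
                      _["trace_step"] = wrap(t_step),
                      _["trace_box"] = wrap(t_box),
                      _["trace_kT"] = wrap(t_kT),
                      _["trace_pe"] = wrap(t_pe),
                      _["final_pe"] = pe);
}

// Structure factor by direct coordinate sum over the reciprocal lattice
// of the periodic box: S(q) = |sum_j exp(i q.r_j)|^2 / N for
// q = (2 pi / L) (h, k, l), one representative per +/-q pair.
// [[Rcpp::export]]
List sk_sum_cpp(NumericMatrix pos, double L, int nmax) {
  const int n = pos.nrow();
  const double b = 2.0 * M_PI / L;
  std::vector<double> qn, sq;
  for (int h = 0; h <= nmax; ++h) {
    const int klo = (h == 0) ? 0 : -nmax;
    for (int k = klo; k <= nmax; ++k) {
      const int llo = (h == 0 && k == 0) ? 1 : -nmax;
      for (int l = llo; l <= nmax; ++l) {
        const int m2 = h * h + k * k + l * l;
        if (m2 == 0 || m2 > nmax * nmax) continue;
        const double qx = b * h, qy = b * k, qz = b * l;
        double cre = 0.0, cim = 0.0;
        for (int j = 0; j < n; ++j) {
          const double ph = qx * pos(j, 0) + qy * pos(j, 1) + qz * pos(j, 2);
          cre += std::cos(ph); cim += std::sin(ph);
        }
        qn.push_back(b * std::sqrt((double)m2));
        sq.push_back((cre * cre + cim * cim) / n);
      }
    }
  }
  return List::create(_["q"] = wrap(qn), _["sq"] = wrap(sq));
}
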