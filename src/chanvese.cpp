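#include <Rcpp.h>
using namespace Rcpp;

// Chan-Vese level-set evolution kernel.
//
// Minimizes  mu*length + nu*area + l1*sum_in (u0-c1)^2 + l2*sum_out (u0-c2)^2
// with a smoothed Heaviside of width eps. Region means are the
// Heaviside-weighted optima (exact minimizers for fixed phi); the level-set
// step follows the energy gradient preconditioned by the smoothed delta, with
// backtracking so the recorded energy trace never increases. phi is kept in
// [-phi_cap, phi_cap].

static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// Most of phi saturates at +/- phi_cap after a few iterations; shortcut the
// atan for those pixels (hcap/dcap are the exact values at the cap).
static inline double heav_f(double p, double eps, double cap, double hcap) {
  if (p >= cap) return hcap;
  if (p <= -cap) return 1.0 - hcap;
  return 0.5 * (1.0 + M_2_PI * atan(p / eps));
}

static inline double delta_f(double p, double eps, double cap, double dcap) {
  if (p >= cap || p <= -cap) return dcap;
  return (eps / M_PI) / (eps * eps + p * p);
}

static double smooth_energy(const NumericMatrix &img, const NumericMatrix &phi,
                            double c1, double c2, double mu, double nu,
                            double l1, double l2, double eps,
                            double cap, double hcap, double dcap) {
  const int h = phi.nrow(), w = phi.ncol();
  double len = 0, area = 0, fit1 = 0, fit2 = 0;
  for (int j = 0; j < w; ++j) {
    int jl = clampi(j - 1, w), jr = clampi(j + 1, w);
    for (int i = 0; i < h; ++i) {
      int iu = clampi(i - 1, h), id = clampi(i + 1, h);
      double p = phi(i, j);
      double heav = heav_f(p, eps, cap, hcap);
      double gx = (phi(i, jr) - phi(i, jl)) / 2.0;
      double gy = (phi(id, j) - phi(iu, j)) / 2.0;
      double g2 = gx * gx + gy * gy;
      if (g2 > 0) len += delta_f(p, eps, cap, dcap) * sqrt(g2);
      area += heav;
      double d = img(i, j);
      fit1 += heav * (d - c1) * (d - c1);
      fit2 += (1.0 - heav) * (d - c2) * (d - c2);
    }
  }
  return mu * len + nu * area + l1 * fit1 + l2 * fit2;
}

// [[Rcpp::export(name = ".chanvese_evolve")]]
List chanvese_evolve(NumericMatrix img, NumericMatrix phi_init,
                     double mu, double nu, double l1, double l2,
                     double eps, double tol, int max_iter, double phi_cap) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix phi = clone(phi_init);
  NumericMatrix force(h, w), cand(h, w);
  std::vector<double> energies;
  energies.reserve(max_iter + 1);
  int iter_done = 0;
  bool collapsed = false;
  const double tiny = 1e-12;
  const double hcap = 0.5 * (1.0 + M_2_PI * atan(phi_cap / eps));
  const double dcap = (eps / M_PI) / (eps * eps + phi_cap * phi_cap);

  for (int it = 1; it <= max_iter; ++it) {
    // Heaviside-weighted region means.
    double sh = 0, shi = 0, so = 0, soi = 0;
    int n_in = 0;
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double p = phi(i, j);
        double heav = heav_f(p, eps, phi_cap, hcap);
        sh += heav; shi += heav * img(i, j);
        so += 1.0 - heav; soi += (1.0 - heav) * img(i, j);
        if (p >= 0) ++n_in;
      }
    }
    if (n_in == 0 || n_in == h * w) {
      collapsed = true;
      iter_done = it;
      break;
    }
    double c1 = shi / sh, c2 = soi / so;
    double e_cur = smooth_energy(img, phi, c1, c2, mu, nu, l1, l2, eps, phi_cap, hcap, dcap);
    if (energies.empty()) energies.push_back(e_cur);

    // Delta-preconditioned descent direction.
    double fmax = 0;
    for (int j = 0; j < w; ++j) {
      int jl = clampi(j - 1, w), jr = clampi(j + 1, w);
      for (int i = 0; i < h; ++i) {
        int iu = clampi(i - 1, h), id = clampi(i + 1, h);
        double gx = (phi(i, jr) - phi(i, jl)) / 2.0;
        double gy = (phi(id, j) - phi(iu, j)) / 2.0;
        double gxx = phi(i, jr) - 2.0 * phi(i, j) + phi(i, jl);
        double gyy = phi(id, j) - 2.0 * phi(i, j) + phi(iu, j);
        double gxy = (phi(id, jr) - phi(id, jl) - phi(iu, jr) + phi(iu, jl)) / 4.0;
        double n2 = gx * gx + gy * gy + 1e-8;
        double kappa = (gxx * gy * gy - 2.0 * gx * gy * gxy + gyy * gx * gx) /
          (n2 * sqrt(n2));
        double d = img(i, j);
        double f = mu * kappa - nu - l1 * (d - c1) * (d - c1) +
          l2 * (d - c2) * (d - c2);
        force(i, j) = f;
        if (fabs(f) > fmax) fmax = fabs(f);
      }
    }
    if (fmax < tiny) {  // no gradient anywhere (e.g. constant image, mu = 0)
      iter_done = it;
      break;
    }

    double dt = 2.0 / fmax;
    double target = std::min(e_cur, energies.back());
    bool accepted = false;
    double e_new = 0;
    for (int bt = 0; bt < 25; ++bt) {
      for (int j = 0; j < w; ++j) {
        for (int i = 0; i < h; ++i) {
          double v = phi(i, j) + dt * force(i, j);
          cand(i, j) = v < -phi_cap ? -phi_cap : (v > phi_cap ? phi_cap : v);
        }
      }
      e_new = smooth_energy(img, cand, c1, c2, mu, nu, l1, l2, eps, phi_cap, hcap, dcap);
      if (e_new <= target + tiny) {
        accepted = true;
        break;
      }
      dt /= 2.0;
    }
    iter_done = it;
    if (!accepted) break;
    std::swap(phi, cand);
    energies.push_back(e_new);
    if (fabs(target - e_new) <= tol * (fabs(target) + tiny)) break;
  }

  return List::create(_["phi"] = phi,
                      _["energies"] = NumericVector(energies.begin(), energies.end()),
                      _["iterations"] = iter_done,
                      _["collapsed"] = collapsed);
}
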