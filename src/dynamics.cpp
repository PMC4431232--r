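#include <Rcpp.h>
#include <cmath>
#include <random>
using namespace Rcpp;

// Forward declarations from interactions.cpp
NumericMatrix cpp_dipolar_fields(NumericMatrix pos, NumericMatrix mom,
                                 double mu0);
List cpp_forces(NumericMatrix pos, NumericMatrix mom, NumericVector diam,
                double eps, double mu0);

// ---------------------------------------------------------------------------
// Stochastic Landau-Lifshitz-Gilbert spin dynamics at fixed positions.
//
//   dm/dt = -gamma/(1+a^2) [ m x B  +  (a/|m|) m x (m x B) ]
//
// with B the effective field (external + dipolar + thermal).  The thermal
// field has independent Gaussian components of variance
// 2 a kB T / (gamma |m| dt) per step (Langevin heat bath).  Heun
// predictor-corrector with the same noise realization in both stages,
// followed by renormalization of |m| (single-domain macrospin contract).
//
// Bext: either 1 row (constant field) or n_steps+1 rows (field at step
// boundaries t_k = k dt).  Records energy components and reduced
// magnetization every record_every steps (plus the final state).
// ---------------------------------------------------------------------------

static inline void llg_rhs(const std::vector<double> &m,
                           const std::vector<double> &B,
                           int n, double pre, double alpha,
                           const std::vector<double> &minv,
                           std::vector<double> &out) {
  for (int i = 0; i < n; ++i) {
    double mx = m[3 * i], my = m[3 * i + 1], mz = m[3 * i + 2];
    double bx = B[3 * i], by = B[3 * i + 1], bz = B[3 * i + 2];
    double cx = my * bz - mz * by;
    double cy = mz * bx - mx * bz;
    double cz = mx * by - my * bx;
    double dx = my * cz - mz * cy;
    double dy = mz * cx - mx * cz;
    double dz = mx * cy - my * cx;
    double ai = alpha * minv[i];
    out[3 * i]     = -pre * (cx + ai * dx);
    out[3 * i + 1] = -pre * (cy + ai * dy);
    out[3 * i + 2] = -pre * (cz + ai * dz);
  }
}

// [[Rcpp::export]]
List cpp_sd_run(NumericMatrix pos, NumericMatrix mom0, double mu0, double kB,
                double alpha, double gamma, double dt, double temperature,
                int n_steps, NumericMatrix Bext, int record_every,
                double seed) {
  int n = pos.nrow();
  bool bconst = (Bext.nrow() == 1);
  if (!bconst && Bext.nrow() < n_steps + 1)
    stop("field table must have n_steps+1 rows");
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> m(3 * n), mmag(n), minv(n);
  for (int i = 0; i < n; ++i) {
    m[3 * i] = mom0(i, 0); m[3 * i + 1] = mom0(i, 1); m[3 * i + 2] = mom0(i, 2);
    mmag[i] = std::sqrt(m[3 * i] * m[3 * i] + m[3 * i + 1] * m[3 * i + 1] +
                        m[3 * i + 2] * m[3 * i + 2]);
    if (mmag[i] <= 0.0) stop("particle %d has zero moment", i + 1);
    minv[i] = 1.0 / mmag[i];
  }
  double pre = gamma / (1.0 + alpha * alpha);
  bool thermal = temperature > 0.0;

  int n_rec = n_steps / std::max(record_every, 1) + 2;
  std::vector<double> rec_t, rec_ed, rec_ez, rec_mx, rec_my, rec_mz;
  rec_t.reserve(n_rec); rec_ed.reserve(n_rec); rec_ez.reserve(n_rec);
  rec_mx.reserve(n_rec); rec_my.reserve(n_rec); rec_mz.reserve(n_rec);

  std::vector<double> Beff(3 * n), Beff2(3 * n), k1(3 * n), k2(3 * n),
      mp(3 * n), noise(3 * n), Bd(3 * n);
  // precompute pair geometry (positions are fixed for the whole call)
  int npair = n * (n - 1) / 2;
  std::vector<double> gux(npair), guy(npair), guz(npair), ginv3(npair);
  std::vector<int> gi(npair), gj(npair);
  {
    double pref = mu0 / (4.0 * M_PI);
    int p = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++p) {
        double rx = pos(i, 0) - pos(j, 0);
        double ry = pos(i, 1) - pos(j, 1);
        double rz = pos(i, 2) - pos(j, 2);
        double r2 = rx * rx + ry * ry + rz * rz;
        if (r2 <= 0.0) stop("coincident particles %d and %d", i + 1, j + 1);
        double r = std::sqrt(r2);
        gi[p] = i; gj[p] = j;
        gux[p] = rx / r; guy[p] = ry / r; guz[p] = rz / r;
        ginv3[p] = pref / (r2 * r);
      }
  }

  auto dip_field = [&](const std::vector<double> &mm,
                       std::vector<double> &out) {
    std::fill(out.begin(), out.end(), 0.0);
    for (int p = 0; p < npair; ++p) {
      int i = gi[p], j = gj[p];
      double ux = gux[p], uy = guy[p], uz = guz[p], c = ginv3[p];
      double mjr = mm[3 * j] * ux + mm[3 * j + 1] * uy + mm[3 * j + 2] * uz;
      out[3 * i]     += c * (3.0 * ux * mjr - mm[3 * j]);
      out[3 * i + 1] += c * (3.0 * uy * mjr - mm[3 * j + 1]);
      out[3 * i + 2] += c * (3.0 * uz * mjr - mm[3 * j + 2]);
      double mir = mm[3 * i] * ux + mm[3 * i + 1] * uy + mm[3 * i + 2] * uz;
      out[3 * j]     += c * (3.0 * ux * mir - mm[3 * i]);
      out[3 * j + 1] += c * (3.0 * uy * mir - mm[3 * i + 1]);
      out[3 * j + 2] += c * (3.0 * uz * mir - mm[3 * i + 2]);
    }
  };

  auto fill_field = [&](const std::vector<double> &mm, int bext_row,
                        std::vector<double> &out, bool add_noise) {
    dip_field(mm, out);
    int br = bconst ? 0 : bext_row;
    for (int i = 0; i < n; ++i) {
      out[3 * i]     += Bext(br, 0);
      out[3 * i + 1] += Bext(br, 1);
      out[3 * i + 2] += Bext(br, 2);
      if (add_noise) {
        out[3 * i] += noise[3 * i];
        out[3 * i + 1] += noise[3 * i + 1];
        out[3 * i + 2] += noise[3 * i + 2];
      }
    }
  };

  auto record = [&](int step) {
    dip_field(m, Bd);
    int br = bconst ? 0 : std::min(step, Bext.nrow() - 1);
    double ed = 0.0, ez = 0.0, sx = 0.0, sy = 0.0, sz = 0.0, stot = 0.0;
    for (int i = 0; i < n; ++i) {
      ed -= 0.5 * (m[3 * i] * Bd[3 * i] + m[3 * i + 1] * Bd[3 * i + 1] +
                   m[3 * i + 2] * Bd[3 * i + 2]);
      ez -= m[3 * i] * Bext(br, 0) + m[3 * i + 1] * Bext(br, 1) +
            m[3 * i + 2] * Bext(br, 2);
      sx += m[3 * i]; sy += m[3 * i + 1]; sz += m[3 * i + 2];
      stot += mmag[i];
    }
    rec_t.push_back(step * dt);
    rec_ed.push_back(ed); rec_ez.push_back(ez);
    rec_mx.push_back(sx / stot); rec_my.push_back(sy / stot);
    rec_mz.push_back(sz / stot);
  };

  record(0);
  for (int s = 0; s < n_steps; ++s) {
    if (thermal) {
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(2.0 * alpha * kB * temperature /
                              (gamma * mmag[i] * dt));
        noise[3 * i] = sd * gauss(rng);
        noise[3 * i + 1] = sd * gauss(rng);
        noise[3 * i + 2] = sd * gauss(rng);
      }
    }
    fill_field(m, s, Beff, thermal);
    llg_rhs(m, Beff, n, pre, alpha, minv, k1);
    for (int q = 0; q < 3 * n; ++q) mp[q] = m[q] + dt * k1[q];
    fill_field(mp, s + 1, Beff2, thermal);
    llg_rhs(mp, Beff2, n, pre, alpha, minv, k2);
    for (int q = 0; q < 3 * n; ++q) m[q] += 0.5 * dt * (k1[q] + k2[q]);
    // renormalize: |m_i| is a material constant of the macrospin
    for (int i = 0; i < n; ++i) {
      double nm = std::sqrt(m[3 * i] * m[3 * i] + m[3 * i + 1] * m[3 * i + 1] +
                            m[3 * i + 2] * m[3 * i + 2]);
      double f = mmag[i] / nm;
      m[3 * i] *= f; m[3 * i + 1] *= f; m[3 * i + 2] *= f;
    }
    if ((s + 1) % std::max(record_every, 1) == 0 && s + 1 < n_steps)
      record(s + 1);
  }
  record(n_steps);

  NumericMatrix momOut(n, 3);
  for (int i = 0; i < n; ++i) {
    momOut(i, 0) = m[3 * i]; momOut(i, 1) = m[3 * i + 1];
    momOut(i, 2) = m[3 * i + 2];
  }
  return List::create(
      _["moments"] = momOut, _["t"] = wrap(rec_t),
      _["E_dipolar"] = wrap(rec_ed), _["E_zeeman"] = wrap(rec_ez),
      _["Mx"] = wrap(rec_mx), _["My"] = wrap(rec_my), _["Mz"] = wrap(rec_mz));
}

// ---------------------------------------------------------------------------
// Overdamped Langevin translation at fixed moments:
//   dx = F/drag dt + sqrt(2 kB T dt / drag) xi
// Reflective box, motion restricted to the first motion_dim coordinates.
// Aborts with an error if any single-step displacement exceeds
// max_disp_frac * d_i (stability contract; advise smaller dt).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_md_run(NumericMatrix pos0, NumericMatrix mom, NumericVector diam,
                double eps, double mu0, double drag, double kB,
                double temperature, double dt, int n_steps,
                NumericVector box, int motion_dim, double seed,
                double max_disp_frac) {
  int n = pos0.nrow();
  std::vector<double> P(3 * n), M(3 * n), Fv(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      P[3 * i + k] = pos0(i, k);
      M[3 * i + k] = mom(i, k);
    }
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double noise_sd = temperature > 0.0
                        ? std::sqrt(2.0 * kB * temperature * dt / drag)
                        : 0.0;
  double max_scl = 0.0;   // max over steps/pairs of sigma/r
  const double WCA_CUT = 1.1224620483093730;
  double pref = 3.0 * mu0 / (4.0 * M_PI);
  const double *dd = diam.begin();
  for (int s = 0; s < n_steps; ++s) {
    std::fill(Fv.begin(), Fv.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double pix = P[3 * i], piy = P[3 * i + 1], piz = P[3 * i + 2];
      const double mix = M[3 * i], miy = M[3 * i + 1], miz = M[3 * i + 2];
      double fix = 0.0, fiy = 0.0, fiz = 0.0;
      for (int j = i + 1; j < n; ++j) {
        double rx = pix - P[3 * j];
        double ry = piy - P[3 * j + 1];
        double rz = piz - P[3 * j + 2];
        double r2 = rx * rx + ry * ry + rz * rz;
        if (r2 <= 0.0) stop("coincident particles %d and %d", i + 1, j + 1);
        double invr = 1.0 / std::sqrt(r2);
        double invr2 = invr * invr;
        double ux = rx * invr, uy = ry * invr, uz = rz * invr;
        double mjx = M[3 * j], mjy = M[3 * j + 1], mjz = M[3 * j + 2];
        double mir = mix * ux + miy * uy + miz * uz;
        double mjr = mjx * ux + mjy * uy + mjz * uz;
        double mimj = mix * mjx + miy * mjy + miz * mjz;
        double cdd = pref * invr2 * invr2;
        double q = mimj - 5.0 * mir * mjr;
        double fx = cdd * (mjr * mix + mir * mjx + q * ux);
        double fy = cdd * (mjr * miy + mir * mjy + q * uy);
        double fz = cdd * (mjr * miz + mir * mjz + q * uz);
        double sigma = 0.5 * (dd[i] + dd[j]);
        double scl = sigma * invr;      // sigma / r
        if (scl > max_scl) max_scl = scl;
        if (scl > 1.0 / WCA_CUT) {
          double sr2 = scl * scl;
          double sr6 = sr2 * sr2 * sr2;
          double fmag = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) * invr;
          fx += fmag * ux; fy += fmag * uy; fz += fmag * uz;
        }
        fix += fx; fiy += fy; fiz += fz;
        Fv[3 * j] -= fx; Fv[3 * j + 1] -= fy; Fv[3 * j + 2] -= fz;
      }
      Fv[3 * i] += fix; Fv[3 * i + 1] += fiy; Fv[3 * i + 2] += fiz;
    }
    double inv_drag_dt = dt / drag;
    for (int i = 0; i < n; ++i) {
      double d2max = max_disp_frac * dd[i];
      for (int k = 0; k < motion_dim; ++k) {
        double step = Fv[3 * i + k] * inv_drag_dt;
        if (noise_sd > 0.0) step += noise_sd * gauss(rng);
        if (std::fabs(step) > d2max)
          stop("MD step displacement %g m exceeds %g m for particle %d at "
               "step %d; reduce dt", std::fabs(step), d2max, i + 1, s + 1);
        double x = P[3 * i + k] + step;
        // reflective walls
        double L = box[k];
        if (x < 0.0) x = -x;
        if (x > L) x = 2.0 * L - x;
        if (x < 0.0 || x > L) x = std::min(std::max(x, 0.0), L);
        P[3 * i + k] = x;
      }
    }
  }
  NumericMatrix pos(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pos(i, k) = P[3 * i + k];
  return List::create(_["positions"] = pos,
                      _["min_scaled_dist"] =
                          max_scl > 0.0 ? 1.0 / max_scl : R_PosInf);
}
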