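#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise magnetic dipole-dipole and WCA kernels.
//
// Conventions shared by every routine here:
//   pos  n x 3 particle centers (m), mom  n x 3 moments (A m^2),
//   diam length-n diameters (m).  The WCA length scale of a pair is the
//   contact distance sigma_ij = (d_i + d_j)/2 and the potential is cut
//   (and shifted to zero) at 2^(1/6) sigma_ij.  All sums are full
//   all-pairs, no cutoff on the dipolar part.

static const double WCA_CUT = 1.1224620483093730;  // 2^(1/6)

// dipolar field at each particle: B_i = sum_j mu0/(4 pi r^3) [3 rh (m_j.rh) - m_j]
// [[Rcpp::export]]
NumericMatrix cpp_dipolar_fields(NumericMatrix pos, NumericMatrix mom,
                                 double mu0) {
  int n = pos.nrow();
  NumericMatrix B(n, 3);
  double pref = mu0 / (4.0 * M_PI);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double rx = pos(i, 0) - pos(j, 0);
      double ry = pos(i, 1) - pos(j, 1);
      double rz = pos(i, 2) - pos(j, 2);
      double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 <= 0.0) stop("coincident particles %d and %d", i + 1, j + 1);
      double r = std::sqrt(r2);
      double inv3 = 1.0 / (r2 * r);
      double ux = rx / r, uy = ry / r, uz = rz / r;
      // field at i from m_j
      double mjr = mom(j, 0) * ux + mom(j, 1) * uy + mom(j, 2) * uz;
      B(i, 0) += pref * inv3 * (3.0 * ux * mjr - mom(j, 0));
      B(i, 1) += pref * inv3 * (3.0 * uy * mjr - mom(j, 1));
      B(i, 2) += pref * inv3 * (3.0 * uz * mjr - mom(j, 2));
      // field at j from m_i (same unit vector works: odd terms cancel)
      double mir = mom(i, 0) * ux + mom(i, 1) * uy + mom(i, 2) * uz;
      B(j, 0) += pref * inv3 * (3.0 * ux * mir - mom(i, 0));
      B(j, 1) += pref * inv3 * (3.0 * uy * mir - mom(i, 1));
      B(j, 2) += pref * inv3 * (3.0 * uz * mir - mom(i, 2));
    }
  }
  return B;
}

// energy components: (dipolar, wca) summed over unordered pairs
// [[Rcpp::export]]
NumericVector cpp_pair_energies(NumericMatrix pos, NumericMatrix mom,
                                NumericVector diam, double eps, double mu0) {
  int n = pos.nrow();
  double pref = mu0 / (4.0 * M_PI);
  double e_dd = 0.0, e_wca = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double rx = pos(i, 0) - pos(j, 0);
      double ry = pos(i, 1) - pos(j, 1);
      double rz = pos(i, 2) - pos(j, 2);
      double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 <= 0.0) stop("coincident particles %d and %d", i + 1, j + 1);
      double r = std::sqrt(r2);
      double ux = rx / r, uy = ry / r, uz = rz / r;
      double mir = mom(i, 0) * ux + mom(i, 1) * uy + mom(i, 2) * uz;
      double mjr = mom(j, 0) * ux + mom(j, 1) * uy + mom(j, 2) * uz;
      double mimj = mom(i, 0) * mom(j, 0) + mom(i, 1) * mom(j, 1) +
                    mom(i, 2) * mom(j, 2);
      e_dd += -pref / (r2 * r) * (3.0 * mir * mjr - mimj);
      double sigma = 0.5 * (diam[i] + diam[j]);
      if (r < WCA_CUT * sigma) {
        double sr6 = std::pow(sigma / r, 6);
        e_wca += 4.0 * eps * (sr6 * sr6 - sr6) + eps;
      }
    }
  }
  return NumericVector::create(e_dd, e_wca);
}

// forces: F_i = -grad_i (H_dd + H_wca), n x 3.  Also reports the minimum
// pair distance scaled by its contact sigma (overlap diagnostic).
// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix mom, NumericVector diam,
                double eps, double mu0) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  double pref = 3.0 * mu0 / (4.0 * M_PI);
  double min_scaled = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double rx = pos(i, 0) - pos(j, 0);
      double ry = pos(i, 1) - pos(j, 1);
      double rz = pos(i, 2) - pos(j, 2);
      double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 <= 0.0) stop("coincident particles %d and %d", i + 1, j + 1);
      double r = std::sqrt(r2);
      double ux = rx / r, uy = ry / r, uz = rz / r;  // unit vector j -> i
      double mir = mom(i, 0) * ux + mom(i, 1) * uy + mom(i, 2) * uz;
      double mjr = mom(j, 0) * ux + mom(j, 1) * uy + mom(j, 2) * uz;
      double mimj = mom(i, 0) * mom(j, 0) + mom(i, 1) * mom(j, 1) +
                    mom(i, 2) * mom(j, 2);
      double c = pref / (r2 * r2);
      // force on i (dipole at r = r_i - r_j relative to j)
      double fx = c * (mjr * mom(i, 0) + mir * mom(j, 0) +
                       (mimj - 5.0 * mir * mjr) * ux);
      double fy = c * (mjr * mom(i, 1) + mir * mom(j, 1) +
                       (mimj - 5.0 * mir * mjr) * uy);
      double fz = c * (mjr * mom(i, 2) + mir * mom(j, 2) +
                       (mimj - 5.0 * mir * mjr) * uz);
      double sigma = 0.5 * (diam[i] + diam[j]);
      if (r / sigma < min_scaled) min_scaled = r / sigma;
      if (r < WCA_CUT * sigma) {
        double sr6 = std::pow(sigma / r, 6);
        double fmag = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r;  // repulsive
        fx += fmag * ux; fy += fmag * uy; fz += fmag * uz;
      }
      F(i, 0) += fx; F(i, 1) += fy; F(i, 2) += fz;
      F(j, 0) -= fx; F(j, 1) -= fy; F(j, 2) -= fz;
    }
  }
  return List::create(_["forces"] = F, _["min_scaled_dist"] = min_scaled);
}

// Exhaustive in-plane (xy) ground-state search on an angular grid, n <= 4.
// Independent oracle for the relaxation integrator: enumerates every
// combination of per-moment azimuth on a step_deg grid and returns the
// lowest total dipolar energy.  Pairwise energy tables make the inner
// loops pure table lookups.
// [[Rcpp::export]]
List cpp_brute_force_inplane(NumericMatrix pos, NumericVector mmag,
                             double mu0, double step_deg) {
  int n = pos.nrow();
  if (n < 2 || n > 4) stop("brute-force search supports 2..4 particles");
  int K = (int)std::lround(360.0 / step_deg);
  std::vector<double> ct(K), st(K);
  for (int a = 0; a < K; ++a) {
    double th = 2.0 * M_PI * a / K;
    ct[a] = std::cos(th); st[a] = std::sin(th);
  }
  // pairwise tables f[p][a_i*K + a_j]
  int npair = n * (n - 1) / 2;
  std::vector<std::vector<double> > f(npair, std::vector<double>(K * K));
  std::vector<int> pi(npair), pj(npair);
  double pref = mu0 / (4.0 * M_PI);
  int p = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j, ++p) {
      pi[p] = i; pj[p] = j;
      double rx = pos(i, 0) - pos(j, 0);
      double ry = pos(i, 1) - pos(j, 1);
      double r2 = rx * rx + ry * ry;
      double r = std::sqrt(r2);
      double ux = rx / r, uy = ry / r;
      double c = -pref / (r2 * r) * mmag[i] * mmag[j];
      for (int a = 0; a < K; ++a) {
        double mira = ct[a] * ux + st[a] * uy;
        for (int b = 0; b < K; ++b) {
          double mjrb = ct[b] * ux + st[b] * uy;
          double dot = ct[a] * ct[b] + st[a] * st[b];
          f[p][a * K + b] = c * (3.0 * mira * mjrb - dot);
        }
      }
    }
  }
  double best = R_PosInf;
  std::vector<int> barg(n, 0);
  if (n == 2) {
    for (int a = 0; a < K; ++a)
      for (int b = 0; b < K; ++b)
        if (f[0][a * K + b] < best) {
          best = f[0][a * K + b]; barg[0] = a; barg[1] = b;
        }
  } else if (n == 3) {
    // pairs: 0:(0,1) 1:(0,2) 2:(1,2)
    for (int a = 0; a < K; ++a) {
      const double *f02 = &f[1][a * K];
      for (int b = 0; b < K; ++b) {
        double e01 = f[0][a * K + b];
        const double *f12 = &f[2][b * K];
        for (int cidx = 0; cidx < K; ++cidx) {
          double e = e01 + f02[cidx] + f12[cidx];
          if (e < best) { best = e; barg[0] = a; barg[1] = b; barg[2] = cidx; }
        }
      }
    }
  } else {
    // pairs: 0:(0,1) 1:(0,2) 2:(0,3) 3:(1,2) 4:(1,3) 5:(2,3)
    std::vector<double> s23(K), s3(K);
    for (int a = 0; a < K; ++a) {
      for (int b = 0; b < K; ++b) {
        double e01 = f[0][a * K + b];
        const double *f02 = &f[1][a * K], *f03 = &f[2][a * K];
        const double *f12 = &f[3][b * K], *f13 = &f[4][b * K];
        for (int d = 0; d < K; ++d) s3[d] = f03[d] + f13[d];
        for (int cidx = 0; cidx < K; ++cidx) {
          double e2 = e01 + f02[cidx] + f12[cidx];
          const double *f23 = &f[5][cidx * K];
          // vector-friendly inner scan
          double loc = R_PosInf; int locd = 0;
          for (int d = 0; d < K; ++d) {
            double e = s3[d] + f23[d];
            if (e < loc) { loc = e; locd = d; }
          }
          if (e2 + loc < best) {
            best = e2 + loc;
            barg[0] = a; barg[1] = b; barg[2] = cidx; barg[3] = locd;
          }
        }
      }
    }
  }
  NumericVector ang(n);
  for (int i = 0; i < n; ++i) ang[i] = 360.0 * barg[i] / K;
  return List::create(_["energy"] = best, _["angles_deg"] = ang);
}
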