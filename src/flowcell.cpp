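#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 2D (length x height) advection-diffusion-reaction solver for the flow
// cell, finite-volume on a wall-graded mesh.
//
// Per time step:
//   1. advection in x: first-order upwind (explicit), inlet Dirichlet
//      c_in(t), free outflow at the outlet;
//   2. diffusion in x: explicit central (unconditionally mild at the
//      channel Peclet numbers of interest; dt is capped in R);
//   3. diffusion in z: backward-Euler implicit (Thomas solve per column),
//      no-flux at the top, Robin reactive flux at the sensor floor with
//      the surface coverage n frozen over the step:
//         D dc/dz|_wall = ka c_wall (1 - n/nA) - kd n/nA
//   4. surface update using the *implicit* wall concentration, so the
//      moles leaving the fluid through the Robin face are exactly the
//      moles added to n (discrete fluid<->surface conservation).
//
// The mole ledger (in / out / stored / bound) uses the same discrete
// fluxes as the scheme, so the residual measures real conservation error.
//
// c is stored as an nz x nx matrix (row j = height cell, col i = along
// flow).  dz[j] are cell heights, zc[j] cell-center heights, u[j] the
// streamwise velocity at cell centers.  width multiplies areas/volumes
// for mole bookkeeping only.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_flowcell_run(NumericMatrix c0, NumericVector n0, double dx,
                      NumericVector dz, NumericVector zc, NumericVector u,
                      double D, double dt, int n_steps, double t0,
                      NumericVector cin, double ka, double kd, double nA,
                      double width, int record_every, int inlet_open) {
  int nz = c0.nrow(), nx = c0.ncol();
  if ((int)cin.size() < n_steps) stop("inlet series shorter than n_steps");
  NumericMatrix c = clone(c0);
  NumericVector n = clone(n0);

  // center-to-center distances
  std::vector<double> h(nz - 1);
  for (int j = 0; j < nz - 1; ++j) h[j] = zc[j + 1] - zc[j];

  double moles_in = 0.0, moles_out = 0.0, moles_bound0 = 0.0, moles0 = 0.0;
  for (int j = 0; j < nz; ++j)
    for (int i = 0; i < nx; ++i) moles0 += c(j, i) * dz[j] * dx * width;
  for (int i = 0; i < nx; ++i) moles_bound0 += n[i] * dx * width;
  int clip_events = 0;

  int nrecmax = n_steps / std::max(record_every, 1) + 2;
  std::vector<double> rec_t, rec_n, rec_cout, rec_cwall;
  rec_t.reserve(nrecmax); rec_n.reserve(nrecmax);
  rec_cout.reserve(nrecmax); rec_cwall.reserve(nrecmax);

  auto record = [&](double t) {
    double nm = 0.0, co = 0.0, cw = 0.0;
    for (int i = 0; i < nx; ++i) nm += n[i];
    for (int j = 0; j < nz; ++j) co += c(j, nx - 1) * dz[j];
    for (int i = 0; i < nx; ++i) cw += c(0, i);
    double H = 0.0; for (int j = 0; j < nz; ++j) H += dz[j];
    rec_t.push_back(t); rec_n.push_back(nm / nx);
    rec_cout.push_back(co / H); rec_cwall.push_back(cw / nx);
  };
  record(t0);

  std::vector<double> cold(nz), a(nz), b(nz), d(nz), rhs(nz), cw(nz);
  bool advect = false;
  for (int j = 0; j < nz; ++j) if (u[j] != 0.0) advect = true;

  for (int s = 0; s < n_steps; ++s) {
    double cin_t = cin[s];
    // --- advection (upwind, u >= 0 assumed) ---
    if (advect) {
      for (int j = 0; j < nz; ++j) {
        double lam = u[j] * dt / dx;
        if (lam == 0.0) continue;
        moles_in += u[j] * cin_t * dz[j] * width * dt;
        moles_out += u[j] * c(j, nx - 1) * dz[j] * width * dt;
        double prev = cin_t;
        for (int i = 0; i < nx; ++i) {
          double cur = c(j, i);
          c(j, i) = cur - lam * (cur - prev);
          prev = cur;
        }
      }
    }
    // --- x diffusion (explicit; Dirichlet c_in at the inlet face,
    //     no-flux at the outlet face) ---
    if (D > 0.0 && nx > 1) {
      double mu = D * dt / (dx * dx);
      for (int j = 0; j < nz; ++j) {
        // inlet face flux D (c_in - c0)/(dx/2) into cell 0
        double fin = inlet_open
                         ? 2.0 * D * (cin_t - c(j, 0)) / dx
                         : 0.0;  // mol m^-2 s^-1
        moles_in += fin * dz[j] * width * dt;
        double left = c(j, 0);
        for (int i = 0; i < nx; ++i) {
          double cur = c(j, i);
          double right = (i < nx - 1) ? c(j, i + 1) : cur;
          double lap = (i == 0) ? (right - cur) : (left - 2.0 * cur + right);
          c(j, i) = cur + mu * lap + ((i == 0) ? fin * dt / dx : 0.0);
          left = cur;
        }
      }
    }
    // --- z diffusion implicit + Robin floor ---
    for (int i = 0; i < nx; ++i) {
      double arob = ka * (1.0 - n[i] / nA);   // m/s
      double brob = kd * n[i] / nA;           // mol m^-2 s^-1
      for (int j = 0; j < nz; ++j) cold[j] = c(j, i);
      // tridiagonal: a sub, d diag, b super
      for (int j = 0; j < nz; ++j) {
        double wlo = (j > 0) ? D / h[j - 1] / dz[j] : 0.0;
        double whi = (j < nz - 1) ? D / h[j] / dz[j] : 0.0;
        a[j] = -dt * wlo;
        b[j] = -dt * whi;
        d[j] = 1.0 + dt * (wlo + whi);
        rhs[j] = cold[j];
      }
      if (arob > 0.0 || brob > 0.0) {
        d[0] += dt * arob / dz[0];
        rhs[0] += dt * brob / dz[0];
      }
      // Thomas
      for (int j = 1; j < nz; ++j) {
        double wf = a[j] / d[j - 1];
        d[j] -= wf * b[j - 1];
        rhs[j] -= wf * rhs[j - 1];
      }
      cw[nz - 1] = rhs[nz - 1] / d[nz - 1];
      for (int j = nz - 2; j >= 0; --j)
        cw[j] = (rhs[j] - b[j] * cw[j + 1]) / d[j];
      for (int j = 0; j < nz; ++j) c(j, i) = cw[j];
      // --- surface update from the implicit wall flux ---
      double J = arob * cw[0] - brob;  // mol m^-2 s^-1 into the surface
      n[i] += dt * J;
      if (n[i] < 0.0) { n[i] = 0.0; ++clip_events; }
      if (n[i] > nA) { n[i] = nA; ++clip_events; }
    }
    if ((s + 1) % std::max(record_every, 1) == 0 || s + 1 == n_steps)
      record(t0 + (s + 1) * dt);
  }

  double stored = 0.0, bound = 0.0;
  for (int j = 0; j < nz; ++j)
    for (int i = 0; i < nx; ++i) stored += c(j, i) * dz[j] * dx * width;
  for (int i = 0; i < nx; ++i) bound += n[i] * dx * width;

  return List::create(
      _["c"] = c, _["n"] = n, _["t"] = wrap(rec_t),
      _["n_mean"] = wrap(rec_n), _["c_outlet"] = wrap(rec_cout),
      _["c_wall"] = wrap(rec_cwall),
      _["moles_in"] = moles_in, _["moles_out"] = moles_out,
      _["moles_stored"] = stored, _["moles_bound"] = bound,
      _["moles_initial"] = moles0 + moles_bound0,
      _["clip_events"] = clip_events);
}
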