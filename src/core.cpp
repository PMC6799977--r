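#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reaction terms of the activator-inhibitor relaxation oscillator.
// dA/dt = F(A) - G(R) A,  dR/dt = (c2 A - c1 R)/tau
// F(A) = [ka A^2/(Ka^2+A^2) + b](At - A),  G(R) = d1 + d2 R
static inline double f_act(double A, double R, double ka, double Ka, double b,
                           double At, double d1, double d2) {
  double FA = (ka * A * A / (Ka * Ka + A * A) + b) * (At - A);
  return FA - (d1 + d2 * R) * A;
}
static inline double f_inh(double A, double R, double c1, double c2, double tau) {
  return (c2 * A - c1 * R) / tau;
}

// [[Rcpp::export]]
List rk4_well_mixed_cpp(double A0, double R0, double dt, int nsteps, int rec,
                        List p) {
  double ka = p["ka"], Ka = p["Ka"], b = p["b"], At = p["At"];
  double d1 = p["d1"], d2 = p["d2"], c1 = p["c1"], c2 = p["c2"], tau = p["tau"];
  int nrec = nsteps / rec + 1;
  NumericVector ts(nrec), As(nrec), Rs(nrec);
  double A = A0, R = R0;
  ts[0] = 0; As[0] = A0; Rs[0] = R0;
  int k = 1;
  for (int s = 1; s <= nsteps; ++s) {
    double k1a = f_act(A, R, ka, Ka, b, At, d1, d2);
    double k1r = f_inh(A, R, c1, c2, tau);
    double k2a = f_act(A + 0.5 * dt * k1a, R + 0.5 * dt * k1r, ka, Ka, b, At, d1, d2);
    double k2r = f_inh(A + 0.5 * dt * k1a, R + 0.5 * dt * k1r, c1, c2, tau);
    double k3a = f_act(A + 0.5 * dt * k2a, R + 0.5 * dt * k2r, ka, Ka, b, At, d1, d2);
    double k3r = f_inh(A + 0.5 * dt * k2a, R + 0.5 * dt * k2r, c1, c2, tau);
    double k4a = f_act(A + dt * k3a, R + dt * k3r, ka, Ka, b, At, d1, d2);
    double k4r = f_inh(A + dt * k3a, R + dt * k3r, c1, c2, tau);
    A += dt / 6.0 * (k1a + 2 * k2a + 2 * k3a + k4a);
    R += dt / 6.0 * (k1r + 2 * k2r + 2 * k3r + k4r);
    if (!std::isfinite(A) || !std::isfinite(R))
      stop("well-mixed integration blew up at step %d", s);
    if (s % rec == 0 && k < nrec) {
      ts[k] = s * dt; As[k] = A; Rs[k] = R; ++k;
    }
  }
  return List::create(_["t"] = ts[Range(0, k - 1)], _["A"] = As[Range(0, k - 1)],
                      _["R"] = Rs[Range(0, k - 1)]);
}

// 1D reaction-diffusion integrator (forward Euler, centered flux stencil).
// reaction = 0: activator-inhibitor system; reaction = 1: single-field cubic
// k (u-u1)(u2-u)(u-u3) (the bistable benchmark with known front speed).
// bc = 0: periodic, 1: no-flux (mirror).
// [[Rcpp::export]]
List rd1d_run_cpp(NumericVector A0, NumericVector R0, List p, double dx,
                  double dt, int nsteps, int rec, int bc, int reaction,
                  bool clamp_R, double sigma,
                  NumericVector cubic) {
  int nx = A0.size();
  double ka = p["ka"], Ka = p["Ka"], b = p["b"], At = p["At"];
  double d1 = p["d1"], d2 = p["d2"], c1 = p["c1"], c2 = p["c2"], tau = p["tau"];
  double DA = p["DA"], DR = p["DR"];
  std::vector<double> A(A0.begin(), A0.end()), R(R0.begin(), R0.end());
  std::vector<double> An(nx), Rn(nx);
  int nrec = nsteps / rec;
  NumericMatrix Ah(nrec, nx), Rh(nrec, nx);
  NumericVector ts(nrec);
  double namp = sigma > 0 ? std::sqrt(sigma * dt / dx) : 0.0;
  bool noisy = namp > 0;
  if (noisy) GetRNGstate();
  int krec = 0;
  long clip = 0;
  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < nx; ++i) {
      int im = i - 1, ip = i + 1;
      if (bc == 0) { if (im < 0) im = nx - 1; if (ip == nx) ip = 0; }
      else { if (im < 0) im = 1; if (ip == nx) ip = nx - 2; }
      double lapA = (A[ip] + A[im] - 2.0 * A[i]) / (dx * dx);
      double ra;
      if (reaction == 0) {
        ra = f_act(A[i], R[i], ka, Ka, b, At, d1, d2);
      } else {
        double kk = cubic[0], u1 = cubic[1], u2 = cubic[2], u3 = cubic[3];
        ra = kk * (A[i] - u1) * (u2 - A[i]) * (A[i] - u3);
      }
      An[i] = A[i] + dt * (DA * lapA + ra);
      if (noisy) An[i] += namp * norm_rand();
      if (reaction == 0 && !clamp_R) {
        double lapR = (R[ip] + R[im] - 2.0 * R[i]) / (dx * dx);
        Rn[i] = R[i] + dt * (DR * lapR + f_inh(A[i], R[i], c1, c2, tau));
        if (noisy) Rn[i] += namp * norm_rand();
      } else {
        Rn[i] = R[i];
      }
    }
    for (int i = 0; i < nx; ++i) {
      if (reaction == 0 && An[i] < 0) { An[i] = 0; ++clip; }
      if (reaction == 0 && Rn[i] < 0) { Rn[i] = 0; ++clip; }
      A[i] = An[i]; R[i] = Rn[i];
      if (!std::isfinite(A[i]))
        stop("1D integration produced non-finite values at step %d", s);
    }
    if (s % rec == 0) {
      for (int i = 0; i < nx; ++i) { Ah(krec, i) = A[i]; Rh(krec, i) = R[i]; }
      ts[krec] = s * dt;
      ++krec;
    }
  }
  if (noisy) PutRNGstate();
  return List::create(_["t"] = ts, _["A"] = Ah, _["R"] = Rh,
                      _["clip_count"] = (double)clip);
}

// Coupled phase-field / reaction-diffusion stepper (forward Euler).
// Per step: (i) advance phi by the force-balance equation
//   xi dphi/dt = eta M(A) |grad phi| + gamma (lap phi - G'(phi)/eps^2)
//                - BS (area - S0) |grad phi|
// (ii) advance A, R with the product-rule discretization of d(phi A)/dt
//   using phi^(n) and phi^(n+1), restricted to the region phi > chi.
// Periodic boundaries throughout; centered stencils.
// [[Rcpp::export]]
List cell2d_run_cpp(NumericMatrix phi0, NumericMatrix A0, NumericMatrix R0,
                    List p, double dx, double dy, double dt, int nsteps,
                    int rec_traj, int rec_snap, double eta_final,
                    bool literal_noise) {
  int nx = phi0.nrow(), ny = phi0.ncol();
  double ka = p["ka"], Ka = p["Ka"], b = p["b"], At = p["At"];
  double d1 = p["d1"], d2 = p["d2"], c1 = p["c1"], c2 = p["c2"], tau = p["tau"];
  double DA = p["DA"], DR = p["DR"], sigma = p["sigma"];
  double gamma = p["gamma"], eps = p["epsilon"], BS = p["BS"], xi = p["xi"];
  double eta = p["eta"], nh = p["n_hill"], Ath = p["A0"], S0 = p["S0"];
  double chi = p["chi"];
  int N = nx * ny;
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> A(A0.begin(), A0.end()), R(R0.begin(), R0.end());
  std::vector<double> phin(N), An(N), Rn(N);
  std::vector<int> xp(nx), xm(nx), yp(ny), ym(ny);
  for (int i = 0; i < nx; ++i) { xp[i] = (i + 1) % nx; xm[i] = (i + nx - 1) % nx; }
  for (int j = 0; j < ny; ++j) { yp[j] = (j + 1) % ny; ym[j] = (j + ny - 1) % ny; }
  // eta ramp: linear interpolation from p$eta to eta_final over the run
  bool ramp = (eta_final >= 0 && eta_final != eta);
  double namp = sigma > 0
    ? (literal_noise ? std::sqrt(sigma * dt) : std::sqrt(sigma * dt / (dx * dy)))
    : 0.0;
  bool noisy = namp > 0;
  if (noisy) GetRNGstate();
  int ntr = nsteps / rec_traj;
  NumericVector tr_t(ntr), tr_x(ntr), tr_y(ntr), tr_area(ntr), tr_eta(ntr);
  int nsn = rec_snap > 0 ? nsteps / rec_snap : 0;
  List snaps(nsn);
  NumericVector snap_t(nsn);
  double twoPi = 2.0 * M_PI;
  double Lx = nx * dx, Ly = ny * dy;
  double prev_x = NA_REAL, prev_y = NA_REAL;
  long clip = 0;
  int ktr = 0, ksn = 0;
  for (int s = 1; s <= nsteps; ++s) {
    double eta_s = ramp ? eta + (eta_final - eta) * ((double)s / nsteps) : eta;
    // cell area
    double area = 0.0;
    for (int q = 0; q < N; ++q) area += phi[q];
    area *= dx * dy;
    double areaF = BS * (area - S0);
    // phase-field update
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int q = i + nx * j;
        double pc = phi[q];
        double pe = phi[xp[i] + nx * j], pw = phi[xm[i] + nx * j];
        double pn = phi[i + nx * yp[j]], ps = phi[i + nx * ym[j]];
        double gx = (pe - pw) / (2.0 * dx), gy = (pn - ps) / (2.0 * dy);
        double gm = std::sqrt(gx * gx + gy * gy);
        double lap = (pe + pw - 2.0 * pc) / (dx * dx) + (pn + ps - 2.0 * pc) / (dy * dy);
        double Gp = 36.0 * pc * (1.0 - pc) * (1.0 - 2.0 * pc);
        double Ai = A[q] > 0 ? A[q] : 0.0;
        double Anh = std::pow(Ai, nh);
        double M = Anh / (Anh + std::pow(Ath, nh));
        phin[q] = pc + dt / xi * (eta_s * M * gm + gamma * (lap - Gp / (eps * eps))
                                  - areaF * gm);
      }
    }
    // reaction-diffusion update on the restricted region phi > chi
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int q = i + nx * j;
        double pc = phi[q];
        if (pc <= chi) { An[q] = 0.0; Rn[q] = 0.0; continue; }
        int qe = xp[i] + nx * j, qw = xm[i] + nx * j;
        int qn = i + nx * yp[j], qs = i + nx * ym[j];
        double pe = phi[qe], pw = phi[qw], pn = phi[qn], ps = phi[qs];
        // face-averaged flux divergence of phi grad A
        double divA =
          ((pe + pc) * (A[qe] - A[q]) - (pc + pw) * (A[q] - A[qw])) / (2.0 * dx * dx) +
          ((pn + pc) * (A[qn] - A[q]) - (pc + ps) * (A[q] - A[qs])) / (2.0 * dy * dy);
        double divR =
          ((pe + pc) * (R[qe] - R[q]) - (pc + pw) * (R[q] - R[qw])) / (2.0 * dx * dx) +
          ((pn + pc) * (R[qn] - R[q]) - (pc + ps) * (R[q] - R[qs])) / (2.0 * dy * dy);
        double ra = f_act(A[q], R[q], ka, Ka, b, At, d1, d2);
        double rr = f_inh(A[q], R[q], c1, c2, tau);
        double zA = noisy ? namp * norm_rand() : 0.0;
        double zR = noisy ? namp * norm_rand() : 0.0;
        double dphi = phin[q] - pc;
        An[q] = A[q] + (dt * (DA * divA + pc * ra) + pc * zA - A[q] * dphi) / pc;
        Rn[q] = R[q] + (dt * (DR * divR + pc * rr) + pc * zR - R[q] * dphi) / pc;
        if (An[q] < 0) { An[q] = 0; ++clip; }
        if (Rn[q] < 0) { Rn[q] = 0; ++clip; }
      }
    }
    for (int q = 0; q < N; ++q) {
      phi[q] = phin[q]; A[q] = An[q]; R[q] = Rn[q];
      if (!std::isfinite(phi[q]) || !std::isfinite(A[q]))
        stop("2D simulation produced non-finite values at step %d", s);
    }
    // mask consistency after phi moved
    for (int q = 0; q < N; ++q) if (phi[q] <= chi) { A[q] = 0.0; R[q] = 0.0; }
    if (s % rec_traj == 0) {
      // phi-weighted centroid via circular mean, then unwrap
      double cx = 0, sx = 0, cy = 0, sy = 0, m = 0;
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double w = phi[i + nx * j];
          if (w <= 0) continue;
          double ax = twoPi * (i + 0.5) / nx, ay = twoPi * (j + 0.5) / ny;
          cx += w * std::cos(ax); sx += w * std::sin(ax);
          cy += w * std::cos(ay); sy += w * std::sin(ay);
          m += w;
        }
      }
      if (m <= 0) stop("cell vanished at step %d", s);
      double xcm = Lx / twoPi * std::atan2(sx / m, cx / m);
      double ycm = Ly / twoPi * std::atan2(sy / m, cy / m);
      if (xcm < 0) xcm += Lx;
      if (ycm < 0) ycm += Ly;
      if (!ISNA(prev_x)) {
        double pwx = std::fmod(prev_x, Lx); if (pwx < 0) pwx += Lx;
        double pwy = std::fmod(prev_y, Ly); if (pwy < 0) pwy += Ly;
        double dxc = xcm - pwx;
        if (dxc > Lx / 2) dxc -= Lx; else if (dxc < -Lx / 2) dxc += Lx;
        xcm = prev_x + dxc;
        double dyc = ycm - pwy;
        if (dyc > Ly / 2) dyc -= Ly; else if (dyc < -Ly / 2) dyc += Ly;
        ycm = prev_y + dyc;
      }
      prev_x = xcm; prev_y = ycm;
      tr_t[ktr] = s * dt; tr_x[ktr] = xcm; tr_y[ktr] = ycm;
      tr_area[ktr] = m * dx * dy; tr_eta[ktr] = eta_s;
      ++ktr;
    }
    if (rec_snap > 0 && s % rec_snap == 0) {
      NumericMatrix ph(nx, ny), Am(nx, ny), Rm(nx, ny);
      std::copy(phi.begin(), phi.end(), ph.begin());
      std::copy(A.begin(), A.end(), Am.begin());
      std::copy(R.begin(), R.end(), Rm.begin());
      snaps[ksn] = List::create(_["phi"] = ph, _["A"] = Am, _["R"] = Rm,
                                _["t"] = s * dt);
      snap_t[ksn] = s * dt;
      ++ksn;
    }
  }
  if (noisy) PutRNGstate();
  NumericMatrix phf(nx, ny), Af(nx, ny), Rf(nx, ny);
  std::copy(phi.begin(), phi.end(), phf.begin());
  std::copy(A.begin(), A.end(), Af.begin());
  std::copy(R.begin(), R.end(), Rf.begin());
  return List::create(
    _["trajectory"] = DataFrame::create(_["t"] = tr_t, _["x"] = tr_x,
                                        _["y"] = tr_y, _["area"] = tr_area,
                                        _["eta"] = tr_eta),
    _["snapshots"] = snaps, _["snapshot_t"] = snap_t,
    _["final"] = List::create(_["phi"] = phf, _["A"] = Af, _["R"] = Rf),
    _["clip_count"] = (double)clip);
}
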