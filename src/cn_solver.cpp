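#include <Rcpp.h>
using namespace Rcpp;

// One theta-weighted finite-volume step of the vertical diffusion-reaction
// equation on a uniform grid (cell 0 at the surface, positive down).
// C has units of fraction per metre; Kf are the n-1 interior face
// diffusivities (m2/day); kw is the surface piston velocity (m/day);
// k1 the first-order decay rate (1/day); dt in days.
//
// The linear operator L combines diffusion (zero-flux bottom), the surface
// mass-transfer sink -kw*C0/dz acting on the top cell, and decay -k1*C.
// The update solves (I - theta*dt*L) C+ = (I + (1-theta)*dt*L) C by the
// Thomas algorithm, and returns via bio/vent the theta-consistent step
// integrals so that the caller's mass budget closes to round-off.
static void theta_step(std::vector<double>& C,
                       const std::vector<double>& Kf,
                       double dz, double dt, double k1, double kw,
                       double theta, bool do_clip,
                       double& bio, double& vent, double& clipped,
                       std::vector<double>& rhs,
                       std::vector<double>& diag,
                       std::vector<double>& work) {
  const int n = C.size();
  const double idz2 = 1.0 / (dz * dz);

  // L's tridiagonal entries: sub[i] = Kf[i-1]*idz2, sup[i] = Kf[i]*idz2,
  // diag from row sums + sinks
  // RHS = C + (1-theta)*dt*(L C)
  for (int i = 0; i < n; ++i) {
    double up = (i > 0) ? Kf[i - 1] * idz2 : 0.0;
    double dn = (i < n - 1) ? Kf[i] * idz2 : 0.0;
    double d = -(up + dn) - k1 - ((i == 0) ? kw / dz : 0.0);
    double LC = d * C[i];
    if (i > 0) LC += up * C[i - 1];
    if (i < n - 1) LC += dn * C[i + 1];
    rhs[i] = C[i] + (1.0 - theta) * dt * LC;
    diag[i] = 1.0 - theta * dt * d;
  }

  // Thomas solve with sub[i] = -theta*dt*Kf[i-1]*idz2 (symmetric structure
  // except the surface sink, which sits on the diagonal only)
  work[0] = (n > 1) ? (-theta * dt * Kf[0] * idz2) / diag[0] : 0.0;
  rhs[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double sub = -theta * dt * Kf[i - 1] * idz2;
    double m = diag[i] - sub * work[i - 1];
    if (i < n - 1) work[i] = (-theta * dt * Kf[i] * idz2) / m;
    rhs[i] = (rhs[i] - sub * rhs[i - 1]) / m;
  }
  for (int i = n - 2; i >= 0; --i) rhs[i] -= work[i] * rhs[i + 1];

  double bio_inc = 0.0, mass = 0.0;
  for (int i = 0; i < n; ++i) {
    double cbar = theta * rhs[i] + (1.0 - theta) * C[i];
    bio_inc += cbar;
  }
  bio += k1 * dt * bio_inc * dz;
  vent += kw * dt * (theta * rhs[0] + (1.0 - theta) * C[0]);

  // clip round-off negatives mass-neutrally (multiplicative rescale)
  if (do_clip) {
    double neg = 0.0, pos = 0.0;
    for (int i = 0; i < n; ++i) {
      if (rhs[i] < 0) { neg -= rhs[i]; rhs[i] = 0.0; }
      pos += rhs[i];
    }
    if (neg > 0 && pos > 0) {
      double f = (pos - neg) / pos;
      if (f > 0) for (int i = 0; i < n; ++i) rhs[i] *= f;
      clipped += neg * dz;
    }
  }
  (void)mass;
  C = std::vector<double>(rhs.begin(), rhs.end());
}

// [[Rcpp::export(name = ".cn_kernel_steps")]]
List cn_kernel_steps(NumericVector C0, NumericVector Kf, double dz, double dt,
                     int n_steps, double k1, double kw, double theta = 0.5,
                     bool clip = true) {
  const int n = C0.size();
  if (Kf.size() != n - 1) stop("Kf must have length(C0) - 1");
  std::vector<double> C(C0.begin(), C0.end());
  std::vector<double> rhs(n), diag(n), work(n);
  double bio = 0.0, vent = 0.0, clipped = 0.0;
  std::vector<double> Kfv(Kf.begin(), Kf.end());
  for (int s = 0; s < n_steps; ++s)
    theta_step(C, Kfv, dz, dt, k1, kw, theta, clip, bio, vent, clipped,
               rhs, diag, work);
  double mass = 0.0;
  for (int i = 0; i < n; ++i) mass += C[i] * dz;
  return List::create(_["C"] = NumericVector(C.begin(), C.end()),
                      _["mass"] = mass, _["biodegraded"] = bio,
                      _["ventilated"] = vent, _["clipped"] = clipped);
}

// Full depletion run with time-varying face diffusivities and surface
// piston velocity. Kf_t: (n-1) x nt matrix of face diffusivities (m2/day)
// at environment snapshot times; kw_t: per-snapshot piston velocity
// (m/day). Snapshots are assumed evenly spaced over a periodic year of
// length `period` days; coefficients are interpolated linearly at each
// step midpoint with wrap-around. Starts at day t0, runs until the
// dissolved mass drops below stop_frac (fractions of released methane) or
// max_days elapse. A few backward-Euler startup half-steps (Rannacher
// smoothing) damp the oscillatory Crank-Nicolson modes excited by the
// sharply peaked deposition profile.
// [[Rcpp::export(name = ".cn_kernel_run")]]
List cn_kernel_run(NumericVector C0, NumericMatrix Kf_t, NumericVector kw_t,
                   double period, double dz, double dt, double k1,
                   double t0, double stop_frac, double max_days,
                   int out_every = 100, double theta = 0.5,
                   int n_smooth = 20) {
  const int n = C0.size();
  const int nt = Kf_t.ncol();
  if (Kf_t.nrow() != n - 1) stop("Kf_t must have length(C0) - 1 rows");
  if (kw_t.size() != nt) stop("kw_t length must match ncol(Kf_t)");
  const double denv = period / nt;

  std::vector<double> C(C0.begin(), C0.end());
  std::vector<double> rhs(n), diag(n), work(n), Kf(n - 1);
  double bio = 0.0, vent = 0.0, clipped = 0.0;
  double t = t0;

  std::vector<double> out_t, out_mass, out_bio, out_vent;
  double mass = 0.0;
  for (int i = 0; i < n; ++i) mass += C[i] * dz;
  out_t.push_back(t); out_mass.push_back(mass);
  out_bio.push_back(bio); out_vent.push_back(vent);

  auto interp = [&](double tm, double& kw_now) {
    double tt = tm - std::floor(tm / period) * period;
    if (tt < 0) tt += period;
    if (tt >= period) tt = 0.0;
    int j = (int)std::floor(tt / denv);
    if (j >= nt) j = nt - 1;
    int j1 = (j + 1) % nt;
    double w = tt / denv - j;
    for (int i = 0; i < n - 1; ++i)
      Kf[i] = (1.0 - w) * Kf_t(i, j) + w * Kf_t(i, j1);
    kw_now = (1.0 - w) * kw_t[j] + w * kw_t[j1];
  };

  long step = 0;
  const long max_steps = (long)std::ceil(max_days / dt);
  bool terminated = false;
  // startup: n_smooth backward-Euler steps of dt/2
  for (int s = 0; s < n_smooth && step * dt < max_days; ++s) {
    double kw_now;
    interp(t + 0.25 * dt, kw_now);
    theta_step(C, Kf, dz, 0.5 * dt, k1, kw_now, 1.0, true, bio, vent,
               clipped, rhs, diag, work);
    t += 0.5 * dt;
  }
  while (step < max_steps) {
    double kw_now;
    interp(t + 0.5 * dt, kw_now);
    theta_step(C, Kf, dz, dt, k1, kw_now, theta, true, bio, vent, clipped,
               rhs, diag, work);
    t += dt;
    ++step;
    mass = 0.0;
    for (int i = 0; i < n; ++i) mass += C[i] * dz;
    if (step % out_every == 0 || mass < stop_frac) {
      out_t.push_back(t); out_mass.push_back(mass);
      out_bio.push_back(bio); out_vent.push_back(vent);
    }
    if (mass < stop_frac) { terminated = true; break; }
  }
  if (!terminated && (out_t.back() < t)) {
    out_t.push_back(t); out_mass.push_back(mass);
    out_bio.push_back(bio); out_vent.push_back(vent);
  }
  return List::create(_["time"] = NumericVector(out_t.begin(), out_t.end()),
                      _["dissolved"] = NumericVector(out_mass.begin(), out_mass.end()),
                      _["biodegraded"] = NumericVector(out_bio.begin(), out_bio.end()),
                      _["ventilated"] = NumericVector(out_vent.begin(), out_vent.end()),
                      _["C"] = NumericVector(C.begin(), C.end()),
                      _["clipped"] = clipped,
                      _["terminated"] = terminated);
}
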