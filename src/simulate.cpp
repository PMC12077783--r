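#include <Rcpp.h>
using namespace Rcpp;

// One-dimensional chain of N unit-mass, unit-radius agents joined by N-1
// viscoelastic bonds.  All dynamics are expressed in gap coordinates:
//   gap_k      = x[k+1] - x[k] - 2r          (zero-stress rest state)
//   gap_rate_k = v[k+1] - v[k]
// Tensile stiffness ka[k] acts when gap > 0, the repulsive stiffness kr when
// gap < 0, and a bond with gap > zone_max is detached (exerts no force).
//
// Kelvin-Voigt: per-bond force  F = K * gap + eta_i * gap_rate  applied as
// +F to the left member and -F to the right member (restoring).
//
// Standard Linear Solid: each bond carries a persistent acceleration state
// h ~ d2(gap)/dt2 obeying the third-order constitutive law
//   dh/dt = -(K1/tau) * gap - (K1 + K2) * gap_rate - h / tau
// and contributes forces -h/2 and +h/2 to its left/right members, so that
// paired contributions cancel (momentum conservation) while the relative
// acceleration of the pair equals h.  A detached SLS bond relaxes its
// stress memory as dh/dt = -h/tau.

struct ChainParams {
  int n;           // number of agents
  int model;       // 0 = KV, 1 = SLS
  double kr;       // compressive stiffness (shared)
  double eta_i;    // KV bond viscosity
  double k2;       // SLS series spring
  double tau;      // SLS relaxation time
  double zone_max; // detachment gap
  double r;        // agent radius
  std::vector<double> ka; // tensile stiffness per bond (n-1)
};

// accelerations a (length n) and, for SLS, dh (length n-1)
static void chain_deriv(const std::vector<double>& x,
                        const std::vector<double>& v,
                        const std::vector<double>& h,
                        const ChainParams& p,
                        std::vector<double>& a,
                        std::vector<double>& dh) {
  const int n = p.n;
  std::fill(a.begin(), a.end(), 0.0);
  for (int k = 0; k < n - 1; ++k) {
    const double gap  = x[k + 1] - x[k] - 2.0 * p.r;
    const double grate = v[k + 1] - v[k];
    const bool detached = gap > p.zone_max;
    const double k1 = (gap > 0.0) ? p.ka[k] : p.kr;
    if (p.model == 0) {
      double f = detached ? 0.0 : (k1 * gap + p.eta_i * grate);
      a[k]     += f;
      a[k + 1] -= f;
    } else {
      if (detached) {
        dh[k] = -h[k] / p.tau;
      } else {
        dh[k] = -(k1 / p.tau) * gap - (k1 + p.k2) * grate - h[k] / p.tau;
        a[k]     += -0.5 * h[k];
        a[k + 1] +=  0.5 * h[k];
      }
    }
  }
}

// Classical RK4 advance of (x, v, h) over nsteps * dt with environmental
// damping applied after each step: v *= eta_env (SLS also h *= eta_env).
// Positions are recorded after every step.  Returns bad_step = 1-based index
// of the first step producing a non-finite value, or 0 on success.
// [[Rcpp::export(name = ".relax_chain_cpp")]]
List relax_chain_cpp(NumericVector x0, NumericVector v0, NumericVector h0,
                     int nsteps, int model, NumericVector ka,
                     double kr, double eta_i, double k2, double tau,
                     double zone_max, double r, double dt, double eta_env) {
  const int n = x0.size();
  const int nb = n - 1;
  ChainParams p;
  p.n = n; p.model = model; p.kr = kr; p.eta_i = eta_i; p.k2 = k2;
  p.tau = tau; p.zone_max = zone_max; p.r = r;
  p.ka.assign(ka.begin(), ka.end());

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> h(h0.begin(), h0.end());

  NumericMatrix pos(nsteps, n);
  int bad_step = 0;

  // scratch for RK4 stages
  std::vector<double> ax(n), dh1(nb), dh2(nb), dh3(nb), dh4(nb);
  std::vector<double> a1(n), a2(n), a3(n), a4(n);
  std::vector<double> xt(n), vt(n), ht(nb);

  for (int s = 0; s < nsteps && bad_step == 0; ++s) {
    // stage 1
    chain_deriv(x, v, h, p, a1, dh1);
    // stage 2
    for (int i = 0; i < n; ++i) { xt[i] = x[i] + 0.5 * dt * v[i]; vt[i] = v[i] + 0.5 * dt * a1[i]; }
    for (int k = 0; k < nb; ++k) ht[k] = h[k] + 0.5 * dt * dh1[k];
    chain_deriv(xt, vt, ht, p, a2, dh2);
    std::vector<double> v2(vt);   // velocities used in stage-2 position slope
    // stage 3
    for (int i = 0; i < n; ++i) { xt[i] = x[i] + 0.5 * dt * v2[i]; vt[i] = v[i] + 0.5 * dt * a2[i]; }
    for (int k = 0; k < nb; ++k) ht[k] = h[k] + 0.5 * dt * dh2[k];
    chain_deriv(xt, vt, ht, p, a3, dh3);
    std::vector<double> v3(vt);
    // stage 4
    for (int i = 0; i < n; ++i) { xt[i] = x[i] + dt * v3[i]; vt[i] = v[i] + dt * a3[i]; }
    for (int k = 0; k < nb; ++k) ht[k] = h[k] + dt * dh3[k];
    chain_deriv(xt, vt, ht, p, a4, dh4);
    std::vector<double> v4(vt);

    for (int i = 0; i < n; ++i) {
      x[i] += dt / 6.0 * (v[i] + 2.0 * v2[i] + 2.0 * v3[i] + v4[i]);
      v[i] += dt / 6.0 * (a1[i] + 2.0 * a2[i] + 2.0 * a3[i] + a4[i]);
    }
    for (int k = 0; k < nb; ++k)
      h[k] += dt / 6.0 * (dh1[k] + 2.0 * dh2[k] + 2.0 * dh3[k] + dh4[k]);

    // environmental damping: retain eta_env of each velocity per timestep
    for (int i = 0; i < n; ++i) v[i] *= eta_env;
    if (model == 1) for (int k = 0; k < nb; ++k) h[k] *= eta_env;

    for (int i = 0; i < n; ++i) {
      pos(s, i) = x[i];
      if (!std::isfinite(x[i]) || !std::isfinite(v[i])) bad_step = s + 1;
    }
  }

  return List::create(_["positions"] = pos,
                      _["x"] = NumericVector(x.begin(), x.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["h"] = NumericVector(h.begin(), h.end()),
                      _["bad_step"] = bad_step);
}

// Instantaneous per-agent accelerations (and SLS per-bond dh/dt) for a given
// chain state; used by the R-level force accessors and their tests.
// [[Rcpp::export(name = ".chain_accel_cpp")]]
List chain_accel_cpp(NumericVector x, NumericVector v, NumericVector h,
                     int model, NumericVector ka, double kr, double eta_i,
                     double k2, double tau, double zone_max, double r) {
  const int n = x.size();
  ChainParams p;
  p.n = n; p.model = model; p.kr = kr; p.eta_i = eta_i; p.k2 = k2;
  p.tau = tau; p.zone_max = zone_max; p.r = r;
  p.ka.assign(ka.begin(), ka.end());
  std::vector<double> xs(x.begin(), x.end()), vs(v.begin(), v.end()),
      hs(h.begin(), h.end());
  std::vector<double> a(n), dh(std::max(n - 1, 1));
  chain_deriv(xs, vs, hs, p, a, dh);
  return List::create(_["a"] = NumericVector(a.begin(), a.end()),
                      _["dh"] = NumericVector(dh.begin(), dh.begin() + (n - 1)));
}
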