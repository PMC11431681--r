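#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Elastic forces and potential energy of a 2D spring network.
// Coincident connected masses (r == 0) are clamped to R_MIN with a fixed
// arbitrary unit direction; a measure-zero event during integration.
static const double R_MIN = 1e-9;

struct Net {
  int n, ns;
  std::vector<int> si, sj;
  std::vector<double> k, l;
  std::vector<char> movable;
};

// one fused pass: forces (optional) + energy
static double forces_energy(const Net &net, const double *x, const double *y,
                            double *fx, double *fy) {
  double V = 0.0;
  if (fx) {
    for (int m = 0; m < net.n; ++m) { fx[m] = 0.0; fy[m] = 0.0; }
  }
  for (int s = 0; s < net.ns; ++s) {
    const int i = net.si[s], j = net.sj[s];
    double dx = x[i] - x[j];
    double dy = y[i] - y[j];
    double r = std::sqrt(dx * dx + dy * dy);
    double ux, uy;
    if (r < R_MIN) {
      r = R_MIN;
      ux = 1.0; uy = 0.0;  // arbitrary fixed direction for the degenerate pair
    } else {
      ux = dx / r; uy = dy / r;
    }
    const double stretch = r - net.l[s];
    V += 0.5 * net.k[s] * stretch * stretch;
    if (fx) {
      const double f = -net.k[s] * stretch;  // > 0 pushes i away from j
      fx[i] += f * ux;
      fy[i] += f * uy;
      fx[j] -= f * ux;
      fy[j] -= f * uy;
    }
  }
  return V;
}

static Net make_net(NumericMatrix pos, IntegerVector si, IntegerVector sj,
                    NumericVector k, NumericVector l,
                    LogicalVector movable) {
  Net net;
  net.n = pos.nrow();
  net.ns = si.size();
  net.si.assign(si.begin(), si.end());
  net.sj.assign(sj.begin(), sj.end());
  net.k.assign(k.begin(), k.end());
  net.l.assign(l.begin(), l.end());
  net.movable.resize(net.n);
  for (int m = 0; m < net.n; ++m) net.movable[m] = movable.size() ? movable[m] : 1;
  return net;
}

//' @noRd
// [[Rcpp::export]]
double energy_engine(NumericMatrix pos, IntegerVector si, IntegerVector sj,
                     NumericVector k, NumericVector l) {
  Net net = make_net(pos, si, sj, k, l, LogicalVector(0));
  std::vector<double> x(net.n), y(net.n);
  for (int m = 0; m < net.n; ++m) { x[m] = pos(m, 0); y[m] = pos(m, 1); }
  return forces_energy(net, x.data(), y.data(), nullptr, nullptr);
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix forces_engine(NumericMatrix pos, IntegerVector si,
                            IntegerVector sj, NumericVector k,
                            NumericVector l) {
  Net net = make_net(pos, si, sj, k, l, LogicalVector(0));
  std::vector<double> x(net.n), y(net.n), fx(net.n), fy(net.n);
  for (int m = 0; m < net.n; ++m) { x[m] = pos(m, 0); y[m] = pos(m, 1); }
  forces_energy(net, x.data(), y.data(), fx.data(), fy.data());
  NumericMatrix F(net.n, 2);
  for (int m = 0; m < net.n; ++m) { F(m, 0) = fx[m]; F(m, 1) = fy[m]; }
  return F;
}

static double max_force(const Net &net, const double *fx, const double *fy) {
  double mx = 0.0;
  for (int m = 0; m < net.n; ++m) {
    if (!net.movable[m]) continue;
    const double f2 = fx[m] * fx[m] + fy[m] * fy[m];
    if (f2 > mx) mx = f2;
  }
  return std::sqrt(mx);
}

// Relax to mechanical equilibrium (max per-mass force < tol).
//
// method 0: explicit Euler on the overdamped flow xdot = F / gamma with an
//   adaptive step; follows the physical first-order trajectory, and the
//   returned `time` is physical.
// method 1: FIRE (fast inertial relaxation engine) -- semi-implicit Euler
//   with unit masses, velocity mixing toward the force direction, and a
//   restart whenever the power P = F.v turns negative. Much faster on
//   ill-conditioned networks; finds a critical point, but the path and
//   `time` are not the physical overdamped trajectory.
// method 2: damped second-order dynamics m vdot = F - gamma v (semi-implicit
//   Euler); the physical lightly damped system whose transients ring.
//   V is not monotone here, but the total energy V + kinetic is dissipated.
// method 3: anneal -- the damped second-order dynamics of method 2 until
//   t >= anneal_time (by when the ringing has decayed and the basin is
//   decided), then FIRE to polish convergence within that basin.
//
// Methods 0 and 1 reject (and retry at half the step, with velocity reset)
// any step that would raise V beyond a 1e-12 relative slack, so V is
// non-increasing at every accepted step.
//
// record_energy = true returns the per-accepted-step Lyapunov trace (V for
// methods 0/1, V + kinetic for method 2).
//' @noRd
// [[Rcpp::export]]
List settle_engine(NumericMatrix pos0, IntegerVector si, IntegerVector sj,
                   NumericVector k, NumericVector l, LogicalVector movable,
                   double gamma, double dt0, double dt_max, double tol,
                   double max_steps, int method, double mass,
                   double anneal_time, bool record_energy) {
  Net net = make_net(pos0, si, sj, k, l, movable);
  const int n = net.n;
  std::vector<double> x(n), y(n), xt(n), yt(n);
  std::vector<double> fx(n), fy(n), fxt(n), fyt(n);
  std::vector<double> vx(n, 0.0), vy(n, 0.0);
  for (int m = 0; m < n; ++m) { x[m] = pos0(m, 0); y[m] = pos0(m, 1); }

  bool fire = method == 1 || method == 3;
  const bool inertial = method == 2 || method == 3;
  const bool polish = method == 3;  // hand over to FIRE after anneal_time
  std::vector<double> trace;
  // FIRE schedule constants (standard values)
  const double f_inc = 1.1, f_dec = 0.5, alpha0 = 0.1, f_alpha = 0.99;
  const int n_min = 5;
  double alpha = alpha0;
  int n_pos = 0;

  double dt = dt0, dtm = dt_max;
  double dt_fire = dt0, dtm_fire = dt_max;
  if (fire || inertial) {
    // scale the step from the stiffest node: dt ~ 1/omega_max
    std::vector<double> node_k(n, 0.0);
    for (int s = 0; s < net.ns; ++s) {
      node_k[net.si[s]] += net.k[s];
      node_k[net.sj[s]] += net.k[s];
    }
    double kmax = 0.0;
    for (int m = 0; m < n; ++m)
      if (net.movable[m] && node_k[m] > kmax) kmax = node_k[m];
    if (kmax <= 0.0) kmax = 1.0;
    dt_fire = 0.25 / std::sqrt(kmax);
    dtm_fire = 10.0 * dt_fire;
    if (inertial) {
      dt = 0.1 / std::sqrt(kmax / mass);
      dtm = 10.0 * dt;
    } else {
      dt = dt_fire;
      dtm = dtm_fire;
    }
  }

  double t = 0.0;
  double V = forces_energy(net, x.data(), y.data(), fx.data(), fy.data());
  double maxF = 0.0;
  bool converged = false;
  double steps = 0.0;

  if (inertial) {
    for (;;) {
      maxF = max_force(net, fx.data(), fy.data());
      double maxv2 = 0.0;
      for (int m = 0; m < n; ++m) {
        if (!net.movable[m]) continue;
        const double v2 = vx[m] * vx[m] + vy[m] * vy[m];
        if (v2 > maxv2) maxv2 = v2;
      }
      if (record_energy) {
        double ke = 0.0;
        for (int m = 0; m < n; ++m)
          if (net.movable[m])
            ke += 0.5 * mass * (vx[m] * vx[m] + vy[m] * vy[m]);
        trace.push_back(V + ke);
      }
      if (maxF < tol && gamma * std::sqrt(maxv2) < tol) {
        converged = true;
        break;
      }
      if (polish && t >= anneal_time) break;
      if (steps >= max_steps) break;
      for (int m = 0; m < n; ++m) {
        if (!net.movable[m]) continue;
        vx[m] += dt * (fx[m] - gamma * vx[m]) / mass;
        vy[m] += dt * (fy[m] - gamma * vy[m]) / mass;
        x[m] += dt * vx[m];
        y[m] += dt * vy[m];
      }
      V = forces_energy(net, x.data(), y.data(), fx.data(), fy.data());
      if (!std::isfinite(V))
        stop("settling diverged (non-finite energy); reduce step_size");
      t += dt;
      steps += 1.0;
    }
    if (!polish || converged) {
      NumericMatrix posi(n, 2);
      for (int m = 0; m < n; ++m) { posi(m, 0) = x[m]; posi(m, 1) = y[m]; }
      return List::create(_["positions"] = posi, _["energy"] = V,
                          _["steps"] = steps, _["max_force"] = maxF,
                          _["converged"] = converged, _["time"] = t,
                          _["energy_trace"] = trace);
    }
    // hand over to FIRE: drop the residual velocity, reset the step
    for (int m = 0; m < n; ++m) { vx[m] = 0.0; vy[m] = 0.0; }
    dt = dt_fire;
    dtm = dtm_fire;
  }

  for (;;) {
    maxF = max_force(net, fx.data(), fy.data());
    if (record_energy) trace.push_back(V);
    if (maxF < tol) { converged = true; break; }
    if (steps >= max_steps) break;

    if (fire) {
      // velocity Verlet-style kick + FIRE mixing on movable masses
      double P = 0.0, vnorm2 = 0.0, fnorm2 = 0.0;
      for (int m = 0; m < n; ++m) {
        if (!net.movable[m]) continue;
        vx[m] += dt * fx[m];
        vy[m] += dt * fy[m];
        P += vx[m] * fx[m] + vy[m] * fy[m];
        vnorm2 += vx[m] * vx[m] + vy[m] * vy[m];
        fnorm2 += fx[m] * fx[m] + fy[m] * fy[m];
      }
      if (P > 0.0) {
        const double mix = alpha * std::sqrt(vnorm2 / (fnorm2 + 1e-300));
        for (int m = 0; m < n; ++m) {
          if (!net.movable[m]) continue;
          vx[m] = (1.0 - alpha) * vx[m] + mix * fx[m];
          vy[m] = (1.0 - alpha) * vy[m] + mix * fy[m];
        }
        if (++n_pos > n_min) {
          dt = std::min(dt * f_inc, dtm);
          alpha *= f_alpha;
        }
      } else {
        for (int m = 0; m < n; ++m) { vx[m] = 0.0; vy[m] = 0.0; }
        dt *= f_dec;
        alpha = alpha0;
        n_pos = 0;
      }
    }

    // propose a step, rejecting energy increases
    double Vnew = 0.0;
    int halvings = 0;
    for (;;) {
      if (fire) {
        for (int m = 0; m < n; ++m) {
          if (net.movable[m]) { xt[m] = x[m] + dt * vx[m]; yt[m] = y[m] + dt * vy[m]; }
          else { xt[m] = x[m]; yt[m] = y[m]; }
        }
      } else {
        const double a = dt / gamma;
        for (int m = 0; m < n; ++m) {
          if (net.movable[m]) { xt[m] = x[m] + a * fx[m]; yt[m] = y[m] + a * fy[m]; }
          else { xt[m] = x[m]; yt[m] = y[m]; }
        }
      }
      Vnew = forces_energy(net, xt.data(), yt.data(), fxt.data(), fyt.data());
      if (!std::isfinite(Vnew))
        stop("settling diverged (non-finite energy); reduce step_size");
      if (Vnew <= V + 1e-12 * std::fabs(V) + 1e-300) break;
      dt *= 0.5;
      if (fire) {
        // rejected inertial step: restart from a pure (small) gradient kick
        for (int m = 0; m < n; ++m) { vx[m] = dt * fx[m]; vy[m] = dt * fy[m]; }
        alpha = alpha0;
        n_pos = 0;
      }
      if (++halvings > 60)
        stop("settling step collapsed without reducing energy; the geometry may be degenerate");
    }
    x.swap(xt); y.swap(yt);
    fx.swap(fxt); fy.swap(fyt);
    t += dt;
    V = Vnew;
    steps += 1.0;
    if (!fire && halvings == 0) dt = std::min(dt * 1.25, dtm);
  }

  NumericMatrix pos(n, 2);
  for (int m = 0; m < n; ++m) { pos(m, 0) = x[m]; pos(m, 1) = y[m]; }
  return List::create(_["positions"] = pos, _["energy"] = V,
                      _["steps"] = steps, _["max_force"] = maxF,
                      _["converged"] = converged, _["time"] = t,
                      _["energy_trace"] = trace);
}
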