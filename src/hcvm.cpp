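#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time 2D harmonically confined Vicsek dynamics.
//
// Update rule (synchronous, metric neighborhoods of radius r0, strict <):
//   F_i = sum_{j: |x_j - x_i| < r0} v_j(t)  - beta * x_i(t)      (focal_once)
//   F_i = sum_{j: |x_j - x_i| < r0} (v_j(t) - beta * x_j(t))     (per_neighbor)
//   v_i(t+1) = v0 * R(xi_i) F_i / |F_i|,   xi_i ~ U[-eta/2, eta/2]
//   x_i(t+1) = x_i(t) + v_i(t+1)
// The focal particle is always its own neighbor. If |F_i| = 0 the previous
// heading is kept before the noise rotation is applied.

static inline void neighbor_sums(const std::vector<double>& x,
                                 const std::vector<double>& y,
                                 const std::vector<double>& vx,
                                 const std::vector<double>& vy,
                                 double r0, bool per_neighbor, double beta,
                                 std::vector<double>& fx,
                                 std::vector<double>& fy) {
  const int n = (int) x.size();
  const double r02 = r0 * r0;
  // self term: both conventions apply -beta x_i once for the focal particle
  for (int i = 0; i < n; ++i) {
    fx[i] = vx[i] - beta * x[i];
    fy[i] = vy[i] - beta * y[i];
  }
  // pair terms, fixed ascending-id accumulation order for reproducibility
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi;
      if (dx * dx + dy * dy < r02) {
        if (per_neighbor) {
          fx[i] += vx[j] - beta * x[j];
          fy[i] += vy[j] - beta * y[j];
          fx[j] += vx[i] - beta * x[i];
          fy[j] += vy[i] - beta * y[i];
        } else {
          fx[i] += vx[j];
          fy[i] += vy[j];
          fx[j] += vx[i];
          fy[j] += vy[i];
        }
      }
    }
  }
}

// focal_once needs the -beta*x_i applied exactly once; the self term above
// already includes it, so pair terms add velocities only.

// [[Rcpp::export]]
NumericMatrix cpp_alignment_force(NumericMatrix pos, NumericVector theta,
                                  double v0, double beta, double r0,
                                  bool per_neighbor) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), vx(n), vy(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1);
    vx[i] = v0 * std::cos(theta[i]); vy[i] = v0 * std::sin(theta[i]);
  }
  neighbor_sums(x, y, vx, vy, r0, per_neighbor, beta, fx, fy);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// [[Rcpp::export]]
List cpp_step(NumericMatrix pos, NumericVector theta, NumericVector noise,
              double v0, double beta, double r0, bool per_neighbor) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), vx(n), vy(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1);
    vx[i] = v0 * std::cos(theta[i]); vy[i] = v0 * std::sin(theta[i]);
  }
  neighbor_sums(x, y, vx, vy, r0, per_neighbor, beta, fx, fy);
  NumericMatrix npos(n, 2);
  NumericVector nth(n);
  for (int i = 0; i < n; ++i) {
    double ang;
    const double fn = std::hypot(fx[i], fy[i]);
    if (fn == 0.0) ang = theta[i]; else ang = std::atan2(fy[i], fx[i]);
    ang += noise[i];
    nth[i] = ang;
    npos(i, 0) = x[i] + v0 * std::cos(ang);
    npos(i, 1) = y[i] + v0 * std::sin(ang);
  }
  return List::create(_["positions"] = npos, _["headings"] = nth);
}

// Tangent-space image of one model step, neighborhoods frozen from the base
// state and noise rotations shared with it:
//   dF_i = sum_{j in N_i} dv_j - beta * dx_i            (focal_once)
//   dF_i = sum_{j in N_i} (dv_j - beta * dx_j)          (per_neighbor)
//   dv_i(t+1) = v0 R(xi_i) (I - Fhat Fhat^T) dF_i / |F_i|
//   dx_i(t+1) = dx_i(t) + dv_i(t+1)
static void tangent_image(const std::vector<double>& x,
                          const std::vector<double>& y,
                          const std::vector<double>& vx,
                          const std::vector<double>& vy,
                          const std::vector<double>& fx,
                          const std::vector<double>& fy,
                          std::vector<double>& dxp, std::vector<double>& dyp,
                          std::vector<double>& dvx, std::vector<double>& dvy,
                          const double* noise,
                          double v0, double beta, double r0,
                          bool per_neighbor) {
  const int n = (int) x.size();
  const double r02 = r0 * r0;
  std::vector<double> sx(n, 0.0), sy(n, 0.0);  // neighbor sums of dv (or dv - beta dx)
  for (int i = 0; i < n; ++i) {
    if (per_neighbor) { sx[i] = dvx[i] - beta * dxp[i]; sy[i] = dvy[i] - beta * dyp[i]; }
    else { sx[i] = dvx[i]; sy[i] = dvy[i]; }
  }
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi;
      if (dx * dx + dy * dy < r02) {
        if (per_neighbor) {
          sx[i] += dvx[j] - beta * dxp[j]; sy[i] += dvy[j] - beta * dyp[j];
          sx[j] += dvx[i] - beta * dxp[i]; sy[j] += dvy[i] - beta * dyp[i];
        } else {
          sx[i] += dvx[j]; sy[i] += dvy[j];
          sx[j] += dvx[i]; sy[j] += dvy[i];
        }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    double dfxi, dfyi;
    if (per_neighbor) { dfxi = sx[i]; dfyi = sy[i]; }
    else { dfxi = sx[i] - beta * dxp[i]; dfyi = sy[i] - beta * dyp[i]; }
    const double fn2 = fx[i] * fx[i] + fy[i] * fy[i];
    double nvx, nvy;
    if (fn2 == 0.0) {
      nvx = dvx[i]; nvy = dvy[i];  // degenerate force: pass perturbation through
    } else {
      const double fn = std::sqrt(fn2);
      const double hx = fx[i] / fn, hy = fy[i] / fn;
      // (I - h h^T) dF / |F|
      const double dot = hx * dfxi + hy * dfyi;
      double px = (dfxi - dot * hx) / fn;
      double py = (dfyi - dot * hy) / fn;
      const double c = std::cos(noise[i]), s = std::sin(noise[i]);
      nvx = v0 * (c * px - s * py);
      nvy = v0 * (s * px + c * py);
    }
    dvx[i] = nvx; dvy[i] = nvy;
    dxp[i] += nvx; dyp[i] += nvy;
  }
}

// [[Rcpp::export]]
List cpp_tangent_step(NumericMatrix pos, NumericVector theta,
                      NumericMatrix dpos, NumericMatrix dvel,
                      NumericVector noise, double v0, double beta, double r0,
                      bool per_neighbor) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), vx(n), vy(n), fx(n), fy(n);
  std::vector<double> dxp(n), dyp(n), dvx(n), dvy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos(i, 0); y[i] = pos(i, 1);
    vx[i] = v0 * std::cos(theta[i]); vy[i] = v0 * std::sin(theta[i]);
    dxp[i] = dpos(i, 0); dyp[i] = dpos(i, 1);
    dvx[i] = dvel(i, 0); dvy[i] = dvel(i, 1);
  }
  neighbor_sums(x, y, vx, vy, r0, per_neighbor, beta, fx, fy);
  tangent_image(x, y, vx, vy, fx, fy, dxp, dyp, dvx, dvy,
                REAL(noise), v0, beta, r0, per_neighbor);
  NumericMatrix odp(n, 2), odv(n, 2);
  for (int i = 0; i < n; ++i) {
    odp(i, 0) = dxp[i]; odp(i, 1) = dyp[i];
    odv(i, 0) = dvx[i]; odv(i, 1) = dvy[i];
  }
  return List::create(_["dpos"] = odp, _["dvel"] = odv);
}

static inline void check_finite(const std::vector<double>& x,
                                const std::vector<double>& y, int step) {
  for (size_t i = 0; i < x.size(); ++i) {
    if (!std::isfinite(x[i]) || !std::isfinite(y[i]) ||
        std::fabs(x[i]) > 1e100 || std::fabs(y[i]) > 1e100) {
      stop("run diverged at step %d: non-finite or overflowing positions", step);
    }
  }
}

// Full run. Noise angles are drawn from R's RNG stream, N per step in
// particle order, so an R-level loop drawing runif(N, -eta/2, eta/2) per step
// reproduces the trajectory exactly. record_states = false keeps only the
// center-of-mass series (for long runs at large N).
// [[Rcpp::export]]
List cpp_run(NumericMatrix pos0, NumericVector theta0, int n_steps,
             double v0, double beta, double eta, double r0,
             bool per_neighbor, bool record_states) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), th(n), vx(n), vy(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); th[i] = theta0[i];
  }
  NumericVector cmx(n_steps + 1), cmy(n_steps + 1);
  NumericVector positions, headings;
  double* P = nullptr; double* H = nullptr;
  const int T = n_steps + 1;
  if (record_states) {
    positions = NumericVector(Dimension(T, n, 2));
    headings = NumericVector(Dimension(T, n));
    P = REAL(positions); H = REAL(headings);
  }
  auto record = [&](int t) {
    double sx = 0.0, sy = 0.0;
    for (int i = 0; i < n; ++i) { sx += x[i]; sy += y[i]; }
    cmx[t] = sx / n; cmy[t] = sy / n;
    if (record_states) {
      for (int i = 0; i < n; ++i) {
        P[t + T * i] = x[i];
        P[t + T * (i + n)] = y[i];
        H[t + T * i] = th[i];
      }
    }
  };
  record(0);
  for (int t = 1; t <= n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      vx[i] = v0 * std::cos(th[i]); vy[i] = v0 * std::sin(th[i]);
    }
    neighbor_sums(x, y, vx, vy, r0, per_neighbor, beta, fx, fy);
    for (int i = 0; i < n; ++i) {
      double ang;
      const double fn2 = fx[i] * fx[i] + fy[i] * fy[i];
      if (fn2 == 0.0) ang = th[i]; else ang = std::atan2(fy[i], fx[i]);
      if (eta > 0.0) ang += eta * (unif_rand() - 0.5);
      th[i] = ang;
      x[i] += v0 * std::cos(ang);
      y[i] += v0 * std::sin(ang);
    }
    check_finite(x, y, t);
    record(t);
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix fpos(n, 2); NumericVector fth(n);
  for (int i = 0; i < n; ++i) { fpos(i, 0) = x[i]; fpos(i, 1) = y[i]; fth[i] = th[i]; }
  List out = List::create(_["cmx"] = cmx, _["cmy"] = cmy,
                          _["final_positions"] = fpos,
                          _["final_headings"] = fth);
  if (record_states) { out["positions"] = positions; out["headings"] = headings; }
  return out;
}

// Benettin co-evolution: model and tangent dynamics share each step's noise
// draws; the 4N tangent vector is renormalized to unit length every step and
// log growth factors ln(alpha_t) are accumulated after `transient` steps.
// [[Rcpp::export]]
List cpp_benettin(NumericMatrix pos0, NumericVector theta0,
                  NumericMatrix dpos0, NumericMatrix dvel0,
                  int n_steps, int transient,
                  double v0, double beta, double eta, double r0,
                  bool per_neighbor) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), th(n), vx(n), vy(n), fx(n), fy(n);
  std::vector<double> dxp(n), dyp(n), dvx(n), dvy(n), noise(n, 0.0);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); th[i] = theta0[i];
    dxp[i] = dpos0(i, 0); dyp[i] = dpos0(i, 1);
    dvx[i] = dvel0(i, 0); dvy[i] = dvel0(i, 1);
  }
  const int n_acc = n_steps - transient;
  if (n_acc < 1) stop("n_steps must exceed transient");
  NumericVector logalpha(n_acc);
  for (int t = 1; t <= n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      vx[i] = v0 * std::cos(th[i]); vy[i] = v0 * std::sin(th[i]);
    }
    neighbor_sums(x, y, vx, vy, r0, per_neighbor, beta, fx, fy);
    if (eta > 0.0) {
      for (int i = 0; i < n; ++i) noise[i] = eta * (unif_rand() - 0.5);
    }
    tangent_image(x, y, vx, vy, fx, fy, dxp, dyp, dvx, dvy,
                  noise.data(), v0, beta, r0, per_neighbor);
    for (int i = 0; i < n; ++i) {
      double ang;
      const double fn2 = fx[i] * fx[i] + fy[i] * fy[i];
      if (fn2 == 0.0) ang = th[i]; else ang = std::atan2(fy[i], fx[i]);
      ang += noise[i];
      th[i] = ang;
      x[i] += v0 * std::cos(ang);
      y[i] += v0 * std::sin(ang);
    }
    check_finite(x, y, t);
    double a2 = 0.0;
    for (int i = 0; i < n; ++i) {
      a2 += dxp[i] * dxp[i] + dyp[i] * dyp[i] + dvx[i] * dvx[i] + dvy[i] * dvy[i];
    }
    const double a = std::sqrt(a2);
    if (a == 0.0) stop("tangent vector collapsed to zero at step %d", t);
    const double inv = 1.0 / a;
    for (int i = 0; i < n; ++i) {
      dxp[i] *= inv; dyp[i] *= inv; dvx[i] *= inv; dvy[i] *= inv;
    }
    if (t > transient) logalpha[t - transient - 1] = std::log(a);
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["logalpha"] = logalpha);
}
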