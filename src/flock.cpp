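#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWO_PI = 2.0 * M_PI;

// wrap a coordinate into [0, E)  (floor-based: no libm fmod)
static inline double wrap_coord(double v, double E) {
  double w = v - E * std::floor(v / E);
  if (w >= E) w = 0.0; // rounding guard
  if (w < 0) w = 0.0;
  return w;
}

// minimal-image component in (-E/2, E/2]
static inline double min_image(double d, double E) {
  double m = d - E * std::floor(d / E); // in [0, E)
  if (m > E / 2.0) m -= E;
  return m;
}

// signed angle a with (h1 + a) mod 2pi = h2, a in (-pi, pi]
static inline double angle_to(double h1, double h2) {
  double d = h2 - h1;
  double a = d - TWO_PI * std::floor(d / TWO_PI); // in [0, 2pi)
  if (a > M_PI) a -= TWO_PI;
  return a;
}

// turn limiter T(a, m) = sign(a) * min(|a|, m)
static inline double limit_turn_c(double a, double m) {
  double mag = std::fabs(a);
  if (mag <= m) return a;
  return (a > 0) ? m : -m;
}

static inline double norm_heading(double h) {
  double w = h - TWO_PI * std::floor(h / TWO_PI);
  if (w >= TWO_PI || w < 0) w = 0.0;
  return w;
}

// One synchronous boids update.  All new headings are computed from the
// time-t state, then every boid advances step_size along its new heading.
static void step_inplace(std::vector<double> &x, std::vector<double> &y,
                         std::vector<double> &h,
                         double EW, double EH, double step_size,
                         double r_vis, double min_sep,
                         double mts, double mta, double mtc,
                         double sep_sign) {
  const int n = (int)x.size();
  std::vector<double> hn(n), hc(n), hs(n);
  for (int j = 0; j < n; ++j) { hc[j] = std::cos(h[j]); hs[j] = std::sin(h[j]); }
  const double r2 = r_vis * r_vis;
  const double hw = EW / 2.0, hh = EH / 2.0;
  // per-boid neighbourhood accumulators, filled in one symmetric pair sweep
  std::vector<double> nearest_d2(n, R_PosInf);
  std::vector<int> nearest_j(n, -1), nnb(n, 0);
  std::vector<double> scos(n, 0.0), ssin(n, 0.0), sdx(n, 0.0), sdy(n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      // positions live in [0, E), so the raw difference is in (-E, E)
      // and one conditional shift gives the minimal image
      double dx = x[j] - x[i];
      if (dx > hw) dx -= EW; else if (dx <= -hw) dx += EW;
      double dy = y[j] - y[i];
      if (dy > hh) dy -= EH; else if (dy <= -hh) dy += EH;
      double d2 = dx * dx + dy * dy;
      if (d2 <= r2) {
        ++nnb[i]; ++nnb[j];
        scos[i] += hc[j]; scos[j] += hc[i];
        ssin[i] += hs[j]; ssin[j] += hs[i];
        sdx[i] += dx; sdx[j] -= dx;
        sdy[i] += dy; sdy[j] -= dy;
        if (d2 < nearest_d2[i]) { nearest_d2[i] = d2; nearest_j[i] = j; }
        if (d2 < nearest_d2[j]) { nearest_d2[j] = d2; nearest_j[j] = i; }
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    int nn = nnb[i];
    double sum_cos = scos[i], sum_sin = ssin[i];
    double sum_dx = sdx[i], sum_dy = sdy[i];
    if (nn == 0) {
      hn[i] = norm_heading(h[i]);
      continue;
    }
    if (std::sqrt(nearest_d2[i]) < min_sep) {
      // separation only: turn away from (or, with sep_sign=+1, toward)
      // the nearest neighbour's heading
      double a = angle_to(h[i], h[nearest_j[i]]);
      hn[i] = norm_heading(h[i] + sep_sign * limit_turn_c(a, mts));
    } else {
      double turn = 0.0;
      double res = std::sqrt(sum_cos * sum_cos + sum_sin * sum_sin);
      if (res > 1e-12) {
        double mean_h = std::atan2(sum_sin, sum_cos);
        turn += limit_turn_c(angle_to(h[i], mean_h), mta);
      }
      double mdx = sum_dx / nn, mdy = sum_dy / nn;
      if (std::sqrt(mdx * mdx + mdy * mdy) > 1e-12) {
        double bearing = std::atan2(mdy, mdx);
        turn += limit_turn_c(angle_to(h[i], bearing), mtc);
      }
      hn[i] = norm_heading(h[i] + turn);
    }
  }
  for (int i = 0; i < n; ++i) {
    h[i] = hn[i];
    x[i] = wrap_coord(x[i] + step_size * std::cos(h[i]), EW);
    y[i] = wrap_coord(y[i] + step_size * std::sin(h[i]), EH);
  }
}

// [[Rcpp::export(name = ".flock_step_cpp")]]
List flock_step_cpp(NumericMatrix pos, NumericVector heading,
                    double EW, double EH, double step_size,
                    double r_vis, double min_sep,
                    double mts, double mta, double mtc,
                    double sep_sign) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), h(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); h[i] = heading[i]; }
  step_inplace(x, y, h, EW, EH, step_size, r_vis, min_sep, mts, mta, mtc, sep_sign);
  NumericMatrix out(n, 2);
  NumericVector hout(n);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; hout[i] = h[i]; }
  return List::create(_["positions"] = out, _["headings"] = hout);
}

// Run `steps` synchronous updates, storing the state at each requested
// time (time 0 = initial state).  snap_times must be sorted and unique.
// [[Rcpp::export(name = ".flock_simulate_cpp")]]
List flock_simulate_cpp(NumericMatrix pos, NumericVector heading,
                        int steps, IntegerVector snap_times,
                        double EW, double EH, double step_size,
                        double r_vis, double min_sep,
                        double mts, double mta, double mtc,
                        double sep_sign) {
  const int n = pos.nrow();
  std::vector<double> x(n), y(n), h(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); h[i] = heading[i]; }
  List snaps(snap_times.size());
  int si = 0;
  auto store = [&](int idx) {
    NumericMatrix p(n, 2);
    NumericVector hh(n);
    for (int i = 0; i < n; ++i) { p(i, 0) = x[i]; p(i, 1) = y[i]; hh[i] = h[i]; }
    snaps[idx] = List::create(_["positions"] = p, _["headings"] = hh);
  };
  if (si < snap_times.size() && snap_times[si] == 0) store(si++);
  for (int t = 1; t <= steps; ++t) {
    step_inplace(x, y, h, EW, EH, step_size, r_vis, min_sep, mts, mta, mtc, sep_sign);
    if (si < snap_times.size() && snap_times[si] == t) store(si++);
  }
  return snaps;
}
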