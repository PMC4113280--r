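// Delay-coupled Lorenz pair, integrated as a delay differential equation
// with fixed-step RK4 and linear interpolation of the delayed source
// coordinate from a per-repetition history buffer (method of steps; the
// step is far smaller than the coupling delay).
//
// System 1 (source) is an autonomous Lorenz system; system 2 (target)
// receives a delayed diffusive drive gamma * (V1(t - delta) - V2(t)) on its
// V-coordinate. Time is measured in milliseconds; `tscale` converts to the
// Lorenz system's natural time units (natural units per ms).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct State {
  double x1, y1, z1, x2, y2, z2;
};

struct Par {
  double sigma, R, b, tscale;
};

// derivative in ms time; `drive` is gamma * (y1(t - delta) - y2) or 0
inline State deriv(const State& s, const Par& p, double drive) {
  State d;
  d.x1 = p.tscale * (p.sigma * (s.y1 - s.x1));
  d.y1 = p.tscale * (s.x1 * (p.R - s.z1) - s.y1);
  d.z1 = p.tscale * (s.x1 * s.y1 - p.b * s.z1);
  d.x2 = p.tscale * (p.sigma * (s.y2 - s.x2));
  d.y2 = p.tscale * (s.x2 * (p.R - s.z2) - s.y2 + drive);
  d.z2 = p.tscale * (s.x2 * s.y2 - p.b * s.z2);
  return d;
}

inline State axpy(const State& s, const State& d, double h) {
  State r;
  r.x1 = s.x1 + h * d.x1;
  r.y1 = s.y1 + h * d.y1;
  r.z1 = s.z1 + h * d.z1;
  r.x2 = s.x2 + h * d.x2;
  r.y2 = s.y2 + h * d.y2;
  r.z2 = s.z2 + h * d.z2;
  return r;
}

}  // namespace

// [[Rcpp::export]]
List cpp_lorenz_pair(int n_reps, int n_samples, double dt_sample, double h,
                     double sigma, double R, double b, double gamma,
                     double delta, double couple_on, double couple_off,
                     double tscale, double burn) {
  NumericMatrix v1(n_reps, n_samples), v2(n_reps, n_samples);
  Par par{sigma, R, b, tscale};
  const double t0 = -burn;                       // integration starts here
  const double t_end = (n_samples - 1) * dt_sample;
  const long n_steps = (long)std::ceil((t_end - t0) / h) + 1;
  const double lag_steps = delta / h;

  RNGScope scope;
  for (int r = 0; r < n_reps; ++r) {
    State s;
    s.x1 = R::rnorm(0.0, 8.0);
    s.y1 = R::rnorm(0.0, 8.0);
    s.z1 = R::rnorm(25.0, 8.0);
    s.x2 = R::rnorm(0.0, 8.0);
    s.y2 = R::rnorm(0.0, 8.0);
    s.z2 = R::rnorm(25.0, 8.0);

    std::vector<double> hist(n_steps + 1);
    hist[0] = s.y1;

    // delayed V1 at fractional step index; history before t0 is clamped to
    // the initial value (coupling is typically off there anyway)
    auto delayed = [&](double step_idx) -> double {
      double q = step_idx - lag_steps;
      if (q <= 0.0) return hist[0];
      long i = (long)std::floor(q);
      double f = q - i;
      return hist[i] * (1.0 - f) + hist[i + 1] * f;
    };

    long next_sample = 0;
    for (long st = 0; st < n_steps; ++st) {
      double t = t0 + st * h;
      // record: sample times coincide with step times (dt_sample multiple of h)
      while (next_sample < n_samples &&
             t >= next_sample * dt_sample - 1e-9) {
        v1(r, next_sample) = s.y1;
        v2(r, next_sample) = s.y2;
        ++next_sample;
      }
      auto drive_at = [&](double tt, double step_idx, double y2_now) {
        bool on = (gamma != 0.0) && tt >= couple_on && tt < couple_off;
        return on ? gamma * (delayed(step_idx) - y2_now) : 0.0;
      };
      State k1 = deriv(s, par, drive_at(t, st, s.y2));
      State s2 = axpy(s, k1, h / 2);
      State k2 = deriv(s2, par, drive_at(t + h / 2, st + 0.5, s2.y2));
      State s3 = axpy(s, k2, h / 2);
      State k3 = deriv(s3, par, drive_at(t + h / 2, st + 0.5, s3.y2));
      State s4 = axpy(s, k3, h);
      State k4 = deriv(s4, par, drive_at(t + h, st + 1.0, s4.y2));
      s.x1 += h / 6 * (k1.x1 + 2 * k2.x1 + 2 * k3.x1 + k4.x1);
      s.y1 += h / 6 * (k1.y1 + 2 * k2.y1 + 2 * k3.y1 + k4.y1);
      s.z1 += h / 6 * (k1.z1 + 2 * k2.z1 + 2 * k3.z1 + k4.z1);
      s.x2 += h / 6 * (k1.x2 + 2 * k2.x2 + 2 * k3.x2 + k4.x2);
      s.y2 += h / 6 * (k1.y2 + 2 * k2.y2 + 2 * k3.y2 + k4.y2);
      s.z2 += h / 6 * (k1.z2 + 2 * k2.z2 + 2 * k3.z2 + k4.z2);
      hist[st + 1] = s.y1;
      if (!std::isfinite(s.y1) || !std::isfinite(s.y2) ||
          std::fabs(s.y1) > 1e6 || std::fabs(s.y2) > 1e6)
        stop("Lorenz integration diverged at t = %.1f ms in repetition %d "
             "(try a smaller step or weaker coupling)", t, r + 1);
    }
    while (next_sample < n_samples) {  // final sample at t_end
      v1(r, next_sample) = s.y1;
      v2(r, next_sample) = s.y2;
      ++next_sample;
    }
  }
  return List::create(_["V1"] = v1, _["V2"] = v2);
}
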