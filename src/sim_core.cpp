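#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Quartic potential V(x) = a*(-x(x+b)(x-c)(x-d) + e) expanded:
//   V(x) = a*(-x^4 + q3 x^3 + q2 x^2 + q1 x + e)
// with q3 = c+d-b, q2 = -(cd - bc - bd), q1 = -bcd.
static inline double pot(double x, double a, double q3, double q2,
                         double q1, double e) {
  return a * (((((-x + q3) * x + q2) * x + q1) * x) + e);
}

static inline double grad(double x, double a, double q3, double q2,
                          double q1) {
  return a * (((-4.0 * x + 3.0 * q3) * x + 2.0 * q2) * x + q1);
}

// Synchronous Euler-Maruyama integration of the community evolution
// equation  dx_i = [(1-alpha) V'(x_i) + alpha*omega*g_i] dt + eps dW_i,
// with the social term g_i = (1/m) sum_j [V(x_j)-V(x_i)](x_j-x_i) over m
// peers sampled without replacement from the other n-1 agents each step,
// a one-way no-return reflection at the valley bottom for agents that
// have already crossed it, and first-arrival latching at x >= x_arrive.
//
// Uses R's RNG (norm_rand / unif_rand): with m == n-1 the draw order is
// identical to the pure-R engine, so the engines agree to FP rounding
// (the social term here is a telescoped sum, so not bit-identical).
//
// [[Rcpp::export]]
List sim_core(NumericVector x0, double a, double b, double c, double d,
              double e, double alpha, double omega, double epsilon,
              double dt, int m, double t_max, double x_barrier,
              double x_arrive, bool no_return, int record_every) {
  const int n = x0.size();
  const double q3 = c + d - b;
  const double q2 = -(c * d - b * c - b * d);
  const double q1 = -b * c * d;
  const double sqdt = std::sqrt(dt);
  const long max_steps = (long)std::ceil(t_max / dt - 1e-9);
  const bool full_sample = (m == n - 1);
  const bool social = (alpha > 0.0 && n > 1);

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> V(n), drift(n);
  std::vector<int> crossed(n), arrived(n);
  std::vector<int> pool(n);
  NumericVector arrival(n);
  int n_arrived = 0;
  bool exited_range = false;

  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(x[i])) stop("non-finite initial position");
    crossed[i] = x[i] > x_barrier;
    arrived[i] = x[i] >= x_arrive;
    arrival[i] = arrived[i] ? 0.0 : R_PosInf;
    if (arrived[i]) ++n_arrived;
  }

  std::vector<double> rec_t;
  std::vector<double> rec_x;
  if (record_every > 0) {
    long cap = max_steps / record_every + 2;
    if (cap > 2000000L) cap = 2000000L;  // guard; grown on demand
    rec_t.reserve((size_t)cap);
    rec_x.reserve((size_t)cap * n);
    rec_t.push_back(0.0);
    for (int i = 0; i < n; ++i) rec_x.push_back(x[i]);
  }

  long step = 0;
  while (n_arrived < n && step < max_steps) {
    // potential at current (pre-step) positions; pair sums for the
    // full-sample social term, which telescopes to O(n)
    double Sv = 0.0, Sx = 0.0, Svx = 0.0;
    for (int i = 0; i < n; ++i) {
      V[i] = pot(x[i], a, q3, q2, q1, e);
      if (social && full_sample) {
        Sv += V[i];
        Sx += x[i];
        Svx += V[i] * x[i];
      }
    }
    for (int i = 0; i < n; ++i) {
      double g = 0.0;
      if (social) {
        if (full_sample) {
          // sum_j [V_j - V_i](x_j - x_i); the j = i term vanishes
          g = (Svx - x[i] * Sv - V[i] * Sx + n * V[i] * x[i]) / m;
        } else {
          // partial Fisher-Yates over the other n-1 agents
          int k = 0;
          for (int j = 0; j < n; ++j)
            if (j != i) pool[k++] = j;
          double s = 0.0;
          for (int t = 0; t < m; ++t) {
            int pick = t + (int)(unif_rand() * (n - 1 - t));
            if (pick > n - 2) pick = n - 2;
            int tmp = pool[t]; pool[t] = pool[pick]; pool[pick] = tmp;
            int j = pool[t];
            s += (V[j] - V[i]) * (x[j] - x[i]);
          }
          g = s / m;
        }
      }
      drift[i] = (1.0 - alpha) * grad(x[i], a, q3, q2, q1) +
                 alpha * omega * g;
    }
    // noise drawn in a second pass: matches rnorm(n) in the R engine
    double t_next = (double)(step + 1) * dt;
    for (int i = 0; i < n; ++i) {
      double xi = x[i] + drift[i] * dt;
      if (epsilon > 0.0) xi += epsilon * sqdt * norm_rand();
      if (no_return && arrived[i] && xi < x_barrier)
        xi = 2.0 * x_barrier - xi;  // reflect at the valley bottom
      if (!std::isfinite(xi))
        stop("non-finite position at t=%g (step too large?)", t_next);
      x[i] = xi;
      if (xi > x_barrier) crossed[i] = 1;
      if (!arrived[i] && xi >= x_arrive) {
        arrived[i] = 1;
        arrival[i] = t_next;
        ++n_arrived;
      }
      if (xi < -10.0 || xi > 15.0) exited_range = true;
    }
    ++step;
    if (record_every > 0 && (step % record_every == 0 || n_arrived == n)) {
      rec_t.push_back(t_next);
      for (int i = 0; i < n; ++i) rec_x.push_back(x[i]);
    }
  }

  NumericMatrix posmat(0, n);
  NumericVector times(0);
  if (record_every > 0) {
    int nr = (int)rec_t.size();
    times = NumericVector(rec_t.begin(), rec_t.end());
    posmat = NumericMatrix(nr, n);
    for (int r = 0; r < nr; ++r)
      for (int i = 0; i < n; ++i) posmat(r, i) = rec_x[(size_t)r * n + i];
  }

  return List::create(
      _["positions"] = NumericVector(x.begin(), x.end()),
      _["crossed"] = LogicalVector(crossed.begin(), crossed.end()),
      _["arrived"] = LogicalVector(arrived.begin(), arrived.end()),
      _["arrival_times"] = arrival,
      _["t_end"] = (double)step * dt,
      _["steps"] = (double)step,
      _["sample_times"] = times,
      _["position_matrix"] = posmat,
      _["exited_range"] = exited_range);
}
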