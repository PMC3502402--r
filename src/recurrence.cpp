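#include <Rcpp.h>
using namespace Rcpp;

// Recurrence periods of an embedded trajectory.
//
// traj: count x m matrix of embedded states (rows are states in time order).
// radius: absolute hypersphere radius (Euclidean).
//
// For every reference state p(n): walk the trajectory forward; each time it
// leaves the r-ball around p(n) and later falls inside again, the elapsed
// time (in samples) since the previous in-ball event (the reference time for
// the first recurrence, the previous re-entry thereafter) is recorded as one
// recurrence period. The scan is O(count^2 * m).
// [[Rcpp::export(name = ".recurrence_periods_cpp")]]
IntegerVector recurrence_periods_cpp(NumericMatrix traj, double radius) {
  const int n = traj.nrow(), m = traj.ncol();
  const double r2 = radius * radius;
  std::vector<int> periods;
  periods.reserve(n);
  for (int i = 0; i < n; ++i) {
    bool inside = true;      // the reference state is inside its own ball
    int last_event = i;
    for (int j = i + 1; j < n; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        const double diff = traj(j, k) - traj(i, k);
        d2 += diff * diff;
      }
      const bool in_ball = d2 <= r2;
      if (inside && !in_ball) {
        inside = false;
      } else if (!inside && in_ball) {
        periods.push_back(j - last_event);
        last_event = j;
        inside = true;
      }
    }
  }
  return wrap(periods);
}
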