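#include <Rcpp.h>
using namespace Rcpp;

// Exact (direct-method) Gillespie simulation of the single-site jump process.
//
// Events, in fixed order:
//   0 repair          X -> 0            hazard k1 * Y * X
//   1 recruit         Y -> Y + 1        hazard k2 * X + k3 * Z
//   2 dissociate      Y -> Y - 1        hazard k4 * Y
//   3 phosphorylate   Z -> Z + 1        hazard k5 * Y
//   4 dephosphorylate Z -> Z - 1        hazard k6 * Z
//   5 bind            (Z,Q) -> (Z-1,Q+1) hazard k8 * tat0 * Z
//   6 unbind          (Z,Q) -> (Z+1,Q-1) hazard k7 * Q
//
// The trajectory is sampled onto `grid` by right-continuous step sampling:
// the recorded value at time t is the state after the last event <= t.
// Uses R's RNG; the caller seeds it with set.seed().

static inline void site_propensities(const double *k, const double *e,
                                     int x, int y, int z, int q, double *a) {
  a[0] = k[0] * y * x;
  a[1] = k[1] * x + k[2] * z;
  a[2] = k[3] * y;
  a[3] = k[4] * y;
  a[4] = k[5] * z;
  a[5] = e[1] * e[2] * z;  // k8 * tat0 * Z
  a[6] = e[0] * q;         // k7 * Q
}

// [[Rcpp::export]]
IntegerMatrix ssa_site_cpp(NumericVector k, NumericVector e,
                           IntegerVector init, NumericVector grid,
                           double max_events) {
  const int ng = grid.size();
  IntegerMatrix out(ng, 4);
  int x = init[0], y = init[1], z = init[2], q = init[3];
  double t = 0.0;
  int gi = 0;
  double a[7];
  double nev = 0.0;

  for (;;) {
    site_propensities(REAL(k), REAL(e), x, y, z, q, a);
    double a0 = 0.0;
    for (int i = 0; i < 7; ++i) a0 += a[i];
    if (!R_finite(a0) || a0 < 0.0)
      stop("non-finite propensity at state X=%d Y=%d Z=%d Q=%d", x, y, z, q);
    double tnext;
    if (a0 == 0.0) {
      tnext = R_PosInf;  // absorbed: state frozen
    } else {
      double u = unif_rand();
      while (u <= 0.0) u = unif_rand();
      tnext = t - log(u) / a0;
    }
    while (gi < ng && grid[gi] < tnext) {
      out(gi, 0) = x; out(gi, 1) = y; out(gi, 2) = z; out(gi, 3) = q;
      ++gi;
    }
    if (gi >= ng || !R_finite(tnext)) break;
    // select and apply event
    double r = unif_rand() * a0, c = 0.0;
    int ev = 6;
    for (int i = 0; i < 7; ++i) { c += a[i]; if (r <= c) { ev = i; break; } }
    switch (ev) {
      case 0: x = 0; break;
      case 1: ++y; break;
      case 2: --y; break;
      case 3: ++z; break;
      case 4: --z; break;
      case 5: --z; ++q; break;
      case 6: ++z; --q; break;
    }
    t = tnext;
    if (++nev > max_events)
      stop("event budget exceeded (%g events); rates may be explosive",
           max_events);
  }
  return out;
}

// Multi-site simulation with population-level de novo damage. Each bound
// antibody molecule carries a re-damage hazard k9; a new DSB lands on a
// uniformly chosen undamaged site, so the total re-damage hazard is
// k9 * sum(Q) * (#undamaged / N), matching the mean-field term
// k9 * <Q> * (1 - <X>) of the ODE reduction. Returns per-site population
// means of (X, Y, Z, Q) on the grid.

// [[Rcpp::export]]
NumericMatrix ssa_population_cpp(NumericVector k, NumericVector e,
                                 IntegerMatrix init, NumericVector grid,
                                 double max_events) {
  const int N = init.nrow(), ng = grid.size();
  if (N < 1) stop("population must contain at least one site");
  std::vector<int> x(N), y(N), z(N), q(N);
  double SX = 0, SY = 0, SZ = 0, SQ = 0, SYX = 0;
  for (int i = 0; i < N; ++i) {
    x[i] = init(i, 0); y[i] = init(i, 1); z[i] = init(i, 2); q[i] = init(i, 3);
    SX += x[i]; SY += y[i]; SZ += z[i]; SQ += q[i]; SYX += (double)y[i] * x[i];
  }
  const double k1 = k[0], k2 = k[1], k3 = k[2], k4 = k[3], k5 = k[4],
               k6 = k[5];
  const double k7 = e[0], k8tat = e[1] * e[2], k9 = e[3];
  NumericMatrix out(ng, 4);
  double t = 0.0, nev = 0.0;
  int gi = 0;

  // pick a site with probability proportional to w(i)
  auto pick = [&](double total, int which) -> int {
    double r = unif_rand() * total, c = 0.0;
    for (int i = 0; i < N; ++i) {
      double w = 0.0;
      switch (which) {
        case 0: w = (double)y[i] * x[i]; break;  // repair
        case 1: w = x[i]; break;                 // damaged, uniform
        case 2: w = z[i]; break;                 // prop. to Z
        case 3: w = y[i]; break;                 // prop. to Y
        case 4: w = q[i]; break;                 // prop. to Q
        case 5: w = 1 - x[i]; break;             // undamaged, uniform
      }
      c += w;
      if (r <= c) return i;
    }
    return N - 1;
  };

  for (;;) {
    double a[8];
    a[0] = k1 * SYX;
    a[1] = k2 * SX + k3 * SZ;
    a[2] = k4 * SY;
    a[3] = k5 * SY;
    a[4] = k6 * SZ;
    a[5] = k8tat * SZ;
    a[6] = k7 * SQ;
    a[7] = k9 * SQ * ((double)(N - SX) / N);
    double a0 = 0.0;
    for (int i = 0; i < 8; ++i) a0 += a[i];
    if (!R_finite(a0) || a0 < 0.0) stop("non-finite population propensity");
    double tnext;
    if (a0 == 0.0) tnext = R_PosInf;
    else {
      double u = unif_rand();
      while (u <= 0.0) u = unif_rand();
      tnext = t - log(u) / a0;
    }
    while (gi < ng && grid[gi] < tnext) {
      out(gi, 0) = SX / N; out(gi, 1) = SY / N;
      out(gi, 2) = SZ / N; out(gi, 3) = SQ / N;
      ++gi;
    }
    if (gi >= ng || !R_finite(tnext)) break;
    double r = unif_rand() * a0, c = 0.0;
    int ev = 7;
    for (int i = 0; i < 8; ++i) { c += a[i]; if (r <= c) { ev = i; break; } }
    int i;
    switch (ev) {
      case 0:  // repair
        i = pick(SYX, 0); x[i] = 0; SX -= 1; SYX -= y[i];
        break;
      case 1:  // recruit: DSB-driven or gamma-H2AX-driven
        if (unif_rand() * a[1] <= k2 * SX) i = pick(SX, 1);
        else i = pick(SZ, 2);
        y[i] += 1; SY += 1; SYX += x[i];
        break;
      case 2:  // dissociate
        i = pick(SY, 3); y[i] -= 1; SY -= 1; SYX -= x[i];
        break;
      case 3:  // phosphorylate
        i = pick(SY, 3); z[i] += 1; SZ += 1;
        break;
      case 4:  // dephosphorylate
        i = pick(SZ, 2); z[i] -= 1; SZ -= 1;
        break;
      case 5:  // bind
        i = pick(SZ, 2); z[i] -= 1; q[i] += 1; SZ -= 1; SQ += 1;
        break;
      case 6:  // unbind
        i = pick(SQ, 4); z[i] += 1; q[i] -= 1; SZ += 1; SQ -= 1;
        break;
      case 7:  // de novo DSB on an undamaged site
        i = pick((double)(N - SX), 5); x[i] = 1; SX += 1; SYX += y[i];
        break;
    }
    t = tnext;
    if (++nev > max_events)
      stop("event budget exceeded (%g events); rates may be explosive",
           max_events);
  }
  return out;
}
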