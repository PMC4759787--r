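/* Right-hand sides of the moment-closure ODE systems, in the compiled-code
 * interface of deSolve (initfunc + derivs called through dllname lookup).
 *
 * Parameter vector (set via dsb_initmod):
 *   0..5  k1..k6      6 k7   7 k8   8 tat0   9 k9
 *
 * Independence ("naive") closure, state (mX, mY, mZ, mQ):
 *   mX' = -k1 mX mY + k9 mQ (1 - mX)
 *   mY' =  k2 mX + k3 mZ - k4 mY
 *   mZ' =  k5 mY - k6 mZ - k8 tat0 mZ + k7 mQ
 *   mQ' =  k8 tat0 mZ - k7 mQ
 * With k7..k9 = 0 and mQ(0) = 0 this is the unextended closure; the
 * de novo damage term k9 mQ (1 - mX) is the mean-field Auger extension.
 *
 * Conditional-mean closure with
 *   p = P(X=1), u = E[Y|X=1], v = E[Z|X=1], b = E[Q|X=1],
 *   w = E[Y|X=0], s = E[Z|X=0], c = E[Q|X=0].
 * Dropping conditional (co)variances gives
 *   p' = -k1 p u
 *   u' =  k2 + k3 v - k4 u
 *   v' =  k5 u - k6 v - k8 tat0 v + k7 b
 *   b' =  k8 tat0 v - k7 b
 * with repair transferring sites carrying their current means (u, v, b)
 * into the X = 0 pool. The repaired-pool equations are integrated in the
 * unnormalized moments W = (1-p) w, S = (1-p) s, C = (1-p) c, which are
 * smooth even while the pool is empty (no division by 1-p):
 *   W' = k3 S - k4 W + k1 p u^2
 *   S' = k5 W - k6 S - k8 tat0 S + k7 C + k1 p u v
 *   C' = k8 tat0 S - k7 C + k1 p u b
 * State vector: (p, u, v, b, W, S, C). Unconditional means follow as
 * mY = p u + W, mZ = p v + S, mQ = p b + C.
 */

static double parms[10];

void dsb_initmod(void (*odeparms)(int *, double *)) {
  int n = 10;
  odeparms(&n, parms);
}

void dsb_derivs_naive(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip) {
  const double k1 = parms[0], k2 = parms[1], k3 = parms[2], k4 = parms[3],
               k5 = parms[4], k6 = parms[5], k7 = parms[6],
               k8tat = parms[7] * parms[8], k9 = parms[9];
  const double mX = y[0], mY = y[1], mZ = y[2], mQ = y[3];
  ydot[0] = -k1 * mX * mY + k9 * mQ * (1.0 - mX);
  ydot[1] = k2 * mX + k3 * mZ - k4 * mY;
  ydot[2] = k5 * mY - k6 * mZ - k8tat * mZ + k7 * mQ;
  ydot[3] = k8tat * mZ - k7 * mQ;
}

void dsb_derivs_cond(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip) {
  const double k1 = parms[0], k2 = parms[1], k3 = parms[2], k4 = parms[3],
               k5 = parms[4], k6 = parms[5], k7 = parms[6],
               k8tat = parms[7] * parms[8];
  const double p = y[0], u = y[1], v = y[2], b = y[3], W = y[4], S = y[5],
               C = y[6];
  const double flux = k1 * p * u;
  ydot[0] = -flux;
  ydot[1] = k2 + k3 * v - k4 * u;
  ydot[2] = k5 * u - k6 * v - k8tat * v + k7 * b;
  ydot[3] = k8tat * v - k7 * b;
  ydot[4] = k3 * S - k4 * W + flux * u;
  ydot[5] = k5 * W - k6 * S - k8tat * S + k7 * C + flux * v;
  ydot[6] = k8tat * S - k7 * C + flux * b;
}
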