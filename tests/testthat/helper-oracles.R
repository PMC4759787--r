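# Shared fixtures and independent oracles for the test suite.

# A deliberately small parameter set: same network shape, event counts low
# enough for brute-force oracles. Stable: k3*k5 = 1.2 < k4*k6 = 7.5.
small_rates <- function() dsb_rates(k1 = 0.5, k2 = 4, k3 = 0.6, k4 = 3,
                                    k5 = 2, k6 = 2.5)

small_ext <- function(tat0 = 0.5) ext_rates(k7 = 1.5, k8 = 2, tat0 = tat0)

# Moderately large molecule counts (peak pATM ~ 25, peak gamma-H2AX ~ 13):
# big enough for the mean-field closures to be accurate, small enough for
# fast ensembles. Stable: k3*k5 = 1.2 < k4*k6 = 7.5.
medium_rates <- function() dsb_rates(k1 = 0.02, k2 = 60, k3 = 0.6, k4 = 3,
                                     k5 = 2, k6 = 2.5)

# Brute-force solution of the master equation on a truncated state space
# (X in {0,1}, 0 <= Y <= ymax, 0 <= Z <= zmax), integrating dP/dt = Q P
# with deSolve. Events leaving the truncation box are switched off, so the
# result is exact for processes that stay inside it with high probability.
# Returns the mean trajectory of (X, Y, Z) on `times`.
master_equation_means <- function(rates, times, ymax, zmax,
                                  init = c(X = 1, Y = 0, Z = 0)) {
  nx <- 2L; ny <- ymax + 1L; nz <- zmax + 1L
  n <- nx * ny * nz
  id <- function(x, y, z) 1L + x + nx * (y + ny * z)
  k <- as.numeric(rates)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(from, to, rate) {
    ii <<- c(ii, to, from); jj <<- c(jj, from, from); vv <<- c(vv, rate, -rate)
  }
  for (x in 0:1) for (y in 0:ymax) for (z in 0:zmax) {
    s <- id(x, y, z)
    if (x == 1 && y > 0) add(s, id(0, y, z), k[1] * y)           # repair
    if (y < ymax) add(s, id(x, y + 1, z), k[2] * x + k[3] * z)   # recruit
    if (y > 0) add(s, id(x, y - 1, z), k[4] * y)                 # dissociate
    if (z < zmax) add(s, id(x, y, z + 1), k[5] * y)              # phosphorylate
    if (z > 0) add(s, id(x, y, z - 1), k[6] * z)                 # dephosphorylate
  }
  Q <- matrix(0, n, n)
  for (e in seq_along(vv)) Q[ii[e], jj[e]] <- Q[ii[e], jj[e]] + vv[e]
  p0 <- numeric(n)
  p0[id(init[["X"]], init[["Y"]], init[["Z"]])] <- 1
  sol <- deSolve::ode(p0, times, function(t, p, parms) list(Q %*% p),
                      atol = 1e-10, rtol = 1e-8)
  grid <- expand.grid(x = 0:1, y = 0:ymax, z = 0:zmax)
  P <- sol[, -1, drop = FALSE]
  data.frame(time_h = sol[, 1],
             mX = as.numeric(P %*% grid$x),
             mY = as.numeric(P %*% grid$y),
             mZ = as.numeric(P %*% grid$z))
}

# Independent R-coded integration of the conditional-mean closure in the
# unnormalized-moment form, used to cross-check the compiled solver.
r_conditional_solution <- function(rates, times, ext = NULL) {
  k <- as.numeric(rates)
  k7 <- if (is.null(ext)) 0 else ext[["k7"]]
  k8t <- if (is.null(ext)) 0 else ext[["k8"]] * ext[["tat0"]]
  rhs <- function(t, y, parms) {
    p <- y[1]; u <- y[2]; v <- y[3]; b <- y[4]; W <- y[5]; S <- y[6]
    C <- y[7]
    flux <- k[1] * p * u
    list(c(-flux,
           k[2] + k[3] * v - k[4] * u,
           k[5] * u - k[6] * v - k8t * v + k7 * b,
           k8t * v - k7 * b,
           k[3] * S - k[4] * W + flux * u,
           k[5] * W - k[6] * S - k8t * S + k7 * C + flux * v,
           k8t * S - k7 * C + flux * b))
  }
  out <- deSolve::ode(c(1, 0, 0, 0, 0, 0, 0), times, rhs, NULL,
                      atol = 1e-12, rtol = 1e-10)
  data.frame(time_h = out[, 1], mX = out[, 2],
             mY = out[, 2] * out[, 3] + out[, 6],
             mZ = out[, 2] * out[, 4] + out[, 7],
             mQ = out[, 2] * out[, 5] + out[, 8])
}

# Classical fixed-step fourth-order Runge-Kutta integrator for step-halving
# oracles; f(y) must return dy/dt.
rk4_integrate <- function(f, y0, t_end, n_steps) {
  h <- t_end / n_steps
  y <- y0
  for (i in seq_len(n_steps)) {
    p1 <- f(y); p2 <- f(y + h / 2 * p1); p3 <- f(y + h / 2 * p2)
    p4 <- f(y + h * p3)
    y <- y + h / 6 * (p1 + 2 * p2 + 2 * p3 + p4)
  }
  y
}
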