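#' Mean-field right-hand sides of the moment-closure systems
#'
#' Reference R implementations of the closed mean equations derived from the
#' single-site master equation. [solve_moments()] integrates compiled
#' versions of the same systems; these functions document the equations and
#' serve as an independent cross-check.
#'
#' `rhs_naive()` is the independence ("ad hoc") closure, which factorizes
#' the damage-repair correlation, `<XY> = <X><Y>`:
#' \deqn{mX' = -k_1 mX\, mY,\quad mY' = k_2 mX + k_3 mZ - k_4 mY,\quad
#'       mZ' = k_5 mY - k_6 mZ.}
#'
#' `rhs_conditional()` closes at the level of conditional means
#' `u = E[Y|X=1]`, `v = E[Z|X=1]`, `w = E[Y|X=0]`, `s = E[Z|X=0]` by
#' neglecting conditional (co)variances. The damaged-branch means obey the
#' mean equations with `mX = 1`; repair transfers sites carrying their
#' current means `(u, v)` into the repaired pool at flux
#' `phi = k1 * u * p / (1 - p)`:
#' \deqn{p' = -k_1 p u,\quad u' = k_2 + k_3 v - k_4 u,\quad
#'       v' = k_5 u - k_6 v,}
#' \deqn{w' = k_3 s - k_4 w + \phi (u - w),\quad
#'       s' = k_5 w - k_6 s + \phi (v - s).}
#' Unconditional means follow from the mixture identities
#' `mY = p u + (1-p) w`, `mZ = p v + (1-p) s`.
#'
#' `rhs_antibody()` augments either closure with reversible sequestration of
#' free gamma-H2AX by the anti-gamma-H2AX-TAT antibody into an inert bound
#' pool `Q`: `mQ' = k8 * tat0 * mZ - k7 * mQ` with the matching sink in
#' `mZ'`. With `tat0 = 0` and `mQ(0) = 0` it coincides with the unextended
#' closure.
#'
#' `rhs_auger()` (independence closure only) adds mean-field de novo damage
#' by Auger electrons from In-111 on the bound antibody: undamaged sites are
#' re-damaged at rate `k9 * mQ`, giving the extra term
#' `+ k9 * mQ * (1 - mX)` in `mX'`. With `k9 = 0` it equals
#' `rhs_antibody()`.
#'
#' @param m named numeric state. For the naive family:
#'   `c(mX=, mY=, mZ=, mQ=)` (`mQ` optional without extension). For the
#'   conditional family: `c(p=, u=, v=, w=, s=, b=, c=)` where `b`, `c` are
#'   the conditional means of `Q` (optional without extension).
#' @param rates a [dsb_rates()] object.
#' @param ext an [ext_rates()] object (antibody/Auger variants).
#' @return Named numeric vector of time derivatives (per hour).
#' @seealso [solve_moments()]
#' @examples
#' rhs_naive(c(mX = 1, mY = 0, mZ = 0), mcf7_rates())
#' @export
rhs_naive <- function(m, rates) {
  rates <- as_dsb_rates(rates)
  d <- c(mX = -rates[["k1"]] * m[["mX"]] * m[["mY"]],
         mY = rates[["k2"]] * m[["mX"]] + rates[["k3"]] * m[["mZ"]] -
              rates[["k4"]] * m[["mY"]],
         mZ = rates[["k5"]] * m[["mY"]] - rates[["k6"]] * m[["mZ"]])
  d
}

#' @rdname rhs_naive
#' @export
rhs_conditional <- function(m, rates) {
  rates <- as_dsb_rates(rates)
  p <- m[["p"]]; u <- m[["u"]]; v <- m[["v"]]; w <- m[["w"]]; s <- m[["s"]]
  du <- rates[["k2"]] + rates[["k3"]] * v - rates[["k4"]] * u
  dv <- rates[["k5"]] * u - rates[["k6"]] * v
  q <- 1 - p
  if (q < 1e-9) {
    dw <- du; ds <- dv
  } else {
    phi <- rates[["k1"]] * u * p / q
    dw <- rates[["k3"]] * s - rates[["k4"]] * w + phi * (u - w)
    ds <- rates[["k5"]] * w - rates[["k6"]] * s + phi * (v - s)
  }
  c(p = -rates[["k1"]] * p * u, u = du, v = dv, w = dw, s = ds)
}

#' @rdname rhs_naive
#' @export
rhs_antibody <- function(m, rates, ext) {
  rates <- as_dsb_rates(rates)
  ext <- as_dsb_ext(ext)
  bindr <- ext[["k8"]] * ext[["tat0"]]
  if (all(c("mX", "mY", "mZ") %in% names(m))) {
    mQ <- if ("mQ" %in% names(m)) m[["mQ"]] else 0
    d <- rhs_naive(m[c("mX", "mY", "mZ")], rates)
    ex <- bindr * m[["mZ"]] - ext[["k7"]] * mQ
    c(d[c("mX", "mY")], mZ = d[["mZ"]] - ex, mQ = ex)
  } else {
    b <- if ("b" %in% names(m)) m[["b"]] else 0
    cc <- if ("c" %in% names(m)) m[["c"]] else 0
    d <- rhs_conditional(m[c("p", "u", "v", "w", "s")], rates)
    p <- m[["p"]]; q <- 1 - p
    exv <- bindr * m[["v"]] - ext[["k7"]] * b
    exs <- bindr * m[["s"]] - ext[["k7"]] * cc
    db <- exv
    if (q < 1e-9) {
      dc <- db
    } else {
      phi <- rates[["k1"]] * m[["u"]] * p / q
      dc <- exs + phi * (b - cc)
    }
    c(p = d[["p"]], u = d[["u"]], v = d[["v"]] - exv,
      w = d[["w"]], s = d[["s"]] - exs, b = db, c = dc)
  }
}

#' @rdname rhs_naive
#' @export
rhs_auger <- function(m, rates, ext) {
  rates <- as_dsb_rates(rates)
  ext <- as_dsb_ext(ext)
  if (!all(c("mX", "mY", "mZ") %in% names(m)))
    stop("the Auger extension is formulated on the independence closure",
         call. = FALSE)
  d <- rhs_antibody(m, rates, ext)
  mQ <- if ("mQ" %in% names(m)) m[["mQ"]] else 0
  d[["mX"]] <- d[["mX"]] + ext[["k9"]] * mQ * (1 - m[["mX"]])
  d
}

#' Integrate a moment-closure system
#'
#' Solves the chosen mean-field reduction with the stiff-capable adaptive
#' integrator `lsoda` (compiled right-hand sides). The conditional-mean
#' closure is the more accurate reduction and the default; the Auger
#' extension (`k9 > 0`) is formulated on the independence closure.
#'
#' @param rates a [dsb_rates()] object.
#' @param ext optional [ext_rates()]; `NULL` for the unextended model.
#' @param closure `"conditional"` or `"naive"`.
#' @param init named initial means. Defaults to one fresh DSB and no bound
#'   molecules: `mX = 1` (and all molecule counts 0). For the conditional
#'   closure the repaired-branch means are initialized at the damaged-branch
#'   means when `p(0) = 1` (the empty pool tracks its donor).
#' @param times output time grid (hours), starting at 0.
#' @param atol,rtol absolute and relative integration tolerances.
#' @return A `dsb_ode`: data frame with columns `time_h, mX, mY, mZ, mQ`
#'   (plus the conditional branch means `u, v, w, s, b, c` when applicable),
#'   with solver diagnostics in attributes. Unconditional means of the
#'   conditional closure are reported through the mixture identities.
#' @examples
#' sol <- solve_moments(mcf7_rates(), times = seq(0, 24, by = 0.1))
#' plot(sol)
#' @export
solve_moments <- function(rates, ext = NULL,
                          closure = c("conditional", "naive"),
                          init = NULL, times = seq(0, 24, by = 0.1),
                          atol = 1e-10, rtol = 1e-8) {
  rates <- as_dsb_rates(rates)
  ext <- as_dsb_ext(ext)
  closure <- match.arg(closure)
  check_grid(times)
  if (atol <= 0 || rtol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  e <- if (is.null(ext)) c(k7 = 0, k8 = 0, tat0 = 0, k9 = 0)
       else ext[c("k7", "k8", "tat0", "k9")]
  if (closure == "conditional" && e[["k9"]] > 0)
    stop("the Auger extension (k9 > 0) is formulated on the independence ",
         "closure; use closure = \"naive\"", call. = FALSE)
  parms <- c(as.numeric(rates), as.numeric(e))

  if (closure == "naive") {
    y0 <- c(mX = 1, mY = 0, mZ = 0, mQ = 0)
    if (!is.null(init)) y0[names(init)] <- init
    out <- deSolve::ode(y = y0, times = as.numeric(times),
                        func = "dsb_derivs_naive", parms = parms,
                        dllname = "dsbkin", initfunc = "dsb_initmod",
                        atol = atol, rtol = rtol, maxsteps = 50000)
    sol <- as.data.frame(out)
    names(sol)[1] <- "time_h"
  } else {
    cm <- c(p = 1, u = 0, v = 0, b = 0, w = 0, s = 0, c = 0)
    if (!is.null(init)) {
      nm <- names(init)
      nm[nm == "mX"] <- "p"
      cm[nm] <- init
    }
    # integrate the repaired pool in unnormalized moments (W, S, C): smooth
    # even while the pool is empty
    q0 <- 1 - cm[["p"]]
    y0 <- c(p = cm[["p"]], u = cm[["u"]], v = cm[["v"]], b = cm[["b"]],
            W = q0 * cm[["w"]], S = q0 * cm[["s"]], C = q0 * cm[["c"]])
    out <- deSolve::ode(y = y0, times = as.numeric(times),
                        func = "dsb_derivs_cond", parms = parms,
                        dllname = "dsbkin", initfunc = "dsb_initmod",
                        atol = atol, rtol = rtol, maxsteps = 50000)
    sol <- as.data.frame(out)
    names(sol)[1] <- "time_h"
    p <- sol$p; q <- 1 - p
    sol$mX <- p
    sol$mY <- p * sol$u + sol$W
    sol$mZ <- p * sol$v + sol$S
    sol$mQ <- p * sol$b + sol$C
    # conditional means of the repaired pool (donor means while empty)
    sol$w <- ifelse(q > 1e-12, sol$W / q, sol$u)
    sol$s <- ifelse(q > 1e-12, sol$S / q, sol$v)
    sol$c <- ifelse(q > 1e-12, sol$C / q, sol$b)
  }
  structure(sol, class = c("dsb_ode", "data.frame"),
            closure = closure, rates = rates, ext = ext,
            atol = atol, rtol = rtol,
            istate = attr(out, "istate"), rstate = attr(out, "rstate"))
}

#' Damage persistence: area under the expected-DSB curve
#'
#' Integrates the expected number of unrepaired DSBs over `[0, t_end]` by
#' trapezoidal quadrature on the solution grid, scaled to a population of
#' `n_dsb0` initial DSBs. Used to compare damage burden across In-111
#' specific activities.
#'
#' @param sol a `dsb_ode` from [solve_moments()] (or any data frame with
#'   `time_h` and `mX` columns).
#' @param n_dsb0 number of DSBs per cell at time 0.
#' @param t_end upper integration limit (hours); must lie within the
#'   solution span.
#' @return Scalar AUC in DSB-hours.
#' @examples
#' sol <- solve_moments(mcf7_rates(), times = seq(0, 24, by = 0.1))
#' persistence_auc(sol, n_dsb0 = 160)
#' @export
persistence_auc <- function(sol, n_dsb0 = 160, t_end = 24) {
  t <- sol$time_h
  x <- sol$mX
  if (t_end > max(t) + 1e-9)
    stop("t_end lies beyond the solution span", call. = FALSE)
  keep <- t <= t_end + 1e-12
  tt <- t[keep]; xx <- x[keep]
  if (max(tt) < t_end) {  # close the last partial interval by interpolation
    xe <- stats::approx(t, x, xout = t_end)$y
    tt <- c(tt, t_end); xx <- c(xx, xe)
  }
  n_dsb0 * sum(diff(tt) * (utils::head(xx, -1) + utils::tail(xx, -1)) / 2)
}

#' Time for the expected DSB signal to halve
#'
#' Locates the first time at which the mean damage indicator falls to half
#' its initial value, by linear interpolation between grid points.
#'
#' @param sol a `dsb_ode` (or any data frame with `time_h` and `mX`).
#' @return Half-repair time in hours (`NA` if the signal never halves on
#'   the solved span).
#' @examples
#' sol <- solve_moments(mcf7_rates(), times = seq(0, 24, by = 0.01))
#' half_repair_time(sol)
#' @export
half_repair_time <- function(sol) {
  t <- sol$time_h
  x <- sol$mX
  target <- x[1] / 2
  i <- which(x <= target)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  t[i - 1] + (t[i] - t[i - 1]) * (x[i - 1] - target) / (x[i - 1] - x[i])
}

#' @export
print.dsb_ode <- function(x, ...) {
  cat(sprintf("Moment-closure solution (%s closure), %d points on [0, %g] h\n",
              attr(x, "closure"), nrow(x), max(x$time_h)))
  print.data.frame(utils::head(as.data.frame(x)[, c("time_h", "mX", "mY",
                                                    "mZ", "mQ")], 4),
                   digits = 4)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' @export
plot.dsb_ode <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$time_h, x$mX, type = "l", xlab = "time (h)",
       ylab = expression(paste("mean DSB indicator ", langle * X * rangle)),
       ylim = c(0, 1), ...)
  tot <- x$mZ + x$mQ
  plot(x$time_h, x$mZ, type = "l", xlab = "time (h)",
       ylab = expression(paste("mean ", gamma, "H2AX molecules")),
       ylim = c(0, max(tot) * 1.05), ...)
  if (any(x$mQ > 0)) {
    graphics::lines(x$time_h, tot, lty = 2)
    graphics::legend("topright", legend = c("free Z", "total Z + Q"),
                     lty = 1:2, bty = "n")
  }
  invisible(x)
}
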