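#' Observation map: mean gamma-H2AX count to per-cell focus count
#'
#' A mature focus is taken to contain `Zmax` gamma-H2AX molecules, so a
#' population of `n_dsb0` initial DSBs with mean per-site gamma-H2AX count
#' `mZ` displays `n_dsb0 * mZ / Zmax` foci per cell. When the antibody
#' extension is active and bound gamma-H2AX is counted, pass the total
#' `mZ + mQ`.
#'
#' @param mZ mean gamma-H2AX molecules per site (vector over time).
#' @param n_dsb0 DSBs per cell at time 0.
#' @param Zmax gamma-H2AX molecules per mature focus.
#' @return Focus counts per cell (same length as `mZ`).
#' @examples
#' foci_from_model(1000, n_dsb0 = 160, Zmax = 1000)  # one focus per DSB
#' @export
foci_from_model <- function(mZ, n_dsb0 = 160, Zmax = 1000) {
  if (Zmax <= 0) stop("Zmax must be positive", call. = FALSE)
  n_dsb0 * mZ / Zmax
}

#' Reference DSB series for the H2AX-deficient condition
#'
#' DSB repair without H2AX proceeds roughly ten times slower. In the absence
#' of explicit measurements the reference series is obtained by dilating the
#' observed DSB time course: `chi1_bar(t) = chi1(t / slowdown)`, with linear
#' interpolation between observations and the end values held outside the
#' observed range. The initial damage is unchanged:
#' `chi1_bar(0) = chi1(0)`.
#'
#' @param time_h observation times (hours).
#' @param chi1 observed mean DSB counts at `time_h`.
#' @param slowdown fold-slowdown of repair without H2AX.
#' @param at times at which to evaluate the dilated series (default
#'   `time_h`).
#' @return Numeric vector `chi1_bar` evaluated at `at`.
#' @examples
#' no_h2ax_reference(c(0, 10), c(160, 80), slowdown = 10, at = c(0, 10))
#' @export
no_h2ax_reference <- function(time_h, chi1, slowdown = 10, at = time_h) {
  if (length(time_h) == 0L) stop("empty chi1 series", call. = FALSE)
  if (slowdown <= 0) stop("slowdown must be positive", call. = FALSE)
  ok <- !is.na(chi1)
  if (!any(ok)) stop("chi1 is all missing", call. = FALSE)
  if (sum(ok) == 1L) return(rep(chi1[ok], length(at)))
  stats::approx(time_h[ok], chi1[ok], xout = at / slowdown, rule = 2)$y
}

# Model curves on a time grid for the three observation channels.
# Returns chi1_hat = n_dsb0 * mX, chi2_hat = foci(mZ [+ mQ]) and
# chi1_bar_hat = n_dsb0 * mX with k5 = 0, plus the peak mY of the full
# solution (for the Ymax excursion penalty).
model_observables <- function(rates, times, ext = NULL,
                              closure = "conditional",
                              constants = assumed_constants(),
                              n_dsb0 = 160, count_bound = TRUE,
                              dense = 101L) {
  grid <- sort(unique(c(times, seq(0, max(times), length.out = dense))))
  full <- suppressWarnings(
    solve_moments(rates, ext = ext, closure = closure, times = grid))
  r0 <- as_dsb_rates(rates)
  r0[["k5"]] <- 0
  bar <- suppressWarnings(
    solve_moments(r0, ext = ext, closure = closure, times = grid))
  # a stiff blow-up returns a truncated or non-finite solution: reject it
  if (nrow(full) < length(grid) || nrow(bar) < length(grid) ||
      !all(is.finite(full$mX)) || !all(is.finite(full$mZ)) ||
      !all(is.finite(bar$mX)))
    stop("integration failed over the observation span", call. = FALSE)
  idx <- match(times, grid)
  mZ <- if (count_bound) full$mZ + full$mQ else full$mZ
  out <- data.frame(
    time_h = times,
    chi1_hat = n_dsb0 * full$mX[idx],
    chi2_hat = foci_from_model(mZ[idx], n_dsb0, constants[["Zmax"]]),
    chi1_bar_hat = n_dsb0 * bar$mX[idx]
  )
  attr(out, "peak_mY") <- max(full$mY)
  out
}

# Per-channel normalizer: the first positive observation; falls back to the
# series maximum (all-zero leading samples), then to 1.
channel_norm <- function(x) {
  x <- x[!is.na(x)]
  pos <- x[x > 0]
  if (length(pos)) pos[1] else if (length(x) && max(x) > 0) max(x) else 1
}

#' Least-squares objective for rate-constant estimation
#'
#' Sum of squared residuals over three channels: the DSB series
#' (`chi1` vs `n_dsb0 * mX`), the focus series (`chi2` vs
#' [foci_from_model()]), and the H2AX-deficient reference
#' (`chi1_bar` vs `n_dsb0 * mX` with `k5 = 0`). Each channel is divided by
#' the square of its first positive observation so that channels of
#' different units contribute comparably. Peak pATM excursions beyond
#' `Ymax` are discouraged by a smooth quadratic penalty. Integrator
#' failures and negative parameters return a large finite value so that
#' direct-search optimizers can proceed.
#'
#' @param params rate constants: a [dsb_rates()] or named numeric `k1..k6`.
#' @param data a `dsb_obs` (see [dsb_observations()]).
#' @param constants an [assumed_constants()] set.
#' @param closure moment closure used for both model solves
#'   (`"conditional"` or `"naive"`).
#' @param ext optional [ext_rates()] (antibody condition).
#' @param n_dsb0 DSBs per cell at time 0; defaults to the observation
#'   attribute, else 160.
#' @param slowdown fold-slowdown used to derive `chi1_bar` when the data do
#'   not carry it.
#' @param count_bound count antibody-bound gamma-H2AX in the focus channel.
#' @return Non-negative scalar.
#' @examples
#' obs <- dsb_observations(c(0, 1, 4), c(160, 60, 5), c(0, 90, 10))
#' dsb_objective(mcf7_rates(), obs)
#' @export
dsb_objective <- function(params, data, constants = assumed_constants(),
                          closure = c("conditional", "naive"), ext = NULL,
                          n_dsb0 = NULL, slowdown = 10, count_bound = TRUE) {
  closure <- match.arg(closure)
  data <- as_dsb_obs(data)
  if (is.null(n_dsb0))
    n_dsb0 <- if (!is.null(attr(data, "n_dsb0"))) attr(data, "n_dsb0") else 160
  k <- unlist(params)[paste0("k", 1:6)]
  if (any(!is.finite(k)) || any(k < 0))
    return(1e10 * (1 + sum(pmin(k, 0)^2, na.rm = TRUE)))
  mod <- tryCatch(
    model_observables(dsb_rates(k[1], k[2], k[3], k[4], k[5], k[6]),
                      times = data$time_h, ext = ext, closure = closure,
                      constants = constants, n_dsb0 = n_dsb0,
                      count_bound = count_bound),
    error = function(e) NULL)
  if (is.null(mod)) return(1e10)
  chi1_bar <- if (!is.null(data$chi1_bar)) data$chi1_bar
              else no_h2ax_reference(data$time_h, data$chi1, slowdown)
  ssq <- function(obs, hat) {
    r <- (obs - hat) / channel_norm(obs)
    sum(r^2, na.rm = TRUE)
  }
  val <- ssq(data$chi1, mod$chi1_hat) + ssq(data$chi2, mod$chi2_hat) +
         ssq(chi1_bar, mod$chi1_bar_hat)
  peak <- attr(mod, "peak_mY")
  if (peak > constants[["Ymax"]])
    val <- val + 1e6 * ((peak - constants[["Ymax"]]) / constants[["Ymax"]])^2
  if (!is.finite(val)) val <- 1e10
  val
}

# Normalized residual vector underlying dsb_objective(); the Ymax excursion
# penalty is appended as one extra residual so that sum(r^2) equals the
# objective. Tighter integration tolerances are used here because the
# Gauss-Newton polish differentiates these residuals numerically.
fit_residuals <- function(k, data, constants, closure, n_dsb0, slowdown,
                          atol = 1e-12, rtol = 1e-11) {
  rates <- dsb_rates(k[1], k[2], k[3], k[4], k[5], k[6])
  grid <- sort(unique(c(data$time_h,
                        seq(0, max(data$time_h), length.out = 101))))
  full <- suppressWarnings(solve_moments(rates, closure = closure,
                                         times = grid, atol = atol,
                                         rtol = rtol))
  r0 <- rates
  r0[["k5"]] <- 0
  bar <- suppressWarnings(solve_moments(r0, closure = closure, times = grid,
                                        atol = atol, rtol = rtol))
  if (nrow(full) < length(grid) || nrow(bar) < length(grid) ||
      !all(is.finite(full$mZ)) || !all(is.finite(bar$mX)))
    stop("integration failed", call. = FALSE)
  idx <- match(data$time_h, grid)
  chi1_hat <- n_dsb0 * full$mX[idx]
  chi2_hat <- foci_from_model(full$mZ[idx] + full$mQ[idx], n_dsb0,
                              constants[["Zmax"]])
  bar_hat <- n_dsb0 * bar$mX[idx]
  chi1_bar <- if (!is.null(data$chi1_bar)) data$chi1_bar
              else no_h2ax_reference(data$time_h, data$chi1, slowdown)
  res <- c((data$chi1 - chi1_hat) / channel_norm(data$chi1),
           (data$chi2 - chi2_hat) / channel_norm(data$chi2),
           (chi1_bar - bar_hat) / channel_norm(chi1_bar))
  res[is.na(res)] <- 0
  excess <- max(0, max(full$mY) - constants[["Ymax"]]) / constants[["Ymax"]]
  c(res, 1e3 * excess)
}

# The latent pATM count has no observable scale: rescaling Y by alpha maps
# (k1, k2, k3, k5) -> (k1/alpha, alpha k2, alpha k3, k5/alpha) and leaves
# the (mX, mZ) trajectories of every closure exactly invariant. The data
# therefore determine the rates only up to this one-parameter family.
GAUGE_EXPONENTS <- c(k1 = -1, k2 = 1, k3 = 1, k4 = 0, k5 = -1, k6 = 0)

# Move k along its gauge orbit to the member closest (in log space) to ref.
gauge_project <- function(k, ref) {
  g <- GAUGE_EXPONENTS
  la <- -sum(g * log(k / ref)) / sum(g * g)
  k * exp(g * la)
}

#' Fit the repair network to DSB and focus time courses
#'
#' Estimates the six rate constants by minimizing [dsb_objective()]. The
#' search runs in log-parameter space (positivity by construction) with the
#' Nelder-Mead simplex, restarted from points drawn log-uniformly within
#' `span` decades around the starting guess, and the best minimum is
#' polished by a Levenberg-Marquardt pass on the residual vector.
#'
#' The latent pATM count has no observable scale: rescaling it by
#' \eqn{\alpha} maps \eqn{(k_1, k_2, k_3, k_5) \to (k_1/\alpha, \alpha k_2,
#' \alpha k_3, k_5/\alpha)} and leaves the model's observable trajectories
#' exactly invariant, so the data determine the rates only up to this
#' one-parameter family. The search is therefore performed over the five
#' identifiable degrees of freedom with `k2` frozen at its starting value
#' (a pure gauge choice), and the reported rates are the member of the
#' fitted gauge orbit closest, in log space, to the starting guess.
#'
#' @param data a `dsb_obs` with both `chi1` and `chi2` channels.
#' @param closure moment closure used in the objective.
#' @param constants an [assumed_constants()] set.
#' @param start named starting guess for `k1..k6`; the default is an
#'   order-of-magnitude-neutral point spanned widely by the restarts.
#' @param restarts number of random restarts (the first start is the guess
#'   itself).
#' @param max_iter Nelder-Mead iteration budget per restart.
#' @param span restart spread in decades around `start`.
#' @param seed integer seed controlling the restart draws.
#' @param n_dsb0,slowdown passed to [dsb_objective()].
#' @return An object of class `dsb_fit` with components `rates`
#'   ([dsb_rates()]), `objective`, `trace` (per-restart results),
#'   `converged`, and the fitting configuration. Supports [coef()],
#'   [predict()], [fitted()], [residuals()], [deviance()], `summary()`,
#'   `plot()` and [simulate()].
#' @examples
#' \donttest{
#' truth <- mcf7_rates()
#' obs <- generate_observations(truth, experiment_design(cv = 0))
#' fit <- dsb_fit(obs, start = unclass(truth) * 0.5, restarts = 2,
#'                max_iter = 200)
#' coef(fit)
#' }
#' @export
dsb_fit <- function(data, closure = c("conditional", "naive"),
                    constants = assumed_constants(), start = NULL,
                    restarts = 50, max_iter = 500, span = 2, seed = 1,
                    n_dsb0 = NULL, slowdown = 10) {
  closure <- match.arg(closure)
  data <- as_dsb_obs(data)
  if (all(is.na(data$chi1)) || all(is.na(data$chi2)))
    stop("both chi1 and chi2 channels are required for fitting",
         call. = FALSE)
  if (is.null(n_dsb0))
    n_dsb0 <- if (!is.null(attr(data, "n_dsb0"))) attr(data, "n_dsb0") else 160
  if (is.null(start))
    start <- c(k1 = 0.01, k2 = 100, k3 = 10, k4 = 100, k5 = 100, k6 = 100)
  start <- unlist(start)[paste0("k", 1:6)]
  if (any(!is.finite(start)) || any(start <= 0))
    stop("start must supply positive k1..k6", call. = FALSE)

  # gauge-fixed parameterization: l5 = log(k1, k3, k4, k5, k6), k2 frozen.
  # The search is confined to a box of span + 1 decades around the start:
  # restarts are drawn within `span` decades, and the box keeps the sloppy
  # directions of the objective from running off to degenerate regimes.
  lk2 <- log(start[["k2"]])
  lo <- log(start[-2]) - (span + 1) * log(10)
  hi <- log(start[-2]) + (span + 1) * log(10)
  expand <- function(l5) {
    l5 <- pmin(pmax(l5, lo), hi)
    k <- exp(c(l5[1], lk2, l5[2:5]))
    names(k) <- paste0("k", 1:6)
    k
  }
  obj5 <- function(l5) {
    dsb_objective(expand(l5), data, constants = constants, closure = closure,
                  n_dsb0 = n_dsb0, slowdown = slowdown)
  }
  resid5 <- function(l5) {
    tryCatch(fit_residuals(expand(l5), data, constants, closure, n_dsb0,
                           slowdown),
             error = function(e) rep(1e4, 3 * nrow(data) + 1))
  }

  set.seed(as.integer(seed))
  start5 <- start[-2]
  trace <- data.frame(restart = integer(), objective = numeric(),
                      convergence = integer())
  best <- NULL
  for (r in seq_len(max(restarts, 1))) {
    s <- if (r == 1L) start5 else start5 * 10^stats::runif(5, -span, span)
    res <- stats::optim(log(s), obj5, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-10))
    trace <- rbind(trace, data.frame(restart = r, objective = res$value,
                                     convergence = res$convergence))
    if (is.null(best) || res$value < best$value) best <- res
  }
  # chained simplex restarts from the incumbent, then Gauss-Newton polish
  for (i in 1:3) {
    res <- stats::optim(best$par, obj5, method = "Nelder-Mead",
                        control = list(maxit = 2 * max_iter,
                                       reltol = 1e-12))
    if (res$value < best$value) best <- res else break
  }
  # staged finite-difference steps: coarse first (robust far from the
  # optimum), then fine (resolves the shallow directions of the valley)
  for (eps in c(1e-8, 1e-10, 1e-12)) {
    lmfit <- tryCatch(
      minpack.lm::nls.lm(pmin(pmax(best$par, lo), hi), fn = resid5,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-16, ptol = 1e-16,
                           epsfcn = eps)),
      error = function(e) NULL)
    if (!is.null(lmfit)) {
      lmval <- obj5(lmfit$par)
      if (lmval < best$value) best <- list(par = lmfit$par, value = lmval,
                                           convergence = 0L)
    }
  }
  k <- gauge_project(expand(best$par), start)
  structure(list(
    rates = dsb_rates(k[1], k[2], k[3], k[4], k[5], k[6]),
    objective = best$value,
    trace = trace,
    converged = best$convergence == 0,
    data = data, closure = closure, constants = constants,
    n_dsb0 = n_dsb0, slowdown = slowdown, start = start,
    seed = as.integer(seed), call = match.call()
  ), class = "dsb_fit")
}

#' @export
coef.dsb_fit <- function(object, ...) {
  setNames(as.numeric(object$rates), paste0("k", 1:6))
}

#' @export
deviance.dsb_fit <- function(object, ...) object$objective

#' Model curves from a fitted repair network
#'
#' @param object a `dsb_fit`.
#' @param times evaluation grid (hours); defaults to a fine grid over the
#'   observed span.
#' @param ... unused.
#' @return Data frame `time_h, chi1_hat, chi2_hat, chi1_bar_hat`.
#' @export
predict.dsb_fit <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- seq(0, max(object$data$time_h), length.out = 121)
  out <- model_observables(object$rates, times = times,
                           closure = object$closure,
                           constants = object$constants,
                           n_dsb0 = object$n_dsb0)
  attr(out, "peak_mY") <- NULL
  out
}

#' @export
fitted.dsb_fit <- function(object, ...) {
  predict(object, times = object$data$time_h)
}

#' @export
residuals.dsb_fit <- function(object, ...) {
  f <- fitted(object)
  d <- object$data
  chi1_bar <- if (!is.null(d$chi1_bar)) d$chi1_bar
              else no_h2ax_reference(d$time_h, d$chi1, object$slowdown)
  data.frame(time_h = d$time_h,
             chi1 = d$chi1 - f$chi1_hat,
             chi2 = d$chi2 - f$chi2_hat,
             chi1_bar = chi1_bar - f$chi1_bar_hat)
}

#' @export
print.dsb_fit <- function(x, ...) {
  cat("Single-site DSB repair model fit (", x$closure, " closure)\n", sep = "")
  cat("Rate constants (h^-1):\n")
  print(signif(coef(x), 4))
  cat(sprintf("objective: %.6g over %d time points; %s\n",
              x$objective, nrow(x$data),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.dsb_fit <- function(object, ...) {
  sc <- stability_check(object$rates)
  structure(list(coefficients = coef(object),
                 objective = object$objective,
                 converged = object$converged,
                 restarts = nrow(object$trace),
                 stability = sc,
                 n_dsb0 = object$n_dsb0,
                 closure = object$closure), class = "summary.dsb_fit")
}

#' @export
print.summary.dsb_fit <- function(x, ...) {
  cat("Fitted single-site DSB repair network (", x$closure, " closure)\n",
      sep = "")
  cat("Rate constants (h^-1):\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("least-squares objective: %.6g (%d restarts, %s)\n",
              x$objective, x$restarts,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("post-repair zero state: %s (margin %.4g h^-2)\n",
              if (x$stability$stable) "stable" else "UNSTABLE",
              x$stability$margin))
  cat(sprintf("initial DSB load: %g per cell\n", x$n_dsb0))
  invisible(x)
}

#' @export
plot.dsb_fit <- function(x, ...) {
  f <- predict(x)
  d <- x$data
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(d$time_h, d$chi1, xlab = "time (h)", ylab = "DSBs per cell",
       ylim = range(0, d$chi1, f$chi1_hat, na.rm = TRUE), pch = 4, ...)
  graphics::lines(f$time_h, f$chi1_hat, lty = 2)
  plot(d$time_h, d$chi2, xlab = "time (h)",
       ylab = expression(paste(gamma, "H2AX foci per cell")),
       ylim = range(0, d$chi2, f$chi2_hat, na.rm = TRUE), pch = 16, ...)
  graphics::lines(f$time_h, f$chi2_hat, lty = 1)
  invisible(x)
}

#' Simulate observation sets from a fitted model
#'
#' @param object a `dsb_fit`.
#' @param nsim number of replicate observation sets.
#' @param seed integer seed.
#' @param cv multiplicative noise coefficient of variation.
#' @param ... unused.
#' @return A list of `nsim` `dsb_obs` objects (a single `dsb_obs` when
#'   `nsim = 1`).
#' @export
simulate.dsb_fit <- function(object, nsim = 1, seed = 1, cv = 0.1, ...) {
  design <- experiment_design(times = object$data$time_h, cv = cv,
                              seed = as.integer(seed))
  design$n_dsb0 <- object$n_dsb0
  out <- lapply(seq_len(nsim), function(i) {
    d <- design
    d$seed <- sub_seed(seed, i)
    generate_observations(object$rates, d, closure = object$closure,
                          constants = object$constants)
  })
  if (nsim == 1) out[[1]] else out
}

#' Fit the antibody binding grouping per concentration
#'
#' With the core rates fixed, the antibody extension adds the reversible
#' binding pair `(k7, k8)`. Focus data alone identify only the
#' quasi-equilibrium grouping `g = k8 * [TAT]0 / k7`, so `k7` is fixed at a
#' reference value and `g` is fitted one-dimensionally to each
#' concentration's focus series. The model predicts `g` to grow linearly
#' with `[TAT]0`; the linear trend over a chosen concentration subset is
#' summarized by slope, intercept and R^2.
#'
#' @param panels list of `dsb_obs`, one per antibody concentration; each
#'   must carry its concentration in the `tat0` attribute.
#' @param baseline fixed core rates: a [dsb_rates()] or a `dsb_fit`.
#' @param constants an [assumed_constants()] set.
#' @param k7 reference dissociation rate (h^-1) fixing the scale of `k8`.
#' @param closure moment closure for the antibody system.
#' @param subset optional indices (into `panels`) used for the linear
#'   trend; default all.
#' @param g_max upper bound of the one-dimensional search.
#' @param count_bound count bound gamma-H2AX in the focus channel.
#' @return An object of class `dsb_grouping`: list with `table`
#'   (`tat0`, fitted `g`, `k8`, objective) and `trend`
#'   (slope, intercept, r_squared), or `trend = NULL` with fewer than two
#'   concentrations.
#' @export
fit_antibody_grouping <- function(panels, baseline,
                                  constants = assumed_constants(),
                                  k7 = 1, closure = c("conditional", "naive"),
                                  subset = NULL, g_max = 50,
                                  count_bound = TRUE) {
  closure <- match.arg(closure)
  rates <- if (inherits(baseline, "dsb_fit")) baseline$rates
           else as_dsb_rates(baseline)
  rows <- lapply(panels, function(obs) {
    obs <- as_dsb_obs(obs)
    tat0 <- attr(obs, "tat0")
    if (is.null(tat0)) stop("each panel must carry a tat0 attribute",
                            call. = FALSE)
    n_dsb0 <- if (!is.null(attr(obs, "n_dsb0"))) attr(obs, "n_dsb0") else 160
    sse_foci <- function(g) {
      ext <- ext_rates(k7 = k7, k8 = if (tat0 > 0) g * k7 / tat0 else 0,
                       tat0 = tat0)
      sol <- solve_moments(rates, ext = ext, closure = closure,
                           times = obs$time_h)
      mZ <- if (count_bound) sol$mZ + sol$mQ else sol$mZ
      hat <- foci_from_model(mZ, n_dsb0, constants[["Zmax"]])
      sum((obs$chi2 - hat)^2, na.rm = TRUE)
    }
    if (tat0 == 0) {
      g <- 0
    } else {
      o <- stats::optimize(function(lg) sse_foci(exp(lg)),
                           interval = c(log(1e-6), log(g_max)),
                           tol = 1e-8)
      g <- exp(o$minimum)
      # the zero-binding boundary is outside the log search; keep it in play
      if (sse_foci(0) < sse_foci(g)) g <- 0
    }
    data.frame(tat0 = tat0, g = g,
               k8 = if (tat0 > 0) g * k7 / tat0 else NA_real_,
               objective = sse_foci(g))
  })
  table <- do.call(rbind, rows)
  table <- table[order(table$tat0), ]
  rownames(table) <- NULL
  trend <- NULL
  idx <- if (is.null(subset)) seq_len(nrow(table)) else subset
  if (length(idx) >= 2) {
    lmfit <- stats::lm(g ~ tat0, data = table[idx, ])
    trend <- list(slope = unname(stats::coef(lmfit)[2]),
                  intercept = unname(stats::coef(lmfit)[1]),
                  r_squared = summary(lmfit)$r.squared)
  }
  structure(list(table = table, trend = trend, k7 = k7, closure = closure,
                 rates = rates), class = "dsb_grouping")
}

#' @export
print.dsb_grouping <- function(x, ...) {
  cat("Antibody binding grouping g = k8*[TAT]0/k7 per concentration",
      sprintf("(k7 fixed at %g h^-1)\n", x$k7))
  print(x$table, digits = 4)
  if (!is.null(x$trend))
    cat(sprintf("linear trend: g = %.4g + %.4g * tat0, R^2 = %.4f\n",
                x$trend$intercept, x$trend$slope, x$trend$r_squared))
  invisible(x)
}

#' @export
plot.dsb_grouping <- function(x, ...) {
  plot(x$table$tat0, x$table$g, xlab = "[TAT]0 (ug/ml)",
       ylab = expression(g == k[8] * group("[", TAT, "]")[0] / k[7]),
       pch = 16, ...)
  if (!is.null(x$trend))
    graphics::abline(x$trend$intercept, x$trend$slope, lty = 2)
  invisible(x)
}
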