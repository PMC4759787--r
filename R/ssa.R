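#' Simulate one DSB site by Gillespie's algorithm
#'
#' Draws an exact sample path of the single-site jump process and samples it
#' onto a time grid by right-continuous step sampling (the value recorded at
#' `t` is the state after the last event at or before `t`). Simulation stops
#' when the grid is exhausted or when every propensity is zero (the site is
#' absorbed in the empty repaired state).
#'
#' @param rates a [dsb_rates()] object.
#' @param ext optional [ext_rates()] enabling the reversible antibody
#'   binding events. The de novo damage rate `k9` is a population-level
#'   mechanism and is ignored for a single site (see
#'   [simulate_population()]).
#' @param init initial [site_state()]; default a freshly damaged site
#'   `(X, Y, Z, Q) = (1, 0, 0, 0)`.
#' @param times numeric time grid in hours, starting at 0, strictly
#'   increasing.
#' @param seed integer seed; identical inputs and seed give an identical
#'   trajectory.
#' @param max_events safety budget on the number of jumps.
#' @return A `dsb_trajectory`: data frame with columns `time_h, X, Y, Z, Q`.
#' @examples
#' tr <- simulate_site(mcf7_rates(), times = seq(0, 4, by = 0.05), seed = 1)
#' head(tr)
#' @export
simulate_site <- function(rates, ext = NULL, init = site_state(),
                          times = seq(0, 24, by = 0.25), seed,
                          max_events = 5e8) {
  rates <- as_dsb_rates(rates)
  ext <- as_dsb_ext(ext)
  init <- as_site_state(init)
  check_grid(times)
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  set.seed(as.integer(seed))
  e <- ext_vector(ext)
  m <- ssa_site_cpp(as.numeric(rates), e, as.integer(init), as.numeric(times),
                    max_events)
  out <- data.frame(time_h = times, X = m[, 1], Y = m[, 2], Z = m[, 3],
                    Q = m[, 4])
  structure(out, class = c("dsb_trajectory", "data.frame"),
            rates = rates, ext = ext, seed = as.integer(seed))
}

#' Simulate a population of DSB sites with Auger re-damage
#'
#' Exact simulation of `n_sites` sites sharing one antibody/radionuclide
#' environment. Bound antibody molecules anywhere in the population carry a
#' de novo damage hazard `k9` each; a new DSB lands on a uniformly chosen
#' undamaged site, so the total re-damage hazard is
#' `k9 * sum(Q) * (undamaged fraction)`, the finite-population counterpart
#' of the mean-field term `k9 * <Q> * (1 - <X>)`.
#'
#' @inheritParams simulate_site
#' @param n_sites number of DNA sites in the population.
#' @param init initial [site_state()] given to every site.
#' @return Data frame of per-site population means
#'   `time_h, mean_X, mean_Y, mean_Z, mean_Q`.
#' @export
simulate_population <- function(rates, ext = NULL, n_sites = 160L,
                                init = site_state(),
                                times = seq(0, 24, by = 0.25), seed,
                                max_events = 5e8) {
  rates <- as_dsb_rates(rates)
  ext <- as_dsb_ext(ext)
  init <- as_site_state(init)
  check_grid(times)
  if (missing(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  set.seed(as.integer(seed))
  im <- matrix(rep(as.integer(init), each = n_sites), nrow = n_sites)
  m <- ssa_population_cpp(as.numeric(rates), ext_vector(ext), im,
                          as.numeric(times), max_events)
  data.frame(time_h = times, mean_X = m[, 1], mean_Y = m[, 2],
             mean_Z = m[, 3], mean_Q = m[, 4])
}

ext_vector <- function(ext) {
  if (is.null(ext)) c(0, 0, 0, 0)
  else as.numeric(ext[c("k7", "k8", "tat0", "k9")])
}

check_grid <- function(times) {
  if (length(times) < 1L || times[1] != 0)
    stop("the time grid must start at 0", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("the time grid must be strictly increasing", call. = FALSE)
  invisible(times)
}

#' Per-replicate sub-seed derivation
#'
#' Replicate `r` of an ensemble uses the seed
#' `(seed + 140737 * r) mod (2^31 - 1)`, a fixed counter-based scheme that
#' makes ensembles reproducible and independent of evaluation order.
#'
#' @param seed master integer seed.
#' @param r replicate index (1-based).
#' @return Integer sub-seed.
#' @keywords internal
sub_seed <- function(seed, r) {
  as.integer((as.double(seed) + 140737 * as.double(r)) %% 2147483647)
}

#' Ensemble statistics of the stochastic model
#'
#' Simulates `n_reps` independent site trajectories and returns grid-wise
#' sample means, Monte-Carlo standard errors and detectable-focus fractions.
#' A focus is counted as detectable at a time point when the gamma-H2AX
#' count exceeds the threshold `Zstar`, either counting free molecules only
#' (`Z >= Zstar`) or including antibody-bound ones (`Z + Q >= Zstar`); both
#' fractions are recorded.
#'
#' @inheritParams simulate_site
#' @param n_reps number of stochastic replicates (>= 2).
#' @param Zstar detection threshold used for the stored detectable-focus
#'   fractions.
#' @return A `dsb_ensemble`: data frame with columns `time_h`,
#'   `mean_X..mean_Q`, `se_X..se_Q`, `det_free` (fraction with
#'   `Z >= Zstar`) and `det_total` (fraction with `Z + Q >= Zstar`), with
#'   attributes `n_reps`, `Zstar`, `seed`.
#' @examples
#' en <- ssa_ensemble(mcf7_rates(), times = seq(0, 2, by = 0.25),
#'                    n_reps = 50, seed = 1)
#' en$mean_X
#' @export
ssa_ensemble <- function(rates, ext = NULL, init = site_state(),
                         times = seq(0, 24, by = 0.25), n_reps = 1000L,
                         seed = 1L, Zstar = 200, max_events = 5e8) {
  rates <- as_dsb_rates(rates)
  ext <- as_dsb_ext(ext)
  init <- as_site_state(init)
  check_grid(times)
  if (n_reps < 2L) stop("n_reps must be at least 2", call. = FALSE)
  ng <- length(times)
  sums <- matrix(0, ng, 4)
  sq <- matrix(0, ng, 4)
  detf <- numeric(ng)
  dett <- numeric(ng)
  e <- ext_vector(ext)
  kk <- as.numeric(rates)
  ii <- as.integer(init)
  tt <- as.numeric(times)
  for (r in seq_len(n_reps)) {
    set.seed(sub_seed(seed, r))
    m <- tryCatch(ssa_site_cpp(kk, e, ii, tt, max_events),
                  error = function(err) {
                    stop(sprintf("replicate %d: %s", r, conditionMessage(err)),
                         call. = FALSE)
                  })
    sums <- sums + m
    sq <- sq + m * m
    detf <- detf + (m[, 3] >= Zstar)
    dett <- dett + (m[, 3] + m[, 4] >= Zstar)
  }
  mean <- sums / n_reps
  # SE of the mean from the replicate-wise sample variance
  v <- pmax(sq - n_reps * mean^2, 0) / (n_reps - 1)
  se <- sqrt(v / n_reps)
  out <- data.frame(time_h = times,
                    mean_X = mean[, 1], mean_Y = mean[, 2],
                    mean_Z = mean[, 3], mean_Q = mean[, 4],
                    se_X = se[, 1], se_Y = se[, 2],
                    se_Z = se[, 3], se_Q = se[, 4],
                    det_free = detf / n_reps, det_total = dett / n_reps)
  structure(out, class = c("dsb_ensemble", "data.frame"),
            rates = rates, ext = ext, n_reps = n_reps,
            Zstar = Zstar, seed = as.integer(seed))
}

#' Expected number of microscopically visible foci
#'
#' Converts the fraction of sites whose gamma-H2AX count exceeds the
#' detection threshold `Zstar` into an expected number of visible foci in a
#' population of `n_dsb` initially damaged sites.
#'
#' @param x a `dsb_ensemble` (uses the detectable fractions stored at
#'   ensemble time; its `Zstar` must match) or a list of `dsb_trajectory`
#'   objects sharing one grid (fractions are computed directly).
#' @param Zstar detection threshold (molecules).
#' @param n_dsb number of DSB sites in the population.
#' @param count_bound should antibody-bound gamma-H2AX count towards
#'   detectability (`Z + Q >= Zstar`)? Defaults to `TRUE`: the staining
#'   antibody still finds the phosphorylated epitope of sequestered
#'   gamma-H2AX.
#' @return Data frame `time_h, foci_visible`.
#' @examples
#' en <- ssa_ensemble(mcf7_rates(), times = seq(0, 2, by = 0.5),
#'                    n_reps = 50, seed = 1)
#' detectable_foci(en, n_dsb = 160)
#' @export
detectable_foci <- function(x, Zstar = 200, n_dsb = 160, count_bound = TRUE) {
  if (Zstar <= 0 || n_dsb <= 0)
    stop("Zstar and n_dsb must be positive", call. = FALSE)
  if (inherits(x, "dsb_ensemble")) {
    if (!isTRUE(all.equal(attr(x, "Zstar"), Zstar)))
      stop("ensemble was summarized with a different Zstar; ",
           "re-run ssa_ensemble() with the desired threshold", call. = FALSE)
    frac <- if (count_bound) x$det_total else x$det_free
    return(data.frame(time_h = x$time_h, foci_visible = n_dsb * frac))
  }
  if (is.list(x) && length(x) && inherits(x[[1]], "dsb_trajectory")) {
    times <- x[[1]]$time_h
    hits <- vapply(x, function(tr) {
      tot <- if (count_bound) tr$Z + tr$Q else tr$Z
      as.numeric(tot >= Zstar)
    }, numeric(length(times)))
    return(data.frame(time_h = times,
                      foci_visible = n_dsb * rowMeans(hits)))
  }
  stop("x must be a dsb_ensemble or a list of dsb_trajectory objects",
       call. = FALSE)
}

#' @export
print.dsb_ensemble <- function(x, ...) {
  cat(sprintf("SSA ensemble: %d replicates, %d time points on [0, %g] h\n",
              attr(x, "n_reps"), nrow(x), max(x$time_h)))
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 4)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}
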