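#' Design of a synthetic irradiation time course
#'
#' Encodes the statistical structure of the foci/comet experiments the
#' generator emulates: a single acute dose sets the initial DSB load
#' (`dose * dsb_per_gy` per cell, 4 Gy x 40 = 160 by default), per-cell
#' means are sampled at a handful of times over 0-24 h, and measurement
#' error is multiplicative Gaussian with a fixed coefficient of variation
#' per channel. Optional per-cell Poisson count noise is available through
#' `cells`.
#'
#' @param dose radiation dose in Gy.
#' @param dsb_per_gy initial DSBs per cell per Gy.
#' @param times sampling times in hours.
#' @param cv coefficient of variation of the multiplicative Gaussian noise
#'   (0 for noiseless curves).
#' @param cells optional number of cells averaged per measurement; when
#'   given, channel means are replaced by Poisson counts over that many
#'   cells (count noise) before the multiplicative noise.
#' @param seed integer seed for the noise draws.
#' @return An object of class `dsb_design` (a list; `n_dsb0` is derived).
#' @export
experiment_design <- function(dose = 4, dsb_per_gy = 40,
                              times = c(0, 0.5, 1, 2, 4, 6, 24),
                              cv = 0.1, cells = NULL, seed = 1) {
  if (dose < 0 || cv < 0) stop("dose and cv must be non-negative",
                               call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  structure(list(dose = dose, dsb_per_gy = dsb_per_gy, times = times,
                 cv = cv, cells = cells, seed = as.integer(seed),
                 n_dsb0 = dose * dsb_per_gy),
            class = "dsb_design")
}

apply_noise <- function(x, cv, cells) {
  if (!is.null(cells))
    x <- stats::rpois(length(x), x * cells) / cells
  if (cv > 0)
    x <- x * (1 + cv * stats::rnorm(length(x)))
  pmax(x, 0)
}

#' Generate synthetic observation series
#'
#' Simulates a condition of the experimental design with either the
#' moment-closure ODEs (default) or the stochastic ensemble, maps the state
#' to the observation channels (`chi1 = n_dsb0 * mX`,
#' `chi2 = foci_from_model(mZ + mQ)`), and applies the design's noise model.
#' With `cv = 0` and no count noise the observations equal the model curves
#' exactly.
#'
#' @param truth generating rate constants ([dsb_rates()]).
#' @param design an [experiment_design()].
#' @param ext optional [ext_rates()] for antibody/Auger conditions.
#' @param generator `"ode"` (moment closure) or `"ssa"` (stochastic
#'   ensemble means).
#' @param closure moment closure for the ODE generator (the Auger term
#'   forces `"naive"`).
#' @param constants an [assumed_constants()] set.
#' @param n_reps ensemble size for the SSA generator.
#' @param count_bound count antibody-bound gamma-H2AX in the focus channel.
#' @param emit_reference also emit the H2AX-deficient reference channel
#'   `chi1_bar` (the `k5 = 0` model solved with the ODE generator), the
#'   synthetic counterpart of measuring DSB kinetics in H2AX-null cells.
#' @return A `dsb_obs` with attributes `truth`, `ext`, `cv`, `seed`,
#'   `generator`, `n_dsb0`, `tat0`, `R`.
#' @examples
#' obs <- generate_observations(mcf7_rates(), experiment_design(cv = 0))
#' obs$chi1[1]  # 160 DSBs per cell at t = 0
#' @export
generate_observations <- function(truth, design = experiment_design(),
                                  ext = NULL,
                                  generator = c("ode", "ssa"),
                                  closure = c("conditional", "naive"),
                                  constants = assumed_constants(),
                                  n_reps = 1000L, count_bound = TRUE,
                                  emit_reference = TRUE) {
  generator <- match.arg(generator)
  closure <- match.arg(closure)
  truth <- as_dsb_rates(truth)
  ext <- as_dsb_ext(ext)
  if (!is.null(ext) && ext[["k9"]] > 0) closure <- "naive"
  n_dsb0 <- design$n_dsb0
  if (generator == "ode") {
    sol <- solve_moments(truth, ext = ext, closure = closure,
                         times = design$times)
    mX <- sol$mX
    mZ <- if (count_bound) sol$mZ + sol$mQ else sol$mZ
  } else {
    en <- ssa_ensemble(truth, ext = ext, times = design$times,
                       n_reps = n_reps, seed = design$seed,
                       Zstar = constants[["Zstar"]])
    mX <- en$mean_X
    mZ <- if (count_bound) en$mean_Z + en$mean_Q else en$mean_Z
  }
  chi1 <- n_dsb0 * mX
  chi2 <- foci_from_model(mZ, n_dsb0, constants[["Zmax"]])
  chi1_bar <- NULL
  if (emit_reference) {
    r0 <- truth
    r0[["k5"]] <- 0
    bar <- solve_moments(r0, ext = ext,
                         closure = if (!is.null(ext) && ext[["k9"]] > 0)
                           "naive" else closure,
                         times = design$times)
    chi1_bar <- n_dsb0 * bar$mX
  }
  set.seed(design$seed)
  chi1 <- apply_noise(chi1, design$cv, design$cells)
  chi2 <- apply_noise(chi2, design$cv, design$cells)
  if (!is.null(chi1_bar))
    chi1_bar <- apply_noise(chi1_bar, design$cv, design$cells)
  obs <- dsb_observations(design$times, chi1, chi2, chi1_bar = chi1_bar,
                          tat0 = if (is.null(ext)) 0 else ext[["tat0"]],
                          R = if (is.null(ext)) 0 else ext[["R"]],
                          n_dsb0 = n_dsb0)
  attr(obs, "truth") <- truth
  attr(obs, "ext") <- ext
  attr(obs, "cv") <- design$cv
  attr(obs, "seed") <- design$seed
  attr(obs, "generator") <- generator
  obs
}

#' Generate an antibody concentration panel
#'
#' One observation set per antibody concentration, sharing the design and
#' noise realization (paired conditions). The `tat0 = 0` member is
#' identical to a baseline generation with the same seed.
#'
#' @param truth generating rate constants.
#' @param ext antibody parameters; `tat0` is overridden per panel member.
#' @param tat0 concentrations (ug/ml).
#' @param design an [experiment_design()].
#' @param ... passed to [generate_observations()].
#' @return Named list of `dsb_obs` (names are the concentrations).
#' @export
generate_antibody_panel <- function(truth, ext = ext_rates(k7 = 1, k8 = 40),
                                    tat0 = c(0, 0.025, 0.05, 0.5),
                                    design = experiment_design(), ...) {
  out <- lapply(tat0, function(a) {
    e <- ext
    e[["tat0"]] <- a
    generate_observations(truth, design, ext = e, ...)
  })
  names(out) <- as.character(tat0)
  out
}
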