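#' Per-cell time-series observations
#'
#' Container for the two observable channels of an irradiation time course:
#' `chi1`, the mean number of DSBs per cell (comet-assay scale, emitted here
#' in DSB-count units), and `chi2`, the mean number of gamma-H2AX foci per
#' cell. An optional `chi1_bar` column carries an explicit reference series
#' for the H2AX-deficient (slow-repair) condition; when absent it is derived
#' by time dilation of `chi1` (see [no_h2ax_reference()]).
#'
#' @param time_h observation times in hours (non-negative, strictly
#'   increasing).
#' @param chi1 mean DSB count per cell.
#' @param chi2 mean gamma-H2AX focus count per cell.
#' @param chi1_bar optional reference DSB series for the no-H2AX condition.
#' @param tat0 antibody concentration (ug/ml) of the condition.
#' @param R In-111 specific activity (MBq/ug) of the condition.
#' @param n_dsb0 number of DSBs per cell at time 0 used by the observation
#'   maps (default `dose 4 Gy x 40 DSB/Gy = 160`).
#' @return A `dsb_obs`: data frame with attributes `tat0`, `R`, `n_dsb0`.
#' @export
dsb_observations <- function(time_h, chi1, chi2, chi1_bar = NULL,
                             tat0 = 0, R = 0, n_dsb0 = 160) {
  if (length(time_h) == 0L) stop("empty observation series", call. = FALSE)
  if (any(time_h < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("times must be strictly increasing (no duplicates)", call. = FALSE)
  if (length(chi1) != length(time_h) || length(chi2) != length(time_h))
    stop("chi1 and chi2 must share the time grid", call. = FALSE)
  if (any(stats::na.omit(c(chi1, chi2, chi1_bar)) < 0))
    stop("counts must be non-negative", call. = FALSE)
  out <- data.frame(time_h = time_h, chi1 = chi1, chi2 = chi2)
  if (!is.null(chi1_bar)) out$chi1_bar <- chi1_bar
  structure(out, class = c("dsb_obs", "data.frame"),
            tat0 = tat0, R = R, n_dsb0 = n_dsb0)
}

as_dsb_obs <- function(x) {
  if (inherits(x, "dsb_obs")) return(x)
  if (is.data.frame(x) && all(c("time_h", "chi1", "chi2") %in% names(x)))
    return(dsb_observations(x$time_h, x$chi1, x$chi2,
                            chi1_bar = x[["chi1_bar"]]))
  stop("expected a dsb_obs or a data frame with time_h, chi1, chi2",
       call. = FALSE)
}

#' @export
print.dsb_obs <- function(x, ...) {
  cat(sprintf(
    "DSB/foci observations: %d time points, tat0 = %g ug/ml, R = %g MBq/ug\n",
    nrow(x), attr(x, "tat0"), attr(x, "R")))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}
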