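#' Rate constants of the single-site repair network
#'
#' Constructs and validates the six first-order rate constants governing the
#' stochastic dynamics at a single DNA double-strand-break (DSB) site. All
#' rates are in units of h^-1.
#'
#' The network couples a telegraph damage indicator `X` (1 = DSB present) to
#' the number `Y` of bound activated diffusible repair molecules (referred to
#' as pATM) and the number `Z` of phosphorylated H2AX (gamma-H2AX) molecules:
#'
#' * repair switches `X` off with hazard `k1 * Y` while `X = 1`;
#' * pATM is recruited at rate `k2` while the DSB is present, and at rate
#'   `k3 * Z` through gamma-H2AX regardless of damage status;
#' * pATM dissociates at rate `k4 * Y`;
#' * H2AX is phosphorylated at rate `k5 * Y` and gamma-H2AX dephosphorylated
#'   at rate `k6 * Z`.
#'
#' @param k1 repair rate per bound pATM molecule (h^-1).
#' @param k2 DSB-driven pATM recruitment rate (h^-1).
#' @param k3 gamma-H2AX-driven pATM recruitment rate per molecule (h^-1).
#' @param k4 pATM dissociation rate per molecule (h^-1).
#' @param k5 phosphorylation rate per pATM molecule (h^-1).
#' @param k6 dephosphorylation rate per gamma-H2AX molecule (h^-1).
#' @return An object of class `dsb_rates`: a named numeric vector `k1..k6`.
#' @seealso [mcf7_rates()], [mda_mb_468_rates()], [stability_check()]
#' @examples
#' r <- dsb_rates(k1 = 0.02, k2 = 1236, k3 = 20, k4 = 87, k5 = 1765, k6 = 565)
#' stability_check(r)
#' @export
dsb_rates <- function(k1, k2, k3, k4, k5, k6) {
  k <- setNames(as.numeric(c(k1, k2, k3, k4, k5, k6)), paste0("k", 1:6))
  validate_nonneg(k, "rate constant")
  structure(k, class = "dsb_rates")
}

#' Antibody and Auger extension parameters
#'
#' Parameters of the two model extensions: reversible binding of an
#' anti-gamma-H2AX-TAT antibody to gamma-H2AX (forming an inert complex `Q`),
#' and de novo DSB induction by Auger electrons emitted from an In-111 label
#' on the bound antibody.
#'
#' The de novo damage rate per bound antibody molecule is `k9`. When a
#' specific activity `R` is supplied, `k9` is taken proportional to it,
#' `k9 = kappa * R`.
#'
#' @param k7 antibody-gamma-H2AX dissociation rate (h^-1).
#' @param k8 antibody binding rate per unit antibody concentration
#'   (h^-1 (ug/ml)^-1).
#' @param tat0 antibody concentration `[TAT]0` (ug/ml).
#' @param k9 de novo DSB induction rate per bound antibody molecule (h^-1).
#'   Computed as `kappa * R` when `R` is given.
#' @param kappa proportionality constant in `k9 = kappa * R`
#'   (h^-1 per MBq/ug).
#' @param R specific activity of the In-111 label (MBq/ug).
#' @return An object of class `dsb_ext`: named numeric vector with elements
#'   `k7, k8, tat0, k9, kappa, R`.
#' @examples
#' ext_rates(k7 = 1, k8 = 40, tat0 = 0.05)           # antibody only
#' ext_rates(k7 = 1, k8 = 40, tat0 = 0.05, kappa = 5e-4, R = 4)  # + Auger
#' @export
ext_rates <- function(k7 = 1, k8 = 0, tat0 = 0, k9 = NULL, kappa = 0, R = 0) {
  if (is.null(k9)) {
    k9 <- kappa * R
  } else if (R > 0 && abs(k9 - kappa * R) > 1e-12 * max(k9, kappa * R)) {
    stop("inconsistent Auger parameters: k9 must equal kappa * R when R is supplied",
         call. = FALSE)
  }
  e <- setNames(as.numeric(c(k7, k8, tat0, k9, kappa, R)),
                c("k7", "k8", "tat0", "k9", "kappa", "R"))
  validate_nonneg(e, "extension parameter")
  structure(e, class = "dsb_ext")
}

#' A priori assumed molecular constants
#'
#' Fixed counts used to relate site-level molecule numbers to the observation
#' scale. `Ymax` and `Zmax` are not enforced as hard caps on the stochastic
#' dynamics: they belong to the observation and fitting layer (`Ymax` enters
#' the least-squares objective as a soft excursion penalty, `Zmax` converts a
#' mean gamma-H2AX count into a per-cell focus count).
#'
#' @param Ymax maximum number of bound pATM molecules per DSB.
#' @param Zmax number of gamma-H2AX molecules in a mature focus.
#' @param Zstar number of gamma-H2AX molecules needed to make a focus
#'   microscopically detectable.
#' @param dsb_per_gy initial DSBs per cell per Gy of ionizing radiation.
#' @return An object of class `dsb_constants` (named numeric vector).
#' @export
assumed_constants <- function(Ymax = 300, Zmax = 1000, Zstar = 200,
                              dsb_per_gy = 40) {
  a <- c(Ymax = Ymax, Zmax = Zmax, Zstar = Zstar, dsb_per_gy = dsb_per_gy)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("all assumed constants must be positive and finite", call. = FALSE)
  if (Zstar >= Zmax)
    stop("detection threshold Zstar must be below the focus size Zmax",
         call. = FALSE)
  structure(a, class = "dsb_constants")
}

#' State of a single DSB site
#'
#' @param X damage indicator, 0 or 1.
#' @param Y number of bound activated diffusible molecules (pATM).
#' @param Z number of free gamma-H2AX molecules.
#' @param Q number of antibody-bound gamma-H2AX molecules.
#' @return An object of class `dsb_state` (named integer vector).
#' @examples
#' site_state()            # freshly damaged site: X = 1, no molecules bound
#' site_state(X = 0)       # repaired, empty site
#' @export
site_state <- function(X = 1L, Y = 0L, Z = 0L, Q = 0L) {
  s <- c(X = X, Y = Y, Z = Z, Q = Q)
  if (any(!is.finite(s)) || any(s < 0) || any(s != round(s)))
    stop("site state components must be non-negative integers", call. = FALSE)
  if (s[["X"]] > 1L)
    stop("the damage indicator X must be 0 or 1", call. = FALSE)
  structure(as.integer(round(s)), names = names(s), class = "dsb_state")
}

validate_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("%s '%s' must be finite and >= 0",
                 what, names(x)[which(!is.finite(x) | x < 0)[1]]),
         call. = FALSE)
  invisible(x)
}

as_dsb_rates <- function(x) {
  if (inherits(x, "dsb_rates")) return(x)
  x <- unlist(x)
  need <- paste0("k", 1:6)
  if (!all(need %in% names(x)))
    stop("rates must supply k1..k6", call. = FALSE)
  do.call(dsb_rates, as.list(x[need]))
}

as_dsb_ext <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "dsb_ext")) return(x)
  do.call(ext_rates, as.list(unlist(x)))
}

#' Fitted rate constants for the MCF7 and MDA-MB-468 cell lines
#'
#' Reference parameter sets obtained by least-squares fitting of the
#' conditional-mean closure to per-cell DSB and gamma-H2AX focus time courses
#' for two human breast cancer cell lines. MCF7 shows the fast foci kinetics
#' typical of most cancer lines; MDA-MB-468 repairs much more slowly.
#'
#' @return A [dsb_rates()] object.
#' @examples
#' mcf7_rates()
#' stability_check(mda_mb_468_rates())
#' @export
mcf7_rates <- function() {
  dsb_rates(k1 = 0.02, k2 = 1236, k3 = 20, k4 = 87, k5 = 1765, k6 = 565)
}

#' @rdname mcf7_rates
#' @export
mda_mb_468_rates <- function() {
  dsb_rates(k1 = 0.0032, k2 = 159, k3 = 142, k4 = 716, k5 = 1056, k6 = 211)
}

# Event identifiers, in the order used throughout the package and in src/.
dsb_events <- function(ext = FALSE) {
  ev <- c("repair", "recruit", "dissociate", "phosphorylate", "dephosphorylate")
  if (ext) ev <- c(ev, "bind", "unbind")
  ev
}

#' Event propensities at a site
#'
#' Returns the instantaneous rate of each elementary event given the current
#' site state. The damage indicator gates repair (`k1 * Y * X`) and
#' DSB-driven recruitment (`k2 * X`); gamma-H2AX-driven recruitment
#' (`k3 * Z`) continues after repair. Antibody-bound gamma-H2AX (`Q`) is
#' inert: it contributes to no propensity except its own unbinding.
#'
#' @param state a [site_state()].
#' @param rates a [dsb_rates()] object.
#' @param ext optional [ext_rates()]; when supplied, the reversible binding
#'   events `bind` (`k8 * tat0 * Z`) and `unbind` (`k7 * Q`) are included.
#' @return Named numeric vector of non-negative propensities (h^-1) over the
#'   events `repair`, `recruit`, `dissociate`, `phosphorylate`,
#'   `dephosphorylate` and, with `ext`, `bind` and `unbind`.
#' @examples
#' propensities(site_state(X = 1, Y = 10, Z = 100), mcf7_rates())
#' @export
propensities <- function(state, rates, ext = NULL) {
  state <- as_site_state(state)
  rates <- as_dsb_rates(rates)
  ext <- as_dsb_ext(ext)
  X <- state[["X"]]; Y <- state[["Y"]]; Z <- state[["Z"]]; Q <- state[["Q"]]
  a <- c(
    repair          = rates[["k1"]] * Y * X,
    recruit         = rates[["k2"]] * X + rates[["k3"]] * Z,
    dissociate      = rates[["k4"]] * Y,
    phosphorylate   = rates[["k5"]] * Y,
    dephosphorylate = rates[["k6"]] * Z
  )
  if (!is.null(ext)) {
    a <- c(a,
           bind   = ext[["k8"]] * ext[["tat0"]] * Z,
           unbind = ext[["k7"]] * Q)
  }
  a
}

as_site_state <- function(x) {
  if (inherits(x, "dsb_state")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) && length(x) %in% c(3L, 4L))
    names(x) <- c("X", "Y", "Z", "Q")[seq_along(x)]
  if (!"Q" %in% names(x)) x <- c(x, Q = 0L)
  do.call(site_state, as.list(x[c("X", "Y", "Z", "Q")]))
}

#' Apply an elementary event to a site state
#'
#' @param state a [site_state()].
#' @param event one of `"repair"`, `"recruit"`, `"dissociate"`,
#'   `"phosphorylate"`, `"dephosphorylate"`, `"bind"`, `"unbind"`.
#' @return The updated [site_state()]. The sum `Z + Q` is conserved by
#'   `bind`/`unbind` and changed only by (de)phosphorylation.
#' @examples
#' apply_event(site_state(X = 1, Y = 3, Z = 7), "repair")
#' @export
apply_event <- function(state, event) {
  state <- as_site_state(state)
  event <- match.arg(event, dsb_events(ext = TRUE))
  d <- switch(event,
    repair          = c(-1L, 0L,  0L,  0L),
    recruit         = c(0L,  1L,  0L,  0L),
    dissociate      = c(0L, -1L,  0L,  0L),
    phosphorylate   = c(0L,  0L,  1L,  0L),
    dephosphorylate = c(0L,  0L, -1L,  0L),
    bind            = c(0L,  0L, -1L,  1L),
    unbind          = c(0L,  0L,  1L, -1L)
  )
  if (event == "repair") {
    if (state[["X"]] != 1L)
      stop("cannot repair a site without a DSB", call. = FALSE)
    new <- state
    new[1L] <- 0L
  } else {
    new <- unclass(state) + d
  }
  if (any(new < 0L))
    stop(sprintf("event '%s' would drive a count negative", event),
         call. = FALSE)
  structure(as.integer(new), names = c("X", "Y", "Z", "Q"),
            class = "dsb_state")
}

#' Stability of the post-repair steady state
#'
#' After repair (`X = 0`) the (pATM, gamma-H2AX) subsystem is linear. The
#' zero state (no pATM, no gamma-H2AX) is a stable steady state precisely
#' when the gamma-H2AX/pATM positive feedback is dominated by dissociation
#' and dephosphorylation, i.e. when `k3 * k5 < k4 * k6`.
#'
#' @param rates a [dsb_rates()] object.
#' @return A list with elements `stable` (logical) and `margin`
#'   (`k4 * k6 - k3 * k5`, in h^-2; positive when stable).
#' @examples
#' stability_check(mcf7_rates())
#' @export
stability_check <- function(rates) {
  rates <- as_dsb_rates(rates)
  margin <- rates[["k4"]] * rates[["k6"]] - rates[["k3"]] * rates[["k5"]]
  list(stable = margin > 0, margin = margin)
}

#' @export
print.dsb_rates <- function(x, ...) {
  cat("Single-site DSB repair rate constants (h^-1)\n")
  print(setNames(as.numeric(x), names(unclass(x))))
  sc <- stability_check(x)
  cat(sprintf("post-repair zero state: %s (margin k4*k6 - k3*k5 = %g)\n",
              if (sc$stable) "stable" else "UNSTABLE", sc$margin))
  invisible(x)
}

#' @export
print.dsb_state <- function(x, ...) {
  cat(sprintf("DSB site state: X=%d Y=%d Z=%d Q=%d\n",
              x[[1]], x[[2]], x[[3]], x[[4]]))
  invisible(x)
}
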