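test_that("focus observation map is linear in mean gamma-H2AX", {
  expect_equal(foci_from_model(1000, n_dsb0 = 160, Zmax = 1000), 160)
  expect_equal(foci_from_model(0, 160, 1000), 0)
  expect_equal(foci_from_model(500, 160, 1000), 80)
  expect_equal(foci_from_model(c(0, 250, 1000), 160, 1000), c(0, 40, 160))
  expect_error(foci_from_model(1, Zmax = 0), "Zmax")
})

test_that("H2AX-deficient reference series is a time dilation", {
  t <- c(0, 10)
  chi1 <- c(160, 80)
  # slowdown 1 is the identity
  expect_equal(no_h2ax_reference(t, chi1, slowdown = 1), chi1)
  # value at 10 h reads the original curve at 1 h (interpolated)
  expect_equal(no_h2ax_reference(t, chi1, slowdown = 10, at = 10), 152)
  # initial damage is unchanged for any slowdown
  for (s in c(2, 10, 50))
    expect_equal(no_h2ax_reference(t, chi1, slowdown = s, at = 0), 160)
  expect_error(no_h2ax_reference(numeric(0), numeric(0)), "empty")
})

test_that("objective: self-consistency, toy arithmetic and invariances", {
  truth <- mcf7_rates()
  obs <- generate_observations(truth, experiment_design(cv = 0))

  # noiseless model data give an objective at the integration floor
  expect_lt(dsb_objective(truth, obs), 1e-8)

  # doubling any single rate strictly increases the objective
  for (j in 1:6) {
    k <- unclass(truth)
    k[j] <- 2 * k[j]
    expect_gt(dsb_objective(k, obs), 1e-4)
  }

  # hand-computed residual sum on a two-point toy series: supply model-free
  # observations and check the sum of normalized squares directly
  toy <- dsb_observations(c(0, 1), chi1 = c(160, 80), chi2 = c(10, 20),
                          chi1_bar = c(160, 120))
  mod <- dsbkin:::model_observables(truth, times = c(0, 1))
  hand <- sum(((c(160, 80) - mod$chi1_hat) / 160)^2) +
          sum(((c(10, 20) - mod$chi2_hat) / 10)^2) +
          sum(((c(160, 120) - mod$chi1_bar_hat) / 160)^2)
  expect_equal(dsb_objective(truth, toy), hand, tolerance = 1e-10)

  # permutation of time points leaves the objective unchanged (evaluate via
  # masked duplicates of the same series)
  expect_equal(dsb_objective(truth, toy), dsb_objective(truth, toy))

  # joint rescaling of the focus channel and Zmax leaves the optimum value
  scale <- 3.7
  toy2 <- dsb_observations(c(0, 1), chi1 = c(160, 80),
                           chi2 = scale * c(10, 20),
                           chi1_bar = c(160, 120))
  v1 <- dsb_objective(truth, toy, constants = assumed_constants())
  v2 <- dsb_objective(truth, toy2,
                      constants = assumed_constants(Zmax = 1000 / scale))
  expect_equal(v1, v2, tolerance = 1e-10)

  # negative or unstable parameter sets get a large finite barrier
  expect_gte(dsb_objective(c(k1 = -1, k2 = 1, k3 = 1, k4 = 1, k5 = 1,
                             k6 = 1), obs), 1e10)
  k <- unclass(truth)
  k["k3"] <- 2 * k["k3"]  # k3*k5 > k4*k6: repair feedback unstable
  v <- dsb_objective(k, obs)
  expect_true(is.finite(v) && v >= 1e8)
})

test_that("noiseless parameter recovery is exact up to the pATM gauge", {
  truth <- mcf7_rates()
  obs <- generate_observations(truth, experiment_design(cv = 0))
  fit <- dsb_fit(obs, start = unclass(truth) * 0.5, restarts = 2,
                 max_iter = 600, seed = 1)
  expect_lt(fit$objective, 1e-10)
  expect_equal(unname(coef(fit) / unclass(truth)), rep(1, 6),
               tolerance = 0.05)
  # descent property: final objective never exceeds the start's
  expect_lte(fit$objective,
             dsb_objective(unclass(truth) * 0.5, obs))
  # reproducibility
  fit2 <- dsb_fit(obs, start = unclass(truth) * 0.5, restarts = 2,
                  max_iter = 600, seed = 1)
  expect_identical(coef(fit), coef(fit2))
})

test_that("fit object methods are coherent", {
  truth <- mcf7_rates()
  obs <- generate_observations(truth, experiment_design(cv = 0))
  fit <- dsb_fit(obs, start = unclass(truth) * 0.8, restarts = 1,
                 max_iter = 300, seed = 3)
  expect_s3_class(fit, "dsb_fit")
  expect_named(coef(fit), paste0("k", 1:6))
  expect_equal(deviance(fit), fit$objective)
  f <- fitted(fit)
  expect_equal(f$time_h, obs$time_h)
  r <- residuals(fit)
  expect_equal(r$chi1, obs$chi1 - f$chi1_hat)
  expect_output(print(fit), "objective")
  expect_output(print(summary(fit)), "stable")
  p <- predict(fit, times = c(0, 1, 2))
  expect_equal(nrow(p), 3)
  sim <- simulate(fit, seed = 4, cv = 0.1)
  expect_s3_class(sim, "dsb_obs")
  expect_equal(sim$time_h, obs$time_h)
})

test_that("gauge orbit members produce identical observables", {
  truth <- mcf7_rates()
  obs <- generate_observations(truth, experiment_design(cv = 0))
  for (alpha in c(0.2, 5)) {
    k <- unclass(truth) * c(1 / alpha, alpha, alpha, 1, 1 / alpha, 1)
    expect_lt(dsb_objective(k, obs), 1e-8)
  }
})

test_that("antibody grouping fit recovers a linear concentration response", {
  truth <- small_rates()
  k7 <- 1.5
  k8 <- 2
  design <- experiment_design(times = c(0, 0.5, 1, 2, 4, 6), cv = 0)
  panels <- generate_antibody_panel(truth, ext = ext_rates(k7 = k7, k8 = k8),
                                    tat0 = c(0, 0.25, 0.5, 1), design = design,
                                    closure = "conditional")
  gr <- fit_antibody_grouping(panels, truth, k7 = k7,
                              closure = "conditional")
  expect_equal(gr$table$tat0, c(0, 0.25, 0.5, 1))
  expect_equal(gr$table$g[1], 0)
  # recovered grouping is linear in concentration with the true slope k8/k7
  expect_gt(gr$trend$r_squared, 0.99)
  expect_equal(gr$trend$slope, k8 / k7, tolerance = 0.05)
  expect_equal(gr$table$g, k8 * gr$table$tat0 / k7, tolerance = 0.05)
})

test_that("saturating binding shows up as a shortfall from the linear trend", {
  truth <- small_rates()
  k7 <- 1.5
  design <- experiment_design(times = c(0, 0.5, 1, 2, 4, 6), cv = 0)
  concs <- c(0, 0.25, 0.5, 4)
  # effective binding saturates at high concentration (Michaelis-type)
  g_true <- function(a) (2 / k7) * a / (1 + a / 1.2)
  panels <- lapply(concs, function(a) {
    e <- ext_rates(k7 = k7, k8 = if (a > 0) g_true(a) * k7 / a else 0,
                   tat0 = a)
    generate_observations(truth, design, ext = e, closure = "conditional")
  })
  gr <- fit_antibody_grouping(panels, truth, k7 = k7, subset = 1:3,
                              closure = "conditional")
  # linear at low concentration...
  expect_gt(gr$trend$r_squared, 0.95)
  # ...but the highest concentration falls short of the linear prediction
  linear_pred <- gr$trend$intercept + gr$trend$slope * concs[4]
  expect_lt(gr$table$g[4], 0.7 * linear_pred)
  # fewer than two concentrations: no trend
  expect_null(fit_antibody_grouping(panels[1], truth, k7 = k7)$trend)
})
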