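test_that("the L1 cost is zero at truth and linear in a uniform offset", {
  coh <- fx_clean_subject()
  s <- coh$truth$subjects[[1]]
  c0 <- ehc_cost(s$params, s$meals, coh$measurements)
  # solver-tolerance floor over the 198 grid cells
  expect_lt(c0, 1e-6 * 198)
  # shifting every measured value by delta adds 198*delta
  delta <- 0.37
  shifted <- coh$measurements
  shifted$conc_umol_per_L <- shifted$conc_umol_per_L + delta
  expect_equal(ehc_cost(s$params, s$meals, shifted), c0 + 198 * delta,
               tolerance = 1e-6)
  # species weights scale their contribution
  wcost <- ehc_cost(s$params, s$meals, shifted,
                    species_weights = c(gCA = 0))
  expect_equal(wcost, (198 - 33) * delta, tolerance = 1e-3)
})

test_that("an unsimulatable candidate costs Inf instead of erroring", {
  coh <- fx_clean_subject()
  s <- coh$truth$subjects[[1]]
  bad <- unclass(s$params)
  bad["V_plasma"] <- 1e-12 # clearance rate CL/V explodes
  bad <- structure(bad, class = "ehc_subject_params")
  expect_true(is.infinite(ehc_cost(bad, s$meals, coh$measurements)) ||
                ehc_cost(bad, s$meals, coh$measurements) > 1e6)
})

test_that("fitting from the bounds midpoint recovers a clean subject", {
  coh <- fx_clean_subject()
  s <- coh$truth$subjects[[1]]
  fit <- ehc_fit(coh$measurements,
                 config = fit_config(n_restarts = 1, iter_max = 150,
                                     eval_max = 8000, seed = 1))
  expect_s3_class(fit, "ehc_fit")
  expect_equal(fit$n_free, 34L)
  expect_lt(fit$cost, 5) # mean absolute error well under the signal scale
  # fitted trajectory close to the truth trajectory
  tp <- as.numeric(simulate_meals(s$params, s$meals)[[1]]$conc)
  fp <- as.numeric(simulate_meals(fit$subject, fit$meals)[[1]]$conc)
  expect_lt(sqrt(mean((fp - tp)^2)) / sqrt(mean(tp^2)), 0.05)
  # meal-specific parameters agree across meals where the data demand it:
  # identified emptying quantities, not the inert cap
  lagv <- vapply(fit$meals, `[[`, numeric(1), "t_lag")
  expect_lt(max(abs(lagv / mean(lagv) - 1)), 0.10)
  eject <- vapply(fit$meals, function(m) {
    1 - exp(-min(m[["k_empty"]] * m[["T_empty"]],
                 -log(1 - m[["F_eject"]])))
  }, numeric(1))
  expect_lt(max(abs(eject / mean(eject) - 1)), 0.10)
})

test_that("fits are deterministic given the seed and improve with restarts", {
  coh <- fx_clean_subject()
  cfg <- fit_config(n_restarts = 2, iter_max = 12, seed = 4)
  f1 <- ehc_fit(coh$measurements, config = cfg)
  f2 <- ehc_fit(coh$measurements, config = cfg)
  expect_identical(coef(f1), coef(f2))
  # restart sets are nested under a common seed, so the best cost is
  # non-increasing in the number of restarts
  f3 <- ehc_fit(coh$measurements,
                config = fit_config(n_restarts = 4, iter_max = 12, seed = 4))
  expect_lte(f3$cost, f1$cost)
  # ensemble is ordered by cost
  expect_equal(f3$ensemble$cost, sort(f3$ensemble$cost))
  # parameters respect the box bounds
  defaults <- ehckin:::.free_param_layout(3)
  b <- ehckin:::.free_param_bounds(defaults, cfg$bounds_factor)
  th <- coef(f3)
  expect_true(all(th >= b$lower - 1e-12 & th <= b$upper + 1e-12))
})

test_that("fit methods expose coefficients, predictions and residuals", {
  coh <- fx_clean_subject()
  fit <- ehc_fit(coh$measurements,
                 config = fit_config(n_restarts = 1, iter_max = 40, seed = 2))
  expect_length(coef(fit), 34L)
  pr <- predict(fit)
  expect_equal(nrow(pr), 3 * 11 * 6)
  expect_setequal(names(pr), c("subject_id", "meal_id", "time_min",
                               "species", "conc_umol_per_L"))
  rs <- residuals(fit)
  expect_equal(nrow(rs), nrow(coh$measurements))
  # residual definition: measured minus fitted
  key <- paste(rs$meal_id, rs$time_min, rs$species)
  fkey <- paste(pr$meal_id, pr$time_min, pr$species)
  expect_equal(rs$residual,
               rs$conc_umol_per_L - pr$conc_umol_per_L[match(key, fkey)])
  expect_output(print(fit), "Personal enterohepatic")
  sims <- simulate(fit, nsim = 2, seed = 9, noise_cv = 0.1)
  expect_length(sims, 2L)
  expect_false(identical(sims[[1]]$conc_umol_per_L,
                         sims[[2]]$conc_umol_per_L))
})

test_that("multi-subject tables require a subject id", {
  coh <- fx_small_cohort()
  expect_error(ehc_fit(coh$measurements), "subject_id")
  expect_error(ehc_fit(coh$measurements, subject_id = "nope"), "no rows")
})
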