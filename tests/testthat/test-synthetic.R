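test_that("Harris-Benedict sizing matches the male equation", {
  hb <- harris_benedict(70, 175, 25)
  expect_equal(hb$daily_kcal, 1735.65, tolerance = 1e-9)
  expect_equal(hb$meal_kcal, 564.09, tolerance = 1e-4)
  expect_error(harris_benedict(70, 175, 25, sex = "female"), "male-only")
  expect_error(harris_benedict(0, 175, 25), "positive")
})

test_that("the default cohort reproduces the study structure", {
  coh <- generate_cohort(cohort_spec(seed = 1))
  tab <- coh$measurements
  expect_equal(nrow(tab), 8 * 3 * 11 * 6)
  expect_equal(length(unique(tab$subject_id)) *
                 length(unique(tab$meal_id)), 24) # meal tests
  expect_setequal(unique(tab$time_min), mmt_schedule())
  expect_setequal(unique(tab$species), ehc_species()$species)
  expect_true(all(tab$conc_umol_per_L >= coh$spec$lod))
  # ground truth sidecar carries full parameter sets
  s <- coh$truth$subjects[[1]]
  expect_length(s$params, 22L)
  expect_length(s$meals, 3L)
  expect_length(s$meals[[2]], 4L)
})

test_that("generation is bitwise deterministic in the seed", {
  a <- generate_cohort(cohort_spec(n_subjects = 2, seed = 7))
  b <- generate_cohort(cohort_spec(n_subjects = 2, seed = 7))
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth$subjects[[2]]$params, b$truth$subjects[[2]]$params)
  c <- generate_cohort(cohort_spec(n_subjects = 2, seed = 8))
  expect_false(identical(a$measurements$conc_umol_per_L,
                         c$measurements$conc_umol_per_L))
  # and the caller's RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_cohort(cohort_spec(n_subjects = 1)))
  expect_identical(runif(1), before)
})

test_that("degenerate spreads collapse to the default subject", {
  spec <- cohort_spec(n_subjects = 2, seed = 3, subject_gsd = 1,
                      fraction_gsd = 1, meal_gsd = 1)
  coh <- generate_cohort(spec)
  for (s in coh$truth$subjects) {
    expect_equal(unclass(s$params), unclass(subject_params()),
                 tolerance = 1e-12)
    expect_equal(unclass(s$meal_baseline), unclass(meal_params()),
                 tolerance = 1e-12)
  }
})

test_that("zero noise and jitter give three identical noiseless curves", {
  coh <- fx_clean_subject()
  tab <- coh$measurements
  m1 <- tab[tab$meal_id == "M1", "conc_umol_per_L"]
  m2 <- tab[tab$meal_id == "M2", "conc_umol_per_L"]
  m3 <- tab[tab$meal_id == "M3", "conc_umol_per_L"]
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_equal(m2, m3, tolerance = 1e-12)
  # and equals the noise-free model output
  s <- coh$truth$subjects[[1]]
  sim <- simulate_meals(s$params, s$meals[1])[[1]]
  expect_equal(m1, pmax(as.numeric(sim$conc), coh$spec$lod),
               tolerance = 1e-9)
})

test_that("subject heterogeneity matches the log-normal target", {
  spec <- cohort_spec(subject_gsd = 1.3)
  draws <- vapply(1:100, function(i) {
    sample_subject(spec, seed = 1000 + i)$params[["k_act_dist"]]
  }, numeric(1))
  emp_cv <- sd(draws) / mean(draws)
  theo_cv <- sqrt(exp(log(1.3)^2) - 1)
  expect_lt(abs(emp_cv - theo_cv) / theo_cv, 0.20)
  # fractions are clipped into (0.01, 0.99)
  fr <- vapply(1:50, function(i) {
    sample_subject(cohort_spec(fraction_gsd = 2), seed = i)$params[["f_gb"]]
  }, numeric(1))
  expect_true(all(fr > 0.009 & fr < 0.991))
})

test_that("measurement noise has the configured multiplicative CV", {
  spec <- cohort_spec(n_subjects = 2, seed = 11, noise_cv = 0.10,
                      meal_jitter_cv = 0)
  coh <- generate_cohort(spec)
  clean <- coh$truth$clean$conc_umol_per_L
  noisy <- coh$measurements$conc_umol_per_L
  keep <- clean > 0.05 # away from the detection floor
  ratio <- noisy[keep] / clean[keep]
  expect_equal(sd(log(ratio)), sqrt(log(1 + 0.1^2)), tolerance = 0.15)
  expect_equal(median(ratio), 1, tolerance = 0.05)
})
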