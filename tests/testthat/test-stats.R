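test_that("trapezoidal auc and iauc match hand-computed values", {
  expect_equal(auc(c(0, 1, 2), c(0, 1, 0)), 1.0)
  expect_equal(auc(c(0, 15, 30), c(1, 3, 2)), 67.5)
  expect_equal(iauc(c(0, 15, 30), c(1, 3, 2)), 37.5)
  tt <- seq(0, 240, 15)
  expect_equal(auc(tt, rep(3.2, length(tt))), 240 * 3.2)
  expect_equal(iauc(tt, rep(3.2, length(tt))), 0)
  # below-baseline curves give negative iauc
  expect_lt(iauc(c(0, 60, 120), c(2, 1, 1)), 0)
  expect_error(auc(c(0, 30, 15), c(1, 2, 3)), "increasing")
  expect_error(auc(0, 1), ">= 2")
})

test_that("auc agrees with a fine-grid Riemann oracle on random curves", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    tt <- sort(runif(n, 0, 240))
    vv <- runif(n, 0, 10)
    # oracle: midpoint Riemann sum on the piecewise-linear interpolant
    # Riemann oracle: fine midpoint sum within each linear segment
    oracle <- sum(vapply(seq_len(n - 1), function(k) {
      g <- seq(tt[k], tt[k + 1], length.out = 201)
      mid <- (g[-1] + g[-length(g)]) / 2
      sum(approx(tt, vv, xout = mid)$y * diff(g))
    }, numeric(1)))
    expect_equal(auc(tt, vv), oracle, tolerance = 1e-10)
  }
})

test_that("cv follows the sample-SD definition and rejects non-positive means", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(1, 2, 3)), 50)
  expect_equal(cv(c(2, 4)), 47.14045, tolerance = 1e-6)
  expect_error(cv(c(-1, 1)), "undefined CV")
  expect_error(cv(3), ">= 2")
  # scale invariance
  set.seed(1)
  x <- rlnorm(10)
  for (a in c(0.01, 1, 250)) expect_equal(cv(a * x), cv(x))
})

test_that("intra-CV summarizes per-subject meal variation with a t-based CI", {
  r <- intra_cv(rbind(c(10, 20, 30), c(5, 5, 5)))
  expect_equal(unname(r$per_subject), c(50, 0))
  expect_equal(r$mean, 25)
  # identical intra-CVs across subjects: zero-width CI at that value
  r2 <- intra_cv(matrix(rep(c(1, 2, 3), each = 8), nrow = 8))
  expect_equal(unname(r2$per_subject), rep(50, 8))
  expect_equal(r2$ci_lower, 50)
  expect_equal(r2$ci_upper, 50)
  # CI matches the textbook t interval
  set.seed(7)
  m <- matrix(rlnorm(24, 1, 0.3), nrow = 8)
  r3 <- intra_cv(m)
  ci <- t.test(r3$per_subject)$conf.int
  expect_equal(c(r3$ci_lower, r3$ci_upper), as.numeric(ci), tolerance = 1e-10)
})

test_that("inter-CV is per meal day across subjects and permutation invariant", {
  m <- cbind(M1 = c(100, 200, 300, 400), M2 = c(100, 110, 90, 100))
  r <- inter_cv(m)
  expect_equal(unname(r["M1"]), 51.63978, tolerance = 1e-5)
  expect_equal(unname(inter_cv(m[c(3, 1, 4, 2), ])), unname(r))
  # identical subjects on a day: zero inter-CV
  expect_equal(unname(inter_cv(cbind(rep(7, 5))))[1], 0)
})

test_that("peak returns the maximum and the earliest attaining time", {
  expect_equal(ba_peak(c(0, 15, 30), c(0, 1, 0)), list(peak = 1, time = 15))
  expect_equal(ba_peak(c(0, 15, 30), c(1, 2, 3))$time, 30) # monotone rise
  expect_equal(ba_peak(c(0, 15, 30), c(2, 5, 5))$time, 15) # tie: earlier
})

test_that("groupings partition the species exactly", {
  tab <- fx_small_cohort()$measurements
  tot <- ba_group(tab, "total")
  pri <- ba_group(tab, "primary")
  sec <- ba_group(tab, "secondary")
  gly <- ba_group(tab, "glycine_conjugated")
  unc <- ba_group(tab, "unconjugated")
  expect_equal(tot$value, pri$value + sec$value, tolerance = 1e-12)
  expect_equal(tot$value, gly$value + unc$value, tolerance = 1e-12)
  # a single nonzero species: its group equals that species
  one <- tab
  one$conc_umol_per_L[one$species != "gCA"] <- 0
  g <- ba_group(one, "glycine_conjugated")
  sp <- one[one$species == "gCA", ]
  sp <- sp[order(sp$subject_id, sp$meal_id, sp$time_min), ]
  expect_equal(g$value, sp$conc_umol_per_L)
  # incomplete grid is rejected
  expect_error(ba_group(tab[-1, ], "total"), "incomplete")
})

test_that("variability report carries the meal-wise scheme and the >20% flag", {
  rep <- variability_report(fx_small_cohort()$measurements,
                            metrics = c("auc", "peak"))
  expect_setequal(unique(rep$grouping),
                  c("total", "primary", "secondary", "glycine_conjugated",
                    "unconjugated"))
  need <- c("mean_M1", "mean_M2", "mean_M3", "cv_pct", "inter_cv_M1",
            "inter_cv_M2", "inter_cv_M3", "intra_cv_mean", "intra_cv_lo",
            "intra_cv_hi", "high_variability")
  got <- rep$statistic[rep$grouping == "total" & rep$metric == "auc"]
  expect_setequal(got, need)
  flags <- rep$value[rep$statistic == "high_variability"]
  cvs <- rep$value[rep$statistic == "cv_pct"]
  expect_equal(flags, as.numeric(!is.na(cvs) & cvs > 20))
})

test_that("zero-noise zero-jitter cohorts have zero intra-CV everywhere", {
  coh <- fx_clean_subject()
  curves <- ba_group(coh$measurements, "total")
  pk <- sapply(split(curves, curves$meal_id), function(d) max(d$value))
  expect_equal(cv(pk), 0, tolerance = 1e-10)
  au <- sapply(split(curves, curves$meal_id),
               function(d) auc(d$time_min, d$value))
  expect_equal(cv(au), 0, tolerance = 1e-10)
})
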