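# Descriptive postprandial statistics: grouped bile acid pools, trapezoidal
# AUC / incremental AUC, peaks, and the coefficient-of-variation scheme
# (meal-test CV, per-day inter-CV across subjects, per-subject intra-CV
# across repeated meals).

.GROUPINGS <- c("total", "primary", "secondary", "glycine_conjugated",
                "unconjugated")

.grouping_species <- function(grouping) {
  sp <- ehc_species()
  switch(grouping,
    total = sp$species,
    primary = sp$species[sp$class == "primary"],
    secondary = sp$species[sp$class == "secondary"],
    glycine_conjugated = sp$species[sp$conjugation == "glycine"],
    unconjugated = sp$species[sp$conjugation == "unconjugated"],
    stop("unknown grouping: ", grouping, call. = FALSE)
  )
}

#' Group species into bile acid pools
#'
#' Pointwise sums of the measured species into the standard pools: `total`
#' (all species), `primary` (CA + CDCA forms), `secondary` (DCA forms),
#' `glycine_conjugated` and `unconjugated`.
#'
#' @param table Long-format measurement table (see [generate_cohort()]).
#' @param grouping One of `"total"`, `"primary"`, `"secondary"`,
#'   `"glycine_conjugated"`, `"unconjugated"`.
#' @return Data frame with columns `subject_id`, `meal_id`, `time_min`,
#'   `value` (micromol/L), one response curve per subject and meal.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 1, seed = 1))
#' head(ba_group(coh$measurements, "primary"))
#' @export
ba_group <- function(table, grouping = .GROUPINGS) {
  grouping <- match.arg(grouping)
  .check_measurements(table)
  want <- .grouping_species(grouping)
  sub <- table[table$species %in% want, , drop = FALSE]
  agg <- stats::aggregate(
    conc_umol_per_L ~ subject_id + meal_id + time_min, data = sub,
    FUN = function(v) {
      if (length(v) != length(want)) {
        stop("incomplete species grid in measurement table", call. = FALSE)
      }
      sum(v)
    }
  )
  names(agg)[names(agg) == "conc_umol_per_L"] <- "value"
  agg[order(agg$subject_id, agg$meal_id, agg$time_min), , drop = FALSE]
}

#' Trapezoidal area under a response curve
#'
#' `auc()` integrates the concentration-time curve with the trapezoidal
#' rule; `iauc()` does the same after subtracting the fasting baseline
#' (the value at the first time point), and may be negative when the curve
#' dips below baseline.
#'
#' @param times Strictly increasing sampling times (min).
#' @param values Concentrations (micromol/L), same length as `times`.
#' @param baseline Baseline for `iauc()`; defaults to `values[1]`.
#' @return Area in micromol/L x min.
#' @examples
#' auc(c(0, 15, 30), c(1, 3, 2))  # 67.5
#' iauc(c(0, 15, 30), c(1, 3, 2)) # 37.5
#' @export
auc <- function(times, values) {
  if (length(times) < 2L || length(times) != length(values)) {
    stop("need >= 2 (time, value) pairs of equal length", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  sum(diff(times) * (values[-1] + values[-length(values)]) / 2)
}

#' @rdname auc
#' @export
iauc <- function(times, values, baseline = values[1]) {
  auc(times, values - baseline)
}

#' Coefficient of variation (percent)
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' times 100. Undefined for non-positive means -- as happens for incremental
#' AUCs of the essentially flat unconjugated responses -- in which case an
#' error is raised (the report functions convert this to a missing value).
#'
#' @param values Numeric vector, length >= 2.
#' @return CV in percent (>= 0).
#' @examples
#' cv(c(1, 2, 3)) # 50
#' cv(c(2, 4))    # 70.71
#' @export
cv <- function(values) {
  if (length(values) < 2L) stop("cv needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop("undefined CV: mean is not positive", call. = FALSE)
  }
  100 * stats::sd(values) / m
}

.cv_safe <- function(values) {
  tryCatch(cv(values), error = function(e) NA_real_)
}

#' Intraindividual coefficient of variation
#'
#' One CV per subject across that subject's repeated meals, summarized as
#' the mean with a t-based 95% confidence interval across subjects.
#'
#' @param x Numeric matrix, subjects in rows, meals in columns (no missing
#'   cells).
#' @return List with `per_subject` (named CVs, %), `mean`, `ci_lower`,
#'   `ci_upper` (95% CI of the mean intra-CV), and `n`.
#' @examples
#' intra_cv(rbind(s1 = c(10, 20, 30), s2 = c(5, 5, 5)))
#' @export
intra_cv <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("intra_cv needs a complete matrix", call. = FALSE)
  per <- apply(x, 1L, .cv_safe)
  vals <- per[!is.na(per)]
  n <- length(vals)
  if (n == 0L) {
    return(list(per_subject = per, mean = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, n = 0L))
  }
  m <- mean(vals)
  half <- if (n > 1L && stats::sd(vals) > 0) {
    stats::qt(0.975, df = n - 1L) * stats::sd(vals) / sqrt(n)
  } else 0
  list(per_subject = per, mean = m, ci_lower = m - half, ci_upper = m + half,
       n = n)
}

#' Interindividual coefficient of variation per meal day
#'
#' One CV per meal column, computed across subjects.
#'
#' @param x Numeric matrix, subjects in rows, meals in columns.
#' @return Named numeric vector of per-meal CVs (%).
#' @examples
#' inter_cv(cbind(M1 = c(100, 200, 300, 400), M2 = c(100, 110, 90, 100)))
#' @export
inter_cv <- function(x) {
  x <- as.matrix(x)
  apply(x, 2L, .cv_safe)
}

#' Peak of a response curve
#'
#' @param times Sampling times (min).
#' @param values Concentrations.
#' @return List with `peak` (maximum value) and `time` (earliest time at
#'   which the maximum is attained).
#' @examples
#' ba_peak(c(0, 15, 30), c(0, 1, 0))
#' @export
ba_peak <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 1L)
  i <- which.max(values) # which.max returns the first maximum
  list(peak = values[i], time = times[i])
}

# subject x meal matrix of one scalar metric computed per response curve
.metric_matrix <- function(curves, fun) {
  split_sm <- split(curves, list(curves$subject_id, curves$meal_id),
                    drop = TRUE)
  vals <- vapply(split_sm, function(d) {
    d <- d[order(d$time_min), ]
    fun(d$time_min, d$value)
  }, numeric(1))
  ids <- do.call(rbind, strsplit(names(vals), ".", fixed = TRUE))
  subjects <- sort(unique(ids[, 1]))
  meals <- sort(unique(ids[, 2]))
  m <- matrix(NA_real_, length(subjects), length(meals),
              dimnames = list(subjects, meals))
  m[cbind(match(ids[, 1], subjects), match(ids[, 2], meals))] <- vals
  m
}

#' Variability report for a measurement table
#'
#' Computes, for every bile acid grouping and metric (AUC, incremental AUC,
#' peak concentration, and optionally each sampling time point), the
#' meal-wise means, the meal-test CV (CV of the three meal means), the
#' per-day interindividual CVs, and the intraindividual CV summary (mean
#' and 95% CI across subjects), with a >20% high-variability flag on the
#' meal-test CV. Undefined CVs (non-positive means) are reported as `NA`.
#'
#' @param table Long-format measurement table.
#' @param metrics Metrics to report; subset of `"auc"`, `"iauc"`, `"peak"`,
#'   `"timepoints"`.
#' @param high_cv Threshold (percent) for the high-variability flag
#'   (default 20).
#' @return Tidy data frame with columns `grouping`, `metric`, `statistic`,
#'   `value`; statistics are `mean_M*`, `cv_pct`, `inter_cv_M*`,
#'   `intra_cv_mean`, `intra_cv_lo`, `intra_cv_hi`, `high_variability`
#'   (0/1 on the meal-test CV).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_subjects = 3, seed = 2))
#' rep <- variability_report(coh$measurements, metrics = c("auc", "peak"))
#' head(rep)
#' @export
variability_report <- function(table, metrics = c("auc", "iauc", "peak"),
                               high_cv = 20) {
  metrics <- match.arg(metrics, c("auc", "iauc", "peak", "timepoints"),
                       several.ok = TRUE)
  .check_measurements(table)
  out <- list()
  for (g in .GROUPINGS) {
    curves <- ba_group(table, g)
    mm <- list()
    if ("auc" %in% metrics) mm$auc <- .metric_matrix(curves, auc)
    if ("iauc" %in% metrics) mm$iauc <- .metric_matrix(curves, iauc)
    if ("peak" %in% metrics) {
      mm$peak <- .metric_matrix(curves, function(t, v) ba_peak(t, v)$peak)
    }
    if ("timepoints" %in% metrics) {
      for (tp in sort(unique(curves$time_min))) {
        mm[[sprintf("conc_t%g", tp)]] <- .metric_matrix(
          curves[curves$time_min == tp, , drop = FALSE],
          function(t, v) v[1]
        )
      }
    }
    for (metric in names(mm)) {
      m <- mm[[metric]]
      meal_means <- colMeans(m)
      icv <- intra_cv(m)
      ecv <- inter_cv(m)
      cvp <- .cv_safe(meal_means)
      stat <- c(
        stats::setNames(meal_means, paste0("mean_", colnames(m))),
        cv_pct = cvp,
        stats::setNames(ecv, paste0("inter_cv_", colnames(m))),
        intra_cv_mean = icv$mean, intra_cv_lo = icv$ci_lower,
        intra_cv_hi = icv$ci_upper,
        high_variability = as.numeric(!is.na(cvp) && cvp > high_cv)
      )
      out[[paste(g, metric)]] <- data.frame(
        grouping = g, metric = metric, statistic = names(stat),
        value = unname(stat), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
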