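# Shared fixtures, built once per test run. Everything is generated in code;
# seeds are fixed so the suite is deterministic.

.fx <- new.env()

# a clean (noise- and jitter-free) one-subject cohort with known truth
fx_clean_subject <- function() {
  if (is.null(.fx$clean)) {
    .fx$clean <- generate_cohort(
      cohort_spec(n_subjects = 1, seed = 5, noise_cv = 0, meal_jitter_cv = 0))
  }
  .fx$clean
}

# small noisy cohort (3 subjects) for statistics / io tests
fx_small_cohort <- function() {
  if (is.null(.fx$small)) {
    .fx$small <- generate_cohort(cohort_spec(n_subjects = 3, seed = 2))
  }
  .fx$small
}

fx_default_sim <- function() {
  if (is.null(.fx$sim)) {
    .fx$sim <- ehc_simulate(subject_params(), meal_params())
  }
  .fx$sim
}

# truth as a flat named vector matching coef(ehc_fit)
fx_truth_vector <- function(subj) {
  c(unclass(subj$params),
    unlist(lapply(seq_along(subj$meals), function(m) {
      v <- unclass(subj$meals[[m]])
      names(v) <- paste0("M", m, ".", names(v))
      v
    })))
}
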