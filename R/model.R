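# Model core: mass-balance ODE system of the enterohepatic circulation of
# six bile acid species with meal-triggered gallbladder emptying.
#
# All rate laws are first order in the source amount, so the system is
# linear time-varying:  dy/dt = A0 y + s + e(t) E y + b(t) B y, with e(t)
# the enhanced gallbladder emptying amplitude and b(t) the refill-bypass
# window (both smooth logistic-product windows). The fasted (meal-free)
# system is linear time-invariant, which gives the fasting steady state by
# direct linear solve.

.WINDOW_STEEP <- 2 # min; fixed steepness of the logistic window edges

# Build the constant part of the system: source vector s and matrix A0
# (37 x 37), plus routing coefficients needed for the time-varying terms.
.build_system <- function(p) {
  ix <- .state_index
  n <- .N_STATE
  A <- matrix(0, n, n)
  s <- numeric(n)

  kL <- .K_LIVER_SECRETION
  f_c <- p[["k_hep_conj"]] / (1 + p[["k_hep_conj"]])
  f_u <- p[["k_hep_unconj"]] / (1 + p[["k_hep_unconj"]])
  f_re <- p[["f_reconj"]]

  liver <- ix$liver; gb <- ix$gallbladder
  sp <- ix$si_proximal; sd <- ix$si_distal; co <- ix$colon
  pl <- ix$plasma; fe <- ix$feces_cumulative; tr <- ix$transform_loss
  conj <- 1:3; unconj <- 4:6

  # Portal uptake of conjugated species j (acid index j): first-pass split
  # between liver (extraction f_c) and systemic plasma spillover.
  take_conj <- function(src, j, rate) {
    A[liver[j], src] <<- A[liver[j], src] + rate * f_c
    A[pl[conj][j], src] <<- A[pl[conj][j], src] + rate * (1 - f_c)
    A[src, src] <<- A[src, src] - rate
  }
  # Portal uptake of unconjugated species (acid index j): extracted portion
  # is reconjugated (fraction f_reconj) into the hepatic conjugated pool or
  # immediately re-secreted unconjugated into the proximal SI.
  take_unconj <- function(src, j, rate) {
    A[liver[j], src] <<- A[liver[j], src] + rate * f_u * f_re
    A[sp[unconj][j], src] <<- A[sp[unconj][j], src] + rate * f_u * (1 - f_re)
    A[pl[unconj][j], src] <<- A[pl[unconj][j], src] + rate * (1 - f_u)
    A[src, src] <<- A[src, src] - rate
  }
  move <- function(from, to, rate) {
    for (k in seq_along(from)) {
      A[to[k], from[k]] <<- A[to[k], from[k]] + rate
      A[from[k], from[k]] <<- A[from[k], from[k]] - rate
    }
  }

  # Hepatic synthesis: conjugated CA and CDCA only; DCA is never made in
  # the liver.
  s[liver[1]] <- p[["s_tot"]] * p[["r_CA"]]
  s[liver[2]] <- p[["s_tot"]] * (1 - p[["r_CA"]])

  # Hepatic bile secretion: fasted routing f_gb to gallbladder, remainder
  # directly to the duodenum.
  move(liver, gb, kL * p[["f_gb"]])
  move(liver, sp[conj], kL * (1 - p[["f_gb"]]))

  # Interdigestive gallbladder emptying.
  move(gb, sp[conj], p[["k_gb_basal"]])

  # Proximal SI: transit; passive uptake of unconjugated species.
  move(sp, sd, p[["k_trans_prox"]])
  for (j in 1:3) take_unconj(sp[unconj][j], j, p[["k_pass_si"]])

  # Distal SI: transit to colon; active (ASBT) uptake of all species with a
  # DCA multiplier; microbial deconjugation; passive uptake (unconjugated).
  move(sd, co, p[["k_trans_dist"]])
  act <- p[["k_act_dist"]] * c(1, 1, p[["m_act_secondary"]])
  for (j in 1:3) {
    take_conj(sd[conj][j], j, act[j])
    take_unconj(sd[unconj][j], j, act[j] + p[["k_pass_si"]])
  }
  move(sd[conj], sd[unconj], p[["k_deconj_dist"]])

  # Colon: fecal transit; deconjugation; CA -> DCA dehydroxylation; CDCA
  # transformation to unmodeled species; passive uptake (unconjugated).
  move(co, fe, p[["k_trans_colon"]])
  move(co[conj], co[unconj], p[["k_deconj_colon"]])
  move(co[unconj][1], co[unconj][3], p[["k_dehydrox_CA"]])
  move(co[unconj][2], tr, p[["k_loss_CDCA"]])
  for (j in 1:3) take_unconj(co[unconj][j], j, p[["k_pass_colon"]])

  # Systemic plasma: concentration-driven hepatic clearance CL * C =
  # (CL / V) * amount. Cleared conjugated species join the hepatic pool;
  # cleared unconjugated species follow the hepatic reconjugation split.
  kcl <- p[["cl_plasma_hep"]] / p[["V_plasma"]]
  move(pl[conj], liver, kcl)
  for (j in 1:3) {
    A[liver[j], pl[unconj][j]] <- A[liver[j], pl[unconj][j]] + kcl * f_re
    A[sp[unconj][j], pl[unconj][j]] <- A[sp[unconj][j], pl[unconj][j]] +
      kcl * (1 - f_re)
    A[pl[unconj][j], pl[unconj][j]] <- A[pl[unconj][j], pl[unconj][j]] - kcl
  }

  list(A = A, s = s, c_bypass = kL * p[["f_gb"]] * p[["f_postprandial_bypass"]])
}

# Emptying/bypass window geometry for one meal. The enhanced window runs
# from t_open = start + t_lag for D = min(T_empty, -log(1-F_eject)/k_empty)
# minutes; its amplitude is rescaled so the windowed integral equals
# min(k_empty * T_empty, -log(1 - F_eject)), making F_eject the ejected
# fraction whenever it (rather than T_empty) is binding and refill is
# suppressed. Gallbladder refilling stays bypassed until k_gb_refill_delay
# past window close.
.meal_window <- function(subject, meal, event = meal_event()) {
  st <- .WINDOW_STEEP
  t_open <- event$start_time + meal[["t_lag"]]
  lnF <- -log(1 - meal[["F_eject"]])
  D <- if (is.finite(lnF)) min(meal[["T_empty"]], lnF / meal[["k_empty"]]) else
    meal[["T_empty"]]
  t_close <- t_open + D
  target <- min(meal[["k_empty"]] * meal[["T_empty"]], lnF)
  # Exact integral of the logistic-product window over the real line.
  cc <- D / st
  W <- if (cc > 1e-10) st * cc / (1 - exp(-cc)) else st
  list(t_open = t_open, t_close = t_close, amp = target / W,
       t_refill_end = t_close + subject[["k_gb_refill_delay"]], steep = st)
}

.window_value <- function(t, w) {
  stats::plogis((t - w$t_open) / w$steep) *
    stats::plogis((w$t_close - t) / w$steep)
}

.bypass_value <- function(t, w) {
  stats::plogis((t - w$t_open) / w$steep) *
    stats::plogis((w$t_refill_end - t) / w$steep)
}

.system_parms <- function(sys, w) {
  c(.N_STATE, w$t_open, w$t_close, w$amp, w$t_refill_end, sys$c_bypass,
    w$steep, sys$s, as.numeric(sys$A))
}

#' Time derivative of the model state
#'
#' Evaluates the mass-balance right-hand side of the enterohepatic
#' circulation model at one instant. Every efflux term of one compartment
#' appears as an influx to exactly one other compartment or sink, so total
#' mass is conserved up to synthesis (source) and the fecal/transformation
#' sinks.
#'
#' @param state Numeric state vector of length 37 (see [state_matrix()] for
#'   the layout), amounts in micromoles.
#' @param t Time (min).
#' @param subject Subject parameters from [subject_params()].
#' @param meals A list of meals, each a list with elements `params`
#'   ([meal_params()]) and optionally `event` ([meal_event()]); or a single
#'   [meal_params()] vector for one meal starting at t = 0. `NULL` gives the
#'   meal-free (fasted) system.
#' @return Numeric vector of the same length as `state`: d(state)/dt in
#'   micromol/min.
#' @examples
#' p <- subject_params()
#' d <- ehc_derivative(fasting_state(p), t = 30, subject = p,
#'                     meals = meal_params())
#' @export
ehc_derivative <- function(state, t, subject, meals = NULL) {
  if (length(state) != .N_STATE) {
    stop("state must have length ", .N_STATE, call. = FALSE)
  }
  if (any(state < -1e-8 * max(1, max(abs(state))))) {
    stop("invalid state: negative amounts beyond solver tolerance",
         call. = FALSE)
  }
  validate_subject_params(subject)
  meals <- .normalize_meals(meals)
  sys <- .build_system(subject)
  d <- as.numeric(sys$A %*% state) + sys$s
  for (m in meals) {
    w <- .meal_window(subject, m$params, m$event)
    e <- w$amp * .window_value(t, w)
    b <- .bypass_value(t, w) * sys$c_bypass
    gb <- .state_index$gallbladder
    spc <- .state_index$si_proximal[1:3]
    liver <- .state_index$liver
    g <- e * state[gb]
    r <- b * state[liver]
    d[gb] <- d[gb] - g - r
    d[spc] <- d[spc] + g + r
  }
  d
}

.normalize_meals <- function(meals) {
  if (is.null(meals)) return(list())
  if (inherits(meals, "ehc_meal_params") ||
      (is.numeric(meals) && length(meals) == 4L)) {
    meals <- list(list(params = meals))
  }
  lapply(meals, function(m) {
    if (is.numeric(m)) m <- list(params = m)
    validate_meal_params(m$params)
    if (is.null(m$event)) m$event <- meal_event()
    m
  })
}

#' Gallbladder emptying flux
#'
#' The emptying flux is `(k_gb_basal + k_enhanced(t)) * gb_amount`, where
#' the enhanced rate is a smooth logistic-product window opening at
#' `start_time + t_lag` and closing after the effective emptying duration
#' `min(T_empty, -log(1 - F_eject)/k_empty)`. The window amplitude is
#' rescaled internally so that, with refilling suppressed, the ejected
#' fraction of the window-start content equals
#' `1 - exp(-min(k_empty * T_empty, -log(1 - F_eject)))`.
#'
#' @param t Time or vector of times (min).
#' @param gb_amount Gallbladder content (micromol), must be nonnegative.
#' @param subject Subject parameters (supplies `k_gb_basal` and the refill
#'   delay).
#' @param meal Meal parameters from [meal_params()].
#' @param event Meal event; defaults to ingestion at t = 0.
#' @return Emptying flux in micromol/min, same length as `t`.
#' @examples
#' gallbladder_flux(c(0, 30, 120), 1500, subject_params(), meal_params())
#' @export
gallbladder_flux <- function(t, gb_amount, subject, meal,
                             event = meal_event()) {
  stopifnot(all(gb_amount >= 0))
  validate_subject_params(subject)
  validate_meal_params(meal)
  w <- .meal_window(subject, meal, event)
  (subject[["k_gb_basal"]] + w$amp * .window_value(t, w)) * gb_amount
}

#' Fasting steady state
#'
#' Computes the interdigestive (meal-free) steady state of the model. The
#' fasted system is linear and time-invariant, so the state solves a linear
#' system directly; the result is then verified by integrating the
#' meal-free model over a 12 h span and requiring every compartment pool to
#' change by less than 0.1% relative. If the direct solve is unusable
#' (degenerate parameters), integration from an empty gut continues in 12 h
#' blocks until the criterion is met, up to a 30-day cap.
#'
#' @param subject Subject parameters.
#' @param check Verify the state by re-integration (default `TRUE`).
#' @return Numeric state vector (length 37) with zeroed sink states.
#' @examples
#' st <- fasting_state(subject_params())
#' state_matrix(st)[, "gallbladder"]
#' @export
fasting_state <- function(subject, check = TRUE) {
  validate_subject_params(subject)
  sys <- .build_system(subject)
  dyn <- seq_len(.N_DYN)
  x <- try(solve(sys$A[dyn, dyn], -sys$s[dyn]), silent = TRUE)
  ok <- !inherits(x, "try-error") && all(is.finite(x)) && all(x > -1e-8) &&
    sum(x) < 1e9 # a pool this large means the system has no finite
                 # steady state (no effective exit route)
  state <- numeric(.N_STATE)
  if (ok) {
    state[dyn] <- pmax(x, 0)
    if (!check) return(state)
  } # else: relax from the empty state by integration
  span <- 720 # 12 h verification / relaxation blocks
  for (block in seq_len(if (ok) 1L else 60L)) {
    out <- .integrate(subject, state, times = c(0, span), meals = list())
    new <- out[nrow(out), 1 + dyn]
    denom <- pmax(abs(state[dyn]), 1e-9)
    drift <- max(abs(new - state[dyn]) / denom)
    state[dyn] <- pmax(new, 0)
    state[-dyn] <- 0
    if (drift < 1e-3) return(state)
  }
  stop("fasting state did not converge within the capped horizon",
       call. = FALSE)
}

# Low-level integration of one meal configuration (possibly meal-free) from
# a given initial state, using the compiled right-hand side and Jacobian.
.integrate <- function(subject, state, times, meals, rtol = 1e-6,
                       atol = 1e-9) {
  sys <- .build_system(subject)
  if (length(meals) == 0L) {
    w <- list(t_open = -1e8, t_close = -1e8 + 1, amp = 0,
              t_refill_end = -1e8 + 1, steep = .WINDOW_STEEP)
  } else if (length(meals) == 1L) {
    w <- .meal_window(subject, meals[[1]]$params, meals[[1]]$event)
  } else {
    stop("compiled path integrates one meal per run", call. = FALSE)
  }
  out <- deSolve::lsoda(
    y = state, times = times, func = "ehc_derivs", parms = .system_parms(sys, w),
    jacfunc = "ehc_jac", jactype = "fullusr", dllname = "ehckin",
    initfunc = "ehc_init", rtol = rtol, atol = atol,
    hmax = 4 * .WINDOW_STEEP
  )
  if (attr(out, "istate")[1L] < 0) {
    stop("ODE solver failed for subject parameter set (s_tot = ",
         signif(subject[["s_tot"]], 4), ")", call. = FALSE)
  }
  out
}

#' Simulate one mixed-meal test
#'
#' Integrates the model from the subject's fasting steady state through a
#' single liquid meal ingested at t = 0 and returns compartment amounts and
#' plasma concentrations on the requested time grid.
#'
#' @param subject Subject parameters ([subject_params()]).
#' @param meal Meal parameters ([meal_params()]).
#' @param times Strictly increasing sampling times (min), starting at 0.
#'   Defaults to the mixed-meal-test schedule [mmt_schedule()].
#' @param event Meal event (timing/energy); default ingestion at t = 0.
#' @param init Optional initial state; defaults to [fasting_state()].
#' @param rtol,atol Solver tolerances (relative; absolute in micromol).
#' @return An object of class `"ehc_sim"`: list with `times`, `states`
#'   (time x 37 state matrix), `conc` (6 x time matrix of plasma
#'   concentrations, micromol/L), `subject`, `meal`, and `flux_audit`
#'   (cumulative synthesis, fecal loss, transformation loss, and the total
#'   circulating pool per time point).
#' @examples
#' sim <- ehc_simulate(subject_params(), meal_params())
#' plot(sim)
#' @export
ehc_simulate <- function(subject, meal, times = mmt_schedule(),
                         event = meal_event(), init = NULL,
                         rtol = 1e-6, atol = 1e-9) {
  validate_subject_params(subject)
  validate_meal_params(meal)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (is.null(init)) init <- fasting_state(subject, check = FALSE)
  t0 <- times[1]
  out <- .integrate(subject, init, times,
                    meals = list(list(params = meal, event = event)),
                    rtol = rtol, atol = atol)
  states <- unname(out[, 1 + seq_len(.N_STATE), drop = FALSE])
  colnames(states) <- .state_names
  pl <- states[, .state_index$plasma, drop = FALSE]
  conc <- t(pl) / subject[["V_plasma"]]
  rownames(conc) <- ehc_species()$species
  dyn <- seq_len(.N_DYN)
  audit <- data.frame(
    time_min = times,
    cum_synthesis = subject[["s_tot"]] * (times - t0),
    cum_fecal = rowSums(states[, .state_index$feces_cumulative, drop = FALSE]),
    cum_transform = states[, .state_index$transform_loss],
    pool_total = rowSums(states[, dyn, drop = FALSE])
  )
  structure(
    list(times = times, states = states, conc = conc, subject = subject,
         meal = meal, event = event, flux_audit = audit),
    class = "ehc_sim"
  )
}

#' Simulate a subject's three meal tests
#'
#' One simulation per meal parameter set, all sharing the same subject
#' parameters and fasting initial state (each test follows an overnight
#' fast).
#'
#' @param subject Subject parameters.
#' @param meal_sets List of [meal_params()] vectors (typically 3).
#' @param times Sampling schedule (min).
#' @return List of [ehc_simulate()] results, one per meal.
#' @export
simulate_meals <- function(subject, meal_sets, times = mmt_schedule()) {
  init <- fasting_state(subject, check = FALSE)
  lapply(meal_sets, function(mp) {
    ehc_simulate(subject, mp, times = times, init = init)
  })
}

#' The mixed-meal-test sampling schedule
#'
#' Venous samples just before and 15, 30, 45, 60, 75, 90, 120, 150, 180 and
#' 240 minutes after meal ingestion.
#'
#' @return Numeric vector of 11 sampling times (min).
#' @export
mmt_schedule <- function() {
  c(0, 15, 30, 45, 60, 75, 90, 120, 150, 180, 240)
}

#' Mass-balance closure audit
#'
#' Relative closure residual of a simulation: the change of the circulating
#' pool must equal cumulative synthesis minus cumulative fecal loss minus
#' cumulative colonic CDCA transformation loss.
#'
#' @param sim An `"ehc_sim"` object.
#' @return Dimensionless residual (relative to the final pool size).
#' @examples
#' mass_balance(ehc_simulate(subject_params(), meal_params()))
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "ehc_sim"))
  a <- sim$flux_audit
  n <- nrow(a)
  d_pool <- a$pool_total[n] - a$pool_total[1]
  expected <- (a$cum_synthesis[n] - a$cum_synthesis[1]) -
    (a$cum_fecal[n] - a$cum_fecal[1]) -
    (a$cum_transform[n] - a$cum_transform[1])
  abs(d_pool - expected) / a$pool_total[n]
}

#' @export
print.ehc_sim <- function(x, ...) {
  cat("Enterohepatic circulation simulation\n")
  cat(sprintf("  %d time points over %g min; meal at t = %g min\n",
              length(x$times), max(x$times), x$event$start_time))
  tot <- colSums(x$conc)
  cat(sprintf("  total plasma bile acid: %.2f (t=0) -> peak %.2f umol/L at %g min\n",
              tot[1], max(tot), x$times[which.max(tot)]))
  invisible(x)
}

#' @export
plot.ehc_sim <- function(x, which = c("plasma", "total"), ...) {
  which <- match.arg(which)
  if (which == "total") {
    graphics::plot(x$times, colSums(x$conc), type = "l", lwd = 2,
                   xlab = "time (min)",
                   ylab = "total plasma bile acids (umol/L)", ...)
  } else {
    graphics::matplot(x$times, t(x$conc), type = "l", lty = 1,
                      xlab = "time (min)",
                      ylab = "plasma concentration (umol/L)", ...)
    graphics::legend("topright", legend = rownames(x$conc), col = 1:6,
                     lty = 1, cex = 0.8, bty = "n")
  }
  invisible(x)
}

#' Physiological calibration summary
#'
#' Fasted-state checkpoints of the shipped (or any) parameterization against
#' the classical description of the enterohepatic circulation: the fraction
#' of distal small-intestinal outflow reclaimed by active transport (vs
#' passed to the colon), the hepatic first-pass extraction of conjugated
#' species, and the ratio of the systemic plasma concentration to the
#' portal-equivalent concentration implied by the total intestinal uptake
#' flux at a reference portal plasma flow of 0.6 L/min.
#'
#' @param subject Subject parameters.
#' @return Named list with `distal_active_fraction`,
#'   `hepatic_extraction_conj`, `hepatic_extraction_unconj`,
#'   `systemic_portal_ratio`, `fasting_total_conc` (micromol/L) and
#'   `portal_equiv_conc` (micromol/L).
#' @examples
#' physiology_summary(subject_params())
#' @export
physiology_summary <- function(subject) {
  validate_subject_params(subject)
  st <- fasting_state(subject, check = FALSE)
  m <- state_matrix(st)
  ix <- .state_index
  # total intestinal uptake flux (micromol/min) at the fasting state
  act <- subject[["k_act_dist"]] * c(1, 1, subject[["m_act_secondary"]])
  sd_conj <- st[ix$si_distal[1:3]]
  sd_unconj <- st[ix$si_distal[4:6]]
  sp_unconj <- st[ix$si_proximal[4:6]]
  co_unconj <- st[ix$colon[4:6]]
  uptake <- sum(act * sd_conj) + sum((act + subject[["k_pass_si"]]) * sd_unconj) +
    sum(subject[["k_pass_si"]] * sp_unconj) +
    sum(subject[["k_pass_colon"]] * co_unconj)
  portal_conc <- uptake / .Q_PORTAL_PLASMA
  fasting_conc <- sum(m[, "plasma"]) / subject[["V_plasma"]]
  list(
    distal_active_fraction =
      subject[["k_act_dist"]] /
        (subject[["k_act_dist"]] + subject[["k_trans_dist"]]),
    hepatic_extraction_conj =
      subject[["k_hep_conj"]] / (1 + subject[["k_hep_conj"]]),
    hepatic_extraction_unconj =
      subject[["k_hep_unconj"]] / (1 + subject[["k_hep_unconj"]]),
    systemic_portal_ratio = fasting_conc / portal_conc,
    fasting_total_conc = fasting_conc,
    portal_equiv_conc = portal_conc
  )
}
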