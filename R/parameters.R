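# Canonical parameter orders. Sensitivity ties are broken by position in
# these vectors, and all serialized parameter sets follow this order.
.SUBJECT_PARAM_NAMES <- c(
  "s_tot", "r_CA", "f_gb", "k_gb_basal",
  "k_trans_prox", "k_trans_dist", "k_trans_colon",
  "k_act_dist", "m_act_secondary", "k_pass_si", "k_pass_colon",
  "k_deconj_dist", "k_deconj_colon", "k_dehydrox_CA", "k_loss_CDCA",
  "k_hep_conj", "k_hep_unconj", "f_reconj",
  "V_plasma", "cl_plasma_hep", "k_gb_refill_delay", "f_postprandial_bypass"
)

.MEAL_PARAM_NAMES <- c("t_lag", "k_empty", "F_eject", "T_empty")

.FRACTION_PARAMS <- c("r_CA", "f_gb", "f_reconj", "f_postprandial_bypass")

# Hepatic bile secretion rate constant (1/min). Fixed structural constant,
# not a free parameter: a ~20 min hepatic residence time for newly made or
# extracted bile acid before biliary secretion.
.K_LIVER_SECRETION <- 0.05

# Reference portal plasma flow (L/min) used only by the physiology
# calibration check (portal-equivalent concentration from uptake flux).
.Q_PORTAL_PLASMA <- 0.6

#' Subject-specific model parameters
#'
#' Construct a validated set of the 22 subject-specific parameters of the
#' personal enterohepatic circulation model. All defaults are calibrated so
#' that the fasted model reproduces the classical description of bile acid
#' physiology: a circulating pool of roughly 5.5 mmol turning over in about
#' a week, hepatic synthesis of 0.45 micromol/min (~265 mg/day), >90% active
#' ileal reabsorption, ~95% hepatic first-pass extraction of conjugated
#' species, and systemic concentrations below 20% of the portal-equivalent
#' level.
#'
#' @param ... Named parameter overrides, e.g. `s_tot = 0.8`.
#'
#' @details The parameters are, in canonical order:
#' \describe{
#'   \item{s_tot}{Total hepatic synthesis rate (micromol/min).}
#'   \item{r_CA}{Fraction of synthesis producing CA (the rest is CDCA).}
#'   \item{f_gb}{Fasting fraction of hepatic bile routed to the gallbladder.}
#'   \item{k_gb_basal}{Interdigestive gallbladder emptying rate (1/min).}
#'   \item{k_trans_prox}{Proximal-to-distal small intestinal transit rate (1/min).}
#'   \item{k_trans_dist}{Distal small intestine to colon transit rate (1/min).}
#'   \item{k_trans_colon}{Colon transit (fecal output) rate (1/min).}
#'   \item{k_act_dist}{Distal-SI active (ASBT) uptake rate (1/min).}
#'   \item{m_act_secondary}{DCA multiplier on active uptake (dimensionless).}
#'   \item{k_pass_si}{SI passive uptake rate, unconjugated species only (1/min).}
#'   \item{k_pass_colon}{Colonic passive uptake rate, unconjugated only (1/min).}
#'   \item{k_deconj_dist}{Distal-SI microbial deconjugation rate (1/min).}
#'   \item{k_deconj_colon}{Colonic deconjugation rate (1/min).}
#'   \item{k_dehydrox_CA}{Colonic CA to DCA 7-alpha-dehydroxylation rate (1/min).}
#'   \item{k_loss_CDCA}{Colonic CDCA transformation-to-unmodeled-species rate (1/min).}
#'   \item{k_hep_conj}{Hepatic first-pass uptake odds for conjugated species;
#'     the extraction fraction is `k/(1+k)` (default 19, i.e. 95% extraction).}
#'   \item{k_hep_unconj}{Hepatic first-pass uptake odds, unconjugated
#'     (default 3, i.e. 75% extraction).}
#'   \item{f_reconj}{Fraction of hepatically extracted unconjugated bile acid
#'     re-secreted as the glycine conjugate.}
#'   \item{V_plasma}{Plasma distribution volume (L).}
#'   \item{cl_plasma_hep}{Concentration-driven systemic plasma clearance to the
#'     liver (L/min); the clearance flux is `cl_plasma_hep * concentration`.}
#'   \item{k_gb_refill_delay}{Duration after the emptying window during which
#'     gallbladder refilling stays suppressed (min).}
#'   \item{f_postprandial_bypass}{Fraction of hepatic output bypassing the
#'     gallbladder while refilling is suppressed.}
#' }
#'
#' @return Named numeric vector of length 22 with class `"ehc_subject_params"`.
#' @examples
#' p <- subject_params()
#' subject_params(s_tot = 1.2, k_act_dist = 0.08)
#' @seealso [meal_params()], [ehc_simulate()]
#' @export
subject_params <- function(...) {
  defaults <- c(
    s_tot = 0.45,
    r_CA = 0.6,
    f_gb = 0.9,
    k_gb_basal = 0.0023,
    k_trans_prox = 0.14,
    k_trans_dist = 0.0055,
    k_trans_colon = 0.0022,
    k_act_dist = 0.056,
    m_act_secondary = 2,
    k_pass_si = 0.0027,
    k_pass_colon = 0.007,
    k_deconj_dist = 0.00065,
    k_deconj_colon = 0.032,
    k_dehydrox_CA = 0.0093,
    k_loss_CDCA = 0.0054,
    k_hep_conj = 19,
    k_hep_unconj = 4.5,
    f_reconj = 0.7,
    V_plasma = 20,
    cl_plasma_hep = 0.22,
    k_gb_refill_delay = 60,
    f_postprandial_bypass = 0.8
  )
  p <- .apply_overrides(defaults, list(...), "subject parameter")
  validate_subject_params(p)
  structure(p, class = "ehc_subject_params")
}

#' Meal-specific gallbladder emptying parameters
#'
#' The four parameters that are allowed to differ between the three meal
#' tests of one subject. All of them shape only the meal-triggered
#' gallbladder emptying flux; everything else in the model is
#' subject-specific.
#'
#' @param ... Named overrides among `t_lag`, `k_empty`, `F_eject`, `T_empty`.
#' @details
#' \describe{
#'   \item{t_lag}{Delay from meal ingestion to onset of enhanced emptying (min).}
#'   \item{k_empty}{First-order postprandial emptying rate inside the window (1/min).}
#'   \item{F_eject}{Target ejection fraction of the gallbladder content in (0, 1].}
#'   \item{T_empty}{Maximum duration of the enhanced-emptying window (min).}
#' }
#' The effective window duration is `min(T_empty, -log(1 - F_eject)/k_empty)`,
#' so the ejected fraction approaches `F_eject` when `k_empty * T_empty`
#' exceeds `-log(1 - F_eject)` and falls short of it otherwise.
#' @return Named numeric vector of length 4 with class `"ehc_meal_params"`.
#' @examples
#' meal_params()
#' meal_params(F_eject = 0.8, t_lag = 5)
#' @export
meal_params <- function(...) {
  defaults <- c(t_lag = 8, k_empty = 0.021, F_eject = 0.86, T_empty = 26)
  p <- .apply_overrides(defaults, list(...), "meal parameter")
  validate_meal_params(p)
  structure(p, class = "ehc_meal_params")
}

.apply_overrides <- function(defaults, dots, what) {
  if (length(dots) == 0L) return(defaults)
  nm <- names(dots)
  if (is.null(nm) || any(nm == "")) {
    stop("all ", what, " overrides must be named", call. = FALSE)
  }
  bad <- setdiff(nm, names(defaults))
  if (length(bad)) {
    stop("unknown ", what, "(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  vals <- vapply(dots, function(x) as.numeric(x)[1L], numeric(1))
  defaults[nm] <- vals
  defaults
}

#' Validate subject parameters
#'
#' @param p Named numeric vector of the 22 subject parameters.
#' @return `p`, invisibly, if valid; otherwise an error describing the
#'   violated constraint.
#' @export
validate_subject_params <- function(p) {
  if (!is.numeric(p) || length(p) != 22L ||
      !identical(sort(names(p)), sort(.SUBJECT_PARAM_NAMES))) {
    stop("subject parameters must be a named numeric vector of the 22 ",
         "canonical parameters", call. = FALSE)
  }
  if (any(!is.finite(p))) stop("subject parameters must be finite", call. = FALSE)
  fr <- p[.FRACTION_PARAMS]
  if (any(fr <= 0 | fr >= 1)) {
    stop("fraction parameters (", paste(.FRACTION_PARAMS, collapse = ", "),
         ") must lie strictly in (0, 1)", call. = FALSE)
  }
  pos <- setdiff(names(p), .FRACTION_PARAMS)
  if (any(p[pos] < 0) || p[["V_plasma"]] <= 0) {
    stop("rates must be nonnegative and V_plasma positive", call. = FALSE)
  }
  invisible(p)
}

#' Validate meal parameters
#'
#' @param p Named numeric vector of the 4 meal parameters.
#' @return `p`, invisibly, if valid.
#' @export
validate_meal_params <- function(p) {
  if (!is.numeric(p) || length(p) != 4L ||
      !identical(sort(names(p)), sort(.MEAL_PARAM_NAMES))) {
    stop("meal parameters must be a named numeric vector of t_lag, k_empty, ",
         "F_eject, T_empty", call. = FALSE)
  }
  if (any(!is.finite(p))) stop("meal parameters must be finite", call. = FALSE)
  if (p[["F_eject"]] <= 0 || p[["F_eject"]] > 1) {
    stop("F_eject must lie in (0, 1]", call. = FALSE)
  }
  if (p[["t_lag"]] < 0 || p[["T_empty"]] < 0) {
    stop("t_lag and T_empty must be nonnegative", call. = FALSE)
  }
  if (p[["k_empty"]] <= 0) stop("k_empty must be positive", call. = FALSE)
  invisible(p)
}

#' A meal event
#'
#' Meal composition is the standardized liquid mixed meal of the study
#' design (49% carbohydrate, 35% fat, 16% protein) and is not a free
#' parameter; only timing and energy vary.
#'
#' @param start_time Meal ingestion time (min); the sampling clock runs from
#'   ingestion, so the default is 0.
#' @param energy Meal energy (kcal); must be positive.
#' @return A list with class `"ehc_meal_event"`.
#' @export
meal_event <- function(start_time = 0, energy = 550) {
  if (!is.numeric(energy) || energy <= 0) stop("energy must be > 0", call. = FALSE)
  structure(
    list(start_time = as.numeric(start_time), energy = as.numeric(energy),
         composition = c(carbohydrate = 0.49, fat = 0.35, protein = 0.16)),
    class = "ehc_meal_event"
  )
}

#' Serialize and restore parameter sets as flat JSON maps
#'
#' Parameters are written as a flat `{name: value}` JSON object with a
#' `schema` version field so that files are self-describing.
#'
#' @param p Subject or meal parameter vector.
#' @param path File path to write to / read from.
#' @return `read_params()` returns the validated parameter vector with the
#'   appropriate class; `write_params()` returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  kind <- if (length(p) == 22L) "subject" else "meal"
  obj <- c(list(schema = "ehckin-params-1", kind = kind), as.list(unclass(p)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$kind
  obj$schema <- NULL
  obj$kind <- NULL
  p <- unlist(obj)
  if (identical(kind, "subject")) {
    p <- p[.SUBJECT_PARAM_NAMES]
    validate_subject_params(p)
    structure(p, class = "ehc_subject_params")
  } else {
    p <- p[.MEAL_PARAM_NAMES]
    validate_meal_params(p)
    structure(p, class = "ehc_meal_params")
  }
}
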