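# Practical identifiability from the multi-start ensemble: near-optimal
# solutions (within 25% of the best cost) define a representative set, and
# the per-parameter coefficient of variation across that set classifies
# each parameter.

#' Representative set of near-optimal solutions
#'
#' All restart solutions whose cost is less than 25% above the best cost
#' (strictly `cost < 1.25 * best`), including the best solution itself.
#'
#' @param fit An `"ehc_fit"` object, or a data frame with one solution per
#'   row and a `cost` column.
#' @param band Relative cost band (default 0.25).
#' @return Data frame of the retained solutions (parameter columns plus
#'   `cost`).
#' @examples
#' ens <- data.frame(k = c(1, 1.1, 3), cost = c(10, 12, 12.6))
#' representative_set(ens) # keeps the first two rows
#' @export
representative_set <- function(fit, band = 0.25) {
  ens <- if (inherits(fit, "ehc_fit")) fit$ensemble else as.data.frame(fit)
  if (!"cost" %in% names(ens)) stop("ensemble needs a cost column", call. = FALSE)
  ens <- ens[is.finite(ens$cost), , drop = FALSE]
  if (nrow(ens) == 0L) stop("no finite-cost solutions in ensemble", call. = FALSE)
  best <- min(ens$cost)
  ens[ens$cost < (1 + band) * best, , drop = FALSE]
}

.classify_cv <- function(cv_par) {
  ifelse(cv_par < 20, "well_identified",
         ifelse(cv_par > 50, "nonidentifiable", "intermediate"))
}

#' Classify parameter identifiability from a solution ensemble
#'
#' Computes the per-parameter coefficient of variation (CV_par, natural
#' scale, percent) across the representative set and classifies each
#' parameter: CV_par < 20% is well identified, CV_par > 50% is
#' nonidentifiable, anything else (equalities included) is intermediate.
#' A singleton set yields CV_par = 0 throughout and is flagged as too small
#' to be informative.
#'
#' @param fit An `"ehc_fit"`, or a data frame/matrix of parameter vectors
#'   (one solution per row; a `cost` column, if present, is used for the
#'   band selection first).
#' @param band Relative cost band passed to [representative_set()].
#' @return Data frame of class `"ehc_ident"` with columns `parameter`,
#'   `cv_par` (percent) and `class`; attributes `n_solutions` (size of the
#'   representative set) and `ensemble_too_small` (TRUE for a singleton).
#' @examples
#' m <- data.frame(a = c(1, 1.1, 0.9), b = c(1, 2, 3))
#' identifiability(m)
#' @export
identifiability <- function(fit, band = 0.25) {
  if (inherits(fit, "ehc_fit")) {
    sel <- representative_set(fit, band)
    par_cols <- seq_len(fit$n_free)
    mat <- as.matrix(sel[, par_cols, drop = FALSE])
  } else {
    sel <- as.data.frame(fit)
    if ("cost" %in% names(sel)) {
      sel <- representative_set(sel, band)
      sel <- sel[, setdiff(names(sel), c("cost", "convergence", "restart")),
                 drop = FALSE]
    }
    mat <- as.matrix(sel)
  }
  if (nrow(mat) == 0L) stop("empty representative set", call. = FALSE)
  single <- nrow(mat) == 1L
  cv_par <- if (single) {
    stats::setNames(rep(0, ncol(mat)), colnames(mat))
  } else {
    apply(mat, 2L, function(v) {
      m <- mean(v)
      if (m <= 0) return(NA_real_)
      100 * stats::sd(v) / m
    })
  }
  out <- data.frame(parameter = colnames(mat), cv_par = unname(cv_par),
                    class = .classify_cv(unname(cv_par)),
                    stringsAsFactors = FALSE)
  attr(out, "n_solutions") <- nrow(mat)
  attr(out, "ensemble_too_small") <- single
  class(out) <- c("ehc_ident", "data.frame")
  out
}

#' @export
print.ehc_ident <- function(x, ...) {
  n <- attr(x, "n_solutions")
  cat(sprintf("Identifiability over %d near-optimal solution(s)%s\n", n,
              if (isTRUE(attr(x, "ensemble_too_small")))
                " [ensemble too small]" else ""))
  tab <- x
  tab$cv_par <- round(tab$cv_par, 1)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}
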