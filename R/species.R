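#' Modeled bile acid species
#'
#' The model tracks the three quantitatively dominant plasma bile acids --
#' the primary acids cholic acid (CA) and chenodeoxycholic acid (CDCA) and
#' the secondary acid deoxycholic acid (DCA) -- each in glycine-conjugated
#' and unconjugated form. Taurine conjugates and the minor secondary acids
#' (LCA, UDCA) are not modeled: taurine forms are barely detectable in
#' plasma and LCA/UDCA contribute little to the postprandial signal.
#'
#' @return A data frame with one row per species and columns `species`
#'   (label used in measurement tables), `acid` (`"CA"`, `"CDCA"`, `"DCA"`),
#'   `conjugation` (`"glycine"` or `"unconjugated"`) and `class`
#'   (`"primary"` or `"secondary"`).
#' @examples
#' ehc_species()
#' @export
ehc_species <- function() {
  data.frame(
    species = c("gCA", "gCDCA", "gDCA", "CA", "CDCA", "DCA"),
    acid = rep(c("CA", "CDCA", "DCA"), 2L),
    conjugation = rep(c("glycine", "unconjugated"), each = 3L),
    class = rep(c("primary", "primary", "secondary"), 2L),
    stringsAsFactors = FALSE
  )
}

#' Model compartments
#'
#' @return Character vector of compartment names. `feces_cumulative` is a
#'   terminal sink; `plasma` is the only observed compartment. The liver and
#'   gallbladder hold conjugated species only (bile is secreted conjugated;
#'   extracted unconjugated bile acid is either reconjugated or immediately
#'   re-secreted).
#' @export
ehc_compartments <- function() {
  c("liver", "gallbladder", "si_proximal", "si_distal", "colon",
    "plasma", "feces_cumulative")
}

# Internal state vector layout (37 states):
#   1:3    liver            gCA gCDCA gDCA   (conjugated only)
#   4:6    gallbladder      gCA gCDCA gDCA   (conjugated only)
#   7:12   si_proximal      all 6 species
#   13:18  si_distal        all 6 species
#   19:24  colon            all 6 species
#   25:30  plasma           all 6 species
#   31:36  feces_cumulative all 6 species (sink)
#   37     cumulative colonic CDCA transformation loss (sink)
.N_STATE <- 37L
.N_DYN <- 30L # states 1:30 are the circulating pool

.state_index <- local({
  sp <- c("gCA", "gCDCA", "gDCA", "CA", "CDCA", "DCA")
  idx <- list(
    liver = stats::setNames(1:3, sp[1:3]),
    gallbladder = stats::setNames(4:6, sp[1:3]),
    si_proximal = stats::setNames(7:12, sp),
    si_distal = stats::setNames(13:18, sp),
    colon = stats::setNames(19:24, sp),
    plasma = stats::setNames(25:30, sp),
    feces_cumulative = stats::setNames(31:36, sp)
  )
  idx$transform_loss <- c(loss = 37L)
  idx
})

.state_names <- local({
  nm <- character(.N_STATE)
  for (comp in names(.state_index)) {
    ii <- .state_index[[comp]]
    nm[ii] <- paste(comp, names(ii), sep = ".")
  }
  nm
})

#' Arrange a raw state vector as a species-by-compartment matrix
#'
#' Amounts are in micromoles. Compartment slots that cannot hold a species
#' (unconjugated forms in liver and gallbladder) are reported as 0.
#'
#' @param state Numeric state vector of length 37 as used internally by the
#'   solver (see [ehc_simulate()]).
#' @return 6 x 7 numeric matrix (species x compartment), plus an attribute
#'   `transform_loss` carrying the cumulative colonic CDCA transformation
#'   loss (micromol).
#' @export
state_matrix <- function(state) {
  stopifnot(length(state) == .N_STATE)
  sp <- ehc_species()$species
  comps <- ehc_compartments()
  m <- matrix(0, nrow = 6L, ncol = length(comps),
              dimnames = list(sp, comps))
  for (comp in comps) {
    ii <- .state_index[[comp]]
    m[names(ii), comp] <- state[ii]
  }
  attr(m, "transform_loss") <- unname(state[.state_index$transform_loss])
  m
}
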