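# Measurement table I/O: long-format CSV is the single interchange format
# (subject_id, meal_id, time_min, species, conc_umol_per_L).

.MEASUREMENT_COLS <- c("subject_id", "meal_id", "time_min", "species",
                       "conc_umol_per_L")

.check_measurements <- function(table, complete_grid = TRUE) {
  missing_cols <- setdiff(.MEASUREMENT_COLS, names(table))
  if (length(missing_cols)) {
    stop("measurement table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_sp <- which(!table$species %in% ehc_species()$species)
  if (length(bad_sp)) {
    stop("unknown species at row(s): ",
         paste(utils::head(bad_sp, 5L), collapse = ", "), call. = FALSE)
  }
  for (col in c("time_min", "conc_umol_per_L")) {
    bad <- which(!is.finite(table[[col]]))
    if (length(bad)) {
      stop("non-numeric or missing ", col, " at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (complete_grid) {
    counts <- table(table$subject_id, table$meal_id, table$time_min,
                    table$species)
    if (length(counts) && any(counts != 1L)) {
      stop("incomplete measurement grid: every subject x meal x time x ",
           "species cell must appear exactly once", call. = FALSE)
    }
  }
  invisible(table)
}

#' Read and write measurement tables
#'
#' Long-format CSV with columns `subject_id`, `meal_id`, `time_min` (min),
#' `species` (one of `r paste(ehc_species()$species, collapse = ", ")`) and
#' `conc_umol_per_L`. Reading validates the schema and the completeness of
#' the subject x meal x time x species grid and reports offending row
#' numbers; extra columns are preserved on read and ignored downstream.
#'
#' @param table Measurement table (data frame).
#' @param path CSV file path.
#' @param complete_grid Require a complete grid on read (default `TRUE`).
#' @return `read_measurements()` returns the validated data frame;
#'   `write_measurements()` returns `path` invisibly.
#' @export
write_measurements <- function(table, path) {
  .check_measurements(table, complete_grid = FALSE)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path, complete_grid = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_measurements(tab, complete_grid = complete_grid)
  tab
}

#' Write simulation output as long-format CSV
#'
#' Two companion files: compartment amounts (`*_amounts.csv`: `subject_id`,
#' `meal_id`, `time_min`, `species`, `compartment`, `amount_umol`) and
#' plasma concentrations in the measurement-table schema.
#'
#' @param sim An `"ehc_sim"` object.
#' @param path_amounts,path_conc Output CSV paths (either may be `NULL` to
#'   skip).
#' @param subject_id,meal_id Identifiers recorded in the files.
#' @return Invisibly, a list of the written data frames.
#' @export
write_simulation <- function(sim, path_amounts = NULL, path_conc = NULL,
                             subject_id = "S1", meal_id = "M1") {
  stopifnot(inherits(sim, "ehc_sim"))
  sp <- ehc_species()$species
  comps <- ehc_compartments()
  amounts <- do.call(rbind, lapply(seq_along(sim$times), function(i) {
    m <- state_matrix(sim$states[i, ])
    data.frame(subject_id = subject_id, meal_id = meal_id,
               time_min = sim$times[i],
               species = rep(sp, times = length(comps)),
               compartment = rep(comps, each = length(sp)),
               amount_umol = as.numeric(m), stringsAsFactors = FALSE)
  }))
  conc <- data.frame(
    subject_id = subject_id, meal_id = meal_id,
    time_min = rep(sim$times, each = length(sp)),
    species = rep(sp, times = length(sim$times)),
    conc_umol_per_L = as.numeric(sim$conc), stringsAsFactors = FALSE
  )
  if (!is.null(path_amounts)) utils::write.csv(amounts, path_amounts,
                                               row.names = FALSE)
  if (!is.null(path_conc)) utils::write.csv(conc, path_conc,
                                            row.names = FALSE)
  invisible(list(amounts = amounts, conc = conc))
}
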