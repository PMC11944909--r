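#' Packaged ship activity-diary fixtures
#'
#' The four published crew activity diaries, shipped as versioned CSV
#' fixtures: the missile frigate and the training sailing ship, each at
#' sea and in port. Every fixture carries the published per-row energy
#' values (column \code{printed_kcal}) alongside the rates, so the
#' package can re-derive and audit them (see [reproduce_ledgers()]).
#'
#' @param table one of \code{"frigate_sea"}, \code{"sailing_sea"},
#'   \code{"frigate_port"}, \code{"sailing_port"}.
#' @return a [daily_schedule()] with extra column \code{printed_kcal} and
#'   attributes \code{ship}, \code{setting}, \code{body_mass_kg},
#'   \code{printed_total_kcal}.
#' @examples
#' sched <- ship_schedule("frigate_sea")
#' attr(sched, "body_mass_kg")
#' @export
ship_schedule <- function(table = c("frigate_sea", "sailing_sea",
                                    "frigate_port", "sailing_port")) {
  table <- match.arg(table)
  meta <- utils::read.csv(
    system.file("extdata", "ship_tables.csv", package = "crewEE"),
    stringsAsFactors = FALSE)
  meta <- meta[meta$table == table, ]
  sched <- read_schedule(
    system.file("extdata", paste0("schedule_", table, ".csv"),
                package = "crewEE"))
  attr(sched, "ship") <- meta$ship
  attr(sched, "setting") <- meta$setting
  attr(sched, "body_mass_kg") <- meta$body_mass_kg
  attr(sched, "printed_total_kcal") <- meta$printed_total_kcal
  sched
}

#' Packaged cohort anthropometrics
#'
#' Published per-cohort means and SDs of age, body mass, height and BMI
#' for the four study cohorts, plus (separately) the published grand
#' "Average" column for cross-checking.
#'
#' @param printed_average if TRUE, return the published grand averages
#'   instead of the per-cohort table.
#' @return a data frame.
#' @export
cohort_anthropometrics <- function(printed_average = FALSE) {
  f <- if (printed_average) "anthropometrics_printed_average.csv" else "anthropometrics.csv"
  utils::read.csv(system.file("extdata", f, package = "crewEE"),
                  stringsAsFactors = FALSE)
}

#' Packaged ration compositions
#'
#' Published planned and as-served ration compositions for both ships
#' (mean and SD of energy and macronutrients).
#'
#' @param ship \code{"missile-frigate"} or \code{"sailing-ship"}; NULL
#'   for the full table.
#' @param provenance \code{"planned"} or \code{"served"}; NULL for both.
#' @return with both \code{ship} and \code{provenance} given, a
#'   [ration()]; otherwise the raw data frame.
#' @export
ship_ration <- function(ship = NULL, provenance = NULL) {
  raw <- utils::read.csv(
    system.file("extdata", "rations.csv", package = "crewEE"),
    stringsAsFactors = FALSE)
  if (is.null(ship) || is.null(provenance)) return(raw)
  row <- raw[raw$ship == ship & raw$provenance == provenance, ]
  if (nrow(row) != 1L) stop("no ration for ", ship, "/", provenance)
  ration(row$energy_kcal, row$protein_g, row$fat_g, row$carb_g,
         provenance = provenance, name = paste(ship, provenance))
}

#' Packaged shift-load summaries
#'
#' Published 12-h service energy-load statistics (mean, SD, median, min,
#' max) for the two border-guard units. The \code{recording_time_h} rows
#' are carried as recording-duration metadata only — they describe how
#' long the monitors ran, not the 12-h shift, and are not recomputed.
#'
#' @param unit \code{"maritime-unit"} or \code{"kashubian-division"};
#'   NULL for both.
#' @return a data frame with columns unit, metric, mean, sd, median,
#'   min, max.
#' @export
shift_loads <- function(unit = NULL) {
  raw <- utils::read.csv(
    system.file("extdata", "shift_loads.csv", package = "crewEE"),
    stringsAsFactors = FALSE)
  if (!is.null(unit)) raw <- raw[raw$unit == unit, ]
  raw
}
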