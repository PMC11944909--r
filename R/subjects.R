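#' Body mass index
#'
#' @param body_mass body mass in kg.
#' @param height height in cm.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(body_mass, height) {
  if (any(body_mass <= 0) || any(height <= 0)) {
    stop("invalid subject: body mass and height must be positive")
  }
  out <- body_mass / (height / 100)^2
  if (any(!is.finite(out) | out <= 0)) stop("BMI must be finite and positive")
  out
}

#' Construct a subject table
#'
#' @param id subject identifiers.
#' @param group cohort label (e.g. "missile-frigate", "sailing-ship",
#'   "maritime-unit", "kashubian-division").
#' @param body_mass body mass, kg.
#' @param height height, cm.
#' @param age age, years.
#' @return a data frame of class \code{crew_subjects} with a derived
#'   \code{bmi} column.
#' @export
subjects <- function(id, group, body_mass, height, age) {
  if (any(body_mass <= 0) || any(height <= 0)) {
    stop("invalid subject: body mass and height must be positive")
  }
  out <- data.frame(
    id = as.character(id), group = as.character(group),
    body_mass = as.numeric(body_mass), height = as.numeric(height),
    age = as.numeric(age), stringsAsFactors = FALSE
  )
  out$bmi <- bmi(out$body_mass, out$height)
  class(out) <- c("crew_subjects", "data.frame")
  out
}

#' Read a subjects file
#'
#' CSV with header columns \code{id}, \code{group}, \code{body_mass_kg},
#' \code{height_cm}, \code{age_yr}.
#'
#' @param file path to the CSV file.
#' @return a [subjects()] table.
#' @export
read_subjects <- function(file) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("id", "group", "body_mass_kg", "height_cm", "age_yr")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("subjects file lacks column(s): ", paste(miss, collapse = ", "))
  subjects(raw$id, raw$group, raw$body_mass_kg, raw$height_cm, raw$age_yr)
}

#' Per-cohort and grand anthropometric summaries
#'
#' Summarises age, body mass, height and BMI per cohort as mean and SD,
#' and reports grand values as the \emph{unweighted} arithmetic mean of
#' the cohort means (each cohort counts once, regardless of its size).
#' This is the convention under which a multi-cohort "Average" column of
#' unequal group sizes is reproducible from the group means alone; a
#' subject-count-weighted mean is deliberately not used.
#'
#' @param x a [subjects()] table, or a data frame of per-group means with
#'   columns \code{group} and \verb{<field>_mean}/\verb{<field>_sd} pairs
#'   (pre-aggregated input, as when only published group statistics are
#'   available).
#' @return an object of class \code{group_summary}: list with
#'   \code{per_group} (data frame of group, n, mean and sd per field) and
#'   \code{grand} (named numeric: unweighted mean of group means per
#'   field) plus \code{grand_sd} (SD across group means).
#' @examples
#' s <- subjects(1:4, rep(c("a", "b"), 2), c(70, 90, 72, 88),
#'               c(175, 180, 176, 181), c(25, 30, 26, 31))
#' summarize_groups(s)
#' @export
summarize_groups <- function(x) {
  fields <- c("age", "body_mass", "height", "bmi")
  if (inherits(x, "crew_subjects") ||
      all(c("group", "body_mass", "height", "age") %in% names(x))) {
    if (!"bmi" %in% names(x)) x$bmi <- bmi(x$body_mass, x$height)
    groups <- split(x, x$group)
    if (any(vapply(groups, nrow, 0L) < 1L)) stop("every group needs >= 1 subject")
    per_group <- do.call(rbind, lapply(names(groups), function(g) {
      d <- groups[[g]]
      row <- data.frame(group = g, n = nrow(d), stringsAsFactors = FALSE)
      for (f in fields) {
        row[[paste0(f, "_mean")]] <- mean(d[[f]])
        row[[paste0(f, "_sd")]] <- stats::sd(d[[f]])
      }
      row
    }))
  } else {
    need <- paste0(fields, "_mean")
    if (!all(c("group", need) %in% names(x))) {
      stop("need subject-level data or per-group '<field>_mean' columns")
    }
    per_group <- as.data.frame(x)
  }
  if (nrow(per_group) < 1L) stop("no groups to summarise")
  grand <- vapply(fields, function(f) mean(per_group[[paste0(f, "_mean")]]), 0)
  grand_sd <- vapply(fields, function(f) stats::sd(per_group[[paste0(f, "_mean")]]), 0)
  for (f in fields) {
    gm <- per_group[[paste0(f, "_mean")]]
    stopifnot(grand[[f]] >= min(gm), grand[[f]] <= max(gm))
  }
  structure(list(per_group = per_group, grand = grand, grand_sd = grand_sd),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, round = 1, ...) {
  cat("Anthropometric summary by cohort (mean ± SD):\n")
  df <- x$per_group
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = round)
  print.data.frame(df, row.names = FALSE)
  cat("Grand values (unweighted mean of cohort means):\n")
  print(round(x$grand, round))
  invisible(x)
}
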