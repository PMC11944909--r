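#' Energy expenditure of a single activity
#'
#' The activity-diary model: the energy cost of a timed activity is its
#' tabulated rate (kcal/min per kg body mass) times its duration (min)
#' times the subject's body mass (kg),
#' \deqn{E = r \times d \times m \; \mathrm{kcal}.}
#' Computation is at full floating precision; rounding to one decimal is a
#' display concern only.
#'
#' @param duration activity duration in minutes (non-negative).
#' @param rate EE rate in kcal/min/kg body mass (non-negative).
#' @param body_mass body mass in kg (> 0).
#' @return kilocalories, vectorised over the inputs.
#' @examples
#' activity_ee(300, 0.0166, 80.4)  # a 5-h sleep block: 400.4 kcal
#' @export
activity_ee <- function(duration, rate, body_mass) {
  if (any(!is.finite(body_mass)) || any(body_mass <= 0)) {
    stop("invalid subject: body mass must be positive")
  }
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("invalid entry: EE rate must be non-negative")
  }
  if (any(!is.finite(duration)) || any(duration < 0)) {
    stop("invalid entry: duration must be non-negative")
  }
  rate * duration * body_mass
}

#' Daily energy-expenditure ledger
#'
#' Computes the per-activity and 24-h energy expenditure for one subject
#' from a validated daily schedule. The daily total is the exact sum of
#' the full-precision per-activity values; comparison against an
#' externally printed total (if the schedule carries a
#' \code{printed_kcal} column) is left to [reproduce_ledgers()].
#'
#' @param schedule a [daily_schedule()]; must pass [validate_schedule()].
#' @param body_mass subject body mass in kg.
#' @param subject optional subject identifier carried into the result.
#' @return an object of class \code{daily_ee} with elements
#'   \code{breakdown} (data frame: activity, duration, rate, kcal),
#'   \code{total_kcal}, \code{body_mass}, \code{subject}.
#' @examples
#' sched <- daily_schedule(c("00:00", "08:00"), c("08:00", "00:00"),
#'                         c("sleep", "duty"), c(0.0166, 0.0412))
#' daily_ee(sched, body_mass = 80.4)
#' @export
daily_ee <- function(schedule, body_mass, subject = NULL) {
  v <- validate_schedule(schedule)
  if (!v$pass) {
    stop("schedule fails validation (total ", v$total_min, " min, ",
         nrow(v$gaps), " gap(s), ", nrow(v$overlaps), " overlap(s))")
  }
  kcal <- activity_ee(schedule$duration, schedule$rate, body_mass)
  breakdown <- data.frame(
    start = schedule$start, end = schedule$end,
    activity = schedule$activity,
    duration = schedule$duration, rate = schedule$rate,
    kcal = kcal, stringsAsFactors = FALSE
  )
  out <- list(
    subject = subject,
    body_mass = body_mass,
    breakdown = breakdown,
    total_kcal = sum(kcal)
  )
  class(out) <- "daily_ee"
  out
}

#' @export
print.daily_ee <- function(x, round = 1, ...) {
  cat("Daily energy expenditure ledger")
  if (!is.null(x$subject)) cat(" for", x$subject)
  cat(" (body mass ", x$body_mass, " kg)\n", sep = "")
  df <- data.frame(
    time = paste0(format_hhmm(x$breakdown$start), "-",
                  format_hhmm(x$breakdown$end)),
    activity = x$breakdown$activity,
    min = x$breakdown$duration,
    `kcal/min/kg` = x$breakdown$rate,
    kcal = round(x$breakdown$kcal, round),
    check.names = FALSE
  )
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("Daily energy expenditure: %s kcal / 1440 min\n",
              format(round(x$total_kcal, round))))
  invisible(x)
}

#' @export
summary.daily_ee <- function(object, ...) {
  rate_min <- object$breakdown$rate * object$body_mass  # kcal/min
  structure(list(
    total_kcal = object$total_kcal,
    severity_daily = classify_daily(object$total_kcal),
    rate_range_kcal_min = range(rate_min),
    severity_rate_range = classify_rate_range(min(rate_min), max(rate_min)),
    n_activities = nrow(object$breakdown)
  ), class = "summary.daily_ee")
}

#' @export
print.summary.daily_ee <- function(x, ...) {
  cat(sprintf("24-h energy expenditure: %.1f kcal -> %s work\n",
              x$total_kcal, as.character(x$severity_daily)))
  cat(sprintf("activity intensities: %.2f to %.2f kcal/min -> %s work\n",
              x$rate_range_kcal_min[1], x$rate_range_kcal_min[2],
              x$severity_rate_range))
  invisible(x)
}
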