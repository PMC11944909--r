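#' Parse clock times to minutes of day
#'
#' Accepts "HH:MM" strings (24-h clock) or bare numeric minutes-of-day.
#' Values must lie in \verb{[0, 1440)}.
#'
#' @param x character vector of "HH:MM" times, or numeric minutes.
#' @return integer-valued numeric vector of minutes since midnight.
#' @examples
#' parse_hhmm(c("03:15", "22:15"))
#' @export
parse_hhmm <- function(x) {
  if (is.numeric(x)) {
    m <- as.numeric(x)
  } else {
    x <- trimws(as.character(x))
    ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
    if (!all(ok)) {
      stop("malformed clock time(s): ", paste(x[!ok], collapse = ", "))
    }
    parts <- strsplit(x, ":", fixed = TRUE)
    m <- vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m >= 1440)) {
    stop("minute-of-day values must lie in [0, 1440)")
  }
  m
}

format_hhmm <- function(m) sprintf("%02d:%02d", m %/% 60 %% 24, m %% 60)

#' Construct a daily activity schedule
#'
#' A day is modelled as an ordered sequence of half-open activity intervals
#' \verb{[start, end)} on the minute-of-day circle; an interval may wrap
#' across midnight (e.g. sleep from 22:15 to 03:15). Each activity carries
#' an energy-expenditure rate in kcal/min per kilogram of body mass, the
#' unit used by military activity-diary tables.
#'
#' @param start,end activity boundaries, "HH:MM" or minutes-of-day.
#' @param activity character activity labels.
#' @param rate non-negative EE rates, kcal/min/kg body mass.
#' @return an object of class \code{daily_schedule}: a data frame with
#'   columns \code{start}, \code{end} (minutes of day), \code{activity},
#'   \code{rate} and derived \code{duration} (minutes).
#' @seealso [validate_schedule()], [daily_ee()], [read_schedule()]
#' @examples
#' sched <- daily_schedule("00:00", "00:00", "rest", 0.017)
#' sched$duration  # 1440
#' @export
daily_schedule <- function(start, end, activity, rate) {
  start <- parse_hhmm(start)
  end <- parse_hhmm(end)
  rate <- as.numeric(rate)
  n <- length(start)
  if (length(end) != n || length(activity) != n || length(rate) != n) {
    stop("start, end, activity and rate must have equal length")
  }
  if (n == 0L) stop("a schedule needs at least one entry")
  if (any(is.na(rate)) || any(rate < 0)) {
    stop("invalid entry: EE rates must be non-negative")
  }
  duration <- (end - start) %% 1440
  duration[duration == 0] <- 1440  # [t, t) spanning the whole day
  out <- data.frame(
    start = start, end = end,
    activity = as.character(activity),
    rate = rate, duration = duration,
    stringsAsFactors = FALSE
  )
  class(out) <- c("daily_schedule", "data.frame")
  out
}

#' Read a daily schedule from a delimited file
#'
#' Expects a UTF-8 CSV (or TSV, detected from the extension) with a header
#' row and columns \code{start}, \code{end} (HH:MM), \code{activity} and
#' \code{rate_kcal_min_kg}. Extra columns are carried along untouched.
#'
#' @param file path to the schedule file.
#' @return a [daily_schedule()] object.
#' @export
read_schedule <- function(file) {
  sep <- if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(file, sep = sep, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = TRUE)
  need <- c("start", "end", "activity", "rate_kcal_min_kg")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("schedule file lacks column(s): ", paste(miss, collapse = ", "))
  sched <- daily_schedule(raw$start, raw$end, raw$activity, raw$rate_kcal_min_kg)
  extra <- setdiff(names(raw), need)
  for (cl in extra) sched[[cl]] <- raw[[cl]]
  sched
}

#' Validate a daily schedule
#'
#' Checks that the entries tile the 1440-minute day: consecutive entries
#' must be contiguous (each start equals the previous end, modulo
#' midnight), intervals must not overlap, and durations must sum to
#' exactly 1440 min. The result is a report, not an error, so callers can
#' decide how strictly to escalate.
#'
#' @param schedule a [daily_schedule()] object.
#' @return an object of class \code{schedule_validation} with elements
#'   \code{pass} (logical), \code{total_min}, \code{deviation_min}
#'   (total \eqn{-} 1440), \code{gaps} and \code{overlaps} (data frames
#'   locating each defect by minute of day).
#' @examples
#' good <- daily_schedule("00:00", "00:00", "rest", 0.017)
#' validate_schedule(good)$pass
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "daily_schedule"))
  n <- nrow(schedule)
  gaps <- overlaps <- data.frame(after_entry = integer(), at_min = numeric(),
                                 length_min = numeric())
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      jump <- (schedule$start[i + 1L] - schedule$end[i]) %% 1440
      if (jump != 0) {
        # A forward jump is a gap; schedules never legitimately rewind, so a
        # jump longer than the remaining day is reported as-is (gap length on
        # the forward circle).
        gaps <- rbind(gaps, data.frame(after_entry = i,
                                       at_min = schedule$end[i],
                                       length_min = jump))
      }
    }
  }
  total <- sum(schedule$duration)
  # Overlap check: accumulate coverage on the minute circle
  cover <- numeric(1440)
  for (i in seq_len(n)) {
    idx <- (seq(schedule$start[i], length.out = schedule$duration[i]) %% 1440) + 1
    cover[idx] <- cover[idx] + 1
  }
  over_min <- which(cover > 1) - 1
  if (length(over_min)) {
    runs <- split(over_min, cumsum(c(1, diff(over_min) != 1)))
    overlaps <- do.call(rbind, lapply(runs, function(r) {
      data.frame(after_entry = NA_integer_, at_min = r[1], length_min = length(r))
    }))
    rownames(overlaps) <- NULL
  }
  out <- list(
    pass = nrow(gaps) == 0 && nrow(overlaps) == 0 && total == 1440,
    total_min = total,
    deviation_min = total - 1440,
    gaps = gaps,
    overlaps = overlaps
  )
  class(out) <- "schedule_validation"
  out
}

#' @export
print.schedule_validation <- function(x, ...) {
  cat("Daily schedule validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  total:", x$total_min, "min (deviation", x$deviation_min, "min)\n")
  if (nrow(x$gaps)) {
    for (i in seq_len(nrow(x$gaps))) {
      cat(sprintf("  gap of %d min at %s (after entry %d)\n",
                  x$gaps$length_min[i], format_hhmm(x$gaps$at_min[i]),
                  x$gaps$after_entry[i]))
    }
  }
  if (nrow(x$overlaps)) {
    for (i in seq_len(nrow(x$overlaps))) {
      cat(sprintf("  overlap of %d min starting at %s\n",
                  x$overlaps$length_min[i], format_hhmm(x$overlaps$at_min[i])))
    }
  }
  invisible(x)
}

#' @export
print.daily_schedule <- function(x, ...) {
  cat("Daily activity schedule:", nrow(x), "entries,",
      sum(x$duration), "min\n")
  df <- data.frame(
    start = format_hhmm(x$start), end = format_hhmm(x$end),
    activity = x$activity, duration = x$duration, rate = x$rate
  )
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
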