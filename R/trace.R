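#' Construct a heart-rate trace
#'
#' @param time_s sample times in seconds since trace start, strictly
#'   increasing.
#' @param hr_bpm heart rate samples, beats/min, within the plausibility
#'   window \verb{[25, 250]}.
#' @return a data frame of class \code{hr_trace}.
#' @export
hr_trace <- function(time_s, hr_bpm) {
  time_s <- as.numeric(time_s); hr_bpm <- as.numeric(hr_bpm)
  if (length(time_s) == 0L) stop("empty trace")
  if (length(time_s) != length(hr_bpm)) stop("time and hr lengths differ")
  if (any(diff(time_s) <= 0)) stop("sample times must be strictly increasing")
  if (any(hr_bpm < 25 | hr_bpm > 250)) {
    stop("heart rate outside the plausibility window [25, 250] bpm")
  }
  out <- data.frame(time_s = time_s, hr_bpm = hr_bpm)
  class(out) <- c("hr_trace", "data.frame")
  out
}

#' Read a heart-rate trace file
#'
#' CSV with columns \code{time_s} and \code{hr_bpm}; the format is
#' device-agnostic (no vendor file parsing), so traces exported from any
#' monitor can be used once converted to these two columns.
#'
#' @param file path to the CSV file.
#' @return an [hr_trace()] object.
#' @export
read_hr_trace <- function(file) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(c("time_s", "hr_bpm"), names(raw))
  if (length(miss)) stop("trace file lacks column(s): ", paste(miss, collapse = ", "))
  hr_trace(raw$time_s, raw$hr_bpm)
}

#' Energy expenditure from a heart-rate trace
#'
#' Converts each HR sample to an instantaneous energy expenditure
#' (kcal/min) with the flex-HR rule — above \code{flex_hr} the calibrated
#' line times the caloric equivalent, below it the resting rate — and
#' integrates the kcal/min series over the actual (possibly non-uniform)
#' timestamps by the trapezoidal rule to a total in kcal. Negative
#' predicted VO2 (possible when extrapolating a steep line to low HR) is
#' clamped to zero with a warning.
#'
#' @param trace an [hr_trace()].
#' @param curve an [fit_calibration()] result (or any list with
#'   \code{slope}, \code{intercept}, \code{flex_hr}, \code{resting_ee},
#'   \code{caloric_equivalent}).
#' @param body_mass body mass, kg, for the per-kilogram normalisations.
#' @return an object of class \code{ee_trace}: list with \code{samples}
#'   (data frame \code{time_s}, \code{hr_bpm}, \code{ee_kcal_min}),
#'   \code{total_kcal}, \code{duration_h}, \code{kcal_per_h},
#'   \code{kcal_per_h_per_kg} and \code{body_mass}.
#' @examples
#' cal <- fit_calibration(hr = c(90, 180), vo2 = c(0.5, 1.4))
#' tr <- hr_trace(seq(0, 3600, by = 60), rep(120, 61))
#' ee_from_trace(tr, cal, body_mass = 80)$total_kcal
#' @export
ee_from_trace <- function(trace, curve, body_mass) {
  stopifnot(inherits(trace, "data.frame"))
  if (nrow(trace) == 0L) stop("empty trace")
  if (body_mass <= 0) stop("invalid subject: body mass must be positive")
  hr <- trace$hr_bpm
  vo2 <- curve$intercept + curve$slope * hr
  above <- hr >= curve$flex_hr
  if (any(above & vo2 < 0)) {
    warning(sum(above & vo2 < 0),
            " sample(s) with negative predicted VO2 clamped to 0")
    vo2 <- pmax(vo2, 0)
  }
  ee <- ifelse(above, curve$caloric_equivalent * vo2, curve$resting_ee)
  t_min <- trace$time_s / 60
  n <- length(t_min)
  total <- if (n == 1L) 0 else sum(diff(t_min) * (ee[-1L] + ee[-n]) / 2)
  dur_h <- (t_min[n] - t_min[1L]) / 60
  out <- list(
    samples = data.frame(time_s = trace$time_s, hr_bpm = hr, ee_kcal_min = ee),
    total_kcal = total,
    duration_h = dur_h,
    kcal_per_h = if (dur_h > 0) total / dur_h else NA_real_,
    kcal_per_h_per_kg = if (dur_h > 0) total / dur_h / body_mass else NA_real_,
    body_mass = body_mass
  )
  class(out) <- "ee_trace"
  out
}

#' @export
print.ee_trace <- function(x, ...) {
  cat(sprintf(
    "HR-derived energy expenditure: %.1f kcal over %.2f h (%.1f kcal/h; %d samples)\n",
    x$total_kcal, x$duration_h, x$kcal_per_h, nrow(x$samples)))
  invisible(x)
}

#' Summarise a work shift
#'
#' Aggregates an HR-derived energy-expenditure series into the standard
#' shift-load summary: total kcal over the shift, hourly and per-minute
#' rates (per-minute is the hourly rate divided by 60, exactly), their
#' per-kilogram normalisations, and the pulse minimum / mean / maximum.
#' When the recording is shorter or longer than the nominal shift, the
#' total is scaled from the recording's mean hourly rate; the recording
#' duration is kept as metadata.
#'
#' @param ee an \code{ee_trace} from [ee_from_trace()].
#' @param shift_hours nominal shift length in hours (> 0), e.g. 12 for a
#'   border-guard service shift or 8 for a work-shift severity rating.
#' @param body_mass body mass, kg; defaults to the one carried in
#'   \code{ee}.
#' @return an object of class \code{shift_summary} with fields
#'   \code{duration_h} (nominal shift), \code{recorded_h},
#'   \code{kcal_total}, \code{kcal_per_h}, \code{kcal_per_min},
#'   \code{kcal_per_h_per_kg}, \code{kcal_per_min_per_kg},
#'   \code{pulse_min}, \code{pulse_max}, \code{pulse_mean}.
#' @export
shift_summary <- function(ee, shift_hours = 12, body_mass = ee$body_mass) {
  stopifnot(inherits(ee, "ee_trace"))
  if (shift_hours <= 0) stop("shift_hours must be positive")
  if (nrow(ee$samples) == 0L) stop("empty energy-expenditure series")
  kcal_per_h <- ee$kcal_per_h
  out <- list(
    duration_h = shift_hours,
    recorded_h = ee$duration_h,
    kcal_total = kcal_per_h * shift_hours,
    kcal_per_h = kcal_per_h,
    kcal_per_min = kcal_per_h / 60,
    kcal_per_h_per_kg = kcal_per_h / body_mass,
    kcal_per_min_per_kg = kcal_per_h / 60 / body_mass,
    pulse_min = min(ee$samples$hr_bpm),
    pulse_max = max(ee$samples$hr_bpm),
    pulse_mean = mean(ee$samples$hr_bpm),
    body_mass = body_mass
  )
  class(out) <- "shift_summary"
  out
}

#' @export
print.shift_summary <- function(x, ...) {
  cat(sprintf("Shift energy load (%g h nominal, %.2f h recorded, %g kg):\n",
              x$duration_h, x$recorded_h, x$body_mass))
  cat(sprintf("  total %.0f kcal; %.1f kcal/h; %.2f kcal/min\n",
              x$kcal_total, x$kcal_per_h, x$kcal_per_min))
  cat(sprintf("  per kg: %.2f kcal/h/kg; %.4f kcal/min/kg\n",
              x$kcal_per_h_per_kg, x$kcal_per_min_per_kg))
  cat(sprintf("  pulse %g / %.1f / %g bpm (min/mean/max)\n",
              x$pulse_min, x$pulse_mean, x$pulse_max))
  invisible(x)
}
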