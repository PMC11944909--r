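#' Named-stream sub-seeds
#'
#' Each generator draws from its own RNG stream, derived from the master
#' seed plus the stream name by a small polynomial string hash (mod
#' 2^31 - 1). Adding a new generator therefore never shifts the draws of
#' existing ones, keeping seeded fixtures stable.
#'
#' @param seed master integer seed.
#' @param stream stream name, e.g. \code{"subjects"}.
#' @return an integer seed for \code{set.seed}.
#' @keywords internal
stream_seed <- function(seed, stream) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(stream)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Default simulation configuration
#'
#' The study conditions the generator emulates: four male cohorts with
#' the reported anthropometric means and SDs (age in years, body mass in
#' kg, height in cm), the at-sea frigate day as the default activity
#' template, a typical individual HR-VO2 calibration line, 3 bpm of HR
#' measurement noise sampled every 5 s, and ration targets at the
#' frigate's planned composition.
#'
#' @return a list with components \code{groups} (data frame of per-cohort
#'   anthropometric means/SDs), \code{template} (a [daily_schedule()]),
#'   \code{calibration} (list: slope, intercept, flex_hr, resting_ee,
#'   caloric_equivalent), \code{hr_noise_sd_bpm},
#'   \code{sample_interval_s}, \code{ration_profile} and
#'   \code{ration_noise_sd}.
#' @export
default_sim_config <- function() {
  groups <- utils::read.csv(
    system.file("extdata", "anthropometrics.csv", package = "crewEE"),
    stringsAsFactors = FALSE)
  template <- ship_schedule("frigate_sea")
  # A representative adult exercise calibration: VO2 rises ~12 mL/min per
  # beat from a ~0.6 L/min deficit; resting metabolism ~1.2 kcal/min. The
  # flex threshold sits below the lightest template activity (sleep at
  # ~73 bpm for an 80-kg subject) so the whole day is on the regression.
  calibration <- list(slope = 0.012, intercept = -0.6, flex_hr = 60,
                      resting_ee = 1.2, caloric_equivalent = 4.85)
  rat <- utils::read.csv(
    system.file("extdata", "rations.csv", package = "crewEE"),
    stringsAsFactors = FALSE)
  rat <- rat[rat$ship == "missile-frigate" & rat$provenance == "planned", ]
  list(
    groups = groups,
    template = template,
    calibration = calibration,
    hr_noise_sd_bpm = 3,
    sample_interval_s = 5,
    ration_profile = c(energy = rat$energy_kcal, protein = rat$protein_g,
                       fat = rat$fat_g, carb = rat$carb_g),
    ration_noise_sd = c(energy = rat$energy_sd, protein = rat$protein_sd,
                        fat = rat$fat_sd, carb = rat$carb_sd)
  )
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd < 0) stop("invalid SD")
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Generate synthetic subjects
#'
#' Draws per-cohort anthropometrics from normal distributions truncated
#' to plausible adult ranges (body mass 50–130 kg, height 150–210 cm,
#' age 18–60 y).
#'
#' @param n_per_group subjects per cohort (recycled over cohorts).
#' @param groups per-cohort parameter table as in
#'   \code{default_sim_config()$groups}.
#' @param seed master seed; the subjects stream is derived from it.
#' @return a [subjects()] table.
#' @examples
#' gen_subjects(5, seed = 1)
#' @export
gen_subjects <- function(n_per_group = 10,
                         groups = default_sim_config()$groups,
                         seed = 1) {
  if (any(c(groups$age_sd, groups$body_mass_sd, groups$height_sd) < 0)) {
    stop("invalid SDs in group configuration")
  }
  set.seed(stream_seed(seed, "subjects"))
  n_per_group <- rep_len(n_per_group, nrow(groups))
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    n <- n_per_group[i]
    data.frame(
      id = paste0(g$group, "-", seq_len(n)),
      group = g$group,
      body_mass = rtrunc_norm(n, g$body_mass_mean, g$body_mass_sd, 50, 130),
      height = rtrunc_norm(n, g$height_mean, g$height_sd, 150, 210),
      age = rtrunc_norm(n, g$age_mean, g$age_sd, 18, 60),
      stringsAsFactors = FALSE
    )
  })
  d <- do.call(rbind, rows)
  subjects(d$id, d$group, d$body_mass, d$height, d$age)
}

#' Generate a jittered daily schedule
#'
#' Perturbs each internal activity boundary of a 1440-min template by an
#' integer number of minutes drawn uniformly from
#' \verb{[-jitter_min, jitter_min]}, clamped so every activity keeps a
#' positive duration. Because only boundaries move, durations adjust in
#' compensating pairs and the total remains exactly 1440 min; the result
#' always passes [validate_schedule()].
#'
#' @param template a valid [daily_schedule()] whose durations sum to 1440.
#' @param jitter_min maximum absolute boundary shift, minutes.
#' @param seed master seed (schedule stream).
#' @return a [daily_schedule()].
#' @export
gen_schedule <- function(template, jitter_min = 0, seed = 1) {
  stopifnot(inherits(template, "daily_schedule"))
  if (sum(template$duration) != 1440) stop("template durations must sum to 1440")
  if (jitter_min < 0) stop("jitter_min must be non-negative")
  n <- nrow(template)
  if (jitter_min == 0 || n == 1L) return(template)
  max_dur <- max(template$duration)
  if (jitter_min >= min(template$duration)) {
    # still feasible thanks to clamping, but refuse absurd requests
    if (jitter_min >= 1440) stop("infeasible jitter")
  }
  set.seed(stream_seed(seed, "schedule"))
  start <- template$start
  dur <- template$duration
  # boundary i sits between entry i and i+1 (the wrap boundary is fixed)
  for (i in seq_len(n - 1L)) {
    shift <- sample(seq(-jitter_min, jitter_min), 1L)
    lo <- -(dur[i] - 1L)       # entry i must keep >= 1 min
    hi <- dur[i + 1L] - 1L     # entry i+1 must keep >= 1 min
    shift <- min(max(shift, lo), hi)
    dur[i] <- dur[i] + shift
    dur[i + 1L] <- dur[i + 1L] - shift
  }
  start_new <- (start[1L] + cumsum(c(0, dur[-n]))) %% 1440
  end_new <- (start_new + dur) %% 1440
  daily_schedule(start_new, end_new, template$activity, template$rate)
}

#' Generate an HR trace with known ground-truth energy expenditure
#'
#' Inverts the HR-to-energy model to create test inputs: for each
#' schedule entry the target heart rate is the one whose calibrated
#' prediction equals the entry's true energy cost
#' (\code{rate} \eqn{\times} body mass, kcal/min), i.e.
#' \deqn{\mathrm{HR} = \frac{E/(c\,) - a}{b}}
#' with caloric equivalent \eqn{c} and line \eqn{a + b\,\mathrm{HR}}.
#' Samples are the piecewise-constant target profile plus Gaussian noise,
#' clamped to the plausibility window. The exact ground-truth total
#' implied by the noiseless profile is returned alongside, so estimator
#' recovery can be measured.
#'
#' @param schedule a valid [daily_schedule()] (or any schedule; the trace
#'   spans its total duration).
#' @param body_mass body mass, kg.
#' @param curve the true calibration (list with \code{slope} > 0,
#'   \code{intercept}, \code{flex_hr}, \code{caloric_equivalent}).
#' @param noise_sd HR measurement noise SD, bpm.
#' @param sample_interval_s sampling interval, seconds.
#' @param seed master seed (trace stream).
#' @return a list with \code{trace} (an [hr_trace()]),
#'   \code{truth_kcal} (exact noiseless total) and \code{target_hr}
#'   (per-entry target heart rates).
#' @export
gen_hr_trace <- function(schedule, body_mass, curve, noise_sd = 3,
                         sample_interval_s = 5, seed = 1) {
  if (curve$slope <= 0) stop("true calibration slope must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  ee_min <- schedule$rate * body_mass                      # kcal/min
  vo2 <- ee_min / curve$caloric_equivalent                 # L/min
  target_hr <- (vo2 - curve$intercept) / curve$slope       # bpm
  if (any(target_hr < curve$flex_hr | target_hr > 250)) {
    stop("EE rate outside the invertible range of the calibration ",
         "(target HR below flex or above 250 bpm)")
  }
  total_min <- sum(schedule$duration)
  times <- seq(0, total_min * 60, by = sample_interval_s)
  # entry index of each sample (piecewise-constant profile, minute offsets
  # from schedule start; last sample belongs to the final entry)
  offs_min <- times / 60
  bounds <- cumsum(schedule$duration)
  idx <- findInterval(offs_min, c(0, bounds), rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[idx == 0L] <- 1L
  hr_clean <- target_hr[idx]
  set.seed(stream_seed(seed, "trace"))
  hr <- hr_clean + stats::rnorm(length(hr_clean), 0, noise_sd)
  hr <- pmin(pmax(hr, 25), 250)
  truth <- sum(ee_min * schedule$duration)
  list(trace = hr_trace(times, hr), truth_kcal = truth,
       target_hr = target_hr)
}

#' Generate a perturbed ration
#'
#' Normal perturbation of each field of a target composition, truncated
#' at zero.
#'
#' @param profile named numeric: \code{energy}, \code{protein},
#'   \code{fat}, \code{carb} targets.
#' @param noise_sd named numeric of per-field SDs (recycled if scalar).
#' @param seed master seed (ration stream).
#' @param provenance passed to [ration()].
#' @return a [ration()].
#' @export
gen_ration <- function(profile = default_sim_config()$ration_profile,
                       noise_sd = default_sim_config()$ration_noise_sd,
                       seed = 1, provenance = "served") {
  fields <- c("energy", "protein", "fat", "carb")
  stopifnot(all(fields %in% names(profile)))
  noise_sd <- rep_len(as.numeric(noise_sd), 4)
  if (any(noise_sd < 0)) stop("invalid SDs")
  set.seed(stream_seed(seed, "ration"))
  vals <- vapply(seq_along(fields), function(i) {
    rtrunc_norm(1, profile[[fields[i]]], noise_sd[i], 0, Inf)
  }, 0)
  ration(vals[1], vals[2], vals[3], vals[4], provenance = provenance,
         name = "synthetic ration")
}

#' Write a synthetic study to disk
#'
#' Runs all generators under one master seed and writes
#' \code{subjects.csv}, \code{schedule.csv}, \code{trace_<id>.csv} (for
#' the first \code{n_traces} subjects), \code{rations.json} and
#' \code{truth.json} (the generative ground truth) into \code{dir}.
#'
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param n_per_group subjects per cohort.
#' @param n_traces how many subjects get an HR trace.
#' @param config a [default_sim_config()]-shaped list.
#' @return invisibly, the list of written paths.
#' @export
simulate_study <- function(dir, seed = 1, n_per_group = 5, n_traces = 1,
                           config = default_sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subs <- gen_subjects(n_per_group, config$groups, seed = seed)
  sched <- gen_schedule(config$template, jitter_min = 5, seed = seed)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    schedule = file.path(dir, "schedule.csv"),
    rations = file.path(dir, "rations.json"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(
    data.frame(id = subs$id, group = subs$group,
               body_mass_kg = subs$body_mass, height_cm = subs$height,
               age_yr = subs$age),
    paths[["subjects"]], row.names = FALSE)
  utils::write.csv(
    data.frame(start = format_hhmm(sched$start), end = format_hhmm(sched$end),
               activity = sched$activity, rate_kcal_min_kg = sched$rate),
    paths[["schedule"]], row.names = FALSE)
  truth <- list(seed = seed, calibration = config$calibration, traces = list())
  for (i in seq_len(min(n_traces, nrow(subs)))) {
    tr <- gen_hr_trace(sched, subs$body_mass[i], config$calibration,
                       noise_sd = config$hr_noise_sd_bpm,
                       sample_interval_s = config$sample_interval_s,
                       seed = seed + i)
    p <- file.path(dir, paste0("trace_", subs$id[i], ".csv"))
    utils::write.csv(tr$trace, p, row.names = FALSE)
    paths <- c(paths, p)
    truth$traces[[subs$id[i]]] <- list(truth_kcal = tr$truth_kcal,
                                       body_mass = subs$body_mass[i])
  }
  rat <- gen_ration(config$ration_profile, config$ration_noise_sd, seed = seed)
  jsonlite::write_json(
    list(energy_kcal = rat$energy, protein_g = rat$protein,
         fat_g = rat$fat, carb_g = rat$carb),
    paths[["rations"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
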