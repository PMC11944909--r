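# Shared test helpers: independent brute-force oracles and tiny builders.

# Per-minute accumulation oracle for a daily ledger: walk the day minute by
# minute and add each minute's rate x mass. Independent of daily_ee().
minute_sum_oracle <- function(schedule, body_mass) {
  total <- 0
  for (i in seq_len(nrow(schedule))) {
    total <- total + sum(rep(schedule$rate[i], schedule$duration[i])) * body_mass
  }
  total
}

# Interval-by-interval trapezoid accumulation, written as an explicit loop so
# it shares no code with ee_from_trace().
trapezoid_oracle <- function(time_s, ee_kcal_min) {
  total <- 0
  for (i in seq_len(length(time_s) - 1L)) {
    dt_min <- (time_s[i + 1L] - time_s[i]) / 60
    total <- total + dt_min * (ee_kcal_min[i] + ee_kcal_min[i + 1L]) / 2
  }
  total
}

# Closed-form normal equations for simple OLS, independent of stats::lm.
normal_equations_fit <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1L], slope = beta[2L])
}

# A small fully-specified calibration curve for trace tests.
test_curve <- function(slope = 0.012, intercept = -0.6, flex_hr = 90,
                       resting_ee = 1.3, caloric_equivalent = 4.85) {
  list(slope = slope, intercept = intercept, flex_hr = flex_hr,
       resting_ee = resting_ee, caloric_equivalent = caloric_equivalent)
}

# Random contiguous integer-duration schedule covering the full day.
random_schedule <- function(n_entries, seed) {
  set.seed(seed)
  cuts <- sort(sample(1:1439, n_entries - 1L))
  dur <- diff(c(0, cuts, 1440))
  start <- c(0, cuts)
  end <- c(cuts, 0)
  daily_schedule(start, end, paste0("a", seq_len(n_entries)),
                 round(stats::runif(n_entries, 0, 0.08), 4))
}
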