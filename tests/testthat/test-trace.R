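test_that("a constant above-flex trace integrates to the closed form", {
  cv <- test_curve()
  hr0 <- 130
  vo2_at <- cv$intercept + cv$slope * hr0
  tr <- hr_trace(seq(0, 3600, by = 30), rep(hr0, 121))
  res <- ee_from_trace(tr, cv, body_mass = 80)
  expect_equal(res$total_kcal, 60 * cv$caloric_equivalent * vo2_at,
               tolerance = 1e-12)
  expect_equal(res$kcal_per_h, res$total_kcal, tolerance = 1e-12)  # 1-h trace
})

test_that("a trace entirely below flex accumulates resting EE", {
  cv <- test_curve(flex_hr = 100, resting_ee = 1.3)
  H <- 3
  tr <- hr_trace(seq(0, H * 3600, by = 60), rep(70, H * 60 + 1))
  res <- ee_from_trace(tr, cv, 80)
  expect_equal(res$total_kcal, cv$resting_ee * 60 * H, tolerance = 1e-12)
})

test_that("trapezoidal integration matches a per-interval brute-force oracle", {
  cv <- test_curve()
  set.seed(31)
  t_s <- cumsum(runif(500, 1, 20))          # non-uniform timestamps
  hr <- pmin(pmax(rnorm(500, 120, 25), 40), 200)
  res <- ee_from_trace(hr_trace(t_s, hr), cv, 80)
  expect_equal(res$total_kcal,
               trapezoid_oracle(t_s, res$samples$ee_kcal_min),
               tolerance = 1e-6)
})

test_that("raising an above-flex sample never decreases the total", {
  cv <- test_curve()
  set.seed(8)
  t_s <- seq(0, 1800, by = 15)
  hr <- rnorm(length(t_s), 120, 15)
  base <- ee_from_trace(hr_trace(t_s, hr), cv, 80)$total_kcal
  for (k in c(5, 60, 100)) {
    hr2 <- hr
    hr2[k] <- hr2[k] + 20
    expect_gte(ee_from_trace(hr_trace(t_s, hr2), cv, 80)$total_kcal, base)
  }
})

test_that("doubling the caloric equivalent doubles above-flex energy", {
  cv1 <- test_curve(caloric_equivalent = 4.85)
  cv2 <- test_curve(caloric_equivalent = 9.70)
  t_s <- seq(0, 3600, by = 60)
  hr <- seq(100, 160, length.out = length(t_s))
  e1 <- ee_from_trace(hr_trace(t_s, hr), cv1, 80)
  e2 <- ee_from_trace(hr_trace(t_s, hr), cv2, 80)
  expect_equal(e2$samples$ee_kcal_min, 2 * e1$samples$ee_kcal_min)
  expect_equal(e2$total_kcal, 2 * e1$total_kcal)
})

test_that("negative predicted VO2 is clamped with a warning", {
  cv <- test_curve(slope = 0.02, intercept = -2.5, flex_hr = 30,
                   resting_ee = 0)
  tr <- hr_trace(c(0, 60, 120), c(40, 40, 40))  # predicted vo2 = -1.7
  expect_warning(res <- ee_from_trace(tr, cv, 80), "clamped")
  expect_true(all(res$samples$ee_kcal_min >= 0))
  expect_equal(res$total_kcal, 0)
})

test_that("trace construction enforces ordering and plausibility", {
  expect_error(hr_trace(numeric(0), numeric(0)), "empty")
  expect_error(hr_trace(c(0, 10, 10), c(80, 80, 80)), "strictly increasing")
  expect_error(hr_trace(c(0, 10), c(80, 300)), "plausibility")
})

test_that("shift summaries aggregate as printed shift-load tables do", {
  # constant 142 kcal/h profile over 12 h
  cv <- test_curve()
  hr0 <- (142 / 60 / cv$caloric_equivalent - cv$intercept) / cv$slope
  tr <- hr_trace(seq(0, 12 * 3600, by = 60), rep(hr0, 12 * 60 + 1))
  ee <- ee_from_trace(tr, cv, body_mass = 84.1)
  s <- shift_summary(ee, shift_hours = 12)
  expect_equal(s$kcal_per_h, 142, tolerance = 1e-9)
  expect_equal(s$kcal_total, 12 * 142, tolerance = 1e-9)
  expect_identical(s$kcal_per_min, s$kcal_per_h / 60)  # exact by construction
  expect_equal(s$kcal_per_h_per_kg, 142 / 84.1, tolerance = 1e-9)
  expect_true(s$pulse_min <= s$pulse_mean && s$pulse_mean <= s$pulse_max)
  expect_error(shift_summary(ee, shift_hours = 0), "positive")
})

test_that("shift summaries match a per-sample aggregation oracle on noisy traces", {
  cfg <- default_sim_config()
  sim <- gen_hr_trace(cfg$template, 84.1, cfg$calibration,
                      noise_sd = 3, sample_interval_s = 30, seed = 12)
  ee <- ee_from_trace(sim$trace, cfg$calibration, 84.1)
  s <- shift_summary(ee, shift_hours = 12, body_mass = 84.1)
  expect_equal(s$pulse_min, min(sim$trace$hr_bpm))
  expect_equal(s$pulse_max, max(sim$trace$hr_bpm))
  expect_equal(s$pulse_mean, mean(sim$trace$hr_bpm))
  expect_equal(s$kcal_per_h,
               trapezoid_oracle(sim$trace$time_s, ee$samples$ee_kcal_min) /
                 ee$duration_h,
               tolerance = 1e-9)
})
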