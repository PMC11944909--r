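test_that("all generators are deterministic under a fixed master seed", {
  cfg <- default_sim_config()
  expect_identical(gen_subjects(5, seed = 42), gen_subjects(5, seed = 42))
  expect_identical(gen_schedule(cfg$template, 5, seed = 42),
                   gen_schedule(cfg$template, 5, seed = 42))
  t1 <- gen_hr_trace(cfg$template, 80, cfg$calibration, seed = 42)
  t2 <- gen_hr_trace(cfg$template, 80, cfg$calibration, seed = 42)
  expect_identical(t1$trace, t2$trace)
  expect_identical(gen_ration(seed = 42), gen_ration(seed = 42))
  expect_false(identical(gen_subjects(5, seed = 42), gen_subjects(5, seed = 43)))
})

test_that("generator streams are named: one generator's draws do not shift another's", {
  s_alone <- gen_subjects(5, seed = 9)
  invisible(gen_ration(seed = 9))  # interleaved call on the same master seed
  s_after <- gen_subjects(5, seed = 9)
  expect_identical(s_alone, s_after)
  expect_true(crewEE:::stream_seed(9, "subjects") !=
                crewEE:::stream_seed(9, "ration"))
})

test_that("zero-SD cohorts collapse to the group means", {
  g <- data.frame(group = "x", n = 3, age_mean = 30, age_sd = 0,
                  body_mass_mean = 80.4, body_mass_sd = 0,
                  height_mean = 178, height_sd = 0, bmi_mean = NA, bmi_sd = NA)
  s <- gen_subjects(3, g, seed = 1)
  expect_equal(s$body_mass, rep(80.4, 3))
  expect_equal(s$height, rep(178, 3))
  g$body_mass_sd <- -1
  expect_error(gen_subjects(3, g, seed = 1), "invalid SD")
})

test_that("large cohorts recover the target anthropometric means", {
  cfg <- default_sim_config()
  frig <- cfg$groups[cfg$groups$group == "missile-frigate", ]
  s <- gen_subjects(1000, frig, seed = 123)
  expect_lt(abs(mean(s$body_mass) - 80.4), 0.5)
  expect_lt(abs(mean(s$height) - 177.9), 1.0)
  expect_true(all(s$body_mass >= 50 & s$body_mass <= 130))
  expect_true(all(s$height >= 150 & s$height <= 210))
})

test_that("schedule jitter preserves the 1440-min day and validity", {
  cfg <- default_sim_config()
  expect_identical(gen_schedule(cfg$template, 0, seed = 1), cfg$template)
  for (seed in 1:10) {
    sch <- gen_schedule(cfg$template, 5, seed = seed)
    expect_true(validate_schedule(sch)$pass)
    expect_equal(sum(sch$duration), 1440)
    expect_true(all(abs(sch$duration - cfg$template$duration) <= 10))
    expect_true(all(sch$duration >= 1))
  }
  expect_error(gen_schedule(cfg$template, 1440, seed = 1), "infeasible")
})

test_that("noiseless HR traces round-trip to the generative ground truth", {
  cfg <- default_sim_config()
  sim <- gen_hr_trace(cfg$template, 80.4, cfg$calibration, noise_sd = 0,
                      sample_interval_s = 5, seed = 3)
  est <- ee_from_trace(sim$trace, cfg$calibration, 80.4)
  expect_lt(abs(est$total_kcal - sim$truth_kcal) / sim$truth_kcal, 0.001)
})

test_that("noisy HR traces recover ground truth within a few percent", {
  cfg <- default_sim_config()
  for (seed in c(5, 11, 23)) {
    sim <- gen_hr_trace(cfg$template, 80.4, cfg$calibration, noise_sd = 3,
                        sample_interval_s = 5, seed = seed)
    est <- ee_from_trace(sim$trace, cfg$calibration, 80.4)
    expect_lt(abs(est$total_kcal - sim$truth_kcal) / sim$truth_kcal, 0.03)
  }
})

test_that("coarser sampling barely changes the recovered total", {
  cfg <- default_sim_config()
  s5 <- gen_hr_trace(cfg$template, 80.4, cfg$calibration, noise_sd = 0,
                     sample_interval_s = 5, seed = 2)
  s10 <- gen_hr_trace(cfg$template, 80.4, cfg$calibration, noise_sd = 0,
                      sample_interval_s = 10, seed = 2)
  e5 <- ee_from_trace(s5$trace, cfg$calibration, 80.4)$total_kcal
  e10 <- ee_from_trace(s10$trace, cfg$calibration, 80.4)$total_kcal
  expect_lt(abs(e10 - e5) / e5, 0.01)
})

test_that("trace generation refuses non-invertible configurations", {
  cfg <- default_sim_config()
  bad <- cfg$calibration; bad$slope <- 0
  expect_error(gen_hr_trace(cfg$template, 80, bad, seed = 1), "slope")
  high_flex <- cfg$calibration; high_flex$flex_hr <- 160
  expect_error(gen_hr_trace(cfg$template, 80, high_flex, seed = 1),
               "invertible")
})

test_that("generated rations are non-negative perturbations of the profile", {
  r <- gen_ration(profile = c(energy = 100, protein = 1, fat = 1, carb = 1),
                  noise_sd = c(200, 5, 5, 5), seed = 4)
  for (f in c("energy", "protein", "fat", "carb")) expect_gte(r[[f]], 0)
  r0 <- gen_ration(noise_sd = 0, seed = 1)
  cfg <- default_sim_config()
  expect_equal(r0$energy, unname(cfg$ration_profile[["energy"]]))
})

test_that("a full synthetic study writes coherent files", {
  dir <- tempfile("sim")
  paths <- simulate_study(dir, seed = 6, n_per_group = 2, n_traces = 1)
  expect_true(all(file.exists(paths)))
  subs <- read_subjects(file.path(dir, "subjects.csv"))
  expect_equal(nrow(subs), 8)
  sch <- read_schedule(file.path(dir, "schedule.csv"))
  expect_true(validate_schedule(sch)$pass)
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  id <- names(truth$traces)[1]
  tr <- read_hr_trace(file.path(dir, paste0("trace_", id, ".csv")))
  est <- ee_from_trace(tr, truth$calibration, truth$traces[[id]]$body_mass)
  expect_lt(abs(est$total_kcal - truth$traces[[id]]$truth_kcal) /
              truth$traces[[id]]$truth_kcal, 0.03)
})
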