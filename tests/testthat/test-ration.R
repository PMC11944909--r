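test_that("Atwater energy follows the 4/9/4 factors", {
  expect_equal(atwater_energy(0, 0, 0), 0)
  expect_equal(atwater_energy(100, 0, 0), 400)
  expect_equal(atwater_energy(0, 10, 0), 90)
  expect_equal(atwater_energy(149.3, 147.4, 547.5), 4113.8, tolerance = 1e-9)
  # within 0.5% of the published (analytically determined) 4120.0 kcal
  expect_lt(abs(atwater_energy(149.3, 147.4, 547.5) - 4120.0) / 4120.0, 0.005)
  expect_error(atwater_energy(-1, 0, 0), "non-negative")
  expect_error(atwater_energy(1, 1, 1, factors = c(4, 9)), "three positive")
})

test_that("Atwater energy is linear and monotone in each macronutrient", {
  base <- atwater_energy(50, 50, 200)
  expect_equal(atwater_energy(100, 100, 400), 2 * base)
  expect_gt(atwater_energy(51, 50, 200), base)
  expect_gt(atwater_energy(50, 51, 200), base)
  expect_gt(atwater_energy(50, 50, 201), base)
})

test_that("energy shares normalise to 100 and match hand arithmetic", {
  served <- ration(4120.0, 149.3, 147.4, 547.5, provenance = "served")
  sh <- energy_shares(served)
  expect_equal(sum(sh), 100, tolerance = 1e-9)
  expect_equal(sh[["pct_fat"]], 9 * 147.4 / 4113.8 * 100, tolerance = 1e-9)
  expect_equal(round(sh[["pct_fat"]], 1), 32.2)
  # equal Atwater energies split evenly
  eq <- energy_shares(ration(NA, 90, 40, 90, provenance = "planned"))
  expect_equal(round(as.numeric(eq), 2), rep(33.33, 3))
  # absent fat contributes nothing
  expect_equal(energy_shares(ration(NA, 100, 0, 100,
                                    provenance = "planned"))[["pct_fat"]], 0)
  expect_error(energy_shares(ration(NA, 0, 0, 0, provenance = "planned")),
               "all-zero")
})

test_that("auditing a ration against itself is the identity report", {
  r <- ration(4000, 150, 140, 500, provenance = "planned")
  rep <- compare_to_standard(r, r)
  expect_equal(rep$delta, rep(0, 4))
  expect_equal(rep$pct_of_reference, rep(100, 4))
  expect_equal(rep$delta_pct_of_reference, rep(0, 4))
})

test_that("the reconstructed standard reproduces all reported shortfalls at once", {
  std <- food_standard()
  expect_equal(std$energy, 4532)
  fr_planned <- ship_ration("missile-frigate", "planned")
  fr_served <- ship_ration("missile-frigate", "served")
  ss_planned <- ship_ration("sailing-ship", "planned")
  ss_served <- ship_ration("sailing-ship", "served")

  p <- compare_to_standard(fr_planned, std)
  s <- compare_to_standard(fr_served, std)
  # energy below the standard by ~101 and ~412 kcal
  expect_equal(p$delta[p$field == "energy"], -101.1, tolerance = 1e-9)
  expect_equal(s$delta[s$field == "energy"], -412.0, tolerance = 1e-9)
  # served protein 15.3 g short = 9.3% of the standard's protein
  expect_equal(s$delta[s$field == "protein"], -15.3, tolerance = 1e-9)
  expect_equal(round(-s$delta_pct_of_reference[s$field == "protein"], 1), 9.3)
  # fat: planned ~56 g over, served 2.1 g over
  expect_equal(round(p$delta[p$field == "fat"], 1), 55.7)
  expect_equal(s$delta[s$field == "fat"], 2.1, tolerance = 1e-9)
  # sailing ship: planned fat ~22 g over; served energy short by ~22.3%
  sp <- compare_to_standard(ss_planned, std)
  ss <- compare_to_standard(ss_served, std)
  expect_equal(round(sp$delta[sp$field == "fat"], 1), 22.2)
  expect_equal(round(-ss$delta_pct_of_reference[ss$field == "energy"], 1), 22.3)
  # carbohydrate is NA in the reconstructed standard -> NA comparisons
  expect_true(is.na(s$delta[s$field == "carb"]))
})

test_that("planned-versus-served audits expose implementation gaps", {
  fr <- compare_planned_vs_served(ship_ration("missile-frigate", "planned"),
                                  ship_ration("missile-frigate", "served"))
  expect_equal(fr$delta[fr$field == "fat"], -53.6, tolerance = 1e-9)
  ss <- compare_planned_vs_served(ship_ration("sailing-ship", "planned"),
                                  ship_ration("sailing-ship", "served"))
  expect_equal(ss$delta[ss$field == "energy"], -713.8, tolerance = 1e-9)
  r <- ration(4000, 150, 140, 500, provenance = "planned")
  expect_equal(compare_planned_vs_served(r, r)$delta, rep(0, 4))
})

test_that("invalid references and rations are refused", {
  good <- ration(4000, 150, 140, 500, provenance = "served")
  zero <- ration(0, 0.0, 0, 0, provenance = "standard")
  expect_error(compare_to_standard(good, zero), "positive")
  expect_error(ration(-1, 10, 10, 10, provenance = "planned"), "non-negative")
})

test_that("rations load from JSON and CSV files", {
  fj <- tempfile(fileext = ".json")
  writeLines('{"energy_kcal": 4120, "protein_g": 149.3, "fat_g": 147.4,
               "carb_g": 547.5, "provenance": "served"}', fj)
  r <- read_ration(fj)
  expect_s3_class(r, "ration")
  expect_equal(r$fat, 147.4)
  fc <- tempfile(fileext = ".csv")
  write.csv(data.frame(energy_kcal = NA, protein_g = 100, fat_g = 50,
                       carb_g = 300), fc, row.names = FALSE)
  r2 <- read_ration(fc)
  expect_equal(r2$energy, atwater_energy(100, 50, 300))
})
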