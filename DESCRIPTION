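Package: crewEE
Title: Occupational Energy Expenditure Accounting for Ship Crews
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing the daily energy expenditure and nutritional
    adequacy of naval and maritime border-guard personnel. Implements
    activity-diary energy ledgers (per-activity and 24-h energy expenditure
    from timed schedules and per-kilogram expenditure rates), heart-rate
    based energy expenditure estimation via individually fitted linear
    HR-VO2 calibration with the flex-heart-rate convention, work-severity
    classification on the Lehmann (daily and 8-h shift) and Christensen
    (kcal/min) scales, Atwater-factor macronutrient energy accounting with
    ration-versus-food-standard adequacy reports, and a seeded synthetic
    data generator (subjects, schedules, heart-rate traces with known
    ground-truth expenditure, rations) for end-to-end parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
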