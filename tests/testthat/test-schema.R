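test_that("temperature conversions are exact and invertible", {
  expect_equal(fahrenheit_to_celsius(97.70), 36.5)
  expect_equal(fahrenheit_to_celsius_delta(0.27), 0.15)
  expect_equal(fahrenheit_to_celsius_delta(0), 0)
  expect_equal(fahrenheit_to_celsius_delta(1.8), 1.0)
  f <- seq(93, 102, by = 0.01)
  expect_equal(celsius_to_fahrenheit(fahrenheit_to_celsius(f)), f, tolerance = 1e-9)
})

test_that("kindara reader converts Fahrenheit and normalizes tokens", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "user_id,cycle_index,cycle_day,cycle_length,temperature_f,temp_time,questionable,menstruation,fluid,fluid_amount,sensation,sex",
    "u1,2,1,28,,,,heavy,,,,",
    "u1,2,5,28,97.70,06:30,FALSE,,eggwhite,lots,wet_lubricate,protected+withdrawal"
  ), path)
  cy <- read_cycles(path, "kindara")
  expect_length(cy, 1)
  d <- cy[[1]]$days
  expect_equal(d$bbt_value[d$cycle_day == 5], 36.5)
  expect_equal(d$bbt_time_minutes[d$cycle_day == 5], 390)
  expect_equal(d$vaginal_sensation[d$cycle_day == 5], "wet_lubricative")
  expect_equal(d$sex[d$cycle_day == 5], "protected+withdrawal")
  expect_equal(d$bleeding[d$cycle_day == 1], "heavy")
})

test_that("empty file with a valid header yields an empty cycle list", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("user_id,cycle_index,cycle_day,cycle_length,temperature_f", path)
  expect_identical(read_cycles(path, "kindara"), list())
})

test_that("sympto reader keeps Celsius, maps scores, folds withdrawal", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "user_id,cycle_index,cycle_day,cycle_length,temperature_c,temp_time,bleeding_score,mucus_score,cervix,sensation,sex,stm_ovulatory",
    "u1,3,1,27,36.50,07:00,3,,,,,TRUE",
    "u1,3,14,27,,,,2,open_soft_high,very_wet,withdrawal,TRUE"
  ), path)
  cy <- read_cycles(path, "sympto")[[1]]
  d <- cy$days
  expect_equal(d$bbt_value[d$cycle_day == 1], 36.50)
  expect_equal(d$bleeding[d$cycle_day == 1], "heavy")
  expect_equal(d$mucus[d$cycle_day == 14], "eggwhite")
  expect_equal(d$mucus_quantity[d$cycle_day == 14], "lots")
  expect_equal(d$cervix_openness[d$cycle_day == 14], "open")
  expect_equal(d$vaginal_sensation[d$cycle_day == 14], "wet_lubricative")
  expect_equal(d$sex[d$cycle_day == 14], "unprotected")  # app folds withdrawal
  expect_true(cy$stm_ovulatory_flag)
})

test_that("unknown tokens are rejected naming row and field", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "user_id,cycle_index,cycle_day,cycle_length,menstruation",
    "u1,2,1,28,heavy",
    "u1,2,2,28,torrential"
  ), path)
  expect_error(read_cycles(path, "kindara"), "row 2.*torrential.*menstruation")
  expect_error(read_cycles(path, "martian"), "unknown dialect")
})

test_that("every dialect category token maps to exactly one canonical value", {
  cats <- fam_categories()
  # sympto token universe
  header <- "user_id,cycle_index,cycle_day,cycle_length,bleeding_score,mucus_score,cervix,sensation"
  bleed <- c("0", "1", "2", "3")
  mucus <- c("0", "1", "2")
  cervix <- c("closed_firm_low", "medium", "open_soft_high")
  sens <- c("dry", "wet", "very_wet")
  combos <- expand.grid(b = bleed, m = mucus, cx = cervix, s = sens,
                        stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header, sprintf("u1,2,%d,200,%s,%s,%s,%s", seq_len(nrow(combos)),
                               combos$b, combos$m, combos$cx, combos$s)), path)
  d <- read_cycles(path, "sympto")[[1]]$days
  expect_equal(nrow(d), nrow(combos))
  expect_true(all(d$bleeding %in% cats$bleeding))
  expect_true(all(is.na(d$mucus) | d$mucus %in% cats$mucus))
  expect_true(all(d$cervix_openness %in% cats$cervix_openness))
  expect_true(all(d$vaginal_sensation %in% cats$vaginal_sensation))
  # sympto 2-level mucus: low row -> (creamy, little), high row -> (eggwhite, lots)
  expect_true(all(d$mucus[combos$m == "1"] == "creamy" &
                    d$mucus_quantity[combos$m == "1"] == "little"))
  expect_true(all(d$mucus[combos$m == "2"] == "eggwhite" &
                    d$mucus_quantity[combos$m == "2"] == "lots"))
  # kindara token universe
  header_k <- "user_id,cycle_index,cycle_day,cycle_length,menstruation,fluid,fluid_amount,cervix_openness,sensation"
  combos_k <- expand.grid(b = cats$bleeding, f = cats$mucus,
                          co = cats$cervix_openness,
                          s = c("dry", "dry_sticky", "wet_moist", "wet_lubricate"),
                          stringsAsFactors = FALSE)
  combos_k$fa <- ifelse(combos_k$f == "none", "", "medium")
  path_k <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header_k, sprintf("u1,2,%d,2000,%s,%s,%s,%s,%s",
                                 seq_len(nrow(combos_k)), combos_k$b, combos_k$f,
                                 combos_k$fa, combos_k$co, combos_k$s)), path_k)
  dk <- read_cycles(path_k, "kindara")[[1]]$days
  expect_equal(nrow(dk), nrow(combos_k))
  expect_true(all(dk$bleeding %in% cats$bleeding))
  expect_true(all(dk$mucus %in% cats$mucus))
  expect_true(all(dk$vaginal_sensation %in% cats$vaginal_sensation))
})

test_that("canonical and kindara CSVs round-trip the canonical fields", {
  coh <- generate_cycles(synthetic_config(n_users = 4, rng_seed = 21), "canonical")
  for (dialect in c("canonical", "kindara")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_cycles(coh$cycles, path, dialect)
    back <- read_cycles(path, dialect)
    expect_length(back, length(coh$cycles))
    for (i in seq_along(back)) {
      a <- coh$cycles[[i]]; b <- back[[i]]
      expect_equal(b$length_days, a$length_days)
      expect_equal(b$goal, a$goal)
      expect_equal(b$days$cycle_day, a$days$cycle_day)
      for (f in c("bleeding", "mucus", "mucus_quantity", "vaginal_sensation", "sex")) {
        expect_identical(b$days[[f]], a$days[[f]])
      }
      expect_equal(b$days$bbt_value, a$days$bbt_value, tolerance = 0.011)
    }
  }
})

test_that("implausible user metadata is blanked, never dropped", {
  users <- user_meta(c("a", "b", "c"),
                     height_cm = c(45, 165, 170),
                     weight_kg = c(60, 60, 500),
                     menarche_age_years = c(13, 13, 3))
  out <- clean_user_meta(users)
  expect_equal(nrow(out), 3)
  expect_true(is.na(out$height_cm[1]))
  expect_equal(out$weight_kg[1], 60)
  expect_equal(out$height_cm[2], 165)
  expect_equal(out$weight_kg[2], 60)
  expect_true(is.na(out$weight_kg[3]))
  expect_true(is.na(out$menarche_age_years[3]))
  expect_equal(nrow(clean_user_meta(user_meta(character()))), 0)
})

test_that("bmi follows weight over squared height in metres", {
  expect_equal(bmi(60, 165), 22.04, tolerance = 1e-3)
  expect_equal(bmi(100, 200), 25.0)
  expect_error(bmi(0, 165), "positive")
})

test_that("mucus fertility grading matches the low/high grouping", {
  expect_equal(mucus_fertility_grade("eggwhite", "lots"), "high")
  expect_equal(mucus_fertility_grade("watery", "medium"), "high")
  expect_equal(mucus_fertility_grade("watery", "lots"), "high")
  expect_equal(mucus_fertility_grade("watery", "little"), "low")
  expect_equal(mucus_fertility_grade("eggwhite", "little"), "low")
  expect_equal(mucus_fertility_grade("eggwhite", "medium"), "low")
  expect_equal(mucus_fertility_grade("creamy", "lots"), "low")
  expect_equal(mucus_fertility_grade("sticky", NA), "low")
  expect_equal(mucus_fertility_grade("none", NA), "none")
  expect_true(is.na(mucus_fertility_grade(NA, NA)))
})
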