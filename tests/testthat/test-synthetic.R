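full_logging <- function(p = 1) {
  lapply(list(conception = 1, contraception = 1, observation = 1), function(.) {
    c(bbt = p, mucus = p, bleeding = p, cervix = p, sensation = p, sex = 0.2)
  })
}

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_users = 3, rng_seed = 7)
  a <- generate_cycles(cfg, "kindara")
  b <- generate_cycles(cfg, "kindara")
  expect_identical(a, b)
  c2 <- generate_cycles(synthetic_config(n_users = 3, rng_seed = 8), "kindara")
  expect_false(identical(a$cycles, c2$cycles))
})

test_that("with all logging probabilities at 1 every cycle day is present", {
  cfg <- synthetic_config(n_users = 3, logging = full_logging(), rng_seed = 3)
  coh <- generate_cycles(cfg, "canonical")
  for (cy in coh$cycles) expect_equal(cy$days$cycle_day, seq_len(cy$length_days))
})

test_that("invalid configs are rejected listing the offending fields", {
  expect_error(synthetic_config(terminal_spotting_prob = 1.2),
               "terminal_spotting_prob")
  expect_error(synthetic_config(luteal_support = 7:9, luteal_probs = c(0.5, 0.6)),
               "luteal_probs")
})

test_that("true follicular lengths have the configured median and spread", {
  coh <- generate_cycles(synthetic_config(n_users = 200, rng_seed = 11), "canonical")
  tt <- truth_phase_table(coh$truths)
  expect_equal(median(tt$follicular), 16, tolerance = 1)
  frac_10_24 <- mean(tt$follicular >= 10 & tt$follicular <= 24)
  expect_gt(frac_10_24, 0.85)
})

test_that("generated phase lengths match the configured distributions", {
  cfg <- synthetic_config(n_users = 280, rng_seed = 5)
  coh <- generate_cycles(cfg, "canonical")
  tt <- truth_phase_table(coh$truths)
  expect_gte(nrow(tt), 2000)
  tt <- tt[seq_len(2000), ]
  # luteal: chi-square against the exact configured pmf
  obs <- table(factor(tt$luteal, levels = cfg$luteal_support))
  p_lut <- suppressWarnings(
    stats::chisq.test(as.vector(obs), p = cfg$luteal_probs)$p.value)
  expect_gt(p_lut, 0.01)
  # follicular: chi-square against the rounded, clamped lognormal
  lo <- cfg$follicular_range[1]; hi <- cfg$follicular_range[2]
  ks <- lo:hi
  pk <- stats::plnorm(ks + 0.5, cfg$follicular_meanlog, cfg$follicular_sdlog) -
    stats::plnorm(ks - 0.5, cfg$follicular_meanlog, cfg$follicular_sdlog)
  pk[1] <- stats::plnorm(lo + 0.5, cfg$follicular_meanlog, cfg$follicular_sdlog)
  pk[length(pk)] <- 1 - stats::plnorm(hi - 0.5, cfg$follicular_meanlog,
                                      cfg$follicular_sdlog)
  obs_f <- table(factor(tt$follicular, levels = ks))
  keep <- pk * 2000 >= 1  # pool ultra-rare bins out of the test
  p_fol <- suppressWarnings(
    stats::chisq.test(as.vector(obs_f)[keep], p = pk[keep] / sum(pk[keep]))$p.value)
  expect_gt(p_fol, 0.01)
  # short-luteal tail exercised: >= 10% of cycles at <= 10 days
  expect_gte(mean(tt$luteal <= 10), 0.10)
})

test_that("noiseless plateau BBT difference equals the configured shift exactly", {
  cfg <- synthetic_config(n_users = 5, bbt_noise_sd_c = 0,
                          terminal_spotting_prob = 0,
                          logging = full_logging(), rng_seed = 13)
  coh <- generate_cycles(cfg, "canonical")
  for (i in seq_along(coh$cycles)) {
    cy <- coh$cycles[[i]]
    tr <- coh$truths[[i]]
    post <- tr$states %in% c("HP", "EP", "LP")
    pre <- seq_along(tr$states) <= tr$ovulation_day  # Rise days excluded
    d <- cy$days
    expect_equal(mean(d$bbt_value[post]) - mean(d$bbt_value[pre]),
                 cfg$bbt_luteal_shift_c, tolerance = 1e-9)
  }
})

test_that("truth state sequences are ordered and have one ovulation day", {
  ord <- hmm_states()
  coh <- generate_cycles(synthetic_config(n_users = 20, rng_seed = 2), "canonical")
  for (tr in coh$truths) {
    idx <- match(tr$states, ord)
    expect_true(all(diff(idx) >= 0))
    expect_equal(sum(tr$states == "Ovu"), 1)
    expect_equal(tr$states[tr$ovulation_day], "Ovu")
    expect_equal(length(tr$states), tr$length_days)
  }
})

test_that("kindara serialization round-trips to the canonical content", {
  cfg <- synthetic_config(n_users = 3, rng_seed = 17)
  canon <- generate_cycles(cfg, "canonical")
  kind <- generate_cycles(cfg, "kindara")
  dir <- withr::local_tempdir()
  write_synthetic_cohort(kind, dir, dialect = "kindara")
  back <- read_cycles(file.path(dir, "cycles.csv"), "kindara")
  expect_length(back, length(canon$cycles))
  for (i in seq_along(back)) {
    a <- canon$cycles[[i]]; b <- back[[i]]
    expect_equal(b$days$cycle_day, a$days$cycle_day)
    expect_identical(b$days$bleeding, a$days$bleeding)
    expect_identical(b$days$mucus, a$days$mucus)
    expect_identical(b$days$mucus_quantity, a$days$mucus_quantity)
    expect_equal(b$days$bbt_value, a$days$bbt_value, tolerance = 0.006)
  }
})

test_that("truth phase table follows the exclusion-based luteal definition", {
  tr <- list(
    list(user_id = "u", cycle_index = 2, length_days = 28, states = character(),
         ovulation_day = 16, logged = NULL),
    list(user_id = "u", cycle_index = 3, length_days = 30, states = character(),
         ovulation_day = 30, logged = NULL),
    list(user_id = "u", cycle_index = 4, length_days = 35, states = character(),
         ovulation_day = NA_integer_, logged = NULL)
  )
  tab <- truth_phase_table(tr)
  expect_equal(tab$luteal, c(12L, 0L, NA_integer_))
  expect_equal(tab$follicular, c(16L, 30L, NA_integer_))
})
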