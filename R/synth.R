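# Synthetic FAM-tracking cohort generator with known ground truth.
#
# Ground-truth state sequences are laid down directly from sampled phase
# durations (not by simulating the inference HMM's transition matrix), so the
# generator and the estimator are independent and parameter-recovery tests
# are meaningful.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of sympto-thermal app data:
#' a biphasic BBT with a ~0.36 degC post-ovulatory shift, follicular lengths
#' lognormal with median 16 d and ~90% of mass in \[10, 24\] d, luteal lengths
#' with median 12-13 d, sd ~2 d and a short-luteal tail (15% of cycles
#' <= 10 d), menses of 3-6 d starting heavy, occasional terminal spotting with
#' a small end-of-cycle BBT dip, high-fertility mucus concentrated in the
#' days up to and including ovulation, and per-field daily logging
#' probabilities that depend on the user's family-planning goal.
#'
#' @param n_users Number of users.
#' @param cycles_per_user_min Minimum cycles per user (users of the apps in
#'   scope have at least 4 logged cycles).
#' @param cycles_per_user_nb `c(size, mu)` of the negative-binomial excess
#'   over the minimum.
#' @param follicular_meanlog,follicular_sdlog Lognormal parameters of the
#'   follicular length (ovulation day); defaults give median 16 d with ~90%
#'   of ovulations between day 10 and day 24.
#' @param follicular_range Hard clamp on follicular length, days.
#' @param luteal_support,luteal_probs Discrete luteal-length distribution.
#' @param bbt_baseline_c Mean pre-ovulatory BBT, degC.
#' @param bbt_baseline_user_sd Between-user sd of the baseline, degC.
#' @param bbt_luteal_shift_c Post-ovulatory BBT shift, degC.
#' @param bbt_noise_sd_c Within-day Gaussian BBT noise, degC.
#' @param bbt_time_base_minutes,bbt_time_user_sd,bbt_time_jitter_sd Temperature
#'   measurement time model (minutes after midnight): per-user habitual time
#'   plus day-to-day jitter. The time feeds only the confidence score; a
#'   time-of-day temperature slope (degC/hour) is available via
#'   `bbt_time_slope_c_per_h` but defaults to 0.
#' @param bbt_time_slope_c_per_h Optional temperature drift per hour of
#'   measurement-time deviation (default 0).
#' @param terminal_spotting_prob Probability a cycle ends with 1-2 days of
#'   spotting/light bleeding (with a small BBT dip on those days).
#' @param terminal_spotting_dip_c BBT dip applied on terminal spotting days.
#' @param anovulatory_cycle_prob Probability a cycle has no ovulation.
#' @param mucus_misreport_prob Probability a day's mucus report is replaced by
#'   a uniformly random category (observation error; magnitude is a guess, no
#'   published error rates exist).
#' @param emit_cervix,emit_vaginal_sensation Generate the secondary signals
#'   (off by default).
#' @param goal_probs Named probabilities of user goals.
#' @param logging Named list (by goal) of named per-field daily logging
#'   probabilities (`bbt`, `mucus`, `bleeding`, `cervix`, `sensation`, `sex`).
#' @param logging_scale Global multiplier applied to the `bbt`, `mucus`,
#'   `cervix` and `sensation` logging probabilities (used to study tracking-
#'   sparsity regimes).
#' @param rng_seed Integer seed; a fixed seed makes [generate_cycles()] output
#'   byte-identical across runs.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_users = 50,
    cycles_per_user_min = 4,
    cycles_per_user_nb = c(size = 2, mu = 3),
    follicular_meanlog = log(16),
    follicular_sdlog = 0.26,
    follicular_range = c(6, 40),
    luteal_support = 7:17,
    luteal_probs = c(0.02, 0.03, 0.05, 0.05, 0.11, 0.20, 0.19, 0.14, 0.10, 0.07, 0.04),
    bbt_baseline_c = 36.4,
    bbt_baseline_user_sd = 0.10,
    bbt_luteal_shift_c = 0.36,
    bbt_noise_sd_c = 0.15,
    bbt_time_base_minutes = 6.5 * 60,
    bbt_time_user_sd = 45,
    bbt_time_jitter_sd = 20,
    bbt_time_slope_c_per_h = 0,
    terminal_spotting_prob = 0.15,
    terminal_spotting_dip_c = 0.08,
    anovulatory_cycle_prob = 0,
    mucus_misreport_prob = 0.05,
    emit_cervix = FALSE,
    emit_vaginal_sensation = FALSE,
    goal_probs = c(conception = 0.4, contraception = 0.35, observation = 0.25),
    logging = list(
      conception    = c(bbt = 0.90, mucus = 0.80, bleeding = 0.95, cervix = 0.5,
                        sensation = 0.5, sex = 0.25),
      contraception = c(bbt = 0.90, mucus = 0.80, bleeding = 0.95, cervix = 0.5,
                        sensation = 0.5, sex = 0.15),
      observation   = c(bbt = 0.80, mucus = 0.70, bleeding = 0.90, cervix = 0.4,
                        sensation = 0.4, sex = 0.08)
    ),
    logging_scale = 1,
    rng_seed = 1L) {
  cfg <- as.list(environment())
  problems <- character()
  chk01 <- function(x, nm) {
    if (any(x < 0 | x > 1)) problems <<- c(problems, nm)
  }
  if (n_users < 1) problems <- c(problems, "n_users")
  if (cycles_per_user_min < 1) problems <- c(problems, "cycles_per_user_min")
  if (length(luteal_support) != length(luteal_probs) ||
      abs(sum(luteal_probs) - 1) > 1e-9 || any(luteal_probs < 0)) {
    problems <- c(problems, "luteal_probs")
  }
  chk01(terminal_spotting_prob, "terminal_spotting_prob")
  chk01(anovulatory_cycle_prob, "anovulatory_cycle_prob")
  chk01(mucus_misreport_prob, "mucus_misreport_prob")
  chk01(unlist(logging), "logging")
  chk01(logging_scale, "logging_scale")
  if (abs(sum(goal_probs) - 1) > 1e-9) problems <- c(problems, "goal_probs")
  if (bbt_noise_sd_c < 0) problems <- c(problems, "bbt_noise_sd_c")
  if (length(problems) > 0) {
    stop("invalid synthetic config field(s): ", paste(unique(problems), collapse = ", "))
  }
  structure(cfg, class = "synthetic_config")
}

# Generator-side mucus emissions: rows are (category, quantity, prob) blocks
# per true state. Independent of the inference spec's emission tables.
.synth_mucus_tables <- function() {
  tbl <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(mucus = m[, 1], quantity = m[, 2],
               prob = as.numeric(m[, 3]), stringsAsFactors = FALSE)
  }
  list(
    HM  = tbl("none", NA, .92, "creamy", "little", .06, "sticky", "little", .02),
    LM  = tbl("none", NA, .90, "creamy", "little", .07, "sticky", "little", .03),
    LE  = tbl("none", NA, .55, "sticky", "little", .15, "creamy", "little", .25,
              "eggwhite", "little", .05),
    HE  = tbl("none", NA, .10, "creamy", "medium", .10, "eggwhite", "medium", .15,
              "eggwhite", "lots", .40, "watery", "lots", .25),
    Ovu = tbl("none", NA, .10, "creamy", "medium", .10, "eggwhite", "medium", .15,
              "eggwhite", "lots", .40, "watery", "lots", .25),
    Rise = tbl("none", NA, .45, "creamy", "little", .30, "eggwhite", "little", .15,
               "eggwhite", "lots", .07, "watery", "medium", .03),
    HP  = tbl("none", NA, .78, "sticky", "little", .10, "creamy", "little", .10,
              "eggwhite", "lots", .02),
    EP  = tbl("none", NA, .55, "creamy", "medium", .25, "eggwhite", "medium", .12,
              "eggwhite", "lots", .08),
    LP  = tbl("none", NA, .88, "sticky", "little", .07, "creamy", "little", .05)
  )
}

.sample_row <- function(tbl) tbl[sample.int(nrow(tbl), 1, prob = tbl$prob), ]

# Phase-duration layout for one ovulatory cycle. Returns per-day true states.
.layout_states <- function(follicular, luteal) {
  hm <- sample(1:3, 1, prob = c(0.25, 0.5, 0.25))
  lm <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
  # keep menses comfortably inside the follicular phase
  while (hm + lm > follicular - 3 && lm > 1) lm <- lm - 1
  while (hm + lm > follicular - 3 && hm > 1) hm <- hm - 1
  he <- sample(3:5, 1)
  he <- max(1, min(he, follicular - 1 - (hm + lm) - 1))
  le <- follicular - 1 - hm - lm - he
  rise <- min(sample(1:2, 1), max(1, luteal - 2))
  rem <- luteal - rise
  if (rem <= 0) {
    hp <- ep <- lp <- 0
  } else {
    hp <- max(1, round(rem * 0.5))
    ep <- if (rem - hp >= 2) sample(1:2, 1) else if (rem - hp >= 1) 1 else 0
    lp <- rem - hp - ep
  }
  c(rep("HM", hm), rep("LM", lm), rep("LE", le), rep("HE", he), "Ovu",
    rep("Rise", rise), rep("HP", hp), rep("EP", ep), rep("LP", lp))
}

#' Generate a synthetic FAM-tracking cohort with ground truth
#'
#' Each cycle is built by sampling phase durations, laying down the true
#' hormonal state sequence (HM, LM, LE, HE, Ovu, Rise, HP, EP, LP), emitting
#' observations per day from state-conditional distributions, and masking
#' days by the goal-dependent logging probabilities. Days on which nothing
#' was logged are absent from `Cycle$days` (but present in the truth's
#' logging mask).
#'
#' Output is byte-identical for a fixed `rng_seed`; the dialect only affects
#' the app-convention details (Sympto cycles always start with a logged heavy
#' bleeding day, Sympto sex events never include withdrawal/insemination
#' tokens), not the random draws.
#'
#' @param config A [synthetic_config()].
#' @param dialect `"sympto"`, `"kindara"` or `"canonical"`.
#' @return List with `cycles` (list of `fam_cycle`), `truths` (list of
#'   per-cycle ground truth: `user_id`, `cycle_index`, `length_days`,
#'   `states`, `ovulation_day`, `logged` mask tibble), and `users` (a
#'   [user_meta()] tibble).
#' @export
generate_cycles <- function(config = synthetic_config(),
                            dialect = c("canonical", "sympto", "kindara")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed)
  mucus_tables <- .synth_mucus_tables()
  cats <- fam_categories()

  cycles <- list()
  truths <- list()
  users_rows <- list()

  for (u in seq_len(config$n_users)) {
    uid <- sprintf("u%04d", u)
    goal <- sample(names(config$goal_probs), 1, prob = config$goal_probs)
    n_cycles <- config$cycles_per_user_min +
      stats::rnbinom(1, size = config$cycles_per_user_nb[["size"]],
                     mu = config$cycles_per_user_nb[["mu"]])
    baseline <- config$bbt_baseline_c + stats::rnorm(1, 0, config$bbt_baseline_user_sd)
    user_time <- config$bbt_time_base_minutes + stats::rnorm(1, 0, config$bbt_time_user_sd)
    users_rows[[u]] <- user_meta(
      uid,
      birth_year = round(stats::rnorm(1, 1988, 5)),
      weight_kg = round(stats::rnorm(1, 62, 10), 1),
      height_cm = round(stats::rnorm(1, 165, 7)),
      menarche_age_years = round(stats::rnorm(1, 13, 1.5))
    )
    lp <- config$logging[[goal]]
    lp_eff <- lp
    for (f in c("bbt", "mucus", "cervix", "sensation")) {
      lp_eff[f] <- min(1, lp[f] * config$logging_scale)
    }

    for (ci in seq_len(n_cycles)) {
      anov <- stats::runif(1) < config$anovulatory_cycle_prob
      if (anov) {
        len <- round(stats::rlnorm(1, log(35), 0.3))
        len <- max(15, min(90, len))
        hm <- sample(1:3, 1, prob = c(0.25, 0.5, 0.25))
        lm <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
        states <- c(rep("HM", hm), rep("LM", lm), rep("LE", len - hm - lm))
        ovu <- NA_integer_
      } else {
        fol <- round(stats::rlnorm(1, config$follicular_meanlog, config$follicular_sdlog))
        fol <- max(config$follicular_range[1], min(config$follicular_range[2], fol))
        lut <- sample(config$luteal_support, 1, prob = config$luteal_probs)
        states <- .layout_states(fol, lut)
        len <- length(states)
        ovu <- fol
      }

      # terminal spotting days (also get a small BBT dip)
      term_spot <- integer(0)
      if (!anov && stats::runif(1) < config$terminal_spotting_prob) {
        nsp <- sample(1:2, 1)
        term_spot <- seq.int(max(1, len - nsp + 1), len)
        term_spot <- term_spot[states[term_spot] %in% c("LP", "EP", "HP")]
      }

      rise_days <- which(states == "Rise")
      shift_frac <- numeric(len)
      shift_frac[states %in% c("HP", "EP", "LP")] <- 1
      if (length(rise_days) > 0) {
        shift_frac[rise_days] <- seq_along(rise_days) / (length(rise_days) + 1)
      }

      bbt_true <- baseline + config$bbt_luteal_shift_c * shift_frac
      bbt_true[term_spot] <- bbt_true[term_spot] - config$terminal_spotting_dip_c
      times <- user_time + stats::rnorm(len, 0, config$bbt_time_jitter_sd)
      bbt <- bbt_true + stats::rnorm(len, 0, config$bbt_noise_sd_c) +
        config$bbt_time_slope_c_per_h * (times - user_time) / 60
      bbt <- pmin(40, pmax(34, bbt))

      bleeding <- rep(NA_character_, len)
      for (t in seq_len(len)) {
        s <- states[t]
        if (s == "HM") {
          bleeding[t] <- if (t == 1) {
            if (dialect == "sympto") "heavy" else sample(c("heavy", "medium"), 1,
                                                         prob = c(0.7, 0.3))
          } else sample(c("heavy", "medium"), 1, prob = c(0.5, 0.5))
        } else if (s == "LM") {
          bleeding[t] <- sample(c("light", "spotting"), 1, prob = c(0.6, 0.4))
        }
      }
      bleeding[term_spot] <- sample(c("spotting", "light"), length(term_spot),
                                    replace = TRUE, prob = c(0.7, 0.3))

      mucus <- rep(NA_character_, len)
      mucus_q <- rep(NA_character_, len)
      for (t in seq_len(len)) {
        s <- states[t]
        tab <- mucus_tables[[s]]
        if (is.null(tab)) tab <- mucus_tables$LE
        if (stats::runif(1) < config$mucus_misreport_prob) {
          mucus[t] <- sample(cats$mucus, 1)
          mucus_q[t] <- if (mucus[t] == "none") NA_character_ else sample(cats$mucus_quantity, 1)
        } else {
          row <- .sample_row(tab)
          mucus[t] <- row$mucus
          mucus_q[t] <- if (is.na(row$quantity)) NA_character_ else row$quantity
        }
      }

      cervix_o <- rep(NA_character_, len)
      sensation <- rep(NA_character_, len)
      if (config$emit_cervix || config$emit_vaginal_sensation) {
        fertile <- states %in% c("HE", "Ovu")
        cervix_o <- ifelse(fertile,
                           sample(c("open", "medium"), len, TRUE, prob = c(0.7, 0.3)),
                           sample(c("closed", "medium"), len, TRUE, prob = c(0.8, 0.2)))
        sens_pool_f <- if (dialect == "sympto") c("wet_moist", "wet_lubricative")
                       else c("wet_moist", "wet_lubricative")
        sens_pool_i <- if (dialect == "sympto") c("dry", "wet_moist")
                       else c("dry", "dry_sticky")
        sensation <- ifelse(fertile,
                            sample(sens_pool_f, len, TRUE, prob = c(0.4, 0.6)),
                            sample(sens_pool_i, len, TRUE, prob = c(0.7, 0.3)))
      }

      sex <- rep(NA_character_, len)
      sex_day <- stats::runif(len) < config$logging[[goal]][["sex"]]
      if (any(sex_day)) {
        pool <- switch(goal,
          conception = if (dialect == "sympto") c("unprotected") else
            c("unprotected", "insemination"),
          contraception = if (dialect == "sympto") c("protected", "unprotected") else
            c("protected", "unprotected", "withdrawal"),
          observation = c("protected", "unprotected")
        )
        probs <- switch(goal,
          conception = if (dialect == "sympto") 1 else c(0.95, 0.05),
          contraception = if (dialect == "sympto") c(0.8, 0.2) else c(0.7, 0.2, 0.1),
          observation = c(0.5, 0.5)
        )
        sex[sex_day] <- sample(pool, sum(sex_day), replace = TRUE, prob = probs)
      }

      # logging mask per field
      log_bbt <- stats::runif(len) < lp_eff[["bbt"]]
      log_mucus <- stats::runif(len) < lp_eff[["mucus"]]
      log_bleed <- stats::runif(len) < lp[["bleeding"]]
      log_cervix <- (config$emit_cervix) & (stats::runif(len) < lp_eff[["cervix"]])
      log_sens <- (config$emit_vaginal_sensation) & (stats::runif(len) < lp_eff[["sensation"]])
      if (dialect == "sympto") log_bleed[1] <- TRUE  # app starts the cycle on it

      obs_bbt <- ifelse(log_bbt, bbt, NA_real_)
      obs_time <- ifelse(log_bbt, round(times), NA_real_)
      obs_bleed <- ifelse(log_bleed, bleeding, NA_character_)
      obs_mucus <- ifelse(log_mucus, mucus, NA_character_)
      obs_mucus_q <- ifelse(log_mucus, mucus_q, NA_character_)
      obs_cervix <- ifelse(log_cervix, cervix_o, NA_character_)
      obs_sens <- ifelse(log_sens, sensation, NA_character_)

      has_obs <- !is.na(obs_bbt) | !is.na(obs_bleed) | !is.na(obs_mucus) |
        !is.na(obs_cervix) | !is.na(obs_sens) | !is.na(sex)
      days <- tibble::tibble(
        cycle_day = seq_len(len),
        bbt_value = obs_bbt,
        bbt_time_minutes = obs_time,
        bbt_questionable = ifelse(is.na(obs_bbt), NA, FALSE),
        bleeding = obs_bleed,
        mucus = obs_mucus,
        mucus_quantity = obs_mucus_q,
        cervix_height = NA_character_,
        cervix_firmness = ifelse(is.na(obs_cervix), NA_character_,
                                 c(closed = "firm", medium = "medium",
                                   open = "soft")[obs_cervix]),
        cervix_openness = obs_cervix,
        vaginal_sensation = obs_sens,
        sex = sex
      )[has_obs, ]
      days$cervix_height <- ifelse(is.na(days$cervix_openness), NA_character_,
                                   c(closed = "low", medium = "medium",
                                     open = "high")[days$cervix_openness])

      cy <- new_cycle(
        user_id = uid, cycle_index = ci, length_days = len, days = days,
        app_dialect = dialect, goal = goal,
        is_last_of_user = (ci == n_cycles),
        stm_ovulatory_flag = if (dialect == "sympto") !anov else NA,
        breastfeeding = FALSE, perimenopause = FALSE
      )
      cycles[[length(cycles) + 1]] <- cy
      truths[[length(truths) + 1]] <- list(
        user_id = uid, cycle_index = ci, length_days = len,
        states = states, ovulation_day = ovu,
        logged = tibble::tibble(
          cycle_day = seq_len(len), bbt = log_bbt, mucus = log_mucus,
          bleeding = log_bleed & !is.na(bleeding), cervix = log_cervix,
          sensation = log_sens, sex = !is.na(sex)
        )
      )
    }
  }
  list(cycles = cycles, truths = truths, users = dplyr::bind_rows(users_rows))
}

#' Ground-truth phase durations
#'
#' Follicular length equals the true ovulation day; luteal length is the
#' number of days between the ovulation day (excluded) and the first day of
#' the next cycle (excluded), i.e. cycle length minus ovulation day.
#' Anovulatory cycles get `NA` phases.
#'
#' @param truths Truth list from [generate_cycles()].
#' @return Tibble with `user_id`, `cycle_index`, `length_days`,
#'   `ovulation_day`, `follicular`, `luteal`.
#' @export
truth_phase_table <- function(truths) {
  dplyr::bind_rows(lapply(truths, function(tr) {
    tibble::tibble(
      user_id = tr$user_id, cycle_index = tr$cycle_index,
      length_days = tr$length_days,
      ovulation_day = as.integer(tr$ovulation_day),
      follicular = as.integer(tr$ovulation_day),
      luteal = as.integer(tr$length_days - tr$ovulation_day)
    )
  }))
}

#' Write a synthetic cohort to disk
#'
#' Serializes the cycles in the requested dialect CSV (see [write_cycles()]),
#' the truth table, the truth state sequences, and the user metadata.
#'
#' @param cohort Result of [generate_cycles()].
#' @param dir Output directory (created if needed).
#' @param dialect Dialect for the cycles CSV.
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir, dialect = "canonical") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cycles(cohort$cycles, file.path(dir, "cycles.csv"), dialect)
  readr::write_csv(truth_phase_table(cohort$truths),
                   file.path(dir, "truth_phases.csv"), na = "", progress = FALSE)
  states_tbl <- dplyr::bind_rows(lapply(cohort$truths, function(tr) {
    tibble::tibble(user_id = tr$user_id, cycle_index = tr$cycle_index,
                   cycle_day = seq_len(tr$length_days), state = tr$states)
  }))
  readr::write_csv(states_tbl, file.path(dir, "truth_states.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(cohort$users, file.path(dir, "users.csv"),
                   na = "", progress = FALSE)
  invisible(dir)
}
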