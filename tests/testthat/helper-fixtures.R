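# Fixture builders and the brute-force HMM oracle used across tests.

# A hand-built cycle: temps/bleeding/mucus vectors indexed by cycle day
# (NA = not logged that day). Days with no logged field are dropped, as in
# the canonical model.
make_cycle <- function(length_days, temps = NULL, bleeding = NULL, mucus = NULL,
                       mucus_quantity = NULL, times = NULL, questionable = NULL,
                       sex = NULL, cycle_index = 2, is_last = FALSE,
                       dialect = "canonical", stm_flag = NA, goal = "unknown",
                       breastfeeding = FALSE, perimenopause = FALSE,
                       user_id = "u1") {
  pad <- function(x, proto) {
    if (is.null(x)) return(rep(proto, length_days))
    length(x) <- length_days
    x
  }
  temps <- pad(temps, NA_real_)
  bleeding <- pad(bleeding, NA_character_)
  mucus <- pad(mucus, NA_character_)
  mucus_quantity <- pad(mucus_quantity, NA_character_)
  times <- pad(times, NA_real_)
  questionable <- if (is.null(questionable)) rep(NA, length_days) else {
    length(questionable) <- length_days; questionable
  }
  sex <- pad(sex, NA_character_)
  keep <- !is.na(temps) | !is.na(bleeding) | !is.na(mucus) | !is.na(sex)
  days <- tibble::tibble(
    cycle_day = seq_len(length_days),
    bbt_value = temps,
    bbt_time_minutes = ifelse(is.na(temps), NA_real_, times),
    bbt_questionable = ifelse(is.na(temps), NA, questionable),
    bleeding = bleeding, mucus = mucus, mucus_quantity = mucus_quantity,
    cervix_height = NA_character_, cervix_firmness = NA_character_,
    cervix_openness = NA_character_, vaginal_sensation = NA_character_,
    sex = sex
  )[keep, ]
  new_cycle(user_id, cycle_index, length_days, days, app_dialect = dialect,
            goal = goal, is_last_of_user = is_last, stm_ovulatory_flag = stm_flag,
            breastfeeding = breastfeeding, perimenopause = perimenopause)
}

# A well-behaved 28-day kindara-style cycle: 5 bleeding days, 12 BBT days
# covering both phases, mucus around ovulation.
standard_kindara_cycle <- function(length_days = 28, cycle_index = 2,
                                   is_last = FALSE) {
  temps <- rep(NA_real_, length_days)
  bbt_days <- c(5, 7, 9, 11, 13, 15, 17, 19, 21, 23, 25, 27)
  temps[bbt_days] <- 36.4 + ifelse(bbt_days > 16, 0.36, 0)
  bleeding <- rep(NA_character_, length_days)
  bleeding[1:5] <- c("heavy", "heavy", "medium", "light", "spotting")
  mucus <- rep(NA_character_, length_days)
  mq <- rep(NA_character_, length_days)
  mucus[13:16] <- "eggwhite"; mq[13:16] <- "lots"
  make_cycle(length_days, temps = temps, bleeding = bleeding, mucus = mucus,
             mucus_quantity = mq, times = rep(390, length_days),
             cycle_index = cycle_index, is_last = is_last, dialect = "kindara")
}

# ---- brute-force HMM oracle ------------------------------------------------

# Enumerate every positive-probability state sequence of length n and return
# exact Viterbi argmax (first in lexicographic state-order on ties), per-day
# marginals, and total likelihood. Exponential; only for n <= 9.
brute_force_decode <- function(cycle, spec) {
  ll <- exp_safe_loglik(cycle, spec)
  n <- nrow(ll)
  K <- length(spec$states)
  paths <- list()
  probs <- numeric()
  recurse <- function(prefix, logp) {
    t <- length(prefix) + 1
    if (t > n) {
      paths[[length(paths) + 1]] <<- prefix
      probs[length(probs) + 1] <<- logp
      return(invisible())
    }
    if (t == 1) {
      for (k in seq_len(K)) {
        if (spec$initial[k] > 0 && is.finite(ll[1, k])) {
          recurse(k, log(spec$initial[k]) + ll[1, k])
        }
      }
    } else {
      prev <- prefix[t - 1]
      for (k in seq_len(K)) {
        if (spec$transition[prev, k] > 0 && is.finite(ll[t, k])) {
          recurse(c(prefix, k), logp + log(spec$transition[prev, k]) + ll[t, k])
        }
      }
    }
  }
  recurse(integer(0), 0)
  stopifnot(length(paths) > 0)
  w <- exp(probs - max(probs))
  best <- which.max(probs)  # lexicographic-first tie handling matches viterbi
  marg <- matrix(0, n, K, dimnames = list(NULL, spec$states))
  for (i in seq_along(paths)) {
    for (t in seq_len(n)) marg[t, paths[[i]][t]] <- marg[t, paths[[i]][t]] + w[i]
  }
  marg <- marg / rowSums(marg)
  list(viterbi = spec$states[paths[[best]]],
       log_likelihood = probs[best],
       posterior = marg)
}

# per-day log-likelihood matrix via the package's public single-day function,
# so the oracle shares only the emission definition, not the decoding path
exp_safe_loglik <- function(cycle, spec) {
  feats <- cyclehmm:::cycle_features(cycle)
  t(vapply(seq_len(nrow(feats)), function(i) day_log_likelihood(feats[i, ], spec),
           numeric(length(spec$states))))
}

# Random short cycle with a mix of present/absent features, for oracle checks.
random_short_cycle <- function(n_days) {
  temps <- ifelse(stats::runif(n_days) < 0.7,
                  round(stats::runif(n_days, 36.2, 37.0), 2), NA_real_)
  bl <- ifelse(stats::runif(n_days) < 0.3,
               sample(c("none", "spotting", "light", "medium", "heavy"), n_days,
                      replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.15, 0.15)),
               NA_character_)
  mu <- ifelse(stats::runif(n_days) < 0.4,
               sample(c("none", "sticky", "creamy", "eggwhite", "watery"), n_days,
                      replace = TRUE),
               NA_character_)
  mq <- ifelse(!is.na(mu) & mu != "none",
               sample(c("little", "medium", "lots"), n_days, replace = TRUE),
               NA_character_)
  make_cycle(n_days, temps = temps, bleeding = bl, mucus = mu, mucus_quantity = mq)
}
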