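# Ten-state hidden Markov model of the hormonal events of an ovulatory
# menstrual cycle, with log-space Viterbi and forward-backward decoding under
# arbitrary per-day missingness.

#' The ten menstrual HMM states, in chain order
#'
#' `HM` onset of menses with heavy/medium flow; `LM` light bleeding or
#' spotting concluding menstruation; `LE` low estrogen; `HE` high estrogen;
#' `Ovu` ovulation (a one-day state); `Rise` the progesterone-driven BBT rise;
#' `HP` high progesterone; `EP` the luteal estrogen peak; `LP` low
#' progesterone; `End` an artificial absorbing end-of-cycle state.
#'
#' @return Character vector of length 10.
#' @export
hmm_states <- function() c("HM", "LM", "LE", "HE", "Ovu", "Rise", "HP", "EP", "LP", "End")

# Features the model emits, with their category levels (bbt is Gaussian on
# the cycle-relative temperature delta-BBT).
.hmm_cat_features <- function() {
  list(
    bleeding = fam_categories()$bleeding,
    mucus_grade = c("none", "low", "high"),
    cervix_openness = fam_categories()$cervix_openness,
    vaginal_sensation = fam_categories()$vaginal_sensation
  )
}

#' Default menstrual HMM parameterization
#'
#' Transitions are quasi-uniform: from each state the non-self mass is spread
#' over the allowed forward moves (the chain order of [hmm_states()], with
#' small-probability skips of LM and EP), and self-loop masses are set so the
#' geometric dwell times match typical phase durations (HM ~3 d, LM ~2 d,
#' LE ~5 d, HE ~4 d, Rise ~2 d, HP ~6 d, EP ~2 d, LP ~4 d). `Ovu` has zero
#' self-transition so the ovulation day is a single, well-defined day; `End`
#' is absorbing and reachable only from EP/LP.
#'
#' Emissions encode the expected body-sign patterns: delta-BBT centred at 0
#' before ovulation and at about +0.36 degC under progesterone (intermediate
#' in `Rise`); heavy/medium bleeding only in `HM`, spotting/light in `LM` and
#' weakly late in the luteal phase; high-fertility mucus concentrated in `HE`
#' and `Ovu`. Every operation takes the spec explicitly, so alternative
#' parameterizations can be substituted (see [read_hmm_spec()]).
#'
#' @param dialect Cycle-start convention: `"sympto"` cycles start on the first
#'   heavy-bleeding day by app rule, so the initial distribution puts all mass
#'   on `HM`; `"kindara"`/`"canonical"` starts are self-assessed and spread
#'   mass over `HM`/`LM`.
#' @return An object of class `hmm_spec`.
#' @export
default_hmm_spec <- function(dialect = c("canonical", "kindara", "sympto")) {
  dialect <- match.arg(dialect)
  st <- hmm_states()
  K <- length(st)
  Tm <- matrix(0, K, K, dimnames = list(st, st))
  # self-loop p gives geometric mean dwell 1/(1-p)
  Tm["HM", c("HM", "LM", "LE")]   <- c(2 / 3, 0.30, 1 / 30)
  Tm["LM", c("LM", "LE")]         <- c(0.5, 0.5)
  Tm["LE", c("LE", "HE")]         <- c(0.8, 0.2)
  Tm["HE", c("HE", "Ovu")]        <- c(0.75, 0.25)
  Tm["Ovu", "Rise"]               <- 1
  Tm["Rise", c("Rise", "HP")]     <- c(0.5, 0.5)
  Tm["HP", c("HP", "EP", "LP")]   <- c(5 / 6, 0.125, 1 / 24)
  Tm["EP", c("EP", "LP", "End")]  <- c(0.5, 0.45, 0.05)
  Tm["LP", c("LP", "End")]        <- c(0.75, 0.25)
  Tm["End", "End"]                <- 1

  init <- stats::setNames(rep(0, K), st)
  if (dialect == "sympto") init["HM"] <- 1 else init[c("HM", "LM")] <- c(0.9, 0.1)

  emis <- list(
    bbt = list(
      mean = stats::setNames(c(0, 0, 0, 0, 0, 0.18, 0.36, 0.36, 0.32, 0.15), st),
      sd   = stats::setNames(c(rep(0.15, 5), 0.20, 0.15, 0.15, 0.15, 0.25), st)
    ),
    bleeding = .emission_table(st, fam_categories()$bleeding, rbind(
      HM   = c(0.02, 0.02, 0.06, 0.45, 0.45),
      LM   = c(0.10, 0.45, 0.40, 0.05, 0.00),
      LE   = c(0.96, 0.03, 0.01, 0.00, 0.00),
      HE   = c(0.98, 0.02, 0.00, 0.00, 0.00),
      Ovu  = c(0.97, 0.03, 0.00, 0.00, 0.00),
      Rise = c(0.98, 0.02, 0.00, 0.00, 0.00),
      HP   = c(0.98, 0.02, 0.00, 0.00, 0.00),
      EP   = c(0.97, 0.03, 0.00, 0.00, 0.00),
      LP   = c(0.88, 0.08, 0.04, 0.00, 0.00),
      End  = c(0.85, 0.10, 0.05, 0.00, 0.00)
    )),
    mucus_grade = .emission_table(st, c("none", "low", "high"), rbind(
      HM   = c(0.90, 0.08, 0.02),
      LM   = c(0.85, 0.13, 0.02),
      LE   = c(0.60, 0.35, 0.05),
      HE   = c(0.15, 0.35, 0.50),
      Ovu  = c(0.15, 0.35, 0.50),
      Rise = c(0.50, 0.40, 0.10),
      HP   = c(0.75, 0.22, 0.03),
      EP   = c(0.55, 0.35, 0.10),
      LP   = c(0.85, 0.13, 0.02),
      End  = c(0.85, 0.13, 0.02)
    )),
    cervix_openness = .emission_table(st, fam_categories()$cervix_openness, rbind(
      HM   = c(0.80, 0.15, 0.05),
      LM   = c(0.80, 0.15, 0.05),
      LE   = c(0.70, 0.25, 0.05),
      HE   = c(0.15, 0.35, 0.50),
      Ovu  = c(0.10, 0.30, 0.60),
      Rise = c(0.50, 0.35, 0.15),
      HP   = c(0.75, 0.20, 0.05),
      EP   = c(0.70, 0.23, 0.07),
      LP   = c(0.75, 0.20, 0.05),
      End  = c(0.75, 0.20, 0.05)
    )),
    vaginal_sensation = .emission_table(st, fam_categories()$vaginal_sensation, rbind(
      HM   = c(0.25, 0.25, 0.35, 0.15),
      LM   = c(0.40, 0.30, 0.25, 0.05),
      LE   = c(0.50, 0.30, 0.18, 0.02),
      HE   = c(0.10, 0.10, 0.40, 0.40),
      Ovu  = c(0.08, 0.07, 0.35, 0.50),
      Rise = c(0.30, 0.30, 0.30, 0.10),
      HP   = c(0.45, 0.30, 0.20, 0.05),
      EP   = c(0.35, 0.30, 0.25, 0.10),
      LP   = c(0.45, 0.30, 0.20, 0.05),
      End  = c(0.45, 0.30, 0.20, 0.05)
    ))
  )
  spec <- structure(
    list(states = st, initial = init, transition = Tm, emissions = emis),
    class = "hmm_spec"
  )
  validate_hmm_spec(spec)
  spec
}

.emission_table <- function(states, levels, mat) {
  dimnames(mat) <- list(states, levels)
  mat
}

#' Validate an HMM specification
#'
#' Checks the structural invariants: rows of the transition matrix and of
#' every categorical emission table sum to 1; only forward moves along the
#' state order (plus self-loops) carry mass; `Ovu` has zero self-transition;
#' `End` is absorbing with entry only from `EP`/`LP`; Gaussian sds are
#' positive; the initial distribution sums to 1.
#'
#' @param spec An `hmm_spec`.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_hmm_spec <- function(spec) {
  st <- spec$states
  K <- length(st)
  Tm <- spec$transition
  stopifnot(identical(dim(Tm), c(K, K)))
  if (any(abs(rowSums(Tm) - 1) > 1e-9)) stop("transition rows must sum to 1")
  lower <- row(Tm) > col(Tm)
  if (any(Tm[lower] != 0)) stop("backward transitions are not allowed")
  if (Tm["Ovu", "Ovu"] != 0) stop("Ovu must be a one-day state (zero self-transition)")
  if (Tm["End", "End"] != 1) stop("End must be absorbing")
  into_end <- Tm[, "End"]
  if (any(into_end[!st %in% c("EP", "LP", "End")] > 0)) {
    stop("End is reachable only from EP/LP")
  }
  if (abs(sum(spec$initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
  if (any(spec$emissions$bbt$sd <= 0)) stop("Gaussian emission sds must be positive")
  for (f in names(.hmm_cat_features())) {
    E <- spec$emissions[[f]]
    if (any(abs(rowSums(E) - 1) > 1e-9)) stop("emission rows for ", f, " must sum to 1")
    if (any(E < 0)) stop("negative emission mass for ", f)
  }
  invisible(spec)
}

# ---- emission likelihoods --------------------------------------------------

# Extract the per-day model features for a cycle: a tibble with one row per
# calendar day 1..length_days (unlogged days are all-NA rows; the chain still
# advances through them). delta_bbt uses the cycle's 25th-percentile reference
# temperature; questionable-flagged BBT values are excluded.
cycle_features <- function(cycle) {
  ref <- cycle_reference_temperature(cycle)
  d <- cycle$days
  full <- tibble::tibble(cycle_day = seq_len(cycle$length_days))
  d$bbt_clean <- ifelse(!is.na(d$bbt_questionable) & d$bbt_questionable,
                        NA_real_, d$bbt_value)
  d$delta_bbt <- if (is.na(ref)) NA_real_ else d$bbt_clean - ref
  d$mucus_grade <- mucus_fertility_grade(d$mucus, d$mucus_quantity)
  dplyr::left_join(
    full,
    d[, c("cycle_day", "delta_bbt", "bleeding", "mucus_grade",
          "cervix_openness", "vaginal_sensation")],
    by = "cycle_day"
  )
}

#' Log-likelihood of one day's observations under each state
#'
#' Sums, over the features present that day, the state-conditional log-density
#' (Gaussian, for delta-BBT) or log-mass (categorical). Absent features
#' contribute 0, i.e. are marginalized out under a missing-at-random reading,
#' so a fully unlogged day is likelihood-neutral for every state.
#'
#' @param obs A list or one-row data frame with any of `delta_bbt`,
#'   `bleeding`, `mucus_grade`, `cervix_openness`, `vaginal_sensation`.
#' @param spec An `hmm_spec`.
#' @return Named numeric vector of log-likelihoods, one per state (may be
#'   `-Inf` where an observed category has zero emission mass).
#' @export
day_log_likelihood <- function(obs, spec) {
  ll <- stats::setNames(rep(0, length(spec$states)), spec$states)
  if (!is.null(obs$delta_bbt) && !is.na(obs$delta_bbt)) {
    ll <- ll + stats::dnorm(obs$delta_bbt, spec$emissions$bbt$mean,
                            spec$emissions$bbt$sd, log = TRUE)
  }
  for (f in names(.hmm_cat_features())) {
    v <- obs[[f]]
    if (!is.null(v) && !is.na(v)) ll <- ll + log(spec$emissions[[f]][, v])
  }
  ll
}

# T x K matrix of per-day log-likelihoods for a whole cycle (vectorized
# equivalent of row-wise day_log_likelihood calls).
cycle_log_likelihoods <- function(cycle, spec) {
  feats <- cycle_features(cycle)
  n <- nrow(feats)
  K <- length(spec$states)
  ll <- matrix(0, n, K, dimnames = list(NULL, spec$states))
  db <- feats$delta_bbt
  ok <- which(!is.na(db))
  if (length(ok) > 0) {
    mu <- spec$emissions$bbt$mean
    sdv <- spec$emissions$bbt$sd
    ll[ok, ] <- ll[ok, ] + t(vapply(db[ok],
                                    function(x) stats::dnorm(x, mu, sdv, log = TRUE),
                                    numeric(K)))
  }
  for (f in names(.hmm_cat_features())) {
    v <- feats[[f]]
    ok <- which(!is.na(v))
    if (length(ok) > 0) {
      ll[ok, ] <- ll[ok, ] + t(log(spec$emissions[[f]][, v[ok], drop = FALSE]))
    }
  }
  ll
}

.log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# ---- decoding --------------------------------------------------------------

#' Viterbi decoding of a cycle
#'
#' Most probable state sequence given the observations, computed in log space
#' (no underflow for cycles of at least 120 days). Ties are broken toward the
#' earlier state in chain order.
#'
#' @param cycle A `fam_cycle`.
#' @param spec An `hmm_spec`.
#' @param loglik Optional precomputed per-day log-likelihood matrix (as from
#'   the internal feature extraction); supplied by [decode_cycle()].
#' @return List with `path` (character state per day) and `log_likelihood`
#'   (joint log-probability of the best path and the observations).
#' @export
viterbi <- function(cycle, spec, loglik = NULL) {
  if (is.null(loglik)) loglik <- cycle_log_likelihoods(cycle, spec)
  n <- nrow(loglik)
  K <- length(spec$states)
  stopifnot(n >= 1)
  logT <- log(spec$transition)
  delta <- matrix(-Inf, n, K)
  back <- matrix(NA_integer_, n, K)
  delta[1, ] <- log(spec$initial) + loglik[1, ]
  if (n > 1) {
    for (t in 2:n) {
      cand <- delta[t - 1, ] + logT          # [from, to]
      j <- max.col(t(cand), ties.method = "first")  # ties -> earlier state
      delta[t, ] <- cand[cbind(j, seq_len(K))] + loglik[t, ]
      back[t, ] <- j
    }
  }
  if (all(!is.finite(delta[n, ]))) stop("cycle inconsistent with model")
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  list(path = spec$states[path], log_likelihood = max(delta[n, ]))
}

#' Forward-backward posterior decoding of a cycle
#'
#' Per-day marginal posterior over the ten states, each day normalized to 1,
#' computed in log space.
#'
#' @inheritParams viterbi
#' @return A days x states matrix of posterior probabilities.
#' @export
forward_backward <- function(cycle, spec, loglik = NULL) {
  if (is.null(loglik)) loglik <- cycle_log_likelihoods(cycle, spec)
  n <- nrow(loglik)
  K <- length(spec$states)
  stopifnot(n >= 1)
  Tm <- spec$transition
  # scaled (normalized) forward/backward recursions: numerically equivalent
  # to log-space, O(n K^2) in plain matrix arithmetic
  b <- matrix(0, n, K)
  for (t in seq_len(n)) {
    m <- max(loglik[t, ])
    if (!is.finite(m)) stop("cycle inconsistent with model")
    b[t, ] <- exp(loglik[t, ] - m)
  }
  alpha <- matrix(0, n, K)
  a <- spec$initial * b[1, ]
  z <- sum(a)
  if (z <= 0) stop("cycle inconsistent with model")
  alpha[1, ] <- a / z
  if (n > 1) {
    for (t in 2:n) {
      a <- as.vector(alpha[t - 1, ] %*% Tm) * b[t, ]
      z <- sum(a)
      if (z <= 0) stop("cycle inconsistent with model")
      alpha[t, ] <- a / z
    }
  }
  beta <- matrix(1, n, K)
  if (n > 1) {
    for (t in (n - 1):1) {
      v <- as.vector(Tm %*% (b[t + 1, ] * beta[t + 1, ]))
      s <- sum(v)
      if (s > 0) v <- v / s
      beta[t, ] <- v
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  dimnames(post) <- list(NULL, spec$states)
  post
}

#' Decode one cycle: Viterbi path plus per-day posteriors
#'
#' @inheritParams viterbi
#' @return An object of class `decoded_cycle`: `user_id`, `cycle_index`,
#'   `viterbi_path`, `log_likelihood`, `posterior` (days x states, rows sum
#'   to 1).
#' @export
decode_cycle <- function(cycle, spec) {
  ll <- cycle_log_likelihoods(cycle, spec)
  vit <- viterbi(cycle, spec, loglik = ll)
  post <- forward_backward(cycle, spec, loglik = ll)
  structure(
    list(
      user_id = cycle$user_id, cycle_index = cycle$cycle_index,
      viterbi_path = vit$path, log_likelihood = vit$log_likelihood,
      posterior = post
    ),
    class = "decoded_cycle"
  )
}

#' Decode a list of cycles
#'
#' @param cycles List of `fam_cycle`.
#' @param spec An `hmm_spec`.
#' @return List of `decoded_cycle`, same order as `cycles`.
#' @export
decode_cycles <- function(cycles, spec) lapply(cycles, decode_cycle, spec = spec)

#' Randomly perturb the transition probabilities of a spec
#'
#' Multiplies each allowed non-self transition mass by an independent factor
#' drawn uniformly in `range` and renormalizes every row; used to probe
#' robustness of ovulation estimates to the quasi-uniform transition choice.
#' Uses the current RNG state.
#'
#' @param spec An `hmm_spec`.
#' @param range Length-2 numeric, the multiplicative factor range.
#' @return A perturbed `hmm_spec` (still passing [validate_hmm_spec()]).
#' @export
perturb_transitions <- function(spec, range = c(0.5, 2)) {
  Tm <- spec$transition
  nonself <- Tm > 0 & row(Tm) != col(Tm)
  Tm[nonself] <- Tm[nonself] * stats::runif(sum(nonself), range[1], range[2])
  Tm <- Tm / rowSums(Tm)
  spec$transition <- Tm
  validate_hmm_spec(spec)
  spec
}

# ---- spec serialization ----------------------------------------------------

#' Write / read an HMM specification as a YAML file
#'
#' Human-readable serialization so users can edit or substitute their own
#' emission and transition tables. Only nonzero transitions are written.
#'
#' @param spec An `hmm_spec`.
#' @param path File path.
#' @return `write_hmm_spec()`: `path` invisibly; `read_hmm_spec()`: an
#'   `hmm_spec`.
#' @export
write_hmm_spec <- function(spec, path) {
  st <- spec$states
  trans <- list()
  for (a in st) for (b in st) {
    if (spec$transition[a, b] > 0) {
      trans[[paste(a, b, sep = "->")]] <- spec$transition[a, b]
    }
  }
  obj <- list(
    states = st,
    initial = as.list(spec$initial[spec$initial > 0]),
    transitions = trans,
    emissions = c(
      list(bbt = list(mean = as.list(spec$emissions$bbt$mean),
                      sd = as.list(spec$emissions$bbt$sd))),
      lapply(.hmm_cat_features(), function(lv) NULL)  # placeholder, filled below
    )
  )
  for (f in names(.hmm_cat_features())) {
    E <- spec$emissions[[f]]
    obj$emissions[[f]] <- stats::setNames(
      lapply(st, function(s) as.list(E[s, ])), st)
  }
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname write_hmm_spec
#' @export
read_hmm_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  st <- unlist(obj$states)
  K <- length(st)
  Tm <- matrix(0, K, K, dimnames = list(st, st))
  for (key in names(obj$transitions)) {
    ab <- strsplit(key, "->", fixed = TRUE)[[1]]
    Tm[ab[1], ab[2]] <- obj$transitions[[key]]
  }
  init <- stats::setNames(rep(0, K), st)
  init[names(obj$initial)] <- unlist(obj$initial)
  emis <- list(bbt = list(
    mean = unlist(obj$emissions$bbt$mean)[st],
    sd = unlist(obj$emissions$bbt$sd)[st]
  ))
  for (f in names(.hmm_cat_features())) {
    lv <- .hmm_cat_features()[[f]]
    E <- t(vapply(st, function(s) unlist(obj$emissions[[f]][[s]])[lv], numeric(length(lv))))
    dimnames(E) <- list(st, lv)
    emis[[f]] <- E
  }
  spec <- structure(
    list(states = st, initial = init, transition = Tm, emissions = emis),
    class = "hmm_spec"
  )
  validate_hmm_spec(spec)
  spec
}
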