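spec_default <- default_hmm_spec("canonical")

test_that("default specs satisfy the structural invariants", {
  for (d in c("canonical", "kindara", "sympto")) {
    spec <- default_hmm_spec(d)
    expect_silent(validate_hmm_spec(spec))
    expect_equal(spec$transition["Ovu", "Ovu"], 0)
    expect_equal(spec$transition["End", "End"], 1)
    # forbidden observations under the default tables
    expect_equal(spec$emissions$bleeding["HP", "heavy"], 0)
    expect_equal(spec$emissions$bleeding["HE", "medium"], 0)
  }
  expect_equal(default_hmm_spec("sympto")$initial[["HM"]], 1)
  bad <- spec_default
  bad$transition["LE", "HM"] <- bad$transition["LE", "LE"] <- 0.4
  expect_error(validate_hmm_spec(bad), "backward")
})

test_that("missing features are marginalized in the day likelihood", {
  ll <- day_log_likelihood(list(), spec_default)
  expect_equal(unname(ll), rep(0, 10))
  # delta-BBT at a state's mean attains that state's Gaussian mode
  m <- spec_default$emissions$bbt$mean[["HP"]]
  ll2 <- day_log_likelihood(list(delta_bbt = m), spec_default)
  expect_equal(ll2[["HP"]],
               dnorm(m, m, spec_default$emissions$bbt$sd[["HP"]], log = TRUE))
  # zero-mass category gives -Inf
  ll3 <- day_log_likelihood(list(bleeding = "heavy"), spec_default)
  expect_true(is.infinite(ll3[["HP"]]) && ll3[["HP"]] < 0)
  expect_true(is.finite(ll3[["HM"]]))
})

test_that("a one-day heavy-bleeding cycle decodes to HM", {
  bl <- "heavy"
  cy <- make_cycle(1, bleeding = bl)
  v <- viterbi(cy, spec_default)
  expect_equal(v$path, "HM")
  post <- forward_backward(cy, spec_default)
  expect_equal(unname(post[1, "HM"]), 1)
})

test_that("viterbi and forward-backward match exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:9, 1)
    cy <- random_short_cycle(n)
    bf <- brute_force_decode(cy, spec_default)
    v <- viterbi(cy, spec_default)
    expect_equal(v$path, bf$viterbi)
    expect_equal(v$log_likelihood, bf$log_likelihood, tolerance = 1e-9)
    post <- forward_backward(cy, spec_default)
    expect_lt(max(abs(post - bf$posterior)), 1e-9)
  }
})

test_that("posterior rows sum to one and an empty cycle gives prior marginals", {
  cy <- make_cycle(12)  # no observations at all
  post <- forward_backward(cy, spec_default)
  expect_equal(rowSums(post), rep(1, 12), tolerance = 1e-9)
  marg <- spec_default$initial
  for (t in 1:12) {
    expect_equal(unname(post[t, ]), unname(marg), tolerance = 1e-9)
    marg <- as.vector(marg %*% spec_default$transition)
  }
})

test_that("log-space decoding survives 120-day cycles", {
  temps <- rep(NA_real_, 120)
  temps[seq(1, 120, by = 2)] <- 36.4 + c(rep(0, 30), rep(0.36, 30))
  cy <- make_cycle(120, temps = temps)
  v <- viterbi(cy, spec_default)
  expect_true(is.finite(v$log_likelihood))
  post <- forward_backward(cy, spec_default)
  expect_equal(rowSums(post), rep(1, 120), tolerance = 1e-9)
})

test_that("an observation sequence with no positive-probability path errors", {
  # heavy bleeding is only emitted by HM, and HM is unreachable after Ovu-side
  # states; heavy on day 1 and day 20 with a sustained shift in between cannot
  # be explained by the forward-only chain... but a long HM dwell can explain
  # two early heavies. Force impossibility with heavy under sympto-start on a
  # day after the chain must have left HM: heavy bleeding cannot recur once
  # the path has passed Ovu, so pin Ovu via a one-day cycle trick instead.
  cy <- make_cycle(2, bleeding = c(NA, "heavy"))
  # day 2 heavy is still reachable (HM self-loop), so this decodes fine
  expect_silent(viterbi(cy, spec_default))
  # truly impossible: an all -Inf day (zero-mass category for every state
  # cannot be built from the default tables, so check the error path directly)
  spec <- spec_default
  spec$emissions$bleeding[, "heavy"] <- 0
  spec$emissions$bleeding <- spec$emissions$bleeding /
    rowSums(spec$emissions$bleeding)
  cy2 <- make_cycle(3, bleeding = c(NA, "heavy", NA))
  expect_error(viterbi(cy2, spec), "inconsistent with model")
  expect_error(forward_backward(cy2, spec), "inconsistent with model")
})

test_that("noiseless full-logging cycles recover true phase boundaries", {
  cfg <- synthetic_config(
    n_users = 6, bbt_noise_sd_c = 0.02, terminal_spotting_prob = 0,
    mucus_misreport_prob = 0,
    logging = stats::setNames(lapply(1:3, function(.)
      c(bbt = 1, mucus = 1, bleeding = 1, cervix = 0, sensation = 0, sex = 0.2)),
      c("conception", "contraception", "observation")),
    rng_seed = 11
  )
  coh <- generate_cycles(cfg, "canonical")
  for (i in seq_along(coh$cycles)) {
    dec <- decode_cycle(coh$cycles[[i]], spec_default)
    true_ovu <- coh$truths[[i]]$ovulation_day
    # Viterbi ovulation boundary within a day of truth
    vit_ovu <- which(dec$viterbi_path == "Ovu")
    expect_equal(length(vit_ovu), 1)
    expect_lte(abs(vit_ovu - true_ovu), 1)
    # posterior argmax may smear slightly where mucus is ambiguous
    est <- estimate_ovulation_day(dec$posterior)
    expect_lte(abs(est - true_ovu), 2)
  }
})

test_that("spec YAML serialization round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_hmm_spec(spec_default, path)
  back <- read_hmm_spec(path)
  expect_equal(back$states, spec_default$states)
  expect_equal(back$initial, spec_default$initial, tolerance = 1e-9)
  expect_equal(back$transition, spec_default$transition, tolerance = 1e-9)
  for (f in names(spec_default$emissions)) {
    expect_equal(back$emissions[[f]], spec_default$emissions[[f]], tolerance = 1e-9)
  }
})

test_that("transition perturbation keeps the spec valid", {
  set.seed(5)
  pert <- perturb_transitions(spec_default)
  expect_silent(validate_hmm_spec(pert))
  expect_false(identical(pert$transition, spec_default$transition))
  # zero entries stay zero
  expect_true(all((spec_default$transition == 0) == (pert$transition == 0)))
})
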