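# Shared synthetic cohorts for the heavier distribution-level tests,
# memoised so several test blocks can reuse one generation + decoding pass.

.cohort_cache <- new.env(parent = emptyenv())

# 500 default-config cycles (first 500 of an 80-user cohort, seed 101),
# decoded and gated with the default canonical spec.
default_cohort_500 <- function() {
  if (!is.null(.cohort_cache$c500)) return(.cohort_cache$c500)
  coh <- generate_cycles(synthetic_config(n_users = 80, rng_seed = 101), "canonical")
  stopifnot(length(coh$cycles) >= 500)
  cycles <- coh$cycles[1:500]
  truths <- coh$truths[1:500]
  spec <- default_hmm_spec("canonical")
  decoded <- decode_cycles(cycles, spec)
  estimates <- estimate_cycles(cycles, decoded)
  .cohort_cache$c500 <- list(
    cycles = cycles, truths = truths, spec = spec,
    decoded = decoded, estimates = estimates,
    truth_ovulation = vapply(truths, function(tr) as.integer(tr$ovulation_day), 0L)
  )
  .cohort_cache$c500
}

# Mask a fraction of one logged signal across a cycle's days (dropping day
# rows that become empty), for missing-data sensitivity experiments.
mask_signal <- function(cycle, signal = c("bbt", "mucus"), frac = 0.5, seed = 1) {
  signal <- match.arg(signal)
  fields <- switch(signal,
    bbt = c("bbt_value", "bbt_time_minutes", "bbt_questionable"),
    mucus = c("mucus", "mucus_quantity")
  )
  set.seed(seed)
  d <- cycle$days
  has <- which(!is.na(d[[fields[1]]]))
  drop <- sample(has, floor(length(has) * frac))
  for (f in fields) d[[f]][drop] <- NA
  keep <- rowSums(!is.na(d[, setdiff(names(d), "cycle_day")])) > 0
  cycle$days <- d[keep, , drop = FALSE]
  cycle
}
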