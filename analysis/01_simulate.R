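#!/usr/bin/env Rscript
# Stage 1: simulate a sympto-thermal self-tracking cohort with known ground
# truth. The generator's defaults encode the study conditions this analysis
# assumes: lognormal follicular lengths (median 16 d), luteal lengths with
# median 12-13 d and a short-luteal tail, a ~0.36 degC post-ovulatory BBT
# shift under 0.15 degC measurement noise, and goal-dependent logging gaps.
suppressMessages(library(cyclehmm))

out <- "results/synthetic"
cfg <- synthetic_config(n_users = 120, rng_seed = 20)

message("Simulating ", cfg$n_users, " users (seed ", cfg$rng_seed, ") ...")
cohort <- generate_cycles(cfg, dialect = "canonical")
write_synthetic_cohort(cohort, out, dialect = "canonical")

tt <- truth_phase_table(cohort$truths)
message("Generated ", length(cohort$cycles), " cycles; true follicular median ",
        median(tt$follicular), " d, luteal median ", median(tt$luteal),
        " d, ", round(100 * mean(tt$luteal <= 10), 1), "% short luteal (<=10 d).")

# the same cohort in the Kindara column dialect, to exercise dialect IO
write_cycles(generate_cycles(cfg, dialect = "kindara")$cycles,
             file.path(out, "cycles_kindara.csv"), "kindara")
message("Wrote ", out, "/cycles.csv (+ kindara dialect copy, truth tables, users).")
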