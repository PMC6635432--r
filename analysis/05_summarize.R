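#!/usr/bin/env Rscript
# Stage 5: cohort-level summaries. (i) The selection-stage count table for
# the synthetic cohort, and the same derivation applied to the published
# per-app counts of the two real datasets. (ii) Phase-duration summaries
# over reliable cycles. (iii) Ovulation-aligned mean state probabilities.
suppressMessages(library(cyclehmm))
suppressMessages(library(ggplot2))

cycles <- read_cycles("results/synthetic/cycles.csv", "canonical")
report <- filter_report(cycles)
std <- cycles[report$standard]
spec <- default_hmm_spec("canonical")
decoded <- decode_cycles(std, spec)
estimates <- readr::read_csv("results/estimates.csv", show_col_types = FALSE)
estimates$reasons[is.na(estimates$reasons)] <- ""

dir.create("results/summaries", showWarnings = FALSE, recursive = TRUE)

tab <- cohort_table(cohort_counts(cycles, report, estimates))
readr::write_csv(tab, "results/summaries/cohort_table_synthetic.csv", na = "")
pub <- cohort_table(published_cohort_counts())
readr::write_csv(pub, "results/summaries/cohort_table_published.csv", na = "")
message("Published-count cross-check: total ", pub$n_users[pub$app == "Total" &
        pub$stage == "full"], " users, ",
        pub$avg_cycles_per_user[pub$app == "Total" & pub$stage == "full"],
        " cycles/user; sympto standard-user retention ",
        pub$pct_users[pub$app == "sympto" & pub$stage == "standard"], "%.")

ph <- phase_summary(estimates)
readr::write_csv(ph$durations, "results/summaries/phase_durations.csv", na = "")
message("Reliable cycles: ", ph$n,
        "; medians (d) - cycle ", ph$medians[["cycle_length"]],
        ", follicular ", ph$medians[["follicular"]],
        ", luteal ", ph$medians[["luteal"]], ".")
message("Ovulation on days 14-15: ",
        round(100 * ph$fractions[["ovulation_day_14_15"]], 1),
        "%; luteal <= 10 d: ", round(100 * ph$fractions[["luteal_le_10"]], 1),
        "%; luteal 12-13 d: ", round(100 * ph$fractions[["luteal_12_13"]], 1), "%.")

aligned <- ovulation_aligned_profiles(decoded, estimates)
readr::write_csv(aligned, "results/summaries/ovulation_aligned_profiles.csv", na = "")

common <- aligned |>
  dplyr::group_by(day_from_ovulation, state) |>
  dplyr::summarise(p = stats::weighted.mean(mean_probability, n_cycles),
                   .groups = "drop") |>
  dplyr::filter(day_from_ovulation >= -20, day_from_ovulation <= 15)
common$state <- factor(common$state, levels = hmm_states())
p <- ggplot(common, aes(day_from_ovulation, p, fill = state)) +
  geom_area(position = "stack") +
  labs(x = "day from estimated ovulation", y = "mean state probability",
       title = "Ovulation-aligned menstrual state probabilities") +
  theme_minimal()
ggsave("results/summaries/ovulation_aligned_states.png", p,
       width = 7, height = 4, dpi = 150)
message("Wrote results/summaries/.")
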