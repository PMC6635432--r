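#!/usr/bin/env Rscript
# Stage 2: apply the standard-cycle selection criteria (finished cycles of
# regular users, gaps <= 15 d, at least one FAM body sign, no mid-cycle
# period-like bleeding in long cycles) and report the selection flowchart.
suppressMessages(library(cyclehmm))

cycles <- read_cycles("results/synthetic/cycles.csv", "canonical")
report <- filter_report(cycles)
readr::write_csv(report, "results/filter_report.csv", na = "")

n_std <- sum(report$standard)
message(length(cycles), " cycles in; ", n_std, " standard (",
        round(100 * n_std / length(cycles)), "%).")
message("Cycles failing each criterion:")
print(attr(report, "criterion_counts"))
message("Median tracking frequency among standard cycles: ",
        round(100 * median(report$tracking_frequency[report$standard])), "%; ",
        round(100 * mean(report$any_sex[report$standard])),
        "% logged sexual intercourse.")
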