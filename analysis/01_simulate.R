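#!/usr/bin/env Rscript
# Simulate a DESTINY-Breast03-like two-arm cohort with known kinetic ground
# truth: 232 control (T-DM1-like) vs 245 experimental (T-DXd-like)
# subjects, 6-weekly (+/- 7 day) scans until RECIST-style progression or
# database lock, multiplicative 5% measurement noise, and OS/PFS hazards
# that increase with the subject's true growth rate.
#
# Writes results/measurements.csv (long scan table) and
# results/subjects.csv (per-subject survival + ground truth).

suppressPackageStartupMessages(library(gscore))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1

scenario <- sim_scenario()
cohort <- simulate_cohort(scenario, seed = seed)

dir.create("results", showWarnings = FALSE)
utils::write.csv(cohort$measurements, "results/measurements.csv",
                 row.names = FALSE)
utils::write.csv(cohort$subjects, "results/subjects.csv", row.names = FALSE)

m <- cohort$measurements
s <- cohort$subjects
scans <- tapply(m$day, m$subject_id, length) - 1
cat(sprintf("Simulated %d subjects (%s) with seed %d\n",
            nrow(s), paste(names(scenario$n_per_arm), scenario$n_per_arm,
                           sep = "=", collapse = ", "), seed))
cat(sprintf("Post-baseline scans per subject: median %d (range %d-%d)\n",
            as.integer(stats::median(scans)), min(scans), max(scans)))
cat(sprintf("True model classes: %s\n",
            paste(names(table(s$true_model)), table(s$true_model),
                  sep = "=", collapse = ", ")))
cat(sprintf("OS events: %d (%.0f%%); PFS events: %d (%.0f%%)\n",
            sum(s$os_event), 100 * mean(s$os_event),
            sum(s$pfs_event), 100 * mean(s$pfs_event)))
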