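#!/usr/bin/env Rscript

# Simulate a 40-participant synthetic cohort on the delayed-feedback task.
#
# The composition mirrors the broad heterogeneity such experiments report:
# a minority who learn the delayed contingency (and so hit the termination
# criterion), a group who perseverate on the never-rewarded option, groups
# with a superstitious E or F bias, unbiased choosers, and participants who
# learn only the immediate contingency. Archetype probabilities are
# stylized artifact parameters, not measured values.
#
# Writes results/cohort/<participant>.csv, labels.csv and a run manifest.

suppressPackageStartupMessages(library(delaycredit))

master_seed <- 20260928L
out_dir <- "results/cohort"

composition <- c(
  c_learner = 9, d_perseverator = 8,
  e_superstitious = 7, f_superstitious = 6,
  random_chooser = 5, immediate_only = 5
)

spec <- cohort_spec(composition, config = session_config(),
                    master_seed = master_seed)
cohort <- generate_cohort(spec)
write_cohort(cohort, out_dir)
write_run_manifest(file.path(out_dir, "manifest.json"), "cohort",
                   list(composition = as.list(composition),
                        config = unclass(spec$config)),
                   master_seed, cohort$labels$seed)

n_term <- sum(vapply(cohort$logs, `[[`, logical(1), "terminated_early"))
cat(sprintf("wrote %d sessions to %s\n", nrow(cohort$labels), out_dir))
cat(sprintf("%d participants hit the termination criterion\n", n_term))
print(table(cohort$labels$archetype))
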