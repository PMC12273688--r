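#!/usr/bin/env Rscript

# Figures from the grid and cohort outputs (run scripts 01-03 first):
#   - final-bin choice-count histograms per algorithm x preset
#   - (P_C, P_A) and (P_C, P_E) choice-rate scatters for the short- and
#     long-trace regimes, with the synthetic cohort's rates overlaid where
#     human rates would go
# Written as PDFs under results/figures/.

suppressPackageStartupMessages({
  library(delaycredit)
  library(ggplot2)
})

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
summaries <- utils::read.csv("results/grid_summaries.csv")

counts_long <- do.call(rbind, lapply(c("A", "C", "E"), function(x) {
  data.frame(algorithm = summaries$algorithm, preset = summaries$preset,
             stimulus = x, count = summaries[[paste0("count_", x)]])
}))
counts_long$preset <- factor(counts_long$preset,
                             c("slow_learning", "high_exploration",
                               "short_trace", "long_trace"))

p_hist <- ggplot(counts_long, aes(count, fill = stimulus)) +
  geom_histogram(binwidth = 1, position = "dodge") +
  facet_grid(algorithm ~ preset) +
  labs(x = "choices in final 10-trial bin", y = "runs",
       title = "Final-bin choice counts across 200 runs per cell") +
  theme_bw()
ggsave("results/figures/final_bin_histograms.pdf", p_hist,
       width = 11, height = 5)

# choice-rate scatters: simulation (trace regimes) + cohort overlay
cohort <- read_cohort("results/cohort")
cohort_rates <- do.call(rbind, lapply(cohort$logs, function(l) {
  as.data.frame(choice_rates(l))
}))
sc <- scatter_summary(summaries[summaries$preset %in%
                                  c("short_trace", "long_trace"), ],
                      cohort_rates)
sc$regime <- ifelse(sc$source == "human", "synthetic cohort", sc$preset)

p_pa <- ggplot(sc, aes(p_C, p_A, colour = regime, shape = source)) +
  geom_point(alpha = 0.6) +
  coord_cartesian(xlim = 0:1, ylim = 0:1) +
  labs(title = "End-of-session choice rates: delayed (C) vs immediate (A)") +
  theme_bw()
p_pe <- ggplot(sc, aes(p_C, p_E, colour = regime, shape = source)) +
  geom_point(alpha = 0.6) +
  coord_cartesian(xlim = 0:1, ylim = 0:1) +
  labs(title = "End-of-session choice rates: delayed (C) vs uncorrelated (E)") +
  theme_bw()
ggsave("results/figures/rates_pc_pa.pdf", p_pa, width = 7, height = 5)
ggsave("results/figures/rates_pc_pe.pdf", p_pe, width = 7, height = 5)

cat("wrote results/figures/{final_bin_histograms,rates_pc_pa,rates_pc_pe}.pdf\n")
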