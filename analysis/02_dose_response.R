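#!/usr/bin/env Rscript
# Dose-response recovery in standard medium: five 100-cell experiments per
# concentration (the published design), full pipeline from raw traces to
# per-dose mean +/- SEM and pooled amplitude histograms.

library(sperca)
dir.create("results", showWarnings = FALSE)

doses <- c("1pM", "1nM", "25uM", "50uM")
seed0 <- 100

all_cells <- list(); all_dose <- list()
for (i in seq_along(doses)) {
  r <- run_cohort_analysis(dde_preset(doses[i]), n_cells = 100,
                           n_experiments = 5, seed = seed0 + i)
  all_cells[[i]] <- r$cells
  all_dose[[i]] <- r$dose
}
dose_tab <- do.call(rbind, all_dose)
cells <- do.call(rbind, all_cells)

cat("Per-dose summary (mean +/- SEM over 5 experiments of 100 cells):\n")
print(transform(dose_tab,
                mean_percent_responsive = round(mean_percent_responsive, 1),
                sem_percent_responsive = round(sem_percent_responsive, 2),
                mean_amplitude = round(mean_amplitude, 1),
                sem_amplitude = round(sem_amplitude, 2)),
      row.names = FALSE)

hist_tab <- amplitude_histogram(cells)
cat("\nAmplitude distribution over responsive cells (% per bin):\n")
print(reshape(hist_tab, idvar = "dose_label", timevar = "bin",
              direction = "wide"), row.names = FALSE)

write.csv(dose_tab, "results/dose_response.csv", row.names = FALSE)
write.csv(hist_tab, "results/amplitude_histogram.csv", row.names = FALSE)
write.csv(cells, "results/dose_response_cells.csv", row.names = FALSE)
cat("\nWrote results/dose_response.csv, amplitude_histogram.csv,",
    "dose_response_cells.csv\n")
cat("Low doses concentrate in the (0,20] bin; 25/50 uM shift to (20,100]",
    "with occasional responses above 100%.\n")
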