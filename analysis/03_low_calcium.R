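#!/usr/bin/env Rscript
# Low-Ca2+ medium abolishes the 25 uM response: eight experiments per
# condition (the published Fig 3 design uses 500 cells over eight
# experiments; we use 8 x 100 cells) comparing standard and low-calcium
# presets at the same agonist dose.

library(sperca)
dir.create("results", showWarnings = FALSE)

std <- run_cohort_analysis(dde_preset("25uM"), n_cells = 100,
                           n_experiments = 8, seed = 200)
low <- run_cohort_analysis(dde_preset("25uM_lowCa"), n_cells = 100,
                           n_experiments = 8, seed = 201)

tab <- rbind(std$dose, low$dose)
cat("25 uM agonist, standard vs low-Ca2+ medium:\n")
print(transform(tab,
                mean_percent_responsive = round(mean_percent_responsive, 2),
                sem_percent_responsive = round(sem_percent_responsive, 2),
                mean_amplitude = round(mean_amplitude, 1)),
      row.names = FALSE)

# two-sample comparison of per-experiment responsive fractions
tt <- t.test(std$experiments$percent_responsive,
             low$experiments$percent_responsive)
cat(sprintf("\nWelch t-test, responsive %% standard vs low-Ca: p = %.2e\n",
            tt$p.value))

h <- amplitude_histogram(low$cells)
cat(sprintf("Responders remaining in low-Ca: %d of %d cells; %.1f%% fall in the (0,20] bin\n",
            sum(low$cells$responsive), nrow(low$cells),
            h$percent[h$bin == "(0,20]"]))
cat("Note: the detected prevalence in low-Ca sits at the classifier's\n",
    "false-positive floor; see the methods vignette for why the printed 2.0%\n",
    "cannot be reached exactly under per-cell alpha = 0.05.\n")

write.csv(tab, "results/low_calcium_comparison.csv", row.names = FALSE)
write.csv(h, "results/low_calcium_histogram.csv", row.names = FALSE)
cat("Wrote results/low_calcium_comparison.csv, low_calcium_histogram.csv\n")
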