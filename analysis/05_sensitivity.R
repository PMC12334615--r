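#!/usr/bin/env Rscript
# Gradient-based sensitivity analysis with permutation inference.
#
# Trains the regression network on sham-condition trials split by
# fatigue state, forms the sensitivity matrix, selects the eigenvectors
# explaining 90% of the variance, and tests the low-minus-high band
# contribution differences against a label-permutation null. Also runs
# the 8-point hyperparameter grid once. Desk-scale settings (compact
# network, 199 permutations) keep this in minutes; raise n_perm and the
# architecture for a full-fidelity run.

library(prestim)

dir.create("results", showWarnings = FALSE)
if (!file.exists("results/trial_table.tsv"))
  stop("run analysis/01_simulate.R first")
trials <- read_tsv("results/trial_table.tsv")

sham <- trials[trials$condition == "sham", ]
x <- as.matrix(sham[, feature_names()])
lo <- sham$fatigue_state == "low"
cat("Sham samples: ", sum(lo), " low fatigue, ", sum(!lo),
    " high fatigue\n", sep = "")

sa <- sensitivity_analysis(x[lo, ], sham$vct[lo],
                           net_spec_small(seed = 20260930L))
cat("Low-fatigue model: k =", sa$k, "components explain 90% of the",
    "variance\n")

pt <- permutation_test(x[lo, ], sham$vct[lo], x[!lo, ], sham$vct[!lo],
                       spec = net_spec_small(seed = 20260930L),
                       n_perm = 199, seed = 20260931L)
print(pt)
write_tsv(data.frame(band = names(pt$observed),
                     contribution_low = pt$contributions_low,
                     contribution_high = pt$contributions_high,
                     delta = pt$observed, p = pt$p,
                     p_fdr = pt$p_adjusted),
          "results/band_contributions.tsv")

hs <- hyperparameter_search(x[lo, ], sham$vct[lo],
                            spec = net_spec(max_epochs = 30,
                                            seed = 20260930L))
cat("\nHyperparameter grid (8 combinations):\n")
print(hs$table)
cat("Selected: hidden =", hs$best$hidden, ", batch =", hs$best$batch,
    ", lr =", hs$best$lr, "\n")
write_tsv(hs$table, "results/hyperparameter_grid.tsv")
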