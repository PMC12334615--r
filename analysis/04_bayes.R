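#!/usr/bin/env Rscript
# Hierarchical Bayesian analysis of the simulated experiment.
#
# Fits the fatigue x condition x block mixed models to the block-level
# outcomes of the dataset produced by 01_simulate.R (rerun it first if
# results/block_table.tsv is missing), extracts the final-block
# low-fatigue sham-minus-stimulation contrasts with the Pr/HPD
# decision rule, and runs the change-score mediation analysis.

library(prestim)

dir.create("results", showWarnings = FALSE)
if (!file.exists("results/block_table.tsv"))
  stop("run analysis/01_simulate.R first")
blocks <- read_tsv("results/block_table.tsv")

rows <- list()
for (outc in c("hbo", "alpha", "beta", "vct")) {
  mf <- model_frame(blocks, outc)
  des <- build_design(mf, ~ baseline + fatigue * condition * block,
                      ~ 1 + fatigue * condition, outcome = "y")
  post <- sample_posterior(des, seed = 20260930L, check = FALSE)
  cs <- cell_contrast(post,
                      list(condition = "sham", block = "5",
                           fatigue = "low"),
                      list(condition = "trns", block = "5",
                           fatigue = "low"),
                      name = paste0(outc, ": sham - trns, block 5, low"))
  print(cs)
  rows[[outc]] <- data.frame(outcome = outc, mean = cs$mean,
                             hpd_lo = cs$hpd[1], hpd_hi = cs$hpd[2],
                             pr = cs$pr, credible = cs$credible)
}
contrasts <- do.call(rbind, rows)
write_tsv(contrasts, "results/state_contrasts.tsv")
cat("\nCredible final-block low-fatigue effects:",
    paste(contrasts$outcome[contrasts$credible], collapse = ", "), "\n")

deltas <- delta_table(blocks)
cat("\nChange-score rows (block 5, low fatigue):",
    sum(deltas$block == 5 & deltas$fatigue == "low"), "\n")
med <- tryCatch(fit_mediation(deltas, "d_alpha", seed = 20260930L),
                error = function(e) {
                  cat("Too few matched block-5 pairs; pooling all",
                      "post-baseline low-fatigue blocks.\n")
                  fit_mediation(deltas[deltas$block > 1, ], "d_alpha",
                                block = NULL, seed = 20260930L)
                })
print(med)
write_tsv(data.frame(effect = c("a", "b", "direct", "indirect", "total"),
                     median = apply(med$draws, 2, median),
                     hpd_lo = apply(med$draws, 2, function(d) hpd(d)[1]),
                     hpd_hi = apply(med$draws, 2, function(d) hpd(d)[2])),
          "results/mediation.tsv")
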