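#!/usr/bin/env Rscript
# Stage 3: univariable causal estimates across the method roster.
#
# Runs the Tukey-loss robust profile score (primary), its l2 variant,
# debiased IVW and classical IVW on the selected instruments, and writes a
# forest-style table (log-odds effect, 95% CI, p, odds ratio). Odds-ratio
# columns are always computed from beta at output time, never stored.

library(robustmr)

exposure <- read_sumstats("results/data/exposure.tsv", trait_label = "transcript")
outcome <- read_sumstats("results/data/outcome.tsv", trait_label = "outcome")
ds <- select_instruments(harmonize(list(exposure), outcome), 1e-4)

methods <- c("ivw", "divw", "raps-l2", "raps-tukey")
rows <- lapply(methods, function(m) {
  est <- total_effect(ds, method = m)
  or <- or_from_beta(est)
  data.frame(method = est$method, n_snps = est$n_snps, beta = est$beta,
             se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
             pvalue = est$pvalue, or = or[["or"]],
             or_ci_low = or[["or_ci_low"]], or_ci_high = or[["or_ci_high"]])
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/univariable_estimates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(tab, digits = 3, row.names = FALSE)
cat("\nwrote results/univariable_estimates.tsv\n")
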