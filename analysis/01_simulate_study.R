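#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the statistical shape of a drug-target MR study: a cis-regulated
# transcript exposure measured in ~32k donors, biobank-scale binary
# cardiometabolic outcomes (log-odds), a diabetes-like mediator, and a small
# cis region with lead eQTLs + a glycaemic biomarker for the inhibition
# proxy. All downstream stages read these delimited tables, never R objects.

library(robustmr)

seed <- 2026
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

med <- simulate_mediation(sim_config(p = 300, seed = seed,
  gamma_dist = list(type = "normal", sd = 0.03),
  mediation = list(theta_xm = 0.5, theta_my = 0.2, theta_direct = 0.2)))
dt <- simulate_drug_target(seed = seed + 1, within_block_r2 = 0.6)

write_sumstats(med$tables$exposure, "results/data/exposure.tsv")
write_sumstats(med$tables$mediator, "results/data/mediator.tsv")

# second, independent mediator source (consortium-style cohort): a fresh
# measurement of the same true mediator associations
set.seed(seed + 2)
mu_m <- med$truth$theta_xm * med$truth$gamma + med$truth$phi
maf2 <- med$tables$mediator$eaf
sm2 <- 1 / sqrt(2 * 300000 * maf2 * (1 - maf2))
m2 <- med$tables$mediator
m2$beta <- rnorm(length(mu_m), mu_m, sm2)
m2$se <- sm2
m2$pvalue <- pmax(2 * pnorm(-abs(m2$beta / m2$se)), 1e-300)
write_sumstats(sumstats(m2, "mediator_replication"),
               "results/data/mediator2.tsv")
outcome_all <- sumstats(rbind(as.data.frame(med$tables$outcome),
                              as.data.frame(dt$outcome)), "outcome")
write_sumstats(outcome_all, "results/data/outcome.tsv")
write_sumstats(dt$eqtl, "results/data/cis_eqtl.tsv")
write_sumstats(dt$biomarker, "results/data/biomarker.tsv")
write.table(data.frame(SNP = dt$ld$snp_ids, dt$ld$r2, check.names = FALSE),
            "results/data/cis_ld.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(snp_id = med$truth$snp_id, gamma = med$truth$gamma,
                       phi = med$truth$phi),
            "results/data/truth_instruments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("generating model: total %.2f = direct %.2f + indirect %.2f\n",
            med$truth$total, med$truth$direct, med$truth$indirect))
cat("wrote study tables to results/data/\n")
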