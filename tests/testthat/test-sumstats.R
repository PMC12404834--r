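test_that("sumstats validation enforces the table invariants", {
  tab <- tiny_table()
  expect_s3_class(tab, "sumstats")
  expect_equal(nrow(tab), 3)

  bad <- data.frame(snp_id = c("rs1", "rs2"), effect_allele = c("A", "G"),
                    other_allele = c("G", "T"), beta = c(0.1, 0.2),
                    se = c(0.02, 0), pvalue = c(0.5, 0.5))
  expect_error(sumstats(bad), "rs2")

  expect_error(sumstats(data.frame(snp_id = "rs1", beta = 0.1)),
               "missing mandatory column")
  dup <- data.frame(snp_id = c("rs1", "rs1"), effect_allele = c("A", "A"),
                    other_allele = c("G", "G"), beta = c(0.1, 0.1),
                    se = c(0.1, 0.1), pvalue = c(0.5, 0.5))
  expect_error(sumstats(dup), "duplicated")
  same_alleles <- data.frame(snp_id = "rs1", effect_allele = "A",
                             other_allele = "A", beta = 0.1, se = 0.1,
                             pvalue = 0.5)
  expect_error(sumstats(same_alleles), "allele")
})

test_that("write/read round trip preserves every field", {
  tab <- tiny_table()
  path <- tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, trait_label = "trait")
  for (col in c("snp_id", "effect_allele", "other_allele", "beta", "se",
                "pvalue", "eaf")) {
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
  }
})

test_that("read_sumstats maps dialects and reports missing columns", {
  df <- data.frame(marker = c("rs1", "rs2"), a1 = c("A", "G"), a2 = c("G", "T"),
                   b = c(0.1, -0.2), s = c(0.05, 0.04), pv = c(0.01, 0.2))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  dialect <- c(snp_id = "marker", effect_allele = "a1", other_allele = "a2",
               beta = "b", se = "s", pvalue = "pv")
  tab <- read_sumstats(path, dialect = dialect)
  expect_equal(tab$beta, df$b)
  expect_error(read_sumstats(path), "lacks column")
})

test_that("harmonization aligns, flips, and drops per policy", {
  exp_tab <- tiny_table()
  # identical alleles: no change
  out_same <- tiny_table(beta = c(0.05, -0.02, 0.01), trait = "outcome")
  ds <- harmonize(list(exp_tab), out_same)
  expect_equal(ds$outcome_beta, c(0.05, -0.02, 0.01))
  expect_true(all(ds$orientation$outcome == "none"))

  # swapped alleles: beta sign flips, eaf complements
  out_swap <- tiny_table(beta = c(-0.1, -0.02, 0.01),
                         ea = c("G", "G", "C"), oa = c("A", "T", "T"),
                         eaf = c(0.8, 0.3, 0.4), trait = "outcome")
  ds2 <- harmonize(list(exp_tab), out_swap)
  expect_equal(ds2$outcome_beta[1], 0.1)
  expect_equal(ds2$orientation$outcome[1], "flip")
  expect_equal(ds2$orientation$outcome[2], "none")

  # palindromic variant with eaf 0.5 is dropped and logged
  exp_pal <- tiny_table(ea = c("A", "A", "C"), oa = c("G", "T", "T"),
                        eaf = c(0.2, 0.50, 0.4))
  out_pal <- tiny_table(ea = c("A", "A", "C"), oa = c("G", "T", "T"),
                        eaf = c(0.2, 0.50, 0.4), beta = c(0.01, 0.02, 0.03),
                        trait = "outcome")
  ds3 <- harmonize(list(exp_pal), out_pal)
  expect_false("rs2" %in% ds3$snp_ids)
  expect_true("rs2" %in% ds3$drop_log$snp_id)
  expect_match(ds3$drop_log$reason[ds3$drop_log$snp_id == "rs2"],
               "palindromic")

  # irreconcilable alleles dropped with reason
  out_bad <- tiny_table(ea = c("A", "C", "C"), oa = c("G", "G", "T"),
                        trait = "outcome")
  ds4 <- harmonize(list(exp_tab), out_bad)
  expect_false("rs2" %in% ds4$snp_ids)
  expect_match(ds4$drop_log$reason[ds4$drop_log$snp_id == "rs2"],
               "irreconcilable")

  expect_error(harmonize(list(exp_tab),
                         tiny_table(snp_id = c("rsX", "rsY", "rsZ"),
                                    trait = "outcome")),
               "empty intersection")
})

test_that("harmonization is idempotent: a second pass applies no flips", {
  sim <- simulate_two_sample(sim_config(p = 50, beta = 0.2, seed = 3))
  ds <- harmonize(list(sim$exposure), sim$outcome)
  exp2 <- as_sumstats(ds, "exposure")
  out2 <- as_sumstats(ds, "outcome")
  ds2 <- harmonize(list(exp2), out2)
  expect_true(all(ds2$orientation$outcome == "none"))
  expect_equal(ds2$outcome_beta, ds$outcome_beta)
  expect_equal(ds2$exposure_beta, ds$exposure_beta, ignore_attr = TRUE)
})

test_that("clumping follows the greedy rule and matches a brute-force oracle", {
  tab <- tiny_table()
  # identity LD keeps everything
  ld_id <- ld_matrix(diag(3), tab$snp_id)
  expect_setequal(clump(tab, ld_id, 0.001), tab$snp_id)

  # perfectly correlated pair keeps only the smaller p-value
  tab2 <- sumstats(data.frame(
    snp_id = c("rsA", "rsB"), effect_allele = c("A", "G"),
    other_allele = c("G", "T"), beta = c(0.3, 0.1), se = c(0.05, 0.05),
    pvalue = c(1e-9, 1e-5)), "t")
  r2 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(clump(tab2, ld_matrix(r2, tab2$snp_id), 0.001), "rsA")

  # absent variant is named in the error
  expect_error(clump(tab2, ld_id, 0.001), "rsA")

  # 50-variant random fixture agrees with the independent oracle
  ld <- random_ld(50, seed = 11)
  set.seed(12)
  tab50 <- sumstats(data.frame(
    snp_id = ld$snp_ids, effect_allele = "A", other_allele = "G",
    beta = rnorm(50), se = runif(50, 0.01, 0.1),
    pvalue = runif(50)^3), "t")
  for (thr in c(0.001, 0.1, 0.5)) {
    expect_equal(clump(tab50, ld, thr), clump_oracle(tab50, ld, thr))
  }
  # threshold above the max off-diagonal keeps all variants
  max_off <- max(ld$r2[upper.tri(ld$r2)])
  expect_setequal(clump(tab50, ld, max_off + 1e-9), tab50$snp_id)
})

test_that("instrument selection thresholds, counts and monotonicity", {
  tab <- sumstats(data.frame(
    snp_id = c("rs1", "rs2", "rs3"), effect_allele = "A", other_allele = "G",
    beta = c(0.5, 0.2, 0.1), se = c(0.05, 0.05, 0.05),
    pvalue = c(1e-9, 5e-5, 2e-3)), "exposure")
  out <- sumstats(data.frame(
    snp_id = c("rs1", "rs2", "rs3"), effect_allele = "A", other_allele = "G",
    beta = c(0.1, 0.05, 0.01), se = c(0.02, 0.02, 0.02),
    pvalue = c(0.1, 0.1, 0.1)), "outcome")
  ds <- harmonize(list(tab), out)
  expect_equal(n_snps(select_instruments(ds, 1.0)), 3)
  sel <- select_instruments(ds, 1e-4)
  expect_equal(n_snps(sel), 2)
  expect_equal(sel$meta$n_genomewide_significant, 1)
  expect_error(select_instruments(ds, 1e-20), "relaxing")

  # recount oracle on simulator output and monotone nesting
  sim <- simulate_two_sample(sim_config(p = 200, beta = 0.2, seed = 5))
  dsim <- harmonize(list(sim$exposure), sim$outcome)
  manual <- sum(sim$exposure$pvalue < 1e-4)
  expect_equal(n_snps(select_instruments(dsim, 1e-4)), manual)
  s_small <- select_instruments(dsim, 1e-6)
  s_large <- select_instruments(dsim, 1e-3)
  expect_true(all(s_small$snp_ids %in% s_large$snp_ids))
})

test_that("harmonized datasets serialize with a provenance side-car", {
  sim <- simulate_two_sample(sim_config(p = 20, beta = 0.2, seed = 8))
  ds <- select_instruments(harmonize(list(sim$exposure), sim$outcome), 1)
  base <- tempfile()
  write_mr_dataset(ds, base)
  tab <- read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(tab), n_snps(ds))
  prov <- yaml::read_yaml(paste0(base, ".provenance.yaml"))
  expect_equal(prov$n_snps, n_snps(ds))
  expect_equal(prov$p_threshold, 1)
})
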