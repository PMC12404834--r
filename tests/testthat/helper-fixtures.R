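# Shared fixtures, all generated in code at fixed seeds.

# strong-instrument two-sample dataset (high mean F)
strong_ds <- function(p = 100, beta = 0.3, seed = 1, ...) {
  simulate_dataset(sim_config(p = p, beta = beta,
                              gamma_dist = list(type = "normal", sd = 0.1),
                              seed = seed, ...))
}

# mixed-strength one-pathway dataset after the 1e-4 screen
one_pathway_ds <- function(seed = 21, p = 200, beta = 0.4) {
  sim <- simulate_two_sample(sim_config(p = p, beta = beta,
    gamma_dist = list(type = "normal", sd = 0.03), seed = seed))
  select_instruments(harmonize(list(sim$exposure), sim$outcome), 1e-4)
}

# two-pathway dataset: 60% direct slope 0.4, 40% confounder slope -0.2
two_pathway_ds <- function(seed = 7, p = 150) {
  sim <- simulate_two_sample(sim_config(p = p, beta = 0.4,
    gamma_dist = list(type = "normal", sd = 0.05),
    pleiotropy = list(type = "correlated", pi = 0.4, slope = -0.2),
    seed = seed))
  list(ds = harmonize(list(sim$exposure), sim$outcome), truth = sim$truth)
}

# reverse-direction construction: the one-pathway arm analyzed in the wrong
# direction, combined with variants that instrument the outcome directly
# (and therefore show no association with the true cause), with instrument
# selection applied to the reversed exposure
reverse_direction_ds <- function(seed = 21, p_forward = 200, p_outcome = 100) {
  s1 <- simulate_two_sample(sim_config(p = p_forward, beta = 0.4,
    n_x = 443107, gamma_dist = list(type = "normal", sd = 0.03), seed = seed))
  s2 <- simulate_two_sample(sim_config(p = p_outcome, beta = 0,
    n_x = 443107, gamma_dist = list(type = "normal", sd = 0.03),
    seed = seed + 1000))
  grab <- function(tab, prefix, ids) {
    data.frame(snp_id = paste0(prefix, ids), effect_allele = tab$effect_allele,
               other_allele = tab$other_allele, eaf = tab$eaf, beta = tab$beta,
               se = tab$se, pvalue = pmax(tab$pvalue, 1e-300), n = tab$n,
               stringsAsFactors = FALSE)
  }
  # reversed exposure: associations with the true outcome
  exp_tab <- rbind(grab(s1$outcome, "a", s1$exposure$snp_id),
                   grab(s2$exposure, "b", s2$exposure$snp_id))
  # reversed outcome: associations with the true exposure
  out_tab <- rbind(grab(s1$exposure, "a", s1$exposure$snp_id),
                   grab(s2$outcome, "b", s2$exposure$snp_id))
  select_instruments(harmonize(list(sumstats(exp_tab, "reversed_exposure")),
                               sumstats(out_tab, "reversed_outcome")), 1e-4)
}

# small hand-built sumstats table
tiny_table <- function(beta = c(0.1, 0.2, -0.05), se = c(0.02, 0.03, 0.01),
                       snp_id = c("rs1", "rs2", "rs3"),
                       ea = c("A", "G", "C"), oa = c("G", "T", "T"),
                       eaf = c(0.2, 0.3, 0.4), trait = "trait") {
  sumstats(data.frame(snp_id = snp_id, effect_allele = ea, other_allele = oa,
                      eaf = eaf, beta = beta, se = se,
                      pvalue = 2 * pnorm(-abs(beta / se)),
                      stringsAsFactors = FALSE), trait_label = trait)
}

# independent brute-force greedy clumping oracle
clump_oracle <- function(table, ld, r2_threshold) {
  ord <- order(table$pvalue, table$snp_id)
  remaining <- table$snp_id[ord]
  kept <- character(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    kept <- c(kept, best)
    drop <- vapply(remaining, function(s)
      s == best || ld$r2[best, s] > r2_threshold, logical(1))
    remaining <- remaining[!drop]
  }
  kept
}

# random LD matrix with clustered correlation structure
random_ld <- function(p, seed, n_hap = 30) {
  set.seed(seed)
  ids <- sprintf("snp%03d", seq_len(p))
  base <- matrix(rnorm(n_hap * p), n_hap, p)
  # induce blocks of correlated columns
  for (b in seq(1, p, by = 5)) {
    idx <- b:min(b + 4, p)
    shared <- rnorm(n_hap)
    base[, idx] <- base[, idx] * 0.6 + shared * runif(length(idx), 0, 1.5)[col(base[, idx, drop = FALSE])]
  }
  r2 <- cor(base)^2
  diag(r2) <- 1
  ld_matrix(r2, ids)
}
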