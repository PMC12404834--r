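#' Construct a genetically proxied drug-target inhibition exposure
#'
#' Builds the instrument set for an "inhibition" exposure from cis-eQTL lead
#' variants of the target gene and a downstream biomarker, mirroring how
#' pharmacological inhibition is proxied genetically: (1) orient every
#' variant to its expression-LOWERING allele, so the exposure is inhibition;
#' (2) harmonize with the biomarker table; (3) keep only variants whose
#' oriented biomarker effect is strictly negative (inhibition must lower the
#' biomarker, e.g. HbA1c for a glucose-lowering target) -- a sign test on
#' point estimates with no p-value filter, since suitable variants are
#' scarce and the downstream estimator tolerates weak instruments;
#' (4) LD-prune the joined set greedily at `r2_threshold`. Counts at every
#' stage are logged and are non-increasing.
#'
#' When lead variants are pooled across tissues, duplicates are resolved by
#' keeping the smallest eQTL p-value per variant.
#'
#' @param eqtl [sumstats] of cis-eQTL lead variants for one gene (beta =
#'   effect of the effect allele on expression); may contain one row per
#'   tissue
#' @param biomarker [sumstats] of the downstream biomarker
#' @param ld an [ld_matrix] covering the joined variants
#' @param r2_threshold pruning threshold (default 0.001; 0.8 is the relaxed
#'   sensitivity preset)
#' @param palindrome_policy passed to [harmonize]
#' @return an `inhibition_instruments` object: snp_ids, oriented_betas (on
#'   the inhibition exposure), oriented_se, biomarker_effects (all < 0),
#'   biomarker_se, stage counts and provenance
#' @export
build_inhibition_exposure <- function(eqtl, biomarker, ld,
                                      r2_threshold = 0.001,
                                      palindrome_policy = "drop_ambiguous") {
  stages <- list()
  # pool tissues: deduplicate by snp_id keeping the smallest eQTL p
  ord <- order(eqtl$snp_id, eqtl$pvalue)
  eqtl <- eqtl[ord, ]
  eqtl <- eqtl[!duplicated(eqtl$snp_id), ]
  eqtl <- sumstats(eqtl, trait_label = attr(eqtl, "trait_label") %||% "expression")
  stages$lead_snps <- nrow(eqtl)

  # orient to the expression-lowering allele: expression-raising alleles are
  # flipped (swap alleles, negate beta, complement eaf) so beta <= 0 means
  # "lowers expression"; after negation the exposure axis is inhibition
  raising <- eqtl$beta > 0
  tmp <- eqtl$effect_allele[raising]
  eqtl$effect_allele[raising] <- eqtl$other_allele[raising]
  eqtl$other_allele[raising] <- tmp
  eqtl$beta[raising] <- -eqtl$beta[raising]
  eqtl$eaf[raising] <- 1 - eqtl$eaf[raising]
  # inhibition exposure: effect of the (now effect-)allele on inhibition is
  # the magnitude of expression lowering
  eqtl$beta <- -eqtl$beta
  inhibition <- sumstats(as.data.frame(eqtl), trait_label = "inhibition")

  ds <- harmonize(list(inhibition), biomarker,
                  palindrome_policy = palindrome_policy)
  stages$after_harmonization <- n_snps(ds)

  # sign filter: oriented biomarker effect must be negative
  neg <- ds$outcome_beta < 0
  if (!any(neg)) {
    stop("build_inhibition_exposure: no variant has a negative oriented ",
         "biomarker effect; empty instrument set", call. = FALSE)
  }
  ds <- subset_snps(ds, which(neg))
  stages$after_sign_filter <- n_snps(ds)

  # LD-prune the joined set, ranking by eQTL p-value
  tab <- as_sumstats(ds, "exposure")
  kept <- clump(tab, ld, r2_threshold = r2_threshold)
  ds <- subset_snps(ds, kept)
  stages$after_ld_pruning <- n_snps(ds)

  if (n_snps(ds) == 0) {
    stop("build_inhibition_exposure: empty instrument set after pruning",
         call. = FALSE)
  }
  structure(list(
    snp_ids = ds$snp_ids,
    oriented_betas = ds$exposure_beta[, 1],
    oriented_se = ds$exposure_se[, 1],
    oriented_pvalue = ds$exposure_pvalue[, 1],
    effect_allele = ds$effect_allele,
    other_allele = ds$other_allele,
    biomarker_effects = ds$outcome_beta,
    biomarker_se = ds$outcome_se,
    provenance = list(r2_threshold = r2_threshold,
                      biomarker = ds$meta$outcome_trait,
                      p_filter = "none", stage_counts = stages)
  ), class = "inhibition_instruments")
}

#' @export
print.inhibition_instruments <- function(x, ...) {
  cat("drug-target inhibition instrument set:", length(x$snp_ids),
      "variant(s)\n")
  sc <- x$provenance$stage_counts
  cat(sprintf("  stages: %d lead -> %d harmonized -> %d sign-consistent -> %d pruned (r2 < %g)\n",
              sc$lead_snps, sc$after_harmonization, sc$after_sign_filter,
              sc$after_ld_pruning, x$provenance$r2_threshold))
  invisible(x)
}

#' Pair an inhibition instrument set with an outcome table for estimation
#'
#' @param instruments an `inhibition_instruments` object
#' @param outcome_table [sumstats] for the outcome
#' @param palindrome_policy passed to [harmonize]
#' @return an `mr_dataset` ready for [divw] (a weak-instrument warning is
#'   raised downstream when the condition number is low)
#' @export
inhibition_dataset <- function(instruments, outcome_table,
                               palindrome_policy = "drop_ambiguous") {
  exp_tab <- sumstats(data.frame(
    snp_id = instruments$snp_ids,
    effect_allele = instruments$effect_allele,
    other_allele = instruments$other_allele,
    beta = instruments$oriented_betas,
    se = instruments$oriented_se,
    pvalue = instruments$oriented_pvalue,
    stringsAsFactors = FALSE), trait_label = "inhibition")
  harmonize(list(exp_tab), outcome_table, palindrome_policy = palindrome_policy)
}
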