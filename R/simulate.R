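#' Configuration for the synthetic summary-statistics generator
#'
#' Defaults emulate the scale of the study design the package targets: a
#' cis-regulated molecular exposure measured in ~30k individuals
#' (exposure n = 31684), binary cardiometabolic outcomes from a biobank-scale
#' GWAS on the log-odds scale (outcome n = 443107), around one hundred
#' instruments of mixed strength after a moderate significance screen, and
#' allele frequencies across the common range. Per-variant standard errors
#' follow the GWAS scaling 1/sqrt(2 n maf (1 - maf)).
#'
#' @param p number of variants
#' @param beta true causal effect (log-odds per exposure unit)
#' @param gamma_dist instrument-strength distribution: list(type = "normal",
#'   sd) or list(type = "spike_slab", sd_strong, sd_weak, prop_strong)
#' @param n_x,n_y effective sample sizes for exposure and outcome
#' @param maf_range uniform range for minor-allele frequency
#' @param pleiotropy list(type = "none") | list(type = "balanced", tau) |
#'   list(type = "directional", mu, tau) | list(type = "correlated", pi,
#'   slope): a fraction pi of variants act through a shared confounder
#'   pathway with apparent outcome slope `slope`, which correlates direct
#'   effects with instrument strength and so violates the
#'   instrument-strength-independence assumption
#' @param mediation optional list(theta_xm, theta_my, theta_direct,
#'   mediator_pleiotropy_sd, n_m)
#' @param selection list(type = "none") | list(type = "same_sample", p_thr) |
#'   list(type = "three_sample", p_thr): same-sample selection reuses the
#'   selected exposure estimates downstream (winner's curse present);
#'   three-sample selects on an independent replicate (curse absent)
#' @param binary_outcome outcomes on the log-odds scale (default TRUE)
#' @param seed mandatory RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(p = 100, beta = 0.3,
                       gamma_dist = list(type = "normal", sd = 0.03),
                       n_x = 31684, n_y = 443107,
                       maf_range = c(0.05, 0.5),
                       pleiotropy = list(type = "none"),
                       mediation = NULL,
                       selection = list(type = "none"),
                       binary_outcome = TRUE, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory", call. = FALSE)
  stopifnot(p >= 1, n_x > 0, n_y > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (pleiotropy$type == "correlated") {
    stopifnot(pleiotropy$pi >= 0, pleiotropy$pi <= 1)
  }
  cfg <- list(p = p, beta = beta, gamma_dist = gamma_dist, n_x = n_x,
              n_y = n_y, maf_range = maf_range, pleiotropy = pleiotropy,
              mediation = mediation, selection = selection,
              binary_outcome = binary_outcome, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

.draw_gamma <- function(cfg) {
  gd <- cfg$gamma_dist
  if (gd$type == "normal") {
    stats::rnorm(cfg$p, 0, gd$sd)
  } else if (gd$type == "spike_slab") {
    strong <- stats::runif(cfg$p) < gd$prop_strong
    ifelse(strong, stats::rnorm(cfg$p, 0, gd$sd_strong),
           stats::rnorm(cfg$p, 0, gd$sd_weak))
  } else {
    stop("unknown gamma_dist type: ", gd$type, call. = FALSE)
  }
}

.draw_alpha <- function(cfg, gamma) {
  pl <- cfg$pleiotropy
  pathway <- rep("direct", cfg$p)
  alpha <- numeric(cfg$p)
  if (pl$type == "balanced") {
    alpha <- stats::rnorm(cfg$p, 0, pl$tau)
  } else if (pl$type == "directional") {
    alpha <- stats::rnorm(cfg$p, pl$mu, pl$tau)
  } else if (pl$type == "correlated") {
    conf <- stats::runif(cfg$p) < pl$pi
    # confounded variants act with apparent slope pl$slope instead of beta
    alpha[conf] <- (pl$slope - cfg$beta) * gamma[conf]
    pathway[conf] <- "confounder"
  }
  list(alpha = alpha, pathway = pathway)
}

.gwas_se <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

.random_alleles <- function(p) {
  # non-palindromic pairs only, so simulated tables harmonize losslessly
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs[sample.int(nrow(pairs), p, replace = TRUE), , drop = FALSE]
}

.make_table <- function(snp_id, alleles, eaf, beta_hat, se, n, trait) {
  sumstats(data.frame(
    snp_id = snp_id, effect_allele = alleles[, 1], other_allele = alleles[, 2],
    eaf = eaf, beta = beta_hat, se = se,
    pvalue = pmax(2 * stats::pnorm(-abs(beta_hat / se)), 1e-300),
    n = n, stringsAsFactors = FALSE), trait_label = trait)
}

#' Simulate a two-sample MR dataset with known ground truth
#'
#' Draws true instrument strengths gamma_j and direct (pleiotropic) outcome
#' effects alpha_j per the configuration, then observed summary estimates
#' gamma_hat ~ N(gamma, sx^2) and Gamma_hat ~ N(beta gamma + alpha, sy^2),
#' independent across the two samples. Optional significance selection is
#' applied either on the exposure estimates used downstream (same-sample:
#' winner's curse present) or on an independent replicate (three-sample:
#' curse absent).
#'
#' @param cfg a [sim_config]
#' @return list(exposure, outcome, truth) where truth is a `sim_truth`
#'   recording gamma, alpha, pathway labels and the selection log
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- cfg$p
  snp_id <- sprintf("rs%06d", seq_len(p))
  alleles <- .random_alleles(p)
  maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  gamma <- .draw_gamma(cfg)
  pl <- .draw_alpha(cfg, gamma)
  sx <- .gwas_se(cfg$n_x, maf)
  sy <- .gwas_se(cfg$n_y, maf)
  gamma_hat <- stats::rnorm(p, gamma, sx)
  Gamma_hat <- stats::rnorm(p, cfg$beta * gamma + pl$alpha, sy)

  selected <- rep(TRUE, p)
  sel <- cfg$selection
  if (sel$type == "same_sample") {
    selected <- 2 * stats::pnorm(-abs(gamma_hat / sx)) < sel$p_thr
  } else if (sel$type == "three_sample") {
    gamma_hat_sel <- stats::rnorm(p, gamma, sx)
    selected <- 2 * stats::pnorm(-abs(gamma_hat_sel / sx)) < sel$p_thr
  }
  if (!any(selected)) {
    stop("simulate_two_sample: selection removed every variant", call. = FALSE)
  }
  keep <- which(selected)

  exposure <- .make_table(snp_id[keep], alleles[keep, , drop = FALSE],
                          maf[keep], gamma_hat[keep], sx[keep], cfg$n_x,
                          "exposure")
  outcome <- .make_table(snp_id[keep], alleles[keep, , drop = FALSE],
                         maf[keep], Gamma_hat[keep], sy[keep], cfg$n_y,
                         "outcome")
  truth <- structure(list(
    snp_id = snp_id, gamma = gamma, alpha = pl$alpha, pathway = pl$pathway,
    beta = cfg$beta, selected = selected, maf = maf,
    selection = sel, config = cfg), class = "sim_truth")
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate an exposure-mediator-outcome mediation system
#'
#' Variants instrument the exposure with strengths gamma_j; the mediator
#' inherits theta_xm * gamma_j plus its own pleiotropic effects phi_j; the
#' outcome receives (theta_direct + theta_xm * theta_my) * gamma_j +
#' theta_my * phi_j. Ground truth records total = theta_direct +
#' theta_xm * theta_my, direct = theta_direct, indirect =
#' theta_xm * theta_my. Returns the four harmonizable datasets the mediation
#' pipeline consumes.
#'
#' @param cfg a [sim_config] whose `mediation` block is set
#' @return list(ds_xy, ds_xm, ds_my, ds_xmy, tables, truth)
#' @export
simulate_mediation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(cfg$mediation))
  md <- cfg$mediation
  set.seed(cfg$seed)
  p <- cfg$p
  snp_id <- sprintf("rs%06d", seq_len(p))
  alleles <- .random_alleles(p)
  maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  gamma <- .draw_gamma(cfg)
  phi_sd <- md$mediator_pleiotropy_sd %||% 0.01
  phi <- stats::rnorm(p, 0, phi_sd)
  n_m <- md$n_m %||% cfg$n_y

  theta_total <- md$theta_direct + md$theta_xm * md$theta_my
  mu_m <- md$theta_xm * gamma + phi
  mu_y <- theta_total * gamma + md$theta_my * phi

  sx <- .gwas_se(cfg$n_x, maf)
  sm <- .gwas_se(n_m, maf)
  sy <- .gwas_se(cfg$n_y, maf)
  gamma_hat <- stats::rnorm(p, gamma, sx)
  m_hat <- stats::rnorm(p, mu_m, sm)
  Gamma_hat <- stats::rnorm(p, mu_y, sy)

  exposure <- .make_table(snp_id, alleles, maf, gamma_hat, sx, cfg$n_x,
                          "exposure")
  mediator <- .make_table(snp_id, alleles, maf, m_hat, sm, n_m, "mediator")
  outcome <- .make_table(snp_id, alleles, maf, Gamma_hat, sy, cfg$n_y,
                         "outcome")

  truth <- structure(list(
    snp_id = snp_id, gamma = gamma, phi = phi,
    total = theta_total, direct = md$theta_direct,
    indirect = md$theta_xm * md$theta_my,
    theta_xm = md$theta_xm, theta_my = md$theta_my,
    config = cfg), class = "sim_truth")

  list(ds_xy = harmonize(list(exposure), outcome),
       ds_xm = harmonize(list(exposure), mediator),
       ds_my = harmonize(list(mediator), outcome),
       ds_xmy = harmonize(list(exposure, mediator), outcome),
       tables = list(exposure = exposure, mediator = mediator,
                     outcome = outcome),
       truth = truth)
}

#' Simulate a cis region for drug-target instrument construction
#'
#' Generates LD-blocked lead variants for one gene, an expression table with
#' mixed allele orientations, a biomarker table whose oriented effects have
#' a planted sign structure (a fraction are sign-inconsistent with
#' inhibition lowering the biomarker), and an outcome table, plus the
#' block-diagonal LD matrix. Ground truth records the planted
#' sign-consistency flags.
#'
#' @param p number of lead variants (default 48)
#' @param block_size LD block width (default 4)
#' @param within_block_r2 squared correlation inside a block (default 0.9)
#' @param prop_sign_consistent fraction of variants whose inhibition-oriented
#'   biomarker effect is negative (default 0.6)
#' @param theta_by effect of inhibition on the biomarker magnitude scale
#'   (default 0.05)
#' @param theta_yo effect of the biomarker on the outcome (default 0.2)
#' @param n_e,n_b,n_o sample sizes for the three tables
#' @param seed mandatory RNG seed
#' @return list(eqtl, biomarker, outcome, ld, truth)
#' @export
simulate_drug_target <- function(p = 48, block_size = 4,
                                 within_block_r2 = 0.9,
                                 prop_sign_consistent = 0.6,
                                 theta_by = 0.05, theta_yo = 0.2,
                                 n_e = 700, n_b = 400000, n_o = 443107,
                                 seed) {
  if (missing(seed)) stop("simulate_drug_target: seed is mandatory", call. = FALSE)
  set.seed(seed)
  snp_id <- sprintf("cis%03d", seq_len(p))
  alleles <- .random_alleles(p)
  maf <- stats::runif(p, 0.05, 0.5)

  block <- ceiling(seq_len(p) / block_size)
  r2 <- outer(block, block, function(a, b) ifelse(a == b, within_block_r2, 0))
  diag(r2) <- 1
  ld <- ld_matrix(r2, snp_id)

  # expression effects with mixed input sign conventions, bounded away from
  # zero so estimated signs match planted signs at these sample sizes
  expr_beta <- sample(c(-1, 1), p, replace = TRUE) * stats::runif(p, 0.3, 1.2)
  se_e <- .gwas_se(n_e, maf)
  se_b <- .gwas_se(n_b, maf)
  se_o <- .gwas_se(n_o, maf)

  # planted orientation: when inhibition-oriented, biomarker effect should be
  # negative for consistent variants, positive for inconsistent
  consistent <- stats::runif(p) < prop_sign_consistent
  oriented_bio <- ifelse(consistent, -1, 1) * theta_by * (0.5 + abs(expr_beta))
  # express the biomarker effect on the raw (expression-raising) allele axis:
  # raising expression = lowering inhibition, so flip sign where expr_beta > 0
  bio_beta <- ifelse(expr_beta > 0, -oriented_bio, oriented_bio)
  out_beta <- theta_yo * bio_beta + stats::rnorm(p, 0, se_o / 2)

  eqtl <- .make_table(snp_id, alleles, maf,
                      stats::rnorm(p, expr_beta, se_e), se_e, n_e,
                      "expression")
  biomarker <- .make_table(snp_id, alleles, maf,
                           stats::rnorm(p, bio_beta, se_b), se_b, n_b,
                           "biomarker")
  outcome <- .make_table(snp_id, alleles, maf,
                         stats::rnorm(p, out_beta, se_o), se_o, n_o,
                         "outcome")
  truth <- structure(list(
    snp_id = snp_id, expr_beta = expr_beta, oriented_bio = oriented_bio,
    sign_consistent = consistent, block = block,
    theta_by = theta_by, theta_yo = theta_yo), class = "sim_truth")
  list(eqtl = eqtl, biomarker = biomarker, outcome = outcome, ld = ld,
       truth = truth)
}

#' Two-sample dataset assembled directly from a simulation
#'
#' Convenience wrapper: simulate, then harmonize exposure and outcome.
#' @param cfg a [sim_config]
#' @return list(ds, truth)
#' @export
simulate_dataset <- function(cfg) {
  sim <- simulate_two_sample(cfg)
  list(ds = harmonize(list(sim$exposure), sim$outcome), truth = sim$truth)
}
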