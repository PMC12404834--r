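#' Build a study configuration
#'
#' A study configuration drives [run_study] end to end: instrument selection,
#' the univariable estimator roster, profile-likelihood mode detection (with
#' optional confounder exposures for the multivariable follow-up), mediation
#' and the drug-target arm. Inputs are either file paths to delimited
#' summary-statistics tables or in-memory [sumstats] objects (simulated
#' fixtures slot in directly).
#'
#' @param exposure,outcome [sumstats] tables or file paths
#' @param mediator optional mediator table/path for the mediation arm
#' @param confounders optional named list of exposure tables for the
#'   multivariable follow-up when the profile is multimodal
#' @param eqtl,biomarker,drug_ld optional inputs for the drug-target arm
#' @param methods univariable estimator roster
#' @param p_threshold instrument p-value threshold (default 1e-4)
#' @param clump_r2 optional LD pruning threshold with `ld` an [ld_matrix]
#' @param ld optional [ld_matrix]
#' @param grid_range,grid_step profile grid
#' @param beside list(components, lambda, iterations, burn_in) or NULL to
#'   skip the Bayesian model-averaging stage
#' @param seed mandatory seed for stochastic stages
#' @return a `study_config`
#' @export
study_config <- function(exposure, outcome, mediator = NULL,
                         confounders = NULL, eqtl = NULL, biomarker = NULL,
                         drug_ld = NULL,
                         methods = c("ivw", "divw", "raps-l2", "raps-tukey"),
                         p_threshold = 1e-4, clump_r2 = NULL, ld = NULL,
                         grid_range = c(-2, 2), grid_step = 0.001,
                         beside = list(components = 1, lambda = 0,
                                       iterations = 20000, burn_in = 5000),
                         seed) {
  if (missing(seed)) stop("study_config: seed is mandatory", call. = FALSE)
  structure(list(exposure = exposure, outcome = outcome, mediator = mediator,
                 confounders = confounders, eqtl = eqtl,
                 biomarker = biomarker, drug_ld = drug_ld, methods = methods,
                 p_threshold = p_threshold, clump_r2 = clump_r2, ld = ld,
                 grid_range = grid_range, grid_step = grid_step,
                 beside = beside, seed = seed), class = "study_config")
}

.load_table <- function(x, label) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "sumstats")) return(x)
  if (is.character(x)) return(read_sumstats(x, trait_label = label))
  stop("run_study: input '", label, "' is neither a sumstats table nor a path",
       call. = FALSE)
}

#' Run the full analysis pipeline on one study configuration
#'
#' Stage order: instrument selection (p-value screen, optional LD pruning)
#' -> univariable estimators over the method roster -> robust profile curve
#' with mode detection and marker-variant attribution -> if the profile is
#' multimodal and confounder tables are supplied, a multivariable fit
#' adjusting for them -> Bayesian model averaging -> mediation (when a
#' mediator table is given) -> drug-target arm (when eQTL + biomarker are
#' given) estimated by debiased IVW. A failing stage is recorded in the
#' report and halts only itself, not the run. All stochastic stages are
#' seeded from the configuration seed, so a fixed configuration reproduces
#' its report byte for byte.
#'
#' @param cfg a [study_config]
#' @return a `study_report` (see [write_report])
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  report <- list(seed = cfg$seed, stages = list(), errors = list())
  zq <- stats::qnorm(0.975)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  ## data layer
  ds <- stage("data", {
    exposure <- .load_table(cfg$exposure, "exposure")
    outcome <- .load_table(cfg$outcome, "outcome")
    if (!is.null(cfg$clump_r2) && !is.null(cfg$ld)) {
      kept <- clump(exposure, cfg$ld, r2_threshold = cfg$clump_r2)
      exposure <- sumstats(exposure[match(kept, exposure$snp_id), ],
                           attr(exposure, "trait_label"))
    }
    d <- harmonize(list(exposure), outcome)
    select_instruments(d, cfg$p_threshold)
  })
  if (is.null(ds)) {
    report$stages$data <- "failed"
    class(report) <- "study_report"
    return(report)
  }
  report$n_snps <- n_snps(ds)
  report$n_genomewide_significant <- ds$meta$n_genomewide_significant

  ## univariable estimators
  est_tab <- stage("estimates", {
    rows <- lapply(cfg$methods, function(m) {
      est <- total_effect(ds, method = m)
      or <- or_from_beta(est)
      data.frame(method = est$method, beta = est$beta, se = est$se,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 pvalue = est$pvalue, or = or[["or"]],
                 or_ci_low = or[["or_ci_low"]],
                 or_ci_high = or[["or_ci_high"]],
                 n_snps = est$n_snps, converged = est$converged,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  report$estimates <- est_tab

  ## profile curve + modes
  modes <- stage("modes", {
    curve <- robust_profile(ds, grid_range = cfg$grid_range,
                            grid_step = cfg$grid_step)
    m <- detect_modes(curve)
    markers <- lapply(m$beta, function(b) marker_snps(ds, b))
    list(modes = m, near_zero_secondary = attr(m, "near_zero_secondary"),
         markers = markers)
  })
  report$modes <- modes

  ## multivariable follow-up when multimodal and confounders supplied
  if (!is.null(modes) && nrow(modes$modes) > 1 && !is.null(cfg$confounders)) {
    report$mvmr <- stage("mvmr", {
      conf_tabs <- lapply(names(cfg$confounders), function(nm)
        .load_table(cfg$confounders[[nm]], nm))
      exposure <- .load_table(cfg$exposure, "exposure")
      outcome <- .load_table(cfg$outcome, "outcome")
      dmv <- harmonize(c(list(exposure), conf_tabs), outcome)
      dmv <- select_instruments(dmv, cfg$p_threshold)
      mvmr_fit(dmv)
    })
  }

  ## Bayesian model averaging
  if (!is.null(cfg$beside)) {
    report$beside <- stage("beside", {
      fit <- run_beside(ds, n_components = cfg$beside$components,
                        lambda = cfg$beside$lambda,
                        iterations = cfg$beside$iterations,
                        burn_in = cfg$beside$burn_in, seed = cfg$seed)
      beside_summarize(fit)
    })
  }

  ## diagnostics on the primary estimator
  report$diagnostics <- stage("diagnostics", {
    est <- raps(ds, loss = "tukey")
    qq <- residual_qq(ds, est)
    q <- conditional_q(ds, est$beta)
    list(q = q, qq = qq, shapiro_p = attr(qq, "shapiro_p"))
  })

  ## mediation arm
  if (!is.null(cfg$mediator)) {
    report$mediation <- stage("mediation", {
      exposure <- .load_table(cfg$exposure, "exposure")
      outcome <- .load_table(cfg$outcome, "outcome")
      mediator <- .load_table(cfg$mediator, "mediator")
      ds_xmy <- select_instruments(
        harmonize(list(exposure, mediator), outcome), cfg$p_threshold)
      tot <- total_effect(ds)
      dir <- direct_effect(ds_xmy)
      med <- mediate(tot, dir,
                     mediator_label = attr(mediator, "trait_label") %||% "mediator")
      med
    })
  }

  ## drug-target arm
  if (!is.null(cfg$eqtl) && !is.null(cfg$biomarker) && !is.null(cfg$drug_ld)) {
    report$drug_target <- stage("drug_target", {
      eqtl <- .load_table(cfg$eqtl, "expression")
      biomarker <- .load_table(cfg$biomarker, "biomarker")
      instruments <- build_inhibition_exposure(eqtl, biomarker, cfg$drug_ld)
      outcome <- .load_table(cfg$outcome, "outcome")
      dsi <- inhibition_dataset(instruments, outcome)
      est <- suppressWarnings(divw(dsi))
      or <- or_from_beta(est)
      list(instruments = instruments,
           table = data.frame(method = "dIVW", beta = est$beta, se = est$se,
                              ci_low = est$ci_low, ci_high = est$ci_high,
                              pvalue = est$pvalue, or = or[["or"]],
                              or_ci_low = or[["or_ci_low"]],
                              or_ci_high = or[["or_ci_high"]],
                              condition = est$condition,
                              n_snps = est$n_snps,
                              stringsAsFactors = FALSE))
    })
  }

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("robustmr")),
    seed = cfg$seed, p_threshold = cfg$p_threshold,
    methods = cfg$methods,
    beside = cfg$beside)
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study report (seed", x$seed, ")\n")
  cat(" instruments:", x$n_snps, "(", x$n_genomewide_significant,
      "genome-wide significant )\n")
  if (!is.null(x$estimates)) {
    cat(" univariable estimates:\n")
    print(x$estimates, digits = 4, row.names = FALSE)
  }
  if (!is.null(x$modes)) {
    cat(" profile modes:", nrow(x$modes$modes), "at",
        paste(round(x$modes$modes$beta, 3), collapse = ", "))
    if (isTRUE(x$modes$near_zero_secondary)) cat("  [near-zero secondary]")
    cat("\n")
  }
  if (!is.null(x$mediation)) print(x$mediation)
  if (!is.null(x$drug_target)) {
    cat(" drug-target dIVW:\n")
    print(x$drug_target$table, digits = 4, row.names = FALSE)
  }
  if (length(x$errors) > 0) {
    cat(" stage errors:\n")
    for (nm in names(x$errors)) cat("   ", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}

#' Write a study report to an output directory
#'
#' Emits machine-readable delimited tables (estimates.tsv, modes.tsv,
#' mediation.tsv, drug_target.tsv as applicable), a provenance YAML and a
#' human-readable summary.md. Output bodies contain no timestamps, so a
#' fixed configuration and seed reproduce them byte for byte.
#'
#' @param report a `study_report`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(report$estimates)) wt(report$estimates, "estimates.tsv")
  if (!is.null(report$modes)) {
    m <- report$modes$modes
    m$near_zero_secondary <- report$modes$near_zero_secondary
    m$markers <- vapply(report$modes$markers, paste, "", collapse = ",")
    wt(m, "modes.tsv")
  }
  if (!is.null(report$mediation)) {
    md <- report$mediation
    wt(data.frame(mediator = md$mediator_label,
                  total = md$total$beta, total_se = md$total$se,
                  direct = md$direct_beta, direct_se = md$direct_se,
                  indirect = md$indirect_beta, indirect_se = md$indirect_se,
                  proportion_mediated = md$proportion_mediated,
                  stringsAsFactors = FALSE), "mediation.tsv")
  }
  if (!is.null(report$drug_target)) wt(report$drug_target$table, "drug_target.tsv")
  if (!is.null(report$beside)) {
    b <- report$beside
    wt(data.frame(component = seq_len(b$n_components),
                  beta_mean = b$beta_mean, beta_sd = b$beta_sd,
                  credible_low = b$credible_low,
                  credible_high = b$credible_high,
                  mean_model_size = b$mean_model_size), "beside.tsv")
    wt(data.frame(snp_id = names(b$ppi), ppi = as.numeric(b$ppi)), "ppi.tsv")
  }
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))

  con <- file(file.path(dir, "summary.md"), "w")
  sink(con)
  on.exit({ sink(); close(con) }, add = TRUE)
  cat("# Study summary\n\n```\n")
  print(report)
  cat("```\n")
  invisible(dir)
}
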