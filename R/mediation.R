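#' Total causal effect of exposure on outcome
#'
#' Delegates to the chosen univariable estimator on the exposure-outcome
#' dataset; the default is the Tukey-loss robust profile score, the
#' package's primary estimator.
#'
#' @param ds_xy exposure-outcome `mr_dataset`
#' @param method "raps-tukey" (default), "raps-huber", "raps-l2", "ivw",
#'   or "divw"
#' @param ... passed to the estimator
#' @return an `mr_estimate`
#' @export
total_effect <- function(ds_xy,
                         method = c("raps-tukey", "raps-huber", "raps-l2",
                                    "ivw", "divw"), ...) {
  method <- match.arg(method)
  switch(method,
         "raps-tukey" = raps(ds_xy, loss = "tukey", ...),
         "raps-huber" = raps(ds_xy, loss = "huber", ...),
         "raps-l2" = raps(ds_xy, loss = "l2", ...),
         "ivw" = ivw(ds_xy, ...),
         "divw" = divw(ds_xy, ...))
}

#' Direct effect of exposure on outcome, adjusted for a mediator
#'
#' Multivariable MR on the {exposure, mediator} dataset; the exposure's
#' coefficient is the direct effect not acting through the mediator.
#'
#' @param ds_xmy `mr_dataset` with exposures {exposure, mediator}
#' @param loss robust loss for the multivariable fit (default "l2")
#' @return an `mvmr_estimate`; element 1 of `betas` is the direct effect
#' @export
direct_effect <- function(ds_xmy, loss = "l2") {
  if (n_exposures(ds_xmy) != 2) {
    stop("direct_effect: expected a two-exposure dataset (exposure + mediator)",
         call. = FALSE)
  }
  mvmr_fit(ds_xmy, loss = loss)
}

#' Mediation decomposition by difference in coefficients
#'
#' indirect = total - direct, exactly; the indirect standard error defaults
#' to the independence approximation sqrt(se_total^2 + se_direct^2) (the two
#' estimates come from separate fits) with a parametric-bootstrap
#' alternative. Proportion mediated = indirect / total with a delta-method
#' interval; it is suppressed (flagged undefined) when |total| < 2 se_total,
#' where the ratio is unstable.
#'
#' @param total an `mr_estimate` of the total effect
#' @param direct either an `mvmr_estimate` (exposure = element 1) or a list
#'   with elements `beta` and `se`
#' @param se_method "independence" (default) or "bootstrap"
#' @param boot_reps bootstrap replicates (default 2000)
#' @param seed seed for the bootstrap
#' @param mediator_label name of the mediator
#' @return a `mediation_result`
#' @export
mediate <- function(total, direct, se_method = c("independence", "bootstrap"),
                    boot_reps = 2000, seed = 1, mediator_label = "mediator") {
  se_method <- match.arg(se_method)
  if (inherits(direct, "mvmr_estimate")) {
    direct <- list(beta = direct$betas[1], se = direct$se[1])
  }
  indirect_beta <- total$beta - direct$beta
  se_ind <- sqrt(total$se^2 + direct$se^2)
  if (se_method == "bootstrap") {
    set.seed(seed)
    draws <- stats::rnorm(boot_reps, total$beta, total$se) -
      stats::rnorm(boot_reps, direct$beta, direct$se)
    se_boot <- stats::sd(draws)
    if (abs(se_boot - se_ind) / se_ind > 0.2) {
      message("mediate: bootstrap and independence SEs disagree by >20% (",
              signif(se_boot, 3), " vs ", signif(se_ind, 3),
              "); reporting bootstrap")
    }
    se_ind <- se_boot
  }
  zq <- stats::qnorm(0.975)
  proportion_defined <- abs(total$beta) >= 2 * total$se
  if (proportion_defined) {
    prop <- indirect_beta / total$beta
    # delta method for a ratio with dependent numerator:
    # var(I/T) ~ (1/T^2) var(I) + (I^2/T^4) var(T) - 2 (I/T^3) cov(I,T),
    # cov(I,T) = var(T) since I = T - D with D independent of T
    vT <- total$se^2
    vI <- se_ind^2
    covIT <- vT
    prop_se <- sqrt(max(0, vI / total$beta^2 +
                          indirect_beta^2 * vT / total$beta^4 -
                          2 * indirect_beta * covIT / total$beta^3))
    prop_ci <- c(prop - zq * prop_se, prop + zq * prop_se)
  } else {
    prop <- NA_real_
    prop_se <- NA_real_
    prop_ci <- c(NA_real_, NA_real_)
  }
  structure(list(
    total = total,
    direct_beta = direct$beta, direct_se = direct$se,
    indirect_beta = indirect_beta, indirect_se = se_ind,
    indirect_ci = c(indirect_beta - zq * se_ind, indirect_beta + zq * se_ind),
    indirect_pvalue = 2 * stats::pnorm(-abs(indirect_beta / se_ind)),
    proportion_mediated = prop, proportion_se = prop_se,
    proportion_ci = prop_ci, proportion_defined = proportion_defined,
    se_method = se_method, mediator_label = mediator_label
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("mediation by difference in coefficients (mediator:",
      x$mediator_label, ")\n")
  cat(sprintf("  total    %.4f (se %.4f)\n", x$total$beta, x$total$se))
  cat(sprintf("  direct   %.4f (se %.4f)\n", x$direct_beta, x$direct_se))
  cat(sprintf("  indirect %.4f (se %.4f, 95%% CI %.4f to %.4f)\n",
              x$indirect_beta, x$indirect_se, x$indirect_ci[1],
              x$indirect_ci[2]))
  if (x$proportion_defined) {
    cat(sprintf("  proportion mediated %.3f (95%% CI %.3f to %.3f)\n",
                x$proportion_mediated, x$proportion_ci[1], x$proportion_ci[2]))
  } else {
    cat("  proportion mediated: undefined (total effect within 2 SE of zero)\n")
  }
  invisible(x)
}
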