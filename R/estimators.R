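#' @keywords internal
mr_estimate <- function(beta, se, method, n_snps, tau2 = 0, converged = TRUE,
                        condition = NA_real_, extra = list()) {
  z <- beta / se
  est <- list(beta = beta, se = se,
              ci_low = beta - stats::qnorm(0.975) * se,
              ci_high = beta + stats::qnorm(0.975) * se,
              pvalue = 2 * stats::pnorm(-abs(z)),
              method = method, tau2 = tau2, converged = converged,
              n_snps = n_snps, condition = condition)
  est <- c(est, extra)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d variants)\n", x$method, x$n_snps))
  cat(sprintf("  beta %.4f  se %.4f  95%% CI (%.4f, %.4f)  p %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  if (!is.na(x$condition)) {
    cat(sprintf("  condition %.2f%s\n", x$condition,
                if (isTRUE(x$weak)) "  [weak instruments]" else ""))
  }
  if (x$tau2 > 0) cat(sprintf("  overdispersion tau2 %.3g\n", x$tau2))
  if (!x$converged) cat("  WARNING: did not converge\n")
  invisible(x)
}

.check_univariable <- function(ds) {
  if (n_exposures(ds) != 1) {
    stop("univariable estimator requires a single exposure", call. = FALSE)
  }
}

#' Inverse-variance weighted estimator
#'
#' The classical two-sample MR estimator: the slope of a zero-intercept
#' regression of outcome on exposure associations with weights 1/se_out^2.
#' The default multiplicative random-effects model inflates the fixed-effect
#' standard error by max(1, sqrt(Q/(p-1))) to absorb balanced heterogeneity.
#'
#' @param ds an `mr_dataset` with one exposure
#' @param random_effects inflate the SE multiplicatively when Q exceeds its
#'   degrees of freedom (default TRUE)
#' @return an `mr_estimate`
#' @export
ivw <- function(ds, random_effects = TRUE) {
  .check_univariable(ds)
  g <- ds$exposure_beta[, 1]
  G <- ds$outcome_beta
  w <- 1 / ds$outcome_se^2
  denom <- sum(w * g^2)
  if (denom <= 0) {
    stop("ivw: degenerate instruments (zero weighted exposure variance)",
         call. = FALSE)
  }
  beta <- sum(w * g * G) / denom
  se <- sqrt(1 / denom)
  p <- n_snps(ds)
  if (random_effects && p >= 2) {
    Q <- sum(w * (G - beta * g)^2)
    se <- se * max(1, sqrt(Q / (p - 1)))
  }
  mr_estimate(beta, se, "IVW", p)
}

#' Effective instrument-strength condition number for debiased IVW
#'
#' kappa = sum((gamma_j^2 - se_xj^2) / se_xj^2) / sqrt(p). Debiased IVW is
#' reliable when this is large; values below `weak_floor` are flagged.
#'
#' @param ds an `mr_dataset` with exposure standard errors
#' @param weak_floor flag threshold (default 20)
#' @return numeric condition value with attribute `weak`
#' @export
condition_number <- function(ds, weak_floor = 20) {
  g <- ds$exposure_beta[, 1]
  sx <- ds$exposure_se[, 1]
  kappa <- sum((g^2 - sx^2) / sx^2) / sqrt(n_snps(ds))
  attr(kappa, "weak") <- kappa < weak_floor
  kappa
}

#' Debiased inverse-variance weighted estimator
#'
#' Corrects the weak-instrument bias of IVW by subtracting the exposure
#' sampling variance from each squared instrument strength in the
#' denominator: beta solves sum_j (g_j G_j - beta (g_j^2 - sx_j^2)) / sy_j^2
#' = 0. Remains consistent with many weak instruments and under significance
#' selection in an independent sample. The standard error is the
#' estimating-equation sandwich with per-variant score variance
#' ((g^2 - sx^2)(sy^2 + beta^2 sx^2) + sx^2 sy^2 + 2 beta^2 sx^4) / sy^4.
#'
#' @param ds an `mr_dataset` with one exposure
#' @param weak_floor condition-number flag threshold (default 20)
#' @return an `mr_estimate` with the `condition` field populated
#' @export
divw <- function(ds, weak_floor = 20) {
  .check_univariable(ds)
  g <- ds$exposure_beta[, 1]
  sx <- ds$exposure_se[, 1]
  G <- ds$outcome_beta
  sy <- ds$outcome_se
  num <- sum(g * G / sy^2)
  den <- sum((g^2 - sx^2) / sy^2)
  if (den <= 0) {
    stop("divw: instruments too weak (non-positive debiased denominator); ",
         "condition = ", format(condition_number(ds)), call. = FALSE)
  }
  beta <- num / den
  V <- sum(((g^2 - sx^2) * (sy^2 + beta^2 * sx^2) + sx^2 * sy^2 +
              2 * beta^2 * sx^4) / sy^4)
  se <- sqrt(V) / den
  kappa <- condition_number(ds, weak_floor)
  if (attr(kappa, "weak")) {
    warning("divw: weak instrument set (condition ", format(round(kappa, 2)),
            " < ", weak_floor, "); estimate may be unstable", call. = FALSE)
  }
  mr_estimate(beta, se, "dIVW", n_snps(ds), condition = as.numeric(kappa),
              extra = list(weak = attr(kappa, "weak")))
}

# standardized profile residuals t_j(beta, tau2) and their variance scale
.t_resid <- function(ds, beta, tau2 = 0) {
  s2 <- ds$outcome_se^2 + beta^2 * ds$exposure_se[, 1]^2 + tau2
  list(t = (ds$outcome_beta - beta * ds$exposure_beta[, 1]) / sqrt(s2), s2 = s2)
}

# profile objective -sum rho(t_j)
.raps_objective <- function(ds, beta, tau2, lo) {
  -sum(lo$rho(.t_resid(ds, beta, tau2)$t))
}

# solve tau2 from sum((psi(t) t - delta) / s2) = 0 given beta
.solve_tau2 <- function(ds, beta, lo, tau2_max = 100) {
  f <- function(tau2) {
    r <- .t_resid(ds, beta, tau2)
    sum((lo$psi(r$t) * r$t - lo$delta) / r$s2)
  }
  if (f(0) <= 0) return(0)  # boundary: no overdispersion needed
  upper <- 1e-4
  while (f(upper) > 0 && upper < tau2_max) upper <- upper * 10
  if (upper >= tau2_max) return(tau2_max)
  stats::uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Robust adjusted profile score estimation
#'
#' Maximizes the robust profile objective -sum_j rho(t_j) with standardized
#' residuals t_j = (G_j - beta g_j) / sqrt(sy_j^2 + beta^2 sx_j^2 + tau2),
#' which profiles out the unknown true instrument strengths and so remains
#' consistent under many weak instruments. The loss is squared error, Huber
#' (k = 1.345) or Tukey biweight (k = 4.685); the bounded losses protect
#' against variants with idiosyncratic pleiotropic effects. With
#' `overdispersion = TRUE` a systematic-pleiotropy variance tau2 is solved
#' jointly from the consistency-corrected second estimating equation
#' sum_j (psi(t_j) t_j - delta) / s_j^2 = 0, delta = E[psi(Z)Z] under
#' standard-normal Z. Standard errors are M-estimator sandwich.
#'
#' @param ds an `mr_dataset` with one exposure
#' @param loss "l2", "huber" or "tukey"
#' @param overdispersion estimate tau2 (default FALSE)
#' @param k optional loss tuning constant override
#' @param beta_range search interval for the fallback grid (default c(-5, 5))
#' @return an `mr_estimate` with `tau2` and an honest `converged` flag
#' @export
raps <- function(ds, loss = c("l2", "huber", "tukey"), overdispersion = FALSE,
                 k = NULL, beta_range = c(-5, 5)) {
  .check_univariable(ds)
  lo <- mr_loss(match.arg(loss), k)
  p <- n_snps(ds)

  # start from dIVW when available: consistent under weak instruments
  start <- tryCatch(suppressWarnings(divw(ds)$beta), error = function(e) NULL)
  if (is.null(start) || !is.finite(start)) start <- ivw(ds)$beta

  tau2 <- 0
  beta <- start
  # bounded losses can be multimodal: coarse scan locates the best basin
  if (lo$name != "l2") {
    coarse <- seq(beta_range[1], beta_range[2], by = 0.01)
    vals <- vapply(coarse, function(b) .raps_objective(ds, b, 0, lo), 0)
    cand <- coarse[which.max(vals)]
    if (.raps_objective(ds, cand, 0, lo) > .raps_objective(ds, beta, 0, lo)) {
      beta <- cand
    }
  }
  converged <- FALSE
  for (it in 1:50) {
    # safeguarded local optimization around the current iterate
    res <- stats::optimize(function(b) .raps_objective(ds, b, tau2, lo),
                           lower = max(beta_range[1], beta - 2),
                           upper = min(beta_range[2], beta + 2),
                           maximum = TRUE, tol = 1e-10)
    beta_new <- res$maximum
    tau2_new <- if (overdispersion) .solve_tau2(ds, beta_new, lo) else 0
    if (abs(beta_new - beta) < 1e-10 && abs(tau2_new - tau2) < 1e-12) {
      beta <- beta_new; tau2 <- tau2_new; converged <- TRUE; break
    }
    beta <- beta_new
    tau2 <- tau2_new
  }

  # fine grid-scan fallback when the alternation failed to settle
  if (!converged) {
    grid <- seq(beta_range[1], beta_range[2], by = 1e-3)
    vals <- vapply(grid, function(b) .raps_objective(ds, b, tau2, lo), 0)
    gb <- grid[which.max(vals)]
    res <- stats::optimize(function(b) .raps_objective(ds, b, tau2, lo),
                           lower = gb - 2e-3, upper = gb + 2e-3,
                           maximum = TRUE, tol = 1e-10)
    if (abs(res$maximum - beta) < 1e-4) {
      converged <- TRUE
    }
    beta <- res$maximum
    if (overdispersion) tau2 <- .solve_tau2(ds, beta, lo)
  }

  se <- .raps_sandwich_se(ds, beta, tau2, lo, overdispersion)
  mr_estimate(beta, se, paste0("RAPS-", lo$name), p, tau2 = tau2,
              converged = converged)
}

# sandwich SE for the (beta[, tau2]) estimating equations
.raps_sandwich_se <- function(ds, beta, tau2, lo, overdispersion) {
  score <- function(theta) {
    b <- theta[1]
    t2 <- if (overdispersion) theta[2] else tau2
    r <- .t_resid(ds, b, t2)
    s <- sqrt(r$s2)
    dtdb <- -(ds$exposure_beta[, 1] / s +
                r$t * b * ds$exposure_se[, 1]^2 / r$s2)
    u1 <- lo$psi(r$t) * dtdb
    if (!overdispersion) return(cbind(u1))
    u2 <- (lo$psi(r$t) * r$t - lo$delta) / r$s2
    cbind(u1, u2)
  }
  # at the tau2 = 0 boundary the overdispersion equation is inactive; treat
  # tau2 as fixed and use the one-parameter sandwich
  if (overdispersion && tau2 <= 0) overdispersion <- FALSE
  theta <- if (overdispersion) c(beta, tau2) else beta
  U <- score(theta)
  B <- crossprod(U)
  d <- length(theta)
  A <- matrix(0, d, d)
  h <- pmax(1e-6, abs(theta) * 1e-4)
  if (overdispersion) h[2] <- min(h[2], tau2 / 2)  # keep tau2 positive
  for (j in seq_len(d)) {
    tp <- tm <- theta
    tp[j] <- tp[j] + h[j]; tm[j] <- tm[j] - h[j]
    A[, j] <- (colSums(score(tp)) - colSums(score(tm))) / (2 * h[j])
  }
  V <- tryCatch(solve(A, B) %*% t(solve(A)), error = function(e) NULL)
  if (is.null(V) || !is.finite(V[1, 1]) || V[1, 1] <= 0) {
    return(NA_real_)
  }
  sqrt(V[1, 1])
}

#' Odds-ratio transform of a log-odds estimate
#'
#' @param est an `mr_estimate` on the log-odds scale
#' @return named numeric vector (or, or_ci_low, or_ci_high)
#' @export
or_from_beta <- function(est) {
  c(or = exp(est$beta), or_ci_low = exp(est$ci_low),
    or_ci_high = exp(est$ci_high))
}
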