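#' Robust profile log-likelihood curve over a grid of causal effects
#'
#' Evaluates the robust profile objective -sum_j rho(t_j(beta)) (tau2 = 0)
#' on a beta grid and refines every strict local maximum by bounded scalar
#' optimization within its bracketing cells. The shape of this curve is the
#' pleiotropic-pathway diagnostic: one mode near the causal effect when
#' instruments act through a single pathway, extra modes when a subset of
#' instruments is routed through a shared confounder, and a secondary mode
#' near zero when the causal direction is misspecified.
#'
#' @param ds an `mr_dataset` with one exposure and at least 3 variants
#' @param grid_range beta interval (default c(-2, 2))
#' @param grid_step grid spacing (default 0.001)
#' @param loss "tukey" (default), "huber" or "l2"
#' @return a `profile_curve`: grid, loglik, modes (data.frame beta /
#'   objective / curvature) and residuals_at_mode (p x n_modes matrix)
#' @export
robust_profile <- function(ds, grid_range = c(-2, 2), grid_step = 0.001,
                           loss = c("tukey", "huber", "l2")) {
  .check_univariable(ds)
  if (n_snps(ds) < 3) stop("robust_profile: need at least 3 variants", call. = FALSE)
  lo <- mr_loss(match.arg(loss))
  grid <- seq(grid_range[1], grid_range[2], by = grid_step)
  loglik <- vapply(grid, function(b) .raps_objective(ds, b, 0, lo), 0)

  n <- length(grid)
  is_max <- c(FALSE, loglik[2:(n - 1)] > loglik[1:(n - 2)] &
                loglik[2:(n - 1)] > loglik[3:n], FALSE)
  idx <- which(is_max)
  if (length(idx) == 0) {
    stop("robust_profile: no interior local maximum bracketed; ",
         "use a finer grid_step or wider grid_range", call. = FALSE)
  }
  modes <- lapply(idx, function(i) {
    opt <- stats::optimize(function(b) .raps_objective(ds, b, 0, lo),
                           lower = grid[i - 1], upper = grid[i + 1],
                           maximum = TRUE, tol = 1e-9)
    h <- grid_step / 2
    curv <- (.raps_objective(ds, opt$maximum + h, 0, lo) -
               2 * opt$objective +
               .raps_objective(ds, opt$maximum - h, 0, lo)) / h^2
    c(beta = opt$maximum, objective = opt$objective, curvature = curv)
  })
  modes <- as.data.frame(do.call(rbind, modes))
  ord <- order(modes$objective, decreasing = TRUE)
  modes <- modes[ord, , drop = FALSE]
  rownames(modes) <- NULL
  resid <- vapply(modes$beta, function(b) .t_resid(ds, b)$t,
                  numeric(n_snps(ds)))
  resid <- matrix(resid, nrow = n_snps(ds),
                  dimnames = list(ds$snp_ids, NULL))
  structure(list(grid = grid, loglik = loglik, modes = modes,
                 residuals_at_mode = resid, loss = lo$name,
                 snp_ids = ds$snp_ids),
            class = "profile_curve")
}

#' Filter profile-curve modes by prominence and separation
#'
#' Keeps local maxima whose objective rises at least `min_prominence` above
#' the higher of the two neighbouring valleys, then enforces pairwise
#' separation (keeping the higher-objective mode). Also raises the
#' reverse-direction diagnostic: a secondary mode within `min_separation`
#' of zero is the signature of a misspecified causal direction.
#'
#' @param curve a `profile_curve`
#' @param min_separation minimum distance between reported modes and the
#'   near-zero flag window (default 0.05)
#' @param min_prominence minimum objective drop to the higher neighbouring
#'   valley (default 2, roughly a likelihood-ratio of 2)
#' @return data.frame of modes (beta, objective, curvature, prominence)
#'   ordered by objective descending, with attribute `near_zero_secondary`
#' @export
detect_modes <- function(curve, min_separation = 0.05, min_prominence = 2) {
  grid <- curve$grid
  ll <- curve$loglik
  modes <- curve$modes
  prominence <- vapply(modes$beta, function(b) {
    i <- which.min(abs(grid - b))
    peak <- ll[i]
    # walk out to each side until the curve rises above the peak (or ends)
    left_min <- peak
    if (i > 1) {
      for (j in (i - 1):1) {
        if (ll[j] > peak) break
        left_min <- min(left_min, ll[j])
      }
    }
    right_min <- peak
    if (i < length(ll)) {
      for (j in (i + 1):length(ll)) {
        if (ll[j] > peak) break
        right_min <- min(right_min, ll[j])
      }
    }
    peak - max(left_min, right_min)
  }, 0)
  modes$prominence <- prominence
  keep <- modes$prominence >= min_prominence
  modes <- modes[keep, , drop = FALSE]
  # enforce separation, preferring the higher-objective mode
  modes <- modes[order(modes$objective, decreasing = TRUE), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(modes))) {
    if (all(abs(modes$beta[i] - modes$beta[kept]) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  modes <- modes[kept, , drop = FALSE]
  rownames(modes) <- NULL
  near_zero <- nrow(modes) >= 2 &&
    any(abs(modes$beta) < min_separation)
  attr(modes, "near_zero_secondary") <- near_zero
  modes
}

#' Marker variants consistent with one profile mode
#'
#' Instruments whose standardized residual at the candidate causal value is
#' small (|t_j| below the cutoff) are the ones driving that mode; attributing
#' them to modes separates pathway memberships.
#'
#' @param ds an `mr_dataset` with one exposure
#' @param mode_beta candidate causal effect (finite)
#' @param residual_cutoff inclusion cutoff on |t| (default 1.0)
#' @return character vector of snp ids
#' @export
marker_snps <- function(ds, mode_beta, residual_cutoff = 1.0) {
  stopifnot(is.finite(mode_beta))
  t <- .t_resid(ds, mode_beta)$t
  ds$snp_ids[abs(t) < residual_cutoff]
}

# K-exposure standardized residuals (independent exposure errors)
.t_resid_mv <- function(ds, betas, tau2 = 0) {
  fitted <- as.numeric(ds$exposure_beta %*% betas)
  s2 <- ds$outcome_se^2 +
    as.numeric(ds$exposure_se^2 %*% betas^2) + tau2
  list(t = (ds$outcome_beta - fitted) / sqrt(s2), s2 = s2)
}

.mvmr_objective <- function(ds, betas, lo) {
  sum(lo$rho(.t_resid_mv(ds, betas)$t))
}

.mvmr_gradient <- function(ds, betas, lo) {
  r <- .t_resid_mv(ds, betas)
  s <- sqrt(r$s2)
  # dt_j/db_k = -(g_jk / s_j + t_j b_k sx_jk^2 / s_j^2)
  dt <- -(ds$exposure_beta / s +
            (r$t / r$s2) * sweep(ds$exposure_se^2, 2, betas, `*`))
  as.numeric(crossprod(dt, lo$psi(r$t)))
}

#' Multivariable MR by robust profile score
#'
#' Joint estimation of K exposure effects from shared instruments: betas
#' minimize sum_j rho(t_j) with t_j = (G_j - sum_k b_k g_jk) /
#' sqrt(sy_j^2 + sum_k b_k^2 sx_jk^2), assuming independent exposure
#' measurement errors. The coefficient on each exposure is its direct effect
#' holding the other exposures fixed. Uncertainty is the M-estimator
#' sandwich; per-exposure Wald p-values carry Bonferroni-adjusted
#' significance flags at 0.05/K.
#'
#' @param ds an `mr_dataset` with K exposures and p > K variants
#' @param loss "l2" (default), "huber" or "tukey"
#' @return an `mvmr_estimate`: betas, cov, se, pvalues, bonferroni flags,
#'   and the conditional heterogeneity Q (q_stat, q_df, q_pvalue)
#' @export
mvmr_fit <- function(ds, loss = c("l2", "huber", "tukey")) {
  lo <- mr_loss(match.arg(loss))
  p <- n_snps(ds)
  K <- n_exposures(ds)
  if (p <= K) {
    stop("mvmr_fit: under-identified (", p, " variants for ", K,
         " exposures)", call. = FALSE)
  }
  # an exposure with no instrument signal at all is pinned at zero (a
  # vacuous adjustment), not treated as a rank failure
  zero_cols <- apply(ds$exposure_beta, 2, function(x) all(x == 0))
  if (any(zero_cols)) {
    sub <- ds
    sub$exposure_beta <- ds$exposure_beta[, !zero_cols, drop = FALSE]
    sub$exposure_se <- ds$exposure_se[, !zero_cols, drop = FALSE]
    sub$exposure_pvalue <- ds$exposure_pvalue[, !zero_cols, drop = FALSE]
    sub$meta$exposure_traits <- ds$meta$exposure_traits[!zero_cols]
    fit <- mvmr_fit(sub, loss = loss)
    betas <- se <- pvalues <- rep(NA_real_, K)
    betas[zero_cols] <- 0
    betas[!zero_cols] <- fit$betas
    se[!zero_cols] <- fit$se
    pvalues[!zero_cols] <- fit$pvalues
    cov <- matrix(NA_real_, K, K)
    cov[!zero_cols, !zero_cols] <- fit$cov
    fit$betas <- betas; fit$se <- se; fit$pvalues <- pvalues; fit$cov <- cov
    fit$bonferroni_significant <- pvalues < 0.05 / K
    fit$ci_low <- betas - stats::qnorm(0.975) * se
    fit$ci_high <- betas + stats::qnorm(0.975) * se
    fit$exposure_traits <- ds$meta$exposure_traits
    return(fit)
  }
  qrX <- qr(ds$exposure_beta)
  if (qrX$rank < K) {
    stop("mvmr_fit: singular information (collinear exposure effects)",
         call. = FALSE)
  }
  # start at the error-naive weighted least squares solution
  w <- 1 / ds$outcome_se^2
  X <- ds$exposure_beta
  start <- as.numeric(solve(crossprod(X, w * X), crossprod(X, w * ds$outcome_beta)))

  fit <- stats::optim(start, function(b) .mvmr_objective(ds, b, lo),
                      gr = function(b) .mvmr_gradient(ds, b, lo),
                      method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  betas <- fit$par
  converged <- fit$convergence == 0

  # sandwich covariance: A = d(score)/d(beta), B = sum of outer score products
  score_mat <- function(b) {
    r <- .t_resid_mv(ds, b)
    s <- sqrt(r$s2)
    dt <- -(ds$exposure_beta / s +
              (r$t / r$s2) * sweep(ds$exposure_se^2, 2, b, `*`))
    dt * lo$psi(r$t)
  }
  U <- score_mat(betas)
  B <- crossprod(U)
  A <- matrix(0, K, K)
  h <- pmax(1e-6, abs(betas) * 1e-6)
  for (j in seq_len(K)) {
    bp <- bm <- betas
    bp[j] <- bp[j] + h[j]; bm[j] <- bm[j] - h[j]
    A[, j] <- (colSums(score_mat(bp)) - colSums(score_mat(bm))) / (2 * h[j])
  }
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    stop("mvmr_fit: singular information at the optimum", call. = FALSE)
  }
  cov <- Ainv %*% B %*% t(Ainv)
  cov <- (cov + t(cov)) / 2
  se <- sqrt(diag(cov))
  pvalues <- 2 * stats::pnorm(-abs(betas / se))
  qres <- conditional_q(ds, betas)

  structure(list(
    betas = betas, cov = cov, se = se, pvalues = pvalues,
    bonferroni_significant = pvalues < 0.05 / K,
    ci_low = betas - stats::qnorm(0.975) * se,
    ci_high = betas + stats::qnorm(0.975) * se,
    q_stat = qres[["q"]], q_df = qres[["df"]], q_pvalue = qres[["pvalue"]],
    loss = lo$name, converged = converged, n_snps = p,
    exposure_traits = ds$meta$exposure_traits
  ), class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("multivariable MR (%s loss, %d variants, %d exposures)\n",
              x$loss, x$n_snps, length(x$betas)))
  for (k in seq_along(x$betas)) {
    cat(sprintf("  %s: beta %.4f se %.4f CI (%.4f, %.4f) p %.3g%s\n",
                x$exposure_traits[k], x$betas[k], x$se[k], x$ci_low[k],
                x$ci_high[k], x$pvalues[k],
                if (x$bonferroni_significant[k]) " *" else ""))
  }
  cat(sprintf("  conditional Q %.2f on %d df (p %.3g)\n",
              x$q_stat, x$q_df, x$q_pvalue))
  invisible(x)
}

#' Modified conditional Cochran's Q for (multivariable) MR
#'
#' Q = sum_j t_j(betas)^2 with the K-exposure standardized residual whose
#' variance includes the exposure measurement error; chi-square with p - K
#' degrees of freedom under instrument validity.
#'
#' @param ds an `mr_dataset`
#' @param betas length-K effect vector at which to evaluate the residuals
#' @return named vector (q, df, pvalue)
#' @export
conditional_q <- function(ds, betas) {
  K <- n_exposures(ds)
  stopifnot(length(betas) == K)
  p <- n_snps(ds)
  df <- p - K
  if (df < 1) stop("conditional_q: df = p - K < 1", call. = FALSE)
  q <- sum(.t_resid_mv(ds, betas)$t^2)
  c(q = q, df = df, pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Quantile-quantile data for standardized profile residuals
#'
#' Pairs the sorted standardized residuals at a fitted estimate with
#' standard-normal quantiles at (i - 0.5)/p. Under instrument validity the
#' residuals are approximately standard normal; systematic departure is
#' evidence against the assumption that pleiotropic effects are independent
#' of instrument strength.
#'
#' @param ds an `mr_dataset` with one exposure
#' @param est an `mr_estimate`
#' @return data.frame (theoretical_quantile, observed_t) with a Shapiro-Wilk
#'   style summary in attributes `shapiro_w` / `shapiro_p`
#' @export
residual_qq <- function(ds, est) {
  t <- .t_resid(ds, est$beta, est$tau2)$t
  p <- length(t)
  out <- data.frame(
    theoretical_quantile = stats::qnorm((seq_len(p) - 0.5) / p),
    observed_t = sort(t))
  if (p >= 3 && p <= 5000 && stats::sd(t) > 0) {
    sw <- stats::shapiro.test(t)
    attr(out, "shapiro_w") <- unname(sw$statistic)
    attr(out, "shapiro_p") <- sw$p.value
  } else {
    attr(out, "shapiro_w") <- NA_real_
    attr(out, "shapiro_p") <- NA_real_
  }
  out
}

#' Plot a profile curve with its detected modes
#' @param x a `profile_curve`
#' @param modes optional output of [detect_modes]
#' @param ... passed to plot()
#' @export
plot.profile_curve <- function(x, modes = NULL, ...) {
  graphics::plot(x$grid, x$loglik, type = "l", xlab = "beta",
                 ylab = "robust profile log-likelihood", ...)
  if (is.null(modes)) modes <- x$modes
  graphics::abline(v = modes$beta, lty = 3, col = seq_len(nrow(modes)) + 1)
  invisible(x)
}
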