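# Per-SNP log-likelihood contribution when included with effect b and
# overdispersion tau2; excluded variants contribute nothing.
.beside_ll_j <- function(ds, j, b, tau2) {
  s2 <- ds$outcome_se[j]^2 + b^2 * ds$exposure_se[j, 1]^2 + tau2
  stats::dnorm(ds$outcome_beta[j], b * ds$exposure_beta[j, 1], sqrt(s2),
               log = TRUE)
}

.beside_ll_all <- function(ds, incl, z, beta, tau2) {
  total <- 0
  for (c in seq_along(beta)) {
    jj <- which(incl & z == c)
    if (length(jj) > 0) {
      s2 <- ds$outcome_se[jj]^2 + beta[c]^2 * ds$exposure_se[jj, 1]^2 + tau2
      total <- total + sum(stats::dnorm(ds$outcome_beta[jj],
                                        beta[c] * ds$exposure_beta[jj, 1],
                                        sqrt(s2), log = TRUE))
    }
  }
  total
}

#' Bayesian model averaging over instrument-inclusion sets (BESIDE-MR)
#'
#' Metropolis-within-Gibbs sampling over (beta, tau, inclusion vector and,
#' for two components, component assignment). Each included variant
#' contributes a normal likelihood for its outcome association centred at
#' beta_c * gamma_j with variance sy^2 + beta_c^2 sx^2 + tau^2; excluded
#' variants contribute nothing, so the posterior probability of inclusion
#' (PPI) of a variant measures how compatible it is with the shared causal
#' effect. The inclusion prior exp(lambda * sum I_j) tilts the average model
#' size: positive lambda favours larger models, negative smaller. Priors:
#' N(0, 10^2) on each beta, half-normal(0.5) on tau. For two components the
#' identifiability constraint beta_1 < beta_2 is enforced by rejection.
#' Random-walk steps adapt toward acceptance in [0.15, 0.6] during burn-in
#' only and are frozen afterwards; a fixed seed yields bit-identical draws.
#'
#' @param ds an `mr_dataset` with one exposure and p >= 4 variants
#' @param n_components 1 or 2 causal-effect components
#' @param lambda model-size penalization (paper-style sensitivity range
#'   -3..3; default 0)
#' @param iterations total MCMC iterations (default 50000)
#' @param burn_in discarded initial iterations (default 10000)
#' @param seed RNG seed (mandatory)
#' @param min_model_size minimum included variants per component (default 2)
#' @return a `beside_fit` with draws (beta matrix, tau2, inclusion matrix,
#'   assignment matrix), acceptance rates and settings
#' @export
run_beside <- function(ds, n_components = 1, lambda = 0, iterations = 50000,
                       burn_in = 10000, seed, min_model_size = 2) {
  .check_univariable(ds)
  stopifnot(n_components %in% c(1, 2))
  if (missing(seed)) stop("run_beside: seed is mandatory", call. = FALSE)
  p <- n_snps(ds)
  if (p < 4) {
    stop("run_beside: insufficient instruments (p = ", p,
         " < 4) for Bayesian model averaging", call. = FALSE)
  }
  if (iterations <= burn_in) stop("iterations must exceed burn_in", call. = FALSE)
  set.seed(seed)

  nc <- n_components
  prior_beta_sd <- 10
  prior_tau_scale <- 0.5
  log_prior <- function(beta, tau, incl) {
    sum(stats::dnorm(beta, 0, prior_beta_sd, log = TRUE)) +
      stats::dnorm(tau, 0, prior_tau_scale, log = TRUE) +  # half-normal kernel
      lambda * sum(incl)
  }

  # initial state: all included, effects around the IVW fit
  incl <- rep(TRUE, p)
  z <- if (nc == 1) rep(1L, p) else
    rep_len(c(1L, 2L), p)[sample.int(p)]
  b0 <- ivw(ds)$beta
  beta <- if (nc == 1) b0 else sort(c(b0 - 0.1, b0 + 0.1))
  tau <- 0.05
  step_beta <- rep(0.1, nc)
  step_tau <- 0.05

  ll <- .beside_ll_all(ds, incl, z, beta, tau^2)
  lp <- log_prior(beta, tau, incl)

  draws_beta <- matrix(NA_real_, iterations, nc)
  draws_tau2 <- numeric(iterations)
  draws_incl <- matrix(FALSE, iterations, p)
  draws_z <- matrix(NA_integer_, iterations, p)
  acc <- c(flip = 0, beta = 0, tau = 0, swap = 0)
  prop <- c(flip = 0, beta = 0, tau = 0, swap = 0)
  acc_beta_window <- 0
  prop_beta_window <- 0
  acc_tau_window <- 0

  comp_sizes <- function(incl, z) {
    vapply(seq_len(nc), function(c) sum(incl & z == c), 0L)
  }

  for (it in seq_len(iterations)) {
    ## inclusion flip
    j <- sample.int(p, 1)
    incl2 <- incl
    incl2[j] <- !incl2[j]
    prop["flip"] <- prop["flip"] + 1
    if (all(comp_sizes(incl2, z) >= min_model_size)) {
      delta <- .beside_ll_j(ds, j, beta[z[j]], tau^2)
      dll <- if (incl2[j]) delta else -delta
      dlp <- lambda * (sum(incl2) - sum(incl))
      if (log(stats::runif(1)) < dll + dlp) {
        incl <- incl2
        ll <- ll + dll
        lp <- lp + dlp
        acc["flip"] <- acc["flip"] + 1
      }
    }

    ## beta random walks (per component)
    for (c in seq_len(nc)) {
      prop["beta"] <- prop["beta"] + 1
      prop_beta_window <- prop_beta_window + 1
      beta2 <- beta
      beta2[c] <- beta[c] + stats::rnorm(1, 0, step_beta[c])
      if (nc == 2 && beta2[1] >= beta2[2]) next  # ordering constraint
      ll2 <- .beside_ll_all(ds, incl, z, beta2, tau^2)
      lp2 <- log_prior(beta2, tau, incl)
      if (log(stats::runif(1)) < (ll2 + lp2) - (ll + lp)) {
        beta <- beta2; ll <- ll2; lp <- lp2
        acc["beta"] <- acc["beta"] + 1
        acc_beta_window <- acc_beta_window + 1
      }
    }

    ## tau random walk with reflection at zero
    prop["tau"] <- prop["tau"] + 1
    tau2p <- abs(tau + stats::rnorm(1, 0, step_tau))
    ll2 <- .beside_ll_all(ds, incl, z, beta, tau2p^2)
    lp2 <- log_prior(beta, tau2p, incl)
    if (log(stats::runif(1)) < (ll2 + lp2) - (ll + lp)) {
      tau <- tau2p; ll <- ll2; lp <- lp2
      acc["tau"] <- acc["tau"] + 1
      acc_tau_window <- acc_tau_window + 1
    }

    ## component reassignment (2 components)
    if (nc == 2) {
      prop["swap"] <- prop["swap"] + 1
      jj <- which(incl)
      j <- jj[sample.int(length(jj), 1)]
      z2 <- z
      z2[j] <- 3L - z[j]
      if (all(comp_sizes(incl, z2) >= min_model_size)) {
        dll <- .beside_ll_j(ds, j, beta[z2[j]], tau^2) -
          .beside_ll_j(ds, j, beta[z[j]], tau^2)
        if (log(stats::runif(1)) < dll) {
          z <- z2; ll <- ll + dll
          acc["swap"] <- acc["swap"] + 1
        }
      }
    }

    ## adapt step sizes during burn-in only (frozen after)
    if (it <= burn_in && it %% 100 == 0 && prop_beta_window > 0) {
      rate <- acc_beta_window / prop_beta_window
      if (rate < 0.15) step_beta <- step_beta * 0.8
      if (rate > 0.6) step_beta <- step_beta * 1.25
      tau_rate <- acc_tau_window / 100
      if (tau_rate < 0.15) step_tau <- step_tau * 0.8
      if (tau_rate > 0.6) step_tau <- step_tau * 1.25
      acc_beta_window <- 0
      prop_beta_window <- 0
      acc_tau_window <- 0
    }

    draws_beta[it, ] <- beta
    draws_tau2[it] <- tau^2
    draws_incl[it, ] <- incl
    draws_z[it, ] <- z
  }

  structure(list(
    draws_beta = draws_beta, draws_tau2 = draws_tau2,
    draws_incl = draws_incl, draws_z = draws_z,
    n_components = nc, lambda = lambda, seed = seed,
    iterations = iterations, burn_in = burn_in,
    acceptance_rates = acc / pmax(prop, 1),
    snp_ids = ds$snp_ids, min_model_size = min_model_size
  ), class = "beside_fit")
}

#' Posterior summaries of a BESIDE-MR run
#'
#' @param fit a `beside_fit`
#' @return a `beside_summary`: per-component posterior mean and central 95%
#'   credible interval, per-variant PPI, mean model size, and a lag-1
#'   autocorrelation effective-sample-size diagnostic for beta
#' @export
beside_summarize <- function(fit) {
  keep <- (fit$burn_in + 1):fit$iterations
  bm <- fit$draws_beta[keep, , drop = FALSE]
  incl <- fit$draws_incl[keep, , drop = FALSE]
  ppi <- colMeans(incl)
  names(ppi) <- fit$snp_ids
  ess <- apply(bm, 2, function(x) {
    r1 <- stats::cor(x[-1], x[-length(x)])
    if (!is.finite(r1) || abs(r1) >= 1) return(NA_real_)
    length(x) * (1 - r1) / (1 + r1)
  })
  structure(list(
    beta_mean = colMeans(bm),
    beta_sd = apply(bm, 2, stats::sd),
    credible_low = apply(bm, 2, stats::quantile, 0.025),
    credible_high = apply(bm, 2, stats::quantile, 0.975),
    tau2_mean = mean(fit$draws_tau2[keep]),
    ppi = ppi,
    mean_model_size = mean(rowSums(incl)),
    ess_beta = ess,
    n_components = fit$n_components, lambda = fit$lambda
  ), class = "beside_summary")
}

#' @export
print.beside_summary <- function(x, ...) {
  cat(sprintf("BESIDE-MR posterior (%d component(s), lambda %.1f)\n",
              x$n_components, x$lambda))
  for (c in seq_len(x$n_components)) {
    cat(sprintf("  beta[%d]: mean %.4f sd %.4f 95%% CrI (%.4f, %.4f)\n",
                c, x$beta_mean[c], x$beta_sd[c], x$credible_low[c],
                x$credible_high[c]))
  }
  cat(sprintf("  mean model size %.2f of %d variants\n",
              x$mean_model_size, length(x$ppi)))
  invisible(x)
}

#' Export posterior draws as a delimited table
#' @param fit a `beside_fit`
#' @param path output TSV path
#' @export
write_beside_draws <- function(fit, path) {
  out <- data.frame(iteration = seq_len(fit$iterations))
  for (c in seq_len(fit$n_components)) {
    out[[paste0("beta", c)]] <- fit$draws_beta[, c]
  }
  out$tau2 <- fit$draws_tau2
  out$inclusion <- apply(fit$draws_incl, 1, function(b)
    paste(as.integer(b), collapse = ""))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Profile-likelihood fit on the high-PPI instrument subset
#'
#' A deterministic companion summary to the full posterior: refits the l2
#' profile score on the variants whose PPI exceeds the cutoff and reports a
#' DerSimonian-Laird-style overdispersion standard error. This is an
#' interpretation of a hybrid estimator, flagged as such in its metadata.
#'
#' @param ds the `mr_dataset` the posterior was fit to
#' @param summary a `beside_summary`
#' @param ppi_cutoff inclusion cutoff (default 0.5)
#' @return an `mr_estimate` with `interpretation = "DL"` metadata
#' @export
beside_dl <- function(ds, summary, ppi_cutoff = 0.5) {
  keep <- which(summary$ppi > ppi_cutoff)
  if (length(keep) < 2) {
    stop("beside_dl: fewer than 2 variants with PPI > ", ppi_cutoff,
         call. = FALSE)
  }
  sub <- subset_snps(ds, keep)
  est <- raps(sub, loss = "l2", overdispersion = TRUE)
  est$method <- "BESIDE-MR (DL)"
  est$interpretation <- "DL"
  est
}
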