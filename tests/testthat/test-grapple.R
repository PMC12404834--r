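test_that("one-pathway fixture yields a single mode at the causal effect", {
  ds <- one_pathway_ds(seed = 21)
  curve <- robust_profile(ds, grid_step = 0.002)
  modes <- detect_modes(curve)
  expect_equal(nrow(modes), 1)
  expect_lt(abs(modes$beta[1] - 0.4), 0.05)
  expect_false(attr(modes, "near_zero_secondary"))
})

test_that("negating outcome associations reflects the profile curve", {
  ds <- one_pathway_ds(seed = 22)
  neg <- ds
  neg$outcome_beta <- -ds$outcome_beta
  m1 <- detect_modes(robust_profile(ds, grid_step = 0.002))
  m2 <- detect_modes(robust_profile(neg, grid_step = 0.002))
  expect_equal(sort(m2$beta), sort(-m1$beta), tolerance = 1e-6)
})

test_that("profile curve is invariant to variant ordering", {
  ds <- one_pathway_ds(seed = 23, p = 100)
  set.seed(1)
  perm <- subset_snps(ds, sample(n_snps(ds)))
  c1 <- robust_profile(ds, grid_step = 0.01)
  c2 <- robust_profile(perm, grid_step = 0.01)
  expect_equal(c1$loglik, c2$loglik, tolerance = 1e-12)
})

test_that("two-pathway fixture yields two modes at oracle locations", {
  fix <- two_pathway_ds(seed = 7)
  curve <- robust_profile(fix$ds, grid_step = 0.002)
  modes <- detect_modes(curve)
  expect_equal(nrow(modes), 2)
  # oracle: exhaustive fine-grid search of the same objective
  lo <- mr_loss("tukey")
  fine <- seq(-2, 2, by = 5e-4)
  obj <- vapply(fine, function(b) {
    t <- (fix$ds$outcome_beta - b * fix$ds$exposure_beta[, 1]) /
      sqrt(fix$ds$outcome_se^2 + b^2 * fix$ds$exposure_se[, 1]^2)
    -sum(lo$rho(t))
  }, 0)
  # oracle locations: best fine-grid point near each generating slope
  for (target in c(0.4, -0.2)) {
    win <- abs(fine - target) < 0.15
    oracle_loc <- fine[win][which.max(obj[win])]
    expect_true(any(abs(modes$beta - oracle_loc) < 0.05))
  }
  expect_false(attr(modes, "near_zero_secondary"))
})

test_that("a strictly concave curve reports exactly its vertex", {
  grid <- seq(-2, 2, by = 0.01)
  curve <- structure(list(
    grid = grid, loglik = -50 * (grid - 0.3)^2,
    modes = data.frame(beta = 0.3, objective = 0, curvature = -100)),
    class = "profile_curve")
  modes <- detect_modes(curve)
  expect_equal(nrow(modes), 1)
  expect_equal(modes$beta, 0.3, tolerance = 1e-6)
})

test_that("mode filtering survives a vanishing prominence threshold", {
  ds <- one_pathway_ds(seed = 24)
  curve <- robust_profile(ds, grid_step = 0.002)
  modes <- detect_modes(curve, min_prominence = 1e-9)
  expect_equal(nrow(modes), 1)
})

test_that("reverse-direction construction raises the near-zero flag", {
  ds <- reverse_direction_ds(seed = 21)
  modes <- detect_modes(robust_profile(ds, grid_range = c(-3, 3),
                                       grid_step = 0.002))
  expect_gte(nrow(modes), 2)
  expect_true(attr(modes, "near_zero_secondary"))
})

test_that("marker variants are attributed by standardized residual", {
  g <- c(0.2, 0.3, 0.1)
  sy <- c(0.01, 0.01, 0.01)
  G <- c(0.5 * 0.2, 0.5 * 0.3, 0.5 * 0.1 + 5 * 0.0101)
  ds <- mr_dataset(c("rs1", "rs2", "rs3"), g, rep(1e-6, 3), G, sy)
  mk <- marker_snps(ds, 0.5)
  expect_true(all(c("rs1", "rs2") %in% mk))
  expect_false("rs3" %in% mk)  # |t| = 5 at the mode

  # two-pathway fixture: marker sets partition by generating pathway
  fix <- two_pathway_ds(seed = 7)
  modes <- detect_modes(robust_profile(fix$ds, grid_step = 0.002))
  m_main <- marker_snps(fix$ds, modes$beta[which.min(abs(modes$beta - 0.4))])
  m_conf <- marker_snps(fix$ds, modes$beta[which.min(abs(modes$beta + 0.2))])
  truth <- fix$truth
  lab <- truth$pathway[match(fix$ds$snp_ids, truth$snp_id)]
  # variants marking exactly one mode partition by generating pathway;
  # weak variants may mark both modes or neither (|t| is noise-limited)
  only_main <- setdiff(m_main, m_conf)
  only_conf <- setdiff(m_conf, m_main)
  correct <- sum(lab[match(only_main, fix$ds$snp_ids)] == "direct") +
    sum(lab[match(only_conf, fix$ds$snp_ids)] == "confounder")
  expect_gte(correct / (length(only_main) + length(only_conf)), 0.9)
})

test_that("multivariable fit with one exposure nests the univariable raps", {
  sim <- strong_ds(p = 40, seed = 25)
  for (loss in c("l2", "tukey")) {
    uni <- raps(sim$ds, loss)
    mv <- mvmr_fit(sim$ds, loss)
    expect_equal(mv$betas[1], uni$beta, tolerance = 1e-6)
  }
})

test_that("collinear exposures raise a singular-information error", {
  sim <- strong_ds(p = 30, seed = 26)
  ds <- sim$ds
  ds$exposure_beta <- cbind(ds$exposure_beta, ds$exposure_beta)
  ds$exposure_se <- cbind(ds$exposure_se, ds$exposure_se)
  ds$exposure_pvalue <- cbind(ds$exposure_pvalue, ds$exposure_pvalue)
  ds$meta$exposure_traits <- c("x1", "x2")
  expect_error(mvmr_fit(ds), "singular")
})

test_that("under-identification is rejected", {
  sim <- strong_ds(p = 2, seed = 27)
  ds <- sim$ds
  ds$exposure_beta <- cbind(ds$exposure_beta, rnorm(2))
  ds$exposure_se <- cbind(ds$exposure_se, rep(0.01, 2))
  ds$exposure_pvalue <- cbind(ds$exposure_pvalue, rep(0.5, 2))
  ds$meta$exposure_traits <- c("x1", "x2")
  expect_error(mvmr_fit(ds), "under-identified")
})

test_that("an instrument irrelevant to every exposure does not move the fit", {
  m <- simulate_mediation(sim_config(p = 80, seed = 28,
    gamma_dist = list(type = "normal", sd = 0.1),
    mediation = list(theta_xm = 0.5, theta_my = 0.2, theta_direct = 0.2)))
  ds <- m$ds_xmy
  fit_full <- mvmr_fit(ds)
  weakest <- which.min(rowSums(abs(ds$exposure_beta / ds$exposure_se)))
  fit_drop <- mvmr_fit(subset_snps(ds, setdiff(seq_len(n_snps(ds)), weakest)))
  expect_lt(abs(fit_full$betas[1] - fit_drop$betas[1]), 2 * fit_full$se[1])
})

test_that("conditional Q is zero at an exact fit and matches chi-square", {
  # exact fit: outcome constructed from the betas
  set.seed(29)
  g <- cbind(rnorm(30, 0, 0.2), rnorm(30, 0, 0.2))
  betas <- c(0.3, -0.1)
  ds <- mr_dataset(sprintf("rs%d", 1:30), g, matrix(0.01, 30, 2),
                   as.numeric(g %*% betas), rep(0.02, 30))
  q <- conditional_q(ds, betas)
  expect_equal(unname(q["q"]), 0, tolerance = 1e-20)
  expect_equal(unname(q["df"]), 28)

  # K = 1 equals the classical Q of the univariable residuals
  sim <- strong_ds(p = 40, seed = 30)
  fit <- raps(sim$ds, "l2")
  q1 <- conditional_q(sim$ds, fit$beta)
  t_manual <- (sim$ds$outcome_beta - fit$beta * sim$ds$exposure_beta[, 1]) /
    sqrt(sim$ds$outcome_se^2 + fit$beta^2 * sim$ds$exposure_se[, 1]^2)
  expect_equal(unname(q1["q"]), sum(t_manual^2), tolerance = 1e-12)

  expect_error(conditional_q(subset_snps(sim$ds, 1), fit$beta), "df")
})

test_that("conditional Q calibrates under the null and detects heterogeneity", {
  reps <- 500
  qs <- numeric(reps)
  rej_null <- logical(reps)
  rej_het <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    p <- 50
    g <- cbind(rnorm(p, 0, 0.15), rnorm(p, 0, 0.15))
    sx <- matrix(0.01, p, 2)
    gh <- g + matrix(rnorm(2 * p, 0, 0.01), p, 2)
    betas <- c(0.3, -0.2)
    sy <- rep(0.02, p)
    G <- as.numeric(g %*% betas) + rnorm(p, 0, sy)
    ds <- mr_dataset(sprintf("rs%d", 1:p), gh, sx, G, sy)
    fit <- mvmr_fit(ds)
    q <- conditional_q(ds, fit$betas)
    qs[r] <- q["q"]
    rej_null[r] <- q["pvalue"] < 0.05
    # planted heterogeneity: 20% of variants get pleiotropic offsets
    G2 <- G
    het <- seq_len(p) <= 10
    G2[het] <- G2[het] + sample(c(-1, 1), 10, TRUE) * 0.08
    ds2 <- mr_dataset(sprintf("rs%d", 1:p), gh, sx, G2, sy)
    fit2 <- mvmr_fit(ds2)
    rej_het[r] <- conditional_q(ds2, fit2$betas)["pvalue"] < 0.05
  }
  mc_se <- sd(qs) / sqrt(reps)
  expect_lt(abs(mean(qs) - 48), 2 * mc_se)
  expect_gt(mean(rej_null), 0.03)
  expect_lt(mean(rej_null), 0.08)
  expect_gt(mean(rej_het), 0.8)
})

test_that("residual QQ output is shaped and calibrated", {
  # residuals exactly standard normal by construction
  set.seed(31)
  p <- 200
  g <- rnorm(p, 0, 0.2)
  sy <- rep(0.02, p)
  beta <- 0.3
  sx <- rep(1e-8, p)
  t_true <- rnorm(p)
  G <- beta * g + t_true * sqrt(sy^2 + beta^2 * sx^2)
  ds <- mr_dataset(sprintf("rs%d", 1:p), g, sx, G, sy)
  est <- raps(ds, "l2")
  est$beta <- beta; est$tau2 <- 0
  qq <- residual_qq(ds, est)
  expect_equal(nrow(qq), p)
  # exact oracle: the observed column is the sorted planted residuals
  expect_equal(qq$observed_t, sort(t_true), tolerance = 1e-8)
  # calibration: close to the diagonal on average, normal by Shapiro-Wilk
  expect_lt(mean(abs(qq$observed_t - qq$theoretical_quantile)), 0.1)
  expect_gt(attr(qq, "shapiro_p"), 0.01)

  # degenerate constant residuals
  Gc <- beta * g + 0.5 * sy
  dsc <- mr_dataset(sprintf("rs%d", 1:p), g, sx, Gc, sy)
  estc <- est; estc$beta <- beta
  qqc <- residual_qq(dsc, estc)
  expect_true(all(abs(qqc$observed_t - 0.5) < 1e-6))
})
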