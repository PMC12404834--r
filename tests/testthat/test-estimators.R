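make_ds <- function(g, sx, G, sy) {
  mr_dataset(sprintf("rs%d", seq_along(g)), g, sx, G, sy)
}

test_that("ivw reduces to the ratio estimate and is duplication-invariant", {
  ds <- make_ds(0.5, 0.01, 0.1, 0.07)
  expect_equal(ivw(ds)$beta, 0.2, tolerance = 1e-12)
  # any outcome SE gives the same single-instrument ratio
  expect_equal(ivw(make_ds(0.5, 0.01, 0.1, 0.3))$beta, 0.2, tolerance = 1e-12)

  set.seed(4)
  g <- rnorm(20, 0, 0.3); G <- 0.25 * g + rnorm(20, 0, 0.02)
  sy <- runif(20, 0.01, 0.05)
  ds20 <- make_ds(g, rep(0.01, 20), G, sy)
  dup <- make_ds(c(g, g), rep(0.01, 40), c(G, G),
                 c(sy, sy))
  expect_equal(ivw(dup)$beta, ivw(ds20)$beta, tolerance = 1e-12)
})

test_that("ivw equals an independent weighted-least-squares oracle", {
  set.seed(9)
  g <- rnorm(20, 0, 0.3); G <- 0.25 * g + rnorm(20, 0, 0.02)
  sy <- runif(20, 0.01, 0.05)
  ds <- make_ds(g, rep(1e-10, 20), G, sy)
  oracle <- lm(G ~ 0 + g, weights = 1 / sy^2)
  expect_equal(ivw(ds)$beta, unname(coef(oracle)), tolerance = 1e-10)
})

test_that("divw debiases and reduces to ivw without exposure error", {
  set.seed(10)
  g <- rnorm(30, 0, 0.2); G <- 0.4 * g + rnorm(30, 0, 0.02)
  ds0 <- make_ds(g, rep(1e-12, 30), G, rep(0.02, 30))
  expect_equal(divw(ds0)$beta, ivw(ds0)$beta, tolerance = 1e-10)

  # single-variant arithmetic forced by the estimating equation
  ds1 <- make_ds(0.5, 0.3, 0.1, 0.1)
  expect_equal(suppressWarnings(divw(ds1))$beta, 0.3125, tolerance = 1e-12)
})

test_that("condition number matches its closed form and a recount", {
  ds <- make_ds(rep(0.2, 4), rep(0.1, 4), rep(0.1, 4), rep(0.1, 4))
  expect_equal(as.numeric(condition_number(ds)), 6, tolerance = 1e-12)

  ds_null <- make_ds(rep(0.07, 5), rep(0.07, 5), rep(0, 5), rep(0.1, 5))
  expect_equal(as.numeric(condition_number(ds_null)), 0, tolerance = 1e-12)

  sim <- strong_ds(p = 60, seed = 2)
  g <- sim$ds$exposure_beta[, 1]; sx <- sim$ds$exposure_se[, 1]
  manual <- sum((g^2 - sx^2) / sx^2) / sqrt(60)
  expect_equal(as.numeric(condition_number(sim$ds)), manual, tolerance = 1e-12)
  expect_false(attr(condition_number(sim$ds), "weak"))
})

test_that("raps with l2 loss and no exposure error equals ivw", {
  set.seed(11)
  g <- rnorm(25, 0, 0.2); G <- 0.3 * g + rnorm(25, 0, 0.02)
  sy <- runif(25, 0.01, 0.05)
  ds <- make_ds(g, rep(1e-12, 25), G, sy)
  fit <- raps(ds, loss = "l2")
  expect_true(fit$converged)
  expect_equal(fit$beta, ivw(ds, random_effects = FALSE)$beta,
               tolerance = 1e-8)
})

test_that("raps maximizes its own objective: grid-search oracle per loss", {
  set.seed(12)
  g <- rnorm(10, 0, 0.2)
  G <- 0.35 * g + rnorm(10, 0, 0.03)
  ds <- make_ds(g, rep(0.05, 10), G, rep(0.03, 10))
  for (loss in c("l2", "huber", "tukey")) {
    lo <- mr_loss(loss)
    grid <- seq(-2, 2, by = 1e-4)
    obj <- vapply(grid, function(b) {
      t <- (ds$outcome_beta - b * ds$exposure_beta[, 1]) /
        sqrt(ds$outcome_se^2 + b^2 * ds$exposure_se[, 1]^2)
      -sum(lo$rho(t))
    }, 0)
    oracle <- grid[which.max(obj)]
    fit <- raps(ds, loss = loss)
    expect_true(fit$converged)
    expect_lt(abs(fit$beta - oracle), 1e-4)
  }
})

test_that("bounded losses resist a planted pleiotropic outlier", {
  set.seed(13)
  p <- 40
  g <- rnorm(p, 0, 0.2)
  G <- 0.3 * g + rnorm(p, 0, 0.01)
  sy <- rep(0.01, p)
  clean <- make_ds(g, rep(0.02, p), G, sy)
  base_l2 <- raps(clean, "l2")$beta
  base_tk <- raps(clean, "tukey")$beta
  G_out <- G
  G_out[1] <- G[1] + 0.1  # 10x the typical outcome scale
  dirty <- make_ds(g, rep(0.02, p), G_out, sy)
  shift_l2 <- abs(raps(dirty, "l2")$beta - base_l2)
  shift_tk <- abs(raps(dirty, "tukey")$beta - base_tk)
  expect_lt(shift_tk, 0.2 * shift_l2)
})

test_that("overdispersion tau2 is recovered and bounded below by zero", {
  sim <- simulate_dataset(sim_config(p = 150, beta = 0.3,
    gamma_dist = list(type = "normal", sd = 0.1),
    pleiotropy = list(type = "balanced", tau = 0.01), seed = 14))
  fit <- raps(sim$ds, "l2", overdispersion = TRUE)
  expect_true(fit$converged)
  expect_gt(fit$tau2, 0)
  # tau2 of the right order (truth 1e-4)
  expect_lt(abs(log10(fit$tau2) - log10(1e-4)), 1)

  clean <- strong_ds(p = 80, seed = 15)
  fit0 <- raps(clean$ds, "l2", overdispersion = TRUE)
  expect_gte(fit0$tau2, 0)
})

test_that("odds-ratio transform is the exponential of beta and its interval", {
  est <- mr_estimate <- raps(strong_ds(p = 30, seed = 16)$ds, "l2")
  est$beta <- 0; est$ci_low <- 0; est$ci_high <- 0
  expect_equal(unname(or_from_beta(est)["or"]), 1)
  est$beta <- log(2)
  expect_equal(unname(or_from_beta(est)["or"]), 2)

  est$beta <- 0.315; est$ci_low <- 0.06; est$ci_high <- 0.56
  or <- or_from_beta(est)
  expect_equal(unname(or["or_ci_low"]), 1.0618, tolerance = 1e-4)
  expect_equal(unname(or["or_ci_high"]), 1.7507, tolerance = 1e-4)
  # consistent with a printed interval of 1.07-1.76 to rounding
  expect_lt(abs(or[["or_ci_low"]] - 1.07), 0.015)
  expect_lt(abs(or[["or_ci_high"]] - 1.76), 0.015)
})

test_that("estimators are scale and sign equivariant in the outcome", {
  sim <- strong_ds(p = 50, seed = 17)
  ds <- sim$ds
  c_scale <- 2.5
  ds_sc <- ds
  ds_sc$outcome_beta <- ds$outcome_beta * c_scale
  ds_sc$outcome_se <- ds$outcome_se * c_scale
  ds_ng <- ds
  ds_ng$outcome_beta <- -ds$outcome_beta
  for (f in list(function(d) ivw(d), function(d) divw(d),
                 function(d) raps(d, "l2"), function(d) raps(d, "tukey"))) {
    base <- f(ds); sc <- f(ds_sc); ng <- f(ds_ng)
    expect_equal(sc$beta, c_scale * base$beta, tolerance = 1e-6)
    expect_equal(sc$se, c_scale * base$se, tolerance = 1e-4)
    expect_equal(ng$beta, -base$beta, tolerance = 1e-6)
    expect_equal(ng$se, base$se, tolerance = 1e-6)
  }
})

test_that("all estimators agree on a strong clean fixture", {
  sim <- strong_ds(p = 100, beta = 0.3, seed = 18)
  fits <- list(ivw(sim$ds), divw(sim$ds), raps(sim$ds, "l2"),
               raps(sim$ds, "tukey"))
  betas <- vapply(fits, function(f) f$beta, 0)
  ses <- vapply(fits, function(f) f$se, 0)
  for (i in 2:4) {
    expect_lt(abs(betas[i] - betas[1]), 2 * sqrt(ses[i]^2 + ses[1]^2))
  }
})

test_that("degenerate inputs raise informative errors", {
  ds_zero <- make_ds(c(0, 0), c(0.1, 0.1), c(0.1, 0.1), c(0.1, 0.1))
  expect_error(ivw(ds_zero), "degenerate")
  expect_error(suppressWarnings(divw(ds_zero)), "weak")
})
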