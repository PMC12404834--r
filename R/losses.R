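#' Robust loss functions for profile-score estimation
#'
#' A loss object bundles rho (the loss), psi (its derivative) and
#' delta = E[psi(Z) Z] for standard-normal Z, the consistency constant used
#' by the overdispersion estimating equation. Tuning constants default to the
#' standard 95%-efficiency values: 1.345 (Huber), 4.685 (Tukey biweight).
#'
#' @param loss one of "l2", "huber", "tukey"
#' @param k tuning constant; ignored for "l2", defaults to 1.345 (huber) or
#'   4.685 (tukey)
#' @return list with elements `rho(t)`, `psi(t)`, `delta`, `name`, `k`
#' @export
mr_loss <- function(loss = c("l2", "huber", "tukey"), k = NULL) {
  loss <- match.arg(loss)
  if (loss == "l2") {
    return(list(name = "l2", k = Inf,
                rho = function(t) t^2 / 2,
                psi = function(t) t,
                delta = 1))
  }
  if (loss == "huber") {
    if (is.null(k)) k <- 1.345
    rho <- function(t) ifelse(abs(t) <= k, t^2 / 2, k * abs(t) - k^2 / 2)
    psi <- function(t) pmax(-k, pmin(k, t))
  } else {
    if (is.null(k)) k <- 4.685
    rho <- function(t) {
      out <- rep(k^2 / 6, length(t))
      inside <- abs(t) <= k
      u <- t[inside] / k
      out[inside] <- k^2 / 6 * (1 - (1 - u^2)^3)
      out
    }
    psi <- function(t) {
      out <- numeric(length(t))
      inside <- abs(t) <= k
      out[inside] <- t[inside] * (1 - (t[inside] / k)^2)^2
      out
    }
  }
  delta <- .psi_z_expectation(psi)
  list(name = loss, k = k, rho = rho, psi = psi, delta = delta)
}

# E[psi(Z) Z] under Z ~ N(0,1), by quadrature
.psi_z_expectation <- function(psi) {
  stats::integrate(function(z) psi(z) * z * stats::dnorm(z),
                   -Inf, Inf, rel.tol = 1e-10)$value
}
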