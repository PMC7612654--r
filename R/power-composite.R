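#' Responder probability under the latent model
#'
#' A patient responds when every component falls at or below its responder
#' cut \eqn{\eta_k} (recode outcomes by a sign flip for "at or above"
#' definitions). Under the arm's latent normal law the response probability
#' is the rectangle integral
#' \deqn{p = \Phi_K(\eta_1, \ldots, \eta_K; \mu^*, \Sigma),}
#' standardized internally so continuous components may carry
#' \eqn{\sigma_k \neq 1}. The optional `at_least` argument generalizes to
#' "response requires at least m of the K components", computed by
#' inclusion-exclusion over component subsets.
#'
#' @param mu_star K-vector of latent means for the arm.
#' @param corr K-by-K latent correlation matrix.
#' @param eta K-vector of responder cuts (entries may be `Inf`).
#' @param sd K-vector of latent scales (1 for discrete components).
#' @param at_least Number of components that must meet their cut (default
#'   K: all of them).
#' @return A probability.
#' @examples
#' response_prob(0, diag(1), 0)               # 0.5
#' response_prob(c(0, 0), diag(2), c(Inf, Inf))  # certain response
#' @export
response_prob <- function(mu_star, corr, eta, sd = 1, at_least = NULL) {
  K <- length(mu_star)
  sd <- rep(sd, length.out = K)
  if (length(eta) != K || nrow(as.matrix(corr)) != K) {
    lp_abort("mu_star, eta and corr must share the same dimension K",
             class = "lp_error_spec")
  }
  upper <- (eta - mu_star) / sd
  at_least <- at_least %||% K
  if (at_least >= K) {
    return(as.numeric(mvn_cdf(upper, corr)))
  }
  if (at_least < 1) return(1)
  # P(at least m of K events) = sum_{j=m}^K (-1)^(j-m) C(j-1, m-1) S_j
  m <- as.integer(at_least)
  total <- 0
  for (j in m:K) {
    Sj <- sum(vapply(utils::combn(K, j, simplify = FALSE), function(idx) {
      as.numeric(mvn_cdf(upper[idx], corr[idx, idx, drop = FALSE]))
    }, numeric(1)))
    total <- total + (-1)^(j - m) * choose(j - 1, m - 1) * Sj
  }
  min(max(total, 0), 1)
}

#' Composite responder treatment effect from a latent fit
#'
#' Computes the per-arm response probabilities (rectangle integrals of the
#' fitted latent law), the latent-model risk difference \eqn{\delta^* = p_T
#' - p_C}, its delta-method variance (when the fit carries a parameter
#' covariance), and the per-observation variance scale \eqn{\sigma^2}
#' recovered from the pilot sample sizes via \eqn{\sigma^2_\delta =
#' \sigma^2 (1/n_T + 1/n_C)}.
#'
#' @param fit A [latent_fit()] (e.g. from [fit_latent_model()]).
#' @param eta K-vector of responder cuts.
#' @param at_least Passed to [response_prob()]; default all K components.
#' @return A `composite_effect` object: `p_T`, `p_C`, `delta_star`,
#'   `var_delta` (`NA` without a covariance), `sigma2`, `eta`.
#' @export
composite_effect <- function(fit, eta, at_least = NULL) {
  pars <- fit_arm_params(fit)
  p_T <- response_prob(pars$mu_T, pars$corr, eta, pars$sd, at_least)
  p_C <- response_prob(pars$mu_C, pars$corr, eta, pars$sd, at_least)
  var_delta <- if (is.null(fit$cov_theta)) {
    NA_real_
  } else {
    delta_method_var(fit, eta, at_least = at_least)
  }
  sigma2 <- NA_real_
  if (!is.na(var_delta) && !is.na(fit$n_T) && !is.na(fit$n_C)) {
    if (fit$n_T != fit$n_C) {
      rlang::warn(paste0("pilot arms are unbalanced; sigma^2 is recovered ",
                         "from sigma_delta^2 / (1/n_T + 1/n_C)"))
    }
    sigma2 <- var_delta / (1 / fit$n_T + 1 / fit$n_C)
  }
  structure(list(p_T = p_T, p_C = p_C, delta_star = p_T - p_C,
                 var_delta = var_delta, sigma2 = sigma2, eta = eta,
                 n_T = fit$n_T, n_C = fit$n_C),
            class = "composite_effect")
}

#' @export
print.composite_effect <- function(x, ...) {
  cat("<composite_effect>\n")
  cat(sprintf("  p_T = %.4f, p_C = %.4f, delta* = %.4f\n",
              x$p_T, x$p_C, x$delta_star))
  if (!is.na(x$var_delta)) {
    cat(sprintf("  var(delta*) = %.5g (delta method)", x$var_delta))
    if (!is.na(x$sigma2)) cat(sprintf(", sigma^2 = %.5g", x$sigma2))
    cat("\n")
  }
  invisible(x)
}

#' Delta-method variance of the composite risk difference
#'
#' First-order Taylor expansion: \eqn{\mathrm{var}(\hat\delta^*) \approx
#' \nabla\delta^{*\top} \, \mathrm{Cov}(\hat\theta) \, \nabla\delta^*},
#' with the gradient taken by central finite differences (relative step
#' `1e-5`) of the rectangle-integral risk difference with respect to every
#' model parameter. A non-positive-semidefinite covariance is projected to
#' the nearest PSD matrix with a warning before the quadratic form.
#'
#' @inheritParams composite_effect
#' @param fd_step Relative finite-difference step.
#' @return Nonnegative variance of \eqn{\hat\delta^*}.
#' @export
delta_method_var <- function(fit, eta, at_least = NULL, fd_step = 1e-5) {
  if (is.null(fit$cov_theta)) {
    lp_abort("fit carries no parameter covariance; supply cov_theta",
             class = "lp_error_spec")
  }
  theta <- fit$theta
  delta_fn <- function(th) {
    pars <- arm_params_from_theta(th, fit$outcomes)
    corr <- pars$corr
    if (nrow(corr) > 1 && min_eigenvalue(corr) <= 1e-10) {
      corr <- psd_project(corr, tol = 1e-8)
      diag(corr) <- 1
    }
    response_prob(pars$mu_T, corr, eta, pars$sd, at_least) -
      response_prob(pars$mu_C, corr, eta, pars$sd, at_least)
  }
  grad <- vapply(seq_along(theta), function(j) {
    h <- fd_step * max(1, abs(theta[[j]]))
    up <- theta; up[[j]] <- up[[j]] + h
    dn <- theta; dn[[j]] <- dn[[j]] - h
    (delta_fn(up) - delta_fn(dn)) / (2 * h)
  }, numeric(1))
  cov_theta <- fit$cov_theta
  if (min_eigenvalue(cov_theta) < -1e-8 * max(1, max(abs(diag(cov_theta))))) {
    rlang::warn("cov_theta is not positive semidefinite; projecting to the nearest PSD matrix")
    cov_theta <- psd_project(cov_theta, tol = 0)
  }
  max(0, drop(t(grad) %*% cov_theta %*% grad))
}

#' Composite endpoint power and sample size
#'
#' The composite hypothesis is univariate, so the standard one-sided
#' normal-approximation machinery applies with the latent-model risk
#' difference and variance:
#' \deqn{1 - \beta = \Phi\!\left(\frac{\delta^*}{\sqrt{2\sigma^2/n}} -
#' z_\alpha\right), \qquad
#' n = \left\lceil \frac{2\sigma^2 (z_{1-\beta} + z_\alpha)^2}
#' {\delta^{*2}} \right\rceil.}
#'
#' @param delta_star Risk difference \eqn{p_T - p_C} (positive favours
#'   treatment).
#' @param sigma2 Per-observation variance scale \eqn{\sigma^2} (so
#'   \eqn{\sigma^2_\delta = 2\sigma^2/n} per group); from
#'   [composite_effect()] or expert input.
#' @param n Per-group sample size.
#' @param alpha One-sided significance level.
#' @param target_power Required power.
#' @return `power_composite()`: a probability. `samplesize_composite()`:
#'   the smallest adequate per-group integer n.
#' @examples
#' power_composite(delta_star = 0.14, sigma2 = 0.048, n = 49)  # ~ 0.886
#' samplesize_composite(delta_star = 0.40, sigma2 = 1)         # 99
#' @export
power_composite <- function(delta_star, sigma2, n, alpha = 0.025) {
  stopifnot(is_number(sigma2), sigma2 > 0, is.numeric(n), all(n >= 2))
  pnorm(delta_star / sqrt(2 * sigma2 / n) - qnorm(1 - alpha))
}

#' @rdname power_composite
#' @export
samplesize_composite <- function(delta_star, sigma2, alpha = 0.025,
                                 target_power = 0.80) {
  stopifnot(is_number(sigma2), sigma2 > 0)
  if (!is_number(delta_star) || delta_star <= 0) {
    lp_abort("delta_star must be positive for a finite sample size",
             class = "lp_error_infeasible")
  }
  as.integer(ceiling(
    2 * sigma2 * (qnorm(target_power) + qnorm(1 - alpha))^2 / delta_star^2
  ))
}

#' Standard two-proportion sample size (comparator)
#'
#' Classical binary-method comparator for the composite endpoint: the
#' two-sample test of proportions with the pooled variance under the null
#' and unpooled variance under the alternative,
#' \deqn{n = \left\lceil \frac{\big(z_\alpha\sqrt{2\bar p \bar q} +
#' z_{1-\beta}\sqrt{p_T q_T + p_C q_C}\big)^2}{(p_T - p_C)^2}
#' \right\rceil.}
#'
#' @param p_T,p_C Response proportions per arm.
#' @inheritParams power_composite
#' @return Per-group sample size.
#' @examples
#' binary_method_n(0.6, 0.4)  # 97
#' @export
binary_method_n <- function(p_T, p_C, alpha = 0.025, target_power = 0.80) {
  check_prob(p_T, "p_T")
  check_prob(p_C, "p_C")
  if (p_T == p_C) {
    lp_abort("p_T and p_C must differ", class = "lp_error_infeasible")
  }
  pbar <- (p_T + p_C) / 2
  num <- (qnorm(1 - alpha) * sqrt(2 * pbar * (1 - pbar)) +
            qnorm(target_power) * sqrt(p_T * (1 - p_T) + p_C * (1 - p_C)))^2
  as.integer(ceiling(num / (p_T - p_C)^2))
}
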