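test_that("response probability handles the canonical special cases", {
  expect_equal(response_prob(0, diag(1), 0), 0.5)
  expect_equal(response_prob(c(0.4, -0.3), diag(2), c(Inf, Inf)), 1)
  # independence: product of marginal normal probabilities
  mu <- c(0.2, -0.1, 0.5)
  eta <- c(0.3, 0, 1)
  sds <- c(1.5, 1, 1)
  expect_equal(response_prob(mu, diag(3), eta, sd = sds),
               prod(pnorm((eta - mu) / sds)), tolerance = 1e-7)
  expect_error(response_prob(c(0, 0), diag(3), c(0, 0)),
               class = "lp_error_spec")
})

test_that("response probability is monotone in means and cuts", {
  corr <- matrix(c(1, 0.4, 0.4, 1), 2)
  base <- response_prob(c(0, 0), corr, c(0.5, 0.5))
  for (k in 1:2) {
    mu <- c(0, 0)
    mu[k] <- 0.4
    expect_lt(response_prob(mu, corr, c(0.5, 0.5)), base)
    eta <- c(0.5, 0.5)
    eta[k] <- 1
    expect_gt(response_prob(c(0, 0), corr, eta), base)
  }
  # m-of-K relaxation can only increase the response probability
  expect_gt(response_prob(c(0, 0), corr, c(0.5, 0.5), at_least = 1), base)
})

test_that("composite effect from a fit matches brute-force Monte Carlo", {
  outcomes <- dplyr::bind_rows(
    outcome_continuous("y1", effect = 0.5, sd = 1.5),
    outcome_binary("y2", effect = 0.4)
  )
  theta <- c("mu_T.y1" = 0.6, "mu_C.y1" = 0, "sigma.y1" = 1.5,
             "mu_T.y2" = 0.35, "mu_C.y2" = -0.1, "rho.y1.y2" = 0.5)
  fit <- latent_fit(theta, outcomes)
  eta <- c(0.8, 0)
  ce <- composite_effect(fit, eta)
  expect_true(is.na(ce$var_delta))
  # brute-force draws from the same latent law
  set.seed(42)
  nmc <- 1e6
  Sig <- diag(c(1.5, 1)) %*% matrix(c(1, 0.5, 0.5, 1), 2) %*% diag(c(1.5, 1))
  U <- chol(Sig)
  draw_p <- function(mu) {
    z <- matrix(rnorm(2 * nmc), nmc, 2) %*% U
    mean(z[, 1] + mu[1] <= eta[1] & z[, 2] + mu[2] <= eta[2])
  }
  pT_mc <- draw_p(c(0.6, 0.35))
  pC_mc <- draw_p(c(0, -0.1))
  mc_se <- sqrt(0.25 / nmc)
  expect_lt(abs(ce$p_T - pT_mc), 3 * mc_se)
  expect_lt(abs(ce$p_C - pC_mc), 3 * mc_se)
  expect_equal(ce$delta_star, ce$p_T - ce$p_C)
  # identical arms give a null effect
  theta0 <- theta
  theta0[c("mu_T.y1", "mu_T.y2")] <- c(0, -0.1)
  expect_equal(composite_effect(latent_fit(theta0, outcomes),
                                eta)$delta_star, 0)
  # raising a latent mean lowers the (below-cut) response
  theta_up <- theta
  theta_up[["mu_T.y1"]] <- 1.2
  expect_lt(composite_effect(latent_fit(theta_up, outcomes), eta)$delta_star,
            ce$delta_star)
})

test_that("delta-method variance matches the analytic binary gradient", {
  outcomes <- outcome_binary("y", effect = 0.5)
  theta <- c("mu_T.y" = 0.3, "mu_C.y" = -0.2)
  covt <- diag(c(0.0041, 0.0037))
  fit <- latent_fit(theta, outcomes, cov_theta = covt, n_T = 300, n_C = 300)
  v <- delta_method_var(fit, eta = 0)
  # delta* = Phi(-mu_T) - Phi(-mu_C): gradient (-phi(mu_T), phi(mu_C))
  v_exact <- dnorm(0.3)^2 * 0.0041 + dnorm(-0.2)^2 * 0.0037
  expect_equal(v, v_exact, tolerance = 1e-6)
  # zero covariance gives zero variance
  fit0 <- latent_fit(theta, outcomes, cov_theta = matrix(0, 2, 2))
  expect_equal(delta_method_var(fit0, eta = 0), 0)
  # missing covariance is an explicit error
  expect_error(delta_method_var(latent_fit(theta, outcomes), eta = 0),
               class = "lp_error_spec")
  # indefinite covariance is projected with a warning
  bad <- matrix(c(0.004, 0.009, 0.009, 0.004), 2)
  fitb <- latent_fit(theta, outcomes, cov_theta = bad)
  expect_warning(vb <- delta_method_var(fitb, eta = 0), regexp = "PSD")
  expect_gte(vb, 0)
})

test_that("delta-method variance tracks the refit-simulation variance", {
  # single binary outcome: refits have the closed form mu-hat = qnorm(p-hat),
  # so the empirical variance of delta*-hat over many replicates is an
  # independent oracle for the delta-method approximation
  mu_T <- 0.3
  mu_C <- -0.2
  n <- 500
  info_var <- function(mu) {
    p <- pnorm(mu)
    p * (1 - p) / (n * dnorm(mu)^2)
  }
  fit <- latent_fit(c("mu_T.y" = mu_T, "mu_C.y" = mu_C),
                    outcome_binary("y", effect = 0.5),
                    cov_theta = diag(c(info_var(mu_T), info_var(mu_C))),
                    n_T = n, n_C = n)
  v_delta <- delta_method_var(fit, eta = 0)
  set.seed(99)
  reps <- 4000
  d_hat <- replicate(reps, {
    pT <- mean(rnorm(n, mu_T) >= 0)
    pC <- mean(rnorm(n, mu_C) >= 0)
    pnorm(-qnorm(pT)) - pnorm(-qnorm(pC))
  })
  expect_lt(abs(stats::var(d_hat) / v_delta - 1), 0.10)
})

test_that("composite power and sample size invert each other", {
  expect_equal(power_composite(0, sigma2 = 1, n = 100), 0.025)
  expect_equal(power_composite(0.14, 0.048, 49), 0.8855, tolerance = 1e-4)
  # closed-form sizes on the latent scale
  expect_identical(samplesize_composite(0.40, sigma2 = 1), 99L)
  expect_identical(samplesize_composite(0.88, sigma2 = 18), 365L)
  # doubling sigma^2 doubles the pre-ceiling size
  n1 <- 2 * 1 * (qnorm(0.8) + qnorm(0.975))^2 / 0.3^2
  expect_identical(samplesize_composite(0.3, 2), as.integer(ceiling(2 * n1)))
  # inversion certificate on a grid of designs
  for (ds in c(0.1, 0.2, 0.4)) {
    for (s2 in c(0.05, 1)) {
      n <- samplesize_composite(ds, s2)
      expect_gte(power_composite(ds, s2, n), 0.80)
      expect_lt(power_composite(ds, s2, n - 1), 0.80)
    }
  }
  # power grows monotonically to one
  pows <- power_composite(0.2, 1, c(50, 200, 800, 3200))
  expect_true(all(diff(pows) > 0))
  expect_gt(pows[4], 0.99)
  expect_error(samplesize_composite(0, 1), class = "lp_error_infeasible")
  expect_error(samplesize_composite(-0.2, 1), class = "lp_error_infeasible")
})

test_that("the binary-method comparator reproduces the classical formula", {
  expect_identical(binary_method_n(0.6, 0.4), 97L)
  # symmetric under arm swap
  expect_identical(binary_method_n(0.4, 0.6), binary_method_n(0.6, 0.4))
  # vanishing difference explodes the requirement
  expect_gt(binary_method_n(0.501, 0.5), 1e5)
  expect_error(binary_method_n(0.5, 0.5), class = "lp_error_infeasible")
})

test_that("a single binary outcome matches the individual latent pathway", {
  # latent-scale effect 0.40 with unit variance: the composite closed form
  # equals the single-outcome two-sample formula
  expect_identical(samplesize_composite(0.40, sigma2 = 1),
                   as.integer(oracle_single_n(0.40)))
  expect_equal(power_composite(0.40, 1, 99),
               oracle_marginal_power(0.40, 99), tolerance = 1e-12)
})

test_that("sigma^2 is recovered from pilot sample sizes", {
  outcomes <- outcome_binary("y", effect = 0.5)
  theta <- c("mu_T.y" = 0.3, "mu_C.y" = -0.2)
  fit <- latent_fit(theta, outcomes, cov_theta = diag(c(0.004, 0.004)),
                    n_T = 200, n_C = 200)
  ce <- composite_effect(fit, eta = 0)
  expect_equal(ce$sigma2, ce$var_delta * 200 / 2)
  # unbalanced pilots warn about the convention
  fit_u <- latent_fit(theta, outcomes, cov_theta = diag(c(0.004, 0.004)),
                      n_T = 200, n_C = 100)
  expect_warning(composite_effect(fit_u, eta = 0), regexp = "unbalanced")
})
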