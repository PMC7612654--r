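# Shared fixtures and independent oracles for the test suite.

# one continuous + one binary outcome, the workhorse two-outcome design
spec_cont_bin <- function(rho = 0.4, effect1 = 0.5, sd1 = 2,
                          p_T = 0.6, p_C = 0.4) {
  mixed_endpoint(dplyr::bind_rows(
    outcome_continuous("y1", effect = effect1, sd = sd1),
    outcome_binary("y2", prob_T = p_T, prob_C = p_C)
  ), rho = rho)
}

# continuous + three-level ordinal + binary
spec_mixed3 <- function(rho = 0.3, delta = c(0.4, 0.3, 0.3)) {
  mixed_endpoint(dplyr::bind_rows(
    outcome_continuous("c1", effect = delta[1], sd = 1),
    outcome_ordinal("o1", n_levels = 3, effect = delta[2]),
    outcome_binary("b1", effect = delta[3])
  ), rho = rho)
}

# independent closed-form oracles (two-sample one-sided z test, kappa = 1)
oracle_single_n <- function(d, alpha = 0.025, power = 0.80) {
  ceiling(2 * (qnorm(power) + qnorm(1 - alpha))^2 / d^2)
}

oracle_marginal_power <- function(d, n, alpha = 0.025) {
  pnorm(d * sqrt(n / 2) - qnorm(1 - alpha))
}
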