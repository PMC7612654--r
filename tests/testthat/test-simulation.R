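test_that("seeded trials are reproducible and hit their marginal targets", {
  spec <- muse_endpoint()
  d1 <- simulate_trial(spec, 2000, seed = 5)
  d2 <- simulate_trial(spec, 2000, seed = 5)
  expect_identical(d1, d2)
  d3 <- simulate_trial(spec, 2000, seed = 6)
  expect_false(identical(d1, d3))
  # control-arm binary response rate ~ its anchor probability
  pC <- mean(d1$Taper[d1$arm == 0] == 1)
  expect_lt(abs(pC - 0.38), 3 * sqrt(0.38 * 0.62 / 2000))
  # treatment latent shift ~ the latent effect
  dz <- mean(d1$.latent_Taper[d1$arm == 1]) -
    mean(d1$.latent_Taper[d1$arm == 0])
  expect_lt(abs(dz - 0.40), 3 * sqrt(2 / 2000))
  # continuous observed column equals its latent column
  expect_identical(d1$SLEDAI, d1$.latent_SLEDAI)
  # default ordinal thresholds give uniform control category probabilities
  spec_u <- mixed_endpoint(outcome_ordinal("o", n_levels = 4, effect = 0.2))
  du <- simulate_trial(spec_u, 3000, seed = 8)
  tab <- tabulate(du$o[du$arm == 0] + 1L, 4) / 3000
  expect_true(all(abs(tab - 0.25) < 3 * sqrt(0.25 * 0.75 / 3000)))
})

test_that("null trials reproduce the threshold-crossing probabilities", {
  spec <- mixed_endpoint(dplyr::bind_rows(
    outcome_ordinal("o", n_levels = 3, effect = 0,
                    thresholds = c(-0.8, 0.6)),
    outcome_binary("b", effect = 0)
  ), rho = 0.2)
  dat <- simulate_trial(spec, 3000, seed = 21)
  p_lvl0 <- mean(dat$o == 0)
  expect_lt(abs(p_lvl0 - pnorm(-0.8)), 3 * sqrt(0.2 * 0.8 / 6000))
  expect_lt(abs(mean(dat$b == 1) - 0.5), 3 * sqrt(0.25 / 6000))
})

test_that("empirical power agrees with analytic power across a plan grid", {
  plans <- list(
    list(spec = grid_endpoint(rep(0.3, 4), rho = 0), endpoint = "coprimary",
         n = 250),
    list(spec = grid_endpoint(rep(0.3, 4), rho = 0.5), endpoint = "coprimary",
         n = 230),
    list(spec = spec_mixed3(rho = 0.3), endpoint = "coprimary", n = 180),
    list(spec = grid_endpoint(c(0.12, 0.35, 0.55, 0.10), 0.3),
         endpoint = "multiple", n = 67),
    list(spec = spec_mixed3(rho = 0), endpoint = "multiple", n = 110),
    list(spec = muse_endpoint(), endpoint = "multiple", n = 46)
  )
  reps <- 800
  for (i in seq_along(plans)) {
    pl <- plans[[i]]
    res <- empirical_power(pl$spec, pl$n, pl$endpoint, reps = reps,
                           seed = 100 + i)
    expect_lt(abs(res$estimate - res$analytic_power),
              3 * sqrt(res$analytic_power * (1 - res$analytic_power) / reps))
  }
})

test_that("replication settings are recorded and validated", {
  res <- empirical_power(spec_cont_bin(), 50, "coprimary", reps = 150,
                         seed = 4)
  expect_identical(res$reps, 150L)
  expect_identical(res$seed, 4)
  expect_error(empirical_power(spec_cont_bin(), 50, reps = 50),
               class = "lp_error_spec")
  expect_error(empirical_power(spec_cont_bin(), 50, "composite",
                               reps = 200, seed = 1),
               regexp = "eta", class = "lp_error_spec")
})

test_that("observed-surface testing approximates the latent surface", {
  spec <- spec_mixed3(rho = 0.3, delta = c(0.4, 0.35, 0.35))
  lat <- empirical_power(spec, 140, "coprimary", reps = 400, seed = 61,
                         surface = "latent")
  obs <- empirical_power(spec, 140, "coprimary", reps = 400, seed = 61,
                         surface = "observed")
  # thresholding loses information (probit latent-mean estimates carry
  # larger standard errors than the known-variance latent tests), so
  # observed-surface power sits below latent-surface power by a bounded gap
  expect_lte(obs$estimate, lat$estimate + 0.03)
  expect_lte(lat$estimate - obs$estimate, 0.25)
  expect_gt(obs$estimate, 2 * 0.025)
})

test_that("composite empirical decisions calibrate and gain power with n", {
  spec <- spec_cont_bin(rho = 0.3, effect1 = 0, p_T = 0.4, p_C = 0.4)
  eta <- c(0.5, 0)
  null_res <- empirical_power(spec, 150, "composite", reps = 2000, seed = 77,
                              eta = eta)
  expect_lt(abs(null_res$estimate - 0.025), 3 * sqrt(0.025 * 0.975 / 2000))
  spec_eff <- spec_cont_bin(rho = 0.3, effect1 = -0.5, p_T = 0.25, p_C = 0.45)
  small_n <- empirical_power(spec_eff, 60, "composite", reps = 400, seed = 78,
                             eta = eta)
  large_n <- empirical_power(spec_eff, 400, "composite", reps = 400,
                             seed = 78, eta = eta)
  expect_gt(large_n$estimate, small_n$estimate)
  expect_gt(large_n$estimate, 0.95)
})

test_that("empirical FWER matches closed forms and adjustment orderings", {
  reps <- 20000
  f0 <- empirical_fwer(4, rho = 0, reps = reps, seed = 11)
  expect_lt(abs(f0$estimate - (1 - 0.975^4)),
            3 * sqrt(0.0963 * (1 - 0.0963) / reps))
  fb <- empirical_fwer(4, rho = 0, adjustment = "bonferroni", reps = reps,
                       seed = 12)
  expect_lte(fb$estimate, 0.025 + 3 * sqrt(0.025 * 0.975 / reps))
  # near-perfect dependence collapses to a single test
  f99 <- empirical_fwer(3, rho = 0.99, reps = reps, seed = 13)
  expect_lt(abs(f99$estimate - f99$analytic_fwer),
            3 * sqrt(0.03 * 0.97 / reps))
  # Holm controls like Bonferroni for the any-rejection event
  fh <- empirical_fwer(4, rho = 0.3, adjustment = "holm", reps = reps,
                       seed = 14)
  fb2 <- empirical_fwer(4, rho = 0.3, adjustment = "bonferroni", reps = reps,
                        seed = 14)
  expect_equal(fh$estimate, fb2$estimate, tolerance = 1e-12)
  # Holm union power dominates Bonferroni (same seed, same replicates)
  spec <- grid_endpoint(c(0.12, 0.35, 0.55, 0.10), 0.3)
  ph <- empirical_power(spec, 67, "multiple", reps = 1000, seed = 15,
                        design = design_params(adjustment = "holm"))
  pb <- empirical_power(spec, 67, "multiple", reps = 1000, seed = 15,
                        design = design_params(adjustment = "bonferroni"))
  expect_gte(ph$estimate, pb$estimate)
})
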