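test_that("continuous-only fits recover the Gaussian ML moments", {
  spec <- mixed_endpoint(dplyr::bind_rows(
    outcome_continuous("y1", effect = 0.5, sd = 2),
    outcome_continuous("y2", effect = 0.2, sd = 1)
  ), rho = 0.3)
  dat <- simulate_trial(spec, 120, seed = 31)
  fit <- fit_latent_model(dat, spec)
  est <- tidy(fit)
  for (y in c("y1", "y2")) {
    expect_equal(est$estimate[est$term == paste0("mu_T.", y)],
                 mean(dat[[y]][dat$arm == 1]), tolerance = 1e-3)
    expect_equal(est$estimate[est$term == paste0("mu_C.", y)],
                 mean(dat[[y]][dat$arm == 0]), tolerance = 1e-3)
    # ML variance: mean squared deviation about the arm means
    resid2 <- c(dat[[y]][dat$arm == 1] - mean(dat[[y]][dat$arm == 1]),
                dat[[y]][dat$arm == 0] - mean(dat[[y]][dat$arm == 0]))^2
    expect_equal(est$estimate[est$term == paste0("sigma.", y)],
                 sqrt(mean(resid2)), tolerance = 1e-2)
  }
  expect_true(glance(fit)$converged)
})

test_that("binary-only fits are the closed-form probit with matching SEs", {
  spec <- mixed_endpoint(outcome_binary("y", prob_T = 0.6, prob_C = 0.4))
  dat <- simulate_trial(spec, 400, seed = 17)
  fit <- fit_latent_model(dat, spec)
  pT <- mean(dat$y[dat$arm == 1] == 1)
  pC <- mean(dat$y[dat$arm == 0] == 1)
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "mu_T.y"], qnorm(pT),
               tolerance = 1e-4)
  expect_equal(est$estimate[est$term == "mu_C.y"], qnorm(pC),
               tolerance = 1e-4)
  # Fisher information of the saturated probit model
  se_closed <- function(p, n) sqrt(p * (1 - p) / (n * dnorm(qnorm(p))^2))
  expect_equal(est$std.error[est$term == "mu_T.y"], se_closed(pT, 400),
               tolerance = 0.01)
  expect_equal(est$std.error[est$term == "mu_C.y"], se_closed(pC, 400),
               tolerance = 0.01)
})

test_that("parameters are recovered within 3 SE in at least 95% of replicates", {
  spec <- spec_cont_bin(rho = 0.4)
  truth <- c("mu_T.y1" = 0.5, "mu_C.y1" = 0, "sigma.y1" = 2,
             "mu_T.y2" = qnorm(0.6), "mu_C.y2" = qnorm(0.4),
             "rho.y1.y2" = 0.4)
  reps <- 200
  set.seed(2024)
  ok <- vapply(seq_len(reps), function(r) {
    dat <- simulate_trial(spec, 250)
    fit <- tryCatch(fit_latent_model(dat, spec), error = function(e) NULL)
    if (is.null(fit)) return(FALSE)
    est <- tidy(fit)
    all(abs(est$estimate - truth[est$term]) <= 3 * est$std.error)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("refits from jittered starts agree in log-likelihood", {
  spec <- spec_cont_bin()
  dat <- simulate_trial(spec, 80, seed = 55)
  fit0 <- fit_latent_model(dat, spec)
  start0 <- fit0$theta
  set.seed(7)
  for (j in 1:5) {
    start <- start0
    free <- !grepl("^sigma", names(start))
    start[free] <- start[free] + rnorm(sum(free), sd = 0.15)
    start[grepl("^rho", names(start))] <-
      pmin(pmax(start[grepl("^rho", names(start))], -0.9), 0.9)
    fitj <- fit_latent_model(dat, spec, start = start, hessian = FALSE)
    expect_lt(abs(fitj$loglik - fit0$loglik), 1e-4)
  }
})

test_that("a fit with two discrete outcomes matches its generator", {
  spec <- spec_mixed3(rho = 0.3, delta = c(0.4, 0.3, 0.3))
  dat <- simulate_trial(spec, 150, seed = 3)
  fit <- fit_latent_model(dat, spec)
  expect_true(glance(fit)$converged)
  est <- tidy(fit)
  truth <- c("mu_T.c1" = 0.4, "mu_C.c1" = 0, "sigma.c1" = 1,
             "mu_T.o1" = 0.3,
             "tau1.o1" = qnorm(1 / 3), "tau2.o1" = qnorm(2 / 3),
             "mu_T.b1" = 0.3, "mu_C.b1" = 0,
             "rho.c1.o1" = 0.3, "rho.c1.b1" = 0.3, "rho.o1.b1" = 0.3)
  expect_true(all(abs(est$estimate - truth[est$term]) <=
                    4 * est$std.error))
})

test_that("identifiability and input problems raise named errors", {
  spec <- spec_cont_bin()
  dat <- simulate_trial(spec, 60, seed = 9)
  # a level never observed in one arm
  dat_bad <- dat
  dat_bad$y2[dat_bad$arm == 0] <- 1
  expect_error(fit_latent_model(dat_bad, spec), regexp = "y2",
               class = "lp_error_identify")
  # arms must be 0/1
  dat_arm <- dat
  dat_arm$arm[1] <- 2
  expect_error(fit_latent_model(dat_arm, spec), class = "lp_error_spec")
  # too-small arms
  expect_error(fit_latent_model(dat[c(1:5, 61:65), ], spec),
               class = "lp_error_spec")
  # rows with missing values are dropped with a message
  dat_na <- dat
  dat_na$y1[1:3] <- NA
  expect_message(fit_latent_model(dat_na, spec), regexp = "3 rows")
})

test_that("latent test statistics reduce to the classical z and calibrate", {
  spec <- spec_cont_bin(rho = 0.2)
  dat <- simulate_trial(spec, 200, seed = 12)
  zs <- latent_test_statistics(dat, "nominal", spec = spec)
  # continuous entry equals the classical two-sample z with known sigma
  lat1 <- dat$.latent_y1
  z_ref <- (mean(lat1[dat$arm == 1]) - mean(lat1[dat$arm == 0])) /
    (2 * sqrt(2 / 200))
  expect_equal(zs$z[zs$name == "y1"], z_ref, tolerance = 1e-12)
  # model mode needs a covariance
  fit <- fit_latent_model(dat, spec)
  zm <- latent_test_statistics(fit, "model")
  expect_identical(names(zm), c("name", "delta_hat", "se", "z"))
  expect_error(
    latent_test_statistics(latent_fit(fit$theta, spec, n_T = 200, n_C = 200),
                           "model"),
    class = "lp_error_spec"
  )
  # under the global null the latent-surface test rejects at ~alpha
  null_spec <- mixed_endpoint(outcome_binary("y", effect = 0))
  set.seed(81)
  rej <- vapply(seq_len(2500), function(r) {
    d <- simulate_trial(null_spec, 40)
    latent_test_statistics(d, "nominal", spec = null_spec)$z > qnorm(0.975)
  }, logical(1))
  mc_band <- 3 * sqrt(0.025 * 0.975 / 2500)
  expect_lt(abs(mean(rej) - 0.025), mc_band)
})
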