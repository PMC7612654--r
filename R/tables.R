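#' Sample-size table for the lupus trial design study
#'
#' Regenerates the design table for the four-outcome lupus endpoint
#' ([muse_endpoint()]): for each assumed variance pair
#' \eqn{\sigma_1^2 \in \{18, 19, 20\}} (SLEDAI, paired with
#' \eqn{\sigma_2^2 = 0.35}) and \eqn{\sigma_2^2 \in \{0.35, 0.45, 0.55,
#' 0.65\}} (PGA, paired with \eqn{\sigma_1^2 = 18}), the per-group sample
#' size of the co-primary endpoint at one-sided `alpha`, of the multiple
#' primary endpoint with Bonferroni `alpha/4`, and the closed-form
#' single-outcome sizes `ss1..ss4`.
#'
#' @param alpha One-sided significance level.
#' @param target_power Required overall power.
#' @return Tibble with columns `sigma1_sq`, `sigma2_sq`, `n_coprimary`,
#'   `n_multiple`, `ss1`, `ss2`, `ss3`, `ss4`.
#' @examples
#' \donttest{run_table1()}
#' @export
run_table1 <- function(alpha = 0.025, target_power = 0.80) {
  rows <- dplyr::bind_rows(
    tibble::tibble(sigma1_sq = c(18, 19, 20), sigma2_sq = 0.35),
    tibble::tibble(sigma1_sq = 18, sigma2_sq = c(0.45, 0.55, 0.65))
  )
  rows <- dplyr::distinct(rows)
  purrr::pmap_dfr(rows, function(sigma1_sq, sigma2_sq) {
    spec <- muse_endpoint(sigma1_sq, sigma2_sq)
    des_co <- design_params(alpha, target_power, adjustment = "none")
    des_mult <- design_params(alpha, target_power, adjustment = "bonferroni")
    d <- standardized_effects(spec)$effect_std
    tibble::tibble(
      sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
      n_coprimary = samplesize_coprimary(spec, des_co)$n_per_group,
      n_multiple = samplesize_multiple(spec, des_mult)$n_per_group,
      ss1 = single_outcome_n(d[1], alpha, target_power),
      ss2 = single_outcome_n(d[2], alpha, target_power),
      ss3 = single_outcome_n(d[3], alpha, target_power),
      ss4 = single_outcome_n(d[4], alpha, target_power)
    )
  })
}

#' Sample-size grid over effect patterns and equicorrelation
#'
#' Regenerates the four-outcome sample-size grid: for each standardized
#' effect pattern and equicorrelation \eqn{\rho \in \{0, 0.3, 0.5, 0.8\}},
#' the co-primary per-group size and the Bonferroni multiple-primary size,
#' optionally with seeded empirical power (latent surface) at the chosen
#' sizes.
#'
#' @param deltas List of length-4 standardized effect vectors (continuous,
#'   continuous, ordinal, binary).
#' @param rho Equicorrelation values.
#' @param empirical Add Monte-Carlo power columns at the returned sizes.
#' @param reps,seed Simulation settings used when `empirical = TRUE`.
#' @inheritParams run_table1
#' @return Tibble with one row per (effect pattern, rho).
#' @examples
#' \donttest{run_table2(deltas = list(rep(0.12, 4)), rho = c(0, 0.8))}
#' @export
run_table2 <- function(deltas = list(rep(0.12, 4),
                                     c(0.35, 0.35, 0.15, 0.15),
                                     c(0.12, 0.35, 0.55, 0.10)),
                       rho = c(0, 0.3, 0.5, 0.8),
                       alpha = 0.025, target_power = 0.80,
                       empirical = FALSE, reps = 10000, seed = NULL) {
  grid <- tidyr::expand_grid(block = seq_along(deltas), rho = rho)
  purrr::pmap_dfr(grid, function(block, rho) {
    spec <- grid_endpoint(deltas[[block]], rho)
    des_co <- design_params(alpha, target_power, adjustment = "none")
    des_mult <- design_params(alpha, target_power, adjustment = "bonferroni")
    n_co <- samplesize_coprimary(spec, des_co)$n_per_group
    n_mult <- samplesize_multiple(spec, des_mult)$n_per_group
    out <- tibble::tibble(
      block = block,
      delta = paste(format(deltas[[block]], trim = TRUE), collapse = "/"),
      rho = rho, n_coprimary = n_co, n_multiple = n_mult
    )
    if (empirical) {
      out$power_coprimary <- empirical_power(
        spec, n_co, "coprimary", reps = reps, seed = seed,
        design = des_co)$estimate * 100
      out$power_multiple <- empirical_power(
        spec, n_mult, "multiple", reps = reps, seed = seed,
        design = des_mult)$estimate * 100
    }
    out
  })
}

#' Power as a function of sample size
#'
#' Evaluates the analytic power of the chosen endpoints over a grid of
#' per-group sample sizes, in long format for plotting
#' ([plot_power_curve()]). `"individual"` adds one curve per outcome
#' (marginal one-sided z test at `alpha`).
#'
#' @param spec A [mixed_endpoint()].
#' @param n Integer vector of per-group sizes.
#' @param endpoints Subset of `"coprimary"`, `"multiple"`, `"individual"`.
#' @param design [design_params()].
#' @return Tibble with columns `endpoint`, `n`, `power`.
#' @export
power_curve <- function(spec, n,
                        endpoints = c("coprimary", "multiple", "individual"),
                        design = design_params()) {
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  design <- as_design(design)
  out <- list()
  if ("coprimary" %in% endpoints) {
    out$co <- tibble::tibble(
      endpoint = "coprimary", n = n,
      power = vapply(n, function(ni) power_coprimary(spec, ni, design)$power,
                     numeric(1)))
  }
  if ("multiple" %in% endpoints) {
    out$mult <- tibble::tibble(
      endpoint = "multiple", n = n,
      power = vapply(n, function(ni) {
        power_union(spec, ni, design, method = "complement")$power
      }, numeric(1)))
  }
  if ("individual" %in% endpoints) {
    d <- standardized_effects(spec)
    kappa <- spec$alloc_ratio
    out$ind <- purrr::map_dfr(seq_len(spec$K), function(k) {
      tibble::tibble(
        endpoint = d$name[k], n = n,
        power = pnorm(d$effect_std[k] * sqrt(kappa * n / (1 + kappa)) -
                        qnorm(1 - design$alpha)))
    })
  }
  dplyr::bind_rows(out)
}
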