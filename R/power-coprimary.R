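#' Shifted critical values for the latent z tests
#'
#' For per-group treatment size `n_T` and allocation ratio \eqn{\kappa =
#' n_C/n_T}, the one-sided z test for outcome k rejects when \eqn{Z_k >
#' z_\alpha}; centring at the alternative gives the shifted critical value
#' \deqn{z_k^\dagger = z_\alpha - d_k \sqrt{\kappa n_T / (1 + \kappa)},}
#' where \eqn{d_k} is the standardized effect ([standardized_effects()]).
#' The joint law of the centred statistics is N(0, \eqn{\Gamma}), so every
#' endpoint-level power is an orthant probability in \eqn{z^\dagger}.
#'
#' @param spec A [mixed_endpoint()].
#' @param n_T Treatment-arm sample size (per group when \eqn{\kappa = 1}).
#' @param alpha_each One-sided level of each outcome-level test.
#' @return Named K-vector of shifted critical values.
#' @export
shifted_criticals <- function(spec, n_T, alpha_each = 0.025) {
  validate_mixed_endpoint(spec)
  if (!is_number(n_T) || n_T < 2) {
    lp_abort("n_T must be at least 2", class = "lp_error_spec")
  }
  d <- standardized_effects(spec)
  kappa <- spec$alloc_ratio
  shift <- sqrt(kappa * n_T / (1 + kappa))
  setNames(qnorm(1 - alpha_each) - d$effect_std * shift, d$name)
}

new_mixed_power <- function(endpoint_type, spec, n_T, design, alpha_each,
                            power, quadrature_error, extra = list()) {
  structure(
    c(list(endpoint_type = endpoint_type,
           power = as.numeric(power),
           n_per_group = as.integer(n_T),
           n_control = as.integer(ceiling(spec$alloc_ratio * n_T)),
           alpha = design$alpha,
           alpha_each = alpha_each,
           adjustment = design$adjustment,
           shifted_criticals = shifted_criticals(spec, n_T, alpha_each),
           quadrature_error = as.numeric(quadrature_error),
           spec = spec),
      extra),
    class = "mixed_power"
  )
}

#' @export
print.mixed_power <- function(x, ...) {
  cat("<mixed_power>", x$endpoint_type,
      "endpoint, K =", x$spec$K, "\n")
  cat(sprintf("  n per group = %d (control %d), alpha = %g (per test %g, %s)\n",
              x$n_per_group, x$n_control, x$alpha, x$alpha_each,
              x$adjustment))
  cat(sprintf("  power = %.4f (quadrature error %.2g)\n",
              x$power, x$quadrature_error))
  invisible(x)
}

#' Co-primary (intersection) endpoint power
#'
#' Power of the intersection test that declares success only when all K
#' outcome-level one-sided z tests reject at level `alpha`:
#' \deqn{1 - \beta = \Phi_K(-z_1^\dagger, \ldots, -z_K^\dagger; \Gamma),}
#' evaluated by deterministic multivariate-normal quadrature. With K = 1
#' this reduces to \eqn{\Phi(-z_1^\dagger)}.
#'
#' @param spec A [mixed_endpoint()].
#' @param n_T Treatment-arm size; with allocation ratio 1 this is the common
#'   per-group size.
#' @param design [design_params()]; co-primary testing needs no multiplicity
#'   adjustment (intersection tests control the type I error at `alpha`).
#' @return A `mixed_power` object; see [tidy.mixed_power()] and
#'   [glance.mixed_power()].
#' @examples
#' power_coprimary(muse_endpoint(), n_T = 403)
#' @export
power_coprimary <- function(spec, n_T, design = design_params()) {
  design <- as_design(design)
  zk <- shifted_criticals(spec, n_T, alpha_each = design$alpha)
  p <- mvn_upper_orthant(zk, spec$corr)
  new_mixed_power("coprimary", spec, n_T, design,
                  alpha_each = design$alpha, power = p,
                  quadrature_error = attr(p, "error"),
                  extra = list(marginal_power = pnorm(-zk)))
}

# Monotone integer search shared by the sample-size functions.
# power_fn(n) must be nondecreasing in n; n_lower is a certified lower bound.
samplesize_search <- function(power_fn, target, n_lower = 2L,
                              n_max = 5e6) {
  n_lower <- max(2L, as.integer(n_lower))
  evals <- list()
  eval_power <- function(n) {
    p <- power_fn(n)
    evals[[length(evals) + 1L]] <<- c(n = n, power = p)
    p
  }
  hi <- n_lower
  p_hi <- eval_power(hi)
  while (p_hi < target) {
    if (hi >= n_max) {
      lp_abort("target power not reachable below n_max; check effects",
               class = "lp_error_infeasible")
    }
    hi <- min(2L * hi, as.integer(n_max))
    p_hi <- eval_power(hi)
  }
  lo <- max(2L, if (hi == n_lower) n_lower - 1L else hi %/% 2L)
  # invariant: power(lo) < target (or lo is the floor), power(hi) >= target
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (eval_power(mid) >= target) hi <- mid else lo <- mid
  }
  p_below <- if (hi > 2L) power_fn(hi - 1L) else NA_real_
  curve <- tibble::as_tibble(do.call(rbind, evals))
  curve <- dplyr::arrange(dplyr::distinct(curve, .data$n, .keep_all = TRUE),
                          .data$n)
  list(n = hi, achieved_power = power_fn(hi),
       power_at_n_minus_1 = p_below, curve = curve)
}

new_mixed_samplesize <- function(endpoint_type, spec, design, search,
                                 alpha_each) {
  structure(
    list(endpoint_type = endpoint_type,
         n_per_group = as.integer(search$n),
         n_control = as.integer(ceiling(spec$alloc_ratio * search$n)),
         achieved_power = search$achieved_power,
         power_at_n_minus_1 = search$power_at_n_minus_1,
         target_power = design$target_power,
         alpha = design$alpha,
         alpha_each = alpha_each,
         adjustment = design$adjustment,
         curve = search$curve,
         spec = spec),
    class = "mixed_samplesize"
  )
}

#' @export
print.mixed_samplesize <- function(x, ...) {
  cat("<mixed_samplesize>", x$endpoint_type, "endpoint\n")
  cat(sprintf("  smallest n per group = %d (control %d) for power >= %g\n",
              x$n_per_group, x$n_control, x$target_power))
  cat(sprintf("  achieved power %.4f; power at n - 1: %.4f\n",
              x$achieved_power, x$power_at_n_minus_1))
  invisible(x)
}

# closed-form per-group n for a single standardized effect (kappa-scaled)
single_outcome_n <- function(d, alpha, target_power, kappa = 1) {
  ceiling((1 + kappa) / kappa * (qnorm(target_power) + qnorm(1 - alpha))^2 / d^2)
}

#' Co-primary sample size
#'
#' Smallest per-group sample size whose intersection-test power reaches the
#' target. The search starts from the largest single-outcome closed-form
#' size (a certified lower bound, since joint power cannot exceed any
#' marginal power), then brackets upward and bisects on the integer
#' lattice; the result carries a minimality certificate (power at `n - 1`
#' falls short of the target).
#'
#' @inheritParams power_coprimary
#' @return A `mixed_samplesize` object with the evaluated power curve for
#'   audit ([autoplot.mixed_samplesize()]).
#' @examples
#' samplesize_coprimary(muse_endpoint())
#' @export
samplesize_coprimary <- function(spec, design = design_params()) {
  design <- as_design(design)
  d <- standardized_effects(spec)
  if (any(d$effect_std <= 0)) {
    bad <- d$name[d$effect_std <= 0][1]
    lp_abort(paste0("co-primary target power is unreachable: outcome '", bad,
                    "' has a nonpositive standardized effect"),
             class = "lp_error_infeasible")
  }
  n0 <- max(single_outcome_n(d$effect_std, design$alpha, design$target_power,
                             spec$alloc_ratio))
  search <- samplesize_search(
    function(n) power_coprimary(spec, n, design)$power,
    target = design$target_power, n_lower = n0
  )
  new_mixed_samplesize("coprimary", spec, design, search,
                       alpha_each = design$alpha)
}
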