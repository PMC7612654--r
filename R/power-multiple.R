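#' Multiple primary (union) endpoint power
#'
#' Power of the union-intersection test that declares success when at least
#' one outcome-level one-sided z test rejects at the multiplicity-adjusted
#' level (Bonferroni: `alpha / K`). The power is computed two ways and
#' cross-checked: by inclusion-exclusion over all nonempty outcome subsets,
#' each term an orthant probability
#' \deqn{P\Big(\bigcup_k \{Z_k^\dagger > z_k^\dagger\}\Big) =
#'   \sum_{i=1}^{K} (-1)^{i-1} \sum_{|I| = i}
#'   P\Big(\bigcap_{k \in I} \{Z_k^\dagger > z_k^\dagger\}\Big),}
#' and by the complement identity \eqn{1 - \Phi_K(z^\dagger; \Gamma)}. The
#' two paths must agree within `1e-6`; the complement value is reported.
#'
#' @inheritParams power_coprimary
#' @param design [design_params()]; `adjustment` sets the per-test level
#'   (`"bonferroni"` = `alpha/K`, `"none"` = `alpha`). Holm has no closed
#'   form; request it through [empirical_power()].
#' @param method `"both"` (default) runs inclusion-exclusion plus the
#'   complement cross-check; `"complement"` skips enumeration (required for
#'   K > 12, where the subset count blows up).
#' @return A `mixed_power` object with elements `power_ie` and
#'   `ie_discrepancy` when both paths run.
#' @examples
#' power_union(muse_endpoint(), n_T = 46)
#' @export
power_union <- function(spec, n_T, design = design_params(),
                        method = c("both", "complement")) {
  design <- as_design(design)
  method <- match.arg(method)
  if (design$adjustment == "holm") {
    lp_abort(paste0("Holm step-down power has no closed form; ",
                    "use empirical_power(..., adjustment = 'holm')"),
             class = "lp_error_spec")
  }
  alpha_each <- if (design$adjustment == "bonferroni") {
    design$alpha / spec$K
  } else {
    design$alpha
  }
  if (method == "both" && spec$K > 12) {
    lp_abort(paste0("inclusion-exclusion over 2^K subsets is refused for ",
                    "K > 12; call power_union(method = 'complement')"),
             class = "lp_error_spec")
  }
  zk <- shifted_criticals(spec, n_T, alpha_each = alpha_each)
  comp <- mvn_cdf(zk, spec$corr)
  p_union <- 1 - as.numeric(comp)
  extra <- list(marginal_power = pnorm(-zk))
  if (method == "both") {
    p_ie <- union_power_incl_excl(zk, spec$corr)
    disc <- abs(p_ie - p_union)
    if (disc > 1e-5) {
      lp_abort(sprintf(paste0("inclusion-exclusion and complement paths ",
                              "disagree by %.2g (tolerance 1e-5)"), disc),
               class = "lp_error_numeric")
    }
    extra$power_ie <- p_ie
    extra$ie_discrepancy <- disc
  }
  new_mixed_power("multiple", spec, n_T, design, alpha_each = alpha_each,
                  power = p_union, quadrature_error = attr(comp, "error"),
                  extra = extra)
}

# inclusion-exclusion over nonempty subsets, ordered by subset size
union_power_incl_excl <- function(zk, corr) {
  K <- length(zk)
  total <- 0
  for (size in seq_len(K)) {
    subsets <- utils::combn(K, size, simplify = FALSE)
    orthants <- vapply(subsets, function(idx) {
      as.numeric(mvn_upper_orthant(zk[idx], corr[idx, idx, drop = FALSE]))
    }, numeric(1))
    total <- total + (-1)^(size - 1) * sum(orthants)
  }
  total
}

#' Multiple primary sample size
#'
#' Smallest per-group sample size whose union-test power (at the adjusted
#' per-test level) reaches the target. Search by exponential bracketing and
#' integer bisection on the complement-form power, with a minimality
#' certificate.
#'
#' @inheritParams power_union
#' @return A `mixed_samplesize` object.
#' @examples
#' samplesize_multiple(muse_endpoint())
#' @export
samplesize_multiple <- function(spec, design = design_params()) {
  design <- as_design(design)
  d <- standardized_effects(spec)
  if (all(d$effect_std <= 0)) {
    lp_abort("union target power is unreachable: no outcome has a positive standardized effect",
             class = "lp_error_infeasible")
  }
  search <- samplesize_search(
    function(n) power_union(spec, n, design, method = "complement")$power,
    target = design$target_power, n_lower = 2L
  )
  alpha_each <- if (design$adjustment == "bonferroni") {
    design$alpha / spec$K
  } else {
    design$alpha
  }
  new_mixed_samplesize("multiple", spec, design, search,
                       alpha_each = alpha_each)
}

#' Analytic family-wise error rate under the global null
#'
#' With all treatment effects fixed at zero, the K one-sided tests at
#' per-test level \eqn{\alpha'} (`alpha` unadjusted, `alpha / K` for
#' Bonferroni) have jointly normal statistics with correlation \eqn{\Gamma},
#' so \deqn{\mathrm{FWER} = 1 - \Phi_K(z_{\alpha'}, \ldots, z_{\alpha'};
#' \Gamma).} Holm has no closed form; use [empirical_fwer()].
#'
#' @param K Number of outcomes.
#' @param corr Correlation matrix of the test statistics; or give `rho`.
#' @param rho Equicorrelation shorthand.
#' @param alpha Nominal one-sided family level.
#' @param adjustment `"none"` or `"bonferroni"`.
#' @return One-row tibble: `K`, `rho`, `alpha`, `adjustment`, `alpha_each`,
#'   `fwer`.
#' @examples
#' fwer_analytic(K = 4, rho = 0, alpha = 0.025)                  # ~ 0.0963
#' fwer_analytic(K = 4, rho = 0, adjustment = "bonferroni")      # <= 0.025
#' @export
fwer_analytic <- function(K, corr = NULL, rho = NULL, alpha = 0.025,
                          adjustment = c("none", "bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  if (adjustment == "holm") {
    lp_abort("Holm FWER has no closed form; use empirical_fwer(adjustment = 'holm')",
             class = "lp_error_spec")
  }
  if (is.null(corr)) {
    if (is.null(rho)) rho <- 0
    corr <- equicorr(K, rho)
  } else {
    rho <- NA_real_
  }
  if (min_eigenvalue(corr) <= 1e-10) {
    lp_abort("corr must be positive definite", class = "lp_error_corr")
  }
  alpha_each <- if (adjustment == "bonferroni") alpha / K else alpha
  fwer <- 1 - as.numeric(mvn_cdf(rep(qnorm(1 - alpha_each), K), corr))
  tibble::tibble(K = as.integer(K), rho = rho, alpha = alpha,
                 adjustment = adjustment, alpha_each = alpha_each,
                 fwer = fwer)
}

#' FWER over a correlation-by-K grid
#'
#' Convenience wrapper mapping [fwer_analytic()] over equicorrelation values
#' and outcome counts, e.g. to study how unadjusted type I error inflation
#' grows with K and shrinks with correlation.
#'
#' @param K Integer vector of outcome counts.
#' @param rho Numeric vector of equicorrelations.
#' @inheritParams fwer_analytic
#' @return Tibble with one row per (K, rho) combination.
#' @examples
#' fwer_grid(K = 2:4, rho = c(0, 0.3, 0.5, 0.8))
#' @export
fwer_grid <- function(K = 2:4, rho = seq(0, 0.8, by = 0.1), alpha = 0.025,
                      adjustment = "none") {
  grid <- tidyr::expand_grid(K = as.integer(K), rho = rho)
  purrr::pmap_dfr(grid, function(K, rho) {
    fwer_analytic(K = K, rho = rho, alpha = alpha, adjustment = adjustment)
  })
}
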