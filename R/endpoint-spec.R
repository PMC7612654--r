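#' Describe a single trial outcome
#'
#' A mixed endpoint is assembled from one-row outcome descriptions, one per
#' component, bound together with [dplyr::bind_rows()] and passed to
#' [mixed_endpoint()]. Continuous outcomes are specified on the observed
#' scale (difference in means and standard deviation); ordinal and binary
#' outcomes live on a latent standard-normal scale, observed only through
#' threshold crossings, and their treatment effect is the difference in
#' latent means \eqn{\delta^* = \Phi^{-1}(\pi_T) - \Phi^{-1}(\pi_C)}, where
#' \eqn{\pi} is the response probability in each arm.
#'
#' For discrete outcomes supply either the per-arm response probabilities
#' (`prob_T`, `prob_C`) or the latent effect directly (`effect`); if both
#' are given, `effect` is used as-is and the probabilities are kept as
#' simulation anchors (the control-arm rate pins the control latent mean).
#' The response event is the upper tail of the latent scale: a binary
#' response is `Y = 1` (latent value at or above the threshold at 0), and an
#' ordinal response is an upper level set `{response_level, ..., w}`
#' (default: the top level only). Positive effects always favour treatment.
#'
#' @param name Outcome name (column name in trial data).
#' @param effect Treatment-minus-control effect. Observed-scale mean
#'   difference for continuous outcomes; latent-scale difference
#'   \eqn{\delta^*} for ordinal/binary outcomes (optional when
#'   probabilities are given).
#' @param sd Standard deviation of a continuous outcome (design input,
#'   treated as known). Discrete latent variances are fixed at 1 for
#'   identifiability and are not settable.
#' @param prob_T,prob_C Response probabilities per arm, strictly inside
#'   (0, 1). Values of exactly 0 or 1 are rejected (the latent effect is
#'   unbounded there).
#' @param n_levels Number of ordinal categories \eqn{w + 1 \ge 2}; levels
#'   are coded `0..w`.
#' @param thresholds Strictly increasing vector of `w` latent cut-points for
#'   an ordinal outcome. Default: standard-normal quantile cuts giving
#'   uniform category probabilities in the control arm. Binary outcomes
#'   have a single threshold fixed at 0.
#' @param response_level First level of the (contiguous, upper) level set
#'   counted as response for an ordinal outcome; default `n_levels - 1`
#'   (top level only).
#' @param responder_cut Responder threshold \eqn{\eta} used only by the
#'   composite endpoint (response means falling at or below the cut).
#' @return A one-row tibble describing the outcome.
#' @seealso [mixed_endpoint()], [standardized_effects()]
#' @examples
#' outcome_continuous("SLEDAI", effect = 0.88, sd = sqrt(18))
#' outcome_binary("Taper", prob_T = 0.54, prob_C = 0.38)
#' outcome_ordinal("BILAG", n_levels = 5, effect = 0.24)
#' @export
outcome_continuous <- function(name, effect, sd, responder_cut = NA_real_) {
  if (!is_number(effect)) {
    lp_abort(paste0("continuous outcome '", name, "' needs a finite effect"),
             class = "lp_error_spec")
  }
  if (!is_number(sd) || sd <= 0) {
    lp_abort(paste0("continuous outcome '", name, "' needs sd > 0"),
             class = "lp_error_spec")
  }
  new_outcome_row(name, "continuous", effect_obs = effect, sd = sd,
                  responder_cut = responder_cut)
}

#' @rdname outcome_continuous
#' @export
outcome_ordinal <- function(name, n_levels, prob_T = NULL, prob_C = NULL,
                            effect = NULL, thresholds = NULL,
                            response_level = NULL,
                            responder_cut = NA_real_) {
  if (!is_number(n_levels) || n_levels < 2 || n_levels != round(n_levels)) {
    lp_abort(paste0("ordinal outcome '", name, "' needs an integer number of levels >= 2"),
             class = "lp_error_spec")
  }
  w <- as.integer(n_levels) - 1L
  if (is.null(thresholds)) {
    thresholds <- qnorm(seq_len(w) / (w + 1))
  }
  if (length(thresholds) != w || any(diff(thresholds) <= 0)) {
    lp_abort(paste0("ordinal outcome '", name, "' needs ", w,
                    " strictly increasing thresholds"),
             class = "lp_error_threshold")
  }
  response_level <- as.integer(response_level %||% w)
  if (response_level < 1L || response_level > w) {
    lp_abort(paste0("response_level for '", name, "' must be in 1..", w),
             class = "lp_error_spec")
  }
  new_discrete_row(name, "ordinal", prob_T, prob_C, effect,
                   n_levels = as.integer(n_levels), thresholds = thresholds,
                   response_level = response_level,
                   responder_cut = responder_cut)
}

#' @rdname outcome_continuous
#' @export
outcome_binary <- function(name, prob_T = NULL, prob_C = NULL, effect = NULL,
                           responder_cut = NA_real_) {
  new_discrete_row(name, "binary", prob_T, prob_C, effect,
                   n_levels = 2L, thresholds = 0,
                   response_level = 1L, responder_cut = responder_cut)
}

new_discrete_row <- function(name, kind, prob_T, prob_C, effect, n_levels,
                             thresholds, response_level, responder_cut) {
  have_probs <- !is.null(prob_T) || !is.null(prob_C)
  if (have_probs) {
    check_prob(prob_T, "prob_T", name)
    check_prob(prob_C, "prob_C", name)
  }
  if (is.null(effect) && !have_probs) {
    lp_abort(paste0(kind, " outcome '", name,
                    "' needs response probabilities or a latent effect"),
             class = "lp_error_spec")
  }
  if (!is.null(effect) && !is_number(effect)) {
    lp_abort(paste0("latent effect for '", name, "' must be a finite number"),
             class = "lp_error_spec")
  }
  new_outcome_row(name, kind,
                  prob_T = prob_T %||% NA_real_,
                  prob_C = prob_C %||% NA_real_,
                  effect_latent = effect %||% NA_real_,
                  n_levels = n_levels, thresholds = thresholds,
                  response_level = response_level,
                  responder_cut = responder_cut)
}

new_outcome_row <- function(name, kind, effect_obs = NA_real_, sd = NA_real_,
                            prob_T = NA_real_, prob_C = NA_real_,
                            effect_latent = NA_real_, n_levels = NA_integer_,
                            thresholds = NULL, response_level = NA_integer_,
                            responder_cut = NA_real_) {
  tibble::tibble(
    name = as.character(name), kind = kind,
    effect_obs = effect_obs, sd = sd,
    prob_T = prob_T, prob_C = prob_C,
    effect_latent = effect_latent,
    n_levels = n_levels,
    thresholds = list(thresholds),
    response_level = response_level,
    responder_cut = responder_cut
  )
}

#' Assemble a mixed-outcome endpoint
#'
#' Bundles the per-outcome descriptions with the latent correlation matrix
#' and the allocation ratio into the single specification object consumed by
#' every power, sample-size and simulation function. Outcomes must be
#' ordered continuous, then ordinal, then binary. A single correlation
#' matrix is shared by both arms; correlations between mixed pairs are
#' interpreted on the latent scale.
#'
#' @param outcomes Tibble of outcome rows from [outcome_continuous()],
#'   [outcome_ordinal()], [outcome_binary()] (bind them with
#'   [dplyr::bind_rows()]).
#' @param corr K-by-K latent correlation matrix (unit diagonal, positive
#'   definite). Supplying a list of two matrices (one per arm) is rejected:
#'   the model shares one matrix across arms.
#' @param rho Scalar equicorrelation shorthand, used when `corr` is `NULL`.
#' @param alloc_ratio Allocation ratio \eqn{\kappa = n_C / n_T} (default 1).
#' @return An object of class `mixed_endpoint` with elements `outcomes`
#'   (tibble), `corr`, `alloc_ratio`, and counts `K`, `k_m` (continuous),
#'   `k_o` (continuous + ordinal).
#' @examples
#' spec <- mixed_endpoint(
#'   dplyr::bind_rows(
#'     outcome_continuous("y1", effect = 0.5, sd = 1),
#'     outcome_binary("y2", prob_T = 0.6, prob_C = 0.4)
#'   ),
#'   rho = 0.3
#' )
#' spec
#' @export
mixed_endpoint <- function(outcomes, corr = NULL, rho = NULL, alloc_ratio = 1) {
  if (!is.data.frame(outcomes) || nrow(outcomes) == 0) {
    lp_abort("`outcomes` must be a non-empty tibble of outcome rows",
             class = "lp_error_spec")
  }
  K <- nrow(outcomes)
  if (is.list(corr) && !is.matrix(corr)) {
    lp_abort(paste0("a single correlation matrix is shared by both arms; ",
                    "arm-specific matrices are not supported"),
             class = "lp_error_corr")
  }
  if (is.null(corr)) {
    corr <- if (is.null(rho)) diag(K) else equicorr(K, rho)
  }
  spec <- structure(
    list(outcomes = tibble::as_tibble(outcomes),
         corr = unname(as.matrix(corr)),
         alloc_ratio = alloc_ratio,
         K = K,
         k_m = sum(outcomes$kind == "continuous"),
         k_o = sum(outcomes$kind != "binary")),
    class = "mixed_endpoint"
  )
  validate_mixed_endpoint(spec)
}

#' Validate a mixed endpoint specification
#'
#' Checks outcome ordering (continuous, then ordinal, then binary),
#' probability ranges, threshold monotonicity and positive-definiteness of
#' the correlation matrix (smallest eigenvalue above `1e-10`). Each violated
#' invariant raises a distinct condition class (`lp_error_ordering`,
#' `lp_error_prob`, `lp_error_threshold`, `lp_error_corr`, `lp_error_spec`).
#'
#' @param spec A `mixed_endpoint` object.
#' @return The validated spec, invisibly annotated (returned unchanged).
#' @export
validate_mixed_endpoint <- function(spec) {
  oc <- spec$outcomes
  K <- spec$K
  kind_rank <- c(continuous = 1L, ordinal = 2L, binary = 3L)
  if (!all(oc$kind %in% names(kind_rank))) {
    lp_abort("outcome kind must be continuous, ordinal or binary",
             class = "lp_error_spec")
  }
  if (is.unsorted(kind_rank[oc$kind])) {
    lp_abort("outcomes must be ordered continuous, then ordinal, then binary",
             class = "lp_error_ordering")
  }
  if (anyDuplicated(oc$name)) {
    lp_abort("outcome names must be unique", class = "lp_error_spec")
  }
  for (i in seq_len(K)) {
    row <- oc[i, ]
    if (row$kind == "continuous") {
      if (!is_number(row$sd) || row$sd <= 0) {
        lp_abort(paste0("sd for '", row$name, "' must be > 0"),
                 class = "lp_error_spec")
      }
    } else {
      if (!is.na(row$prob_T)) check_prob(row$prob_T, "prob_T", row$name)
      if (!is.na(row$prob_C)) check_prob(row$prob_C, "prob_C", row$name)
      thr <- row$thresholds[[1]]
      if (length(thr) != row$n_levels - 1L || any(diff(thr) <= 0)) {
        lp_abort(paste0("thresholds for '", row$name,
                        "' must be strictly increasing with one cut per level boundary"),
                 class = "lp_error_threshold")
      }
      if (row$kind == "binary" && !identical(unname(thr), 0)) {
        lp_abort(paste0("binary outcome '", row$name,
                        "' has its threshold fixed at 0"),
                 class = "lp_error_threshold")
      }
    }
  }
  corr <- spec$corr
  if (!is.matrix(corr) || nrow(corr) != K || ncol(corr) != K ||
      max(abs(corr - t(corr))) > 1e-8 || any(abs(diag(corr) - 1) > 1e-12)) {
    lp_abort("corr must be a symmetric K x K matrix with unit diagonal",
             class = "lp_error_corr")
  }
  off <- corr[upper.tri(corr)]
  if (length(off) && any(abs(off) >= 1)) {
    lp_abort("off-diagonal correlations must lie in (-1, 1)",
             class = "lp_error_corr")
  }
  if (min_eigenvalue(corr) <= 1e-10) {
    lp_abort("corr must be positive definite (smallest eigenvalue > 1e-10)",
             class = "lp_error_corr")
  }
  if (!is_number(spec$alloc_ratio) || spec$alloc_ratio <= 0) {
    lp_abort("alloc_ratio must be a positive number", class = "lp_error_spec")
  }
  invisible(spec)
}

#' @export
print.mixed_endpoint <- function(x, ...) {
  cat("<mixed_endpoint> K =", x$K,
      "(continuous:", x$k_m,
      "ordinal:", x$k_o - x$k_m,
      "binary:", x$K - x$k_o, ")\n")
  print(dplyr::select(x$outcomes, "name", "kind", "effect_obs", "sd",
                      "prob_T", "prob_C", "effect_latent"))
  cat("alloc_ratio (nC/nT):", x$alloc_ratio, "\n")
  if (x$K > 1) {
    cat("latent correlations:\n")
    print(round(x$corr, 3))
  }
  invisible(x)
}

#' Design parameters for hypothesis testing
#'
#' One-sided superiority testing throughout: `alpha` is the one-sided
#' significance level (default 0.025) and `target_power` the required
#' overall power. `adjustment` applies to multiple primary (union) testing
#' only: Bonferroni tests each outcome at `alpha / K`; Holm has no closed
#' form and is available through the simulation functions.
#'
#' @param alpha One-sided significance level in (0, 0.5].
#' @param target_power Required power in (0, 1).
#' @param adjustment Multiplicity adjustment for union testing:
#'   `"bonferroni"` (default), `"none"`, or `"holm"`.
#' @return A `design_params` list.
#' @export
design_params <- function(alpha = 0.025, target_power = 0.80,
                          adjustment = c("bonferroni", "none", "holm")) {
  adjustment <- match.arg(adjustment)
  if (!is_number(alpha) || alpha <= 0 || alpha > 0.5) {
    lp_abort("alpha must lie in (0, 0.5]", class = "lp_error_spec")
  }
  if (!is_number(target_power) || target_power <= 0 || target_power >= 1) {
    lp_abort("target_power must lie in (0, 1)", class = "lp_error_spec")
  }
  structure(list(alpha = alpha, target_power = target_power,
                 adjustment = adjustment),
            class = "design_params")
}

as_design <- function(design) {
  if (inherits(design, "design_params")) return(design)
  do.call(design_params, as.list(design))
}

# ---- observed <-> latent transforms ---------------------------------------

#' Latent-scale transforms for discrete outcomes
#'
#' `latent_mean_from_prob()` maps a response probability to the latent mean
#' \eqn{\mu^* = \Phi^{-1}(\pi)}; `latent_effect_from_probs()` gives the
#' latent treatment effect \eqn{\delta^* = \Phi^{-1}(\pi_T) -
#' \Phi^{-1}(\pi_C)}; `ordinal_category_prob()` evaluates the probability
#' that a latent N(`mu_star`, 1) variable falls in a contiguous set of
#' ordinal levels given the threshold vector (with implicit cuts at
#' \eqn{\pm\infty}).
#'
#' @param pi,pi_T,pi_C Response probabilities, strictly inside (0, 1).
#' @param outcome Optional outcome name used in error messages.
#' @param thresholds Strictly increasing latent cut-points (length `w` for
#'   `w + 1` levels).
#' @param mu_star Latent mean.
#' @param levels Contiguous integer levels in `0..w` whose total probability
#'   is required.
#' @return A single probability or latent-scale real.
#' @examples
#' latent_effect_from_probs(0.54, 0.38)  # Taper effect ~ 0.41
#' ordinal_category_prob(c(-1, 1), mu_star = 0, levels = 1)
#' @export
latent_mean_from_prob <- function(pi, outcome = NULL) {
  check_prob(pi, "response probability", outcome)
  qnorm(pi)
}

#' @rdname latent_mean_from_prob
#' @export
latent_effect_from_probs <- function(pi_T, pi_C, outcome = NULL) {
  latent_mean_from_prob(pi_T, outcome) - latent_mean_from_prob(pi_C, outcome)
}

#' @rdname latent_mean_from_prob
#' @export
ordinal_category_prob <- function(thresholds, mu_star, levels) {
  if (any(diff(thresholds) <= 0)) {
    lp_abort("thresholds must be strictly increasing",
             class = "lp_error_threshold")
  }
  w <- length(thresholds)
  levels <- sort(unique(as.integer(levels)))
  if (length(levels) == 0L || any(levels < 0L) || any(levels > w) ||
      (length(levels) > 1L && any(diff(levels) != 1L))) {
    lp_abort("levels must be a non-empty contiguous subset of 0..w",
             class = "lp_error_spec")
  }
  cuts <- c(-Inf, thresholds, Inf)
  lo <- cuts[levels[1] + 1L]
  hi <- cuts[levels[length(levels)] + 2L]
  pnorm(hi - mu_star) - pnorm(lo - mu_star)
}

#' Standardized effect vector
#'
#' Returns the per-outcome standardized effects \eqn{d_k} entering every
#' power function: \eqn{\delta_k / \sigma_k} for continuous outcomes and the
#' latent effect \eqn{\delta_k^*} for ordinal/binary outcomes (taken
#' directly if supplied, otherwise derived from the response
#' probabilities).
#'
#' @param spec A [mixed_endpoint()].
#' @return A tibble with columns `name`, `kind`, `effect_std`.
#' @examples
#' standardized_effects(muse_endpoint())
#' @export
standardized_effects <- function(spec) {
  validate_mixed_endpoint(spec)
  oc <- spec$outcomes
  eff <- purrr::pmap_dbl(
    list(oc$kind, oc$effect_obs, oc$sd, oc$prob_T, oc$prob_C,
         oc$effect_latent, oc$name),
    function(kind, effect_obs, sd, prob_T, prob_C, effect_latent, name) {
      if (kind == "continuous") {
        effect_obs / sd
      } else if (!is.na(effect_latent)) {
        effect_latent
      } else {
        latent_effect_from_probs(prob_T, prob_C, outcome = name)
      }
    }
  )
  tibble::tibble(name = oc$name, kind = oc$kind, effect_std = eff)
}

# latent means per arm implied by the spec (orientation: response = upper tail)
latent_arm_means <- function(spec) {
  oc <- spec$outcomes
  d <- standardized_effects(spec)$effect_std
  mu_C <- numeric(spec$K)
  for (i in seq_len(spec$K)) {
    row <- oc[i, ]
    if (row$kind == "continuous") {
      mu_C[i] <- 0
    } else if (!is.na(row$prob_C)) {
      thr <- row$thresholds[[1]]
      cut <- if (row$kind == "binary") 0 else thr[row$response_level]
      # P(Y* >= cut) = prob_C  =>  mu = cut + qnorm(prob_C)
      mu_C[i] <- cut + qnorm(row$prob_C)
    } else {
      mu_C[i] <- 0
    }
  }
  mu_T <- mu_C
  for (i in seq_len(spec$K)) {
    mu_T[i] <- mu_C[i] +
      if (oc$kind[i] == "continuous") oc$effect_obs[i] else d[i]
  }
  list(mu_T = mu_T, mu_C = mu_C)
}

# per-outcome latent scale (sd for continuous, 1 for discrete)
latent_scales <- function(spec) {
  ifelse(spec$outcomes$kind == "continuous", spec$outcomes$sd, 1)
}
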