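# broom-style tidiers and ggplot2 helpers for the result objects.

#' Tidy a power result
#'
#' @param x A `mixed_power` object from [power_coprimary()] or
#'   [power_union()].
#' @param ... Unused.
#' @return `tidy()`: one row per outcome (`name`, `effect_std`,
#'   `z_crit_shifted`, `marginal_power`); `glance()`: one-row summary.
#' @method tidy mixed_power
#' @export
tidy.mixed_power <- function(x, ...) {
  d <- standardized_effects(x$spec)
  tibble::tibble(
    name = d$name, kind = d$kind, effect_std = d$effect_std,
    z_crit_shifted = unname(x$shifted_criticals),
    marginal_power = unname(x$marginal_power)
  )
}

#' @rdname tidy.mixed_power
#' @method glance mixed_power
#' @export
glance.mixed_power <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint_type, K = x$spec$K,
    n_per_group = x$n_per_group, n_control = x$n_control,
    alpha = x$alpha, alpha_each = x$alpha_each, adjustment = x$adjustment,
    power = x$power, quadrature_error = x$quadrature_error
  )
}

#' Tidy a sample-size result
#'
#' @param x A `mixed_samplesize` object.
#' @param ... Unused.
#' @return `tidy()`: the evaluated power curve (`n`, `power`); `glance()`:
#'   one-row summary with the minimality certificate.
#' @method tidy mixed_samplesize
#' @export
tidy.mixed_samplesize <- function(x, ...) {
  x$curve
}

#' @rdname tidy.mixed_samplesize
#' @method glance mixed_samplesize
#' @export
glance.mixed_samplesize <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint_type,
    n_per_group = x$n_per_group, n_control = x$n_control,
    target_power = x$target_power,
    achieved_power = x$achieved_power,
    power_at_n_minus_1 = x$power_at_n_minus_1,
    alpha = x$alpha, alpha_each = x$alpha_each, adjustment = x$adjustment
  )
}

#' Tidy a latent model fit
#'
#' @param x A [latent_fit()].
#' @param ... Unused.
#' @return `tidy()`: `term`, `estimate`, `std.error`; `glance()`: one-row
#'   fit summary.
#' @method tidy latent_fit
#' @export
tidy.latent_fit <- function(x, ...) {
  se <- if (is.null(x$cov_theta)) NA_real_ else sqrt(diag(x$cov_theta))
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 std.error = unname(se))
}

#' @rdname tidy.latent_fit
#' @method glance latent_fit
#' @export
glance.latent_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, nobs = x$n_T + x$n_C, n_T = x$n_T, n_C = x$n_C,
    n_params = length(x$theta), converged = x$converged
  )
}

#' Plot the evaluated power curve of a sample-size search
#'
#' @param object A `mixed_samplesize` object.
#' @param ... Unused.
#' @return A ggplot: power at every n visited by the search, the target
#'   power, and the selected minimal n.
#' @method autoplot mixed_samplesize
#' @export
autoplot.mixed_samplesize <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$n, y = .data$power)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$target_power,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$n_per_group,
                        linetype = "dotted") +
    ggplot2::labs(
      x = "n per group", y = "power",
      title = paste0(object$endpoint_type, " endpoint: n = ",
                     object$n_per_group)
    ) +
    ggplot2::theme_minimal()
}

#' Plot power curves for a mixed endpoint
#'
#' @param data Output of [power_curve()].
#' @return A ggplot of power against per-group n, one line per endpoint.
#' @export
plot_power_curve <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$n, y = .data$power,
                                     colour = .data$endpoint)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "n per group", y = "power", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a family-wise error rate grid
#'
#' @param data Output of [fwer_grid()] (or row-bound [empirical_fwer()]
#'   results with a `fwer` or `estimate` column).
#' @param alpha Reference level drawn as a dashed line.
#' @return A ggplot of FWER against equicorrelation, one line per K.
#' @export
plot_fwer <- function(data, alpha = unique(data$alpha)[1]) {
  ycol <- if ("fwer" %in% names(data)) "fwer" else "estimate"
  ggplot2::ggplot(data, ggplot2::aes(x = .data$rho, y = .data[[ycol]],
                                     colour = factor(.data$K),
                                     linetype = .data$adjustment)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed") +
    ggplot2::labs(x = "equicorrelation", y = "FWER", colour = "K",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}
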