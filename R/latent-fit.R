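# Latent model parameter container shared by the estimation and composite
# modules. Parameters follow the identifiability conventions of the
# probit-threshold model: continuous outcomes have free per-arm means and a
# common sd; ordinal outcomes have control mean fixed at 0, free treatment
# mean and free increasing thresholds; binary outcomes have the threshold
# fixed at 0 and free per-arm means; discrete latent variances are 1; one
# correlation matrix is shared by both arms.

# expected theta names for a given outcome table
theta_template <- function(outcomes) {
  nm <- character(0)
  for (i in seq_len(nrow(outcomes))) {
    row <- outcomes[i, ]
    y <- row$name
    nm <- c(nm, paste0("mu_T.", y))
    if (row$kind != "ordinal") nm <- c(nm, paste0("mu_C.", y))
    if (row$kind == "continuous") nm <- c(nm, paste0("sigma.", y))
    if (row$kind == "ordinal") {
      nm <- c(nm, paste0("tau", seq_len(row$n_levels - 1L), ".", y))
    }
  }
  K <- nrow(outcomes)
  if (K > 1) {
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        nm <- c(nm, paste0("rho.", outcomes$name[i], ".", outcomes$name[j]))
      }
    }
  }
  nm
}

#' Construct a latent model fit object
#'
#' Container for the latent-model parameter vector \eqn{\hat\theta} and its
#' covariance, either produced by [fit_latent_model()] or assembled by hand
#' from published pilot-trial summaries. Parameter names follow the pattern
#' `mu_T.<name>`, `mu_C.<name>`, `sigma.<name>`, `tau<j>.<name>`,
#' `rho.<name1>.<name2>`; ordinal control means and binary thresholds are
#' fixed by the identifiability conventions and do not appear.
#'
#' @param theta Named parameter vector.
#' @param outcomes Outcome structure: a [mixed_endpoint()] or the outcome
#'   tibble itself (only `name`, `kind`, `n_levels` are used).
#' @param cov_theta Covariance matrix of `theta` (rows/columns in the same
#'   order), or `NULL` when unavailable.
#' @param n_T,n_C Pilot per-arm sample sizes (used to convert the
#'   delta-method variance to a per-observation scale).
#' @param loglik,converged Fit metadata.
#' @return An object of class `latent_fit`.
#' @export
latent_fit <- function(theta, outcomes, cov_theta = NULL, n_T = NA_integer_,
                       n_C = NA_integer_, loglik = NA_real_,
                       converged = NA) {
  if (inherits(outcomes, "mixed_endpoint")) outcomes <- outcomes$outcomes
  expected <- theta_template(outcomes)
  if (!setequal(names(theta), expected)) {
    missing <- setdiff(expected, names(theta))
    extra <- setdiff(names(theta), expected)
    lp_abort(paste0("theta names do not match the outcome structure",
                    if (length(missing)) paste0("; missing: ",
                                                paste(missing, collapse = ", ")),
                    if (length(extra)) paste0("; unexpected: ",
                                              paste(extra, collapse = ", "))),
             class = "lp_error_spec")
  }
  theta <- theta[expected]
  if (!is.null(cov_theta)) {
    cov_theta <- as.matrix(cov_theta)
    if (nrow(cov_theta) != length(theta) ||
        ncol(cov_theta) != length(theta)) {
      lp_abort("cov_theta must be square and aligned to theta",
               class = "lp_error_spec")
    }
    dimnames(cov_theta) <- list(expected, expected)
  }
  fit <- structure(
    list(theta = theta, cov_theta = cov_theta,
         outcomes = tibble::as_tibble(outcomes),
         n_T = n_T, n_C = n_C, loglik = loglik, converged = converged),
    class = "latent_fit"
  )
  fit_arm_params(fit)  # validates thresholds / correlations
  fit
}

#' @export
print.latent_fit <- function(x, ...) {
  cat("<latent_fit>", nrow(x$outcomes), "outcomes,",
      length(x$theta), "parameters\n")
  if (!is.na(x$n_T)) cat(sprintf("  n_T = %d, n_C = %d\n", x$n_T, x$n_C))
  if (!is.na(x$loglik)) {
    cat(sprintf("  loglik = %.3f, converged = %s\n", x$loglik,
                as.character(x$converged)))
  }
  cat("  use tidy() for estimates",
      if (is.null(x$cov_theta)) "(no covariance attached)" else
        "with standard errors", "\n")
  invisible(x)
}

# rebuild per-arm latent means, scales, thresholds and correlation matrix
# from a named theta vector
arm_params_from_theta <- function(theta, outcomes) {
  K <- nrow(outcomes)
  mu_T <- mu_C <- sds <- numeric(K)
  thresholds <- vector("list", K)
  for (i in seq_len(K)) {
    row <- outcomes[i, ]
    y <- row$name
    mu_T[i] <- theta[[paste0("mu_T.", y)]]
    mu_C[i] <- if (row$kind == "ordinal") 0 else theta[[paste0("mu_C.", y)]]
    sds[i] <- if (row$kind == "continuous") theta[[paste0("sigma.", y)]] else 1
    thresholds[[i]] <- switch(
      row$kind,
      continuous = NULL,
      binary = 0,
      ordinal = unname(vapply(seq_len(row$n_levels - 1L), function(j) {
        theta[[paste0("tau", j, ".", y)]]
      }, numeric(1)))
    )
    if (row$kind == "continuous" && sds[i] <= 0) {
      lp_abort(paste0("sigma for '", y, "' must be positive"),
               class = "lp_error_spec")
    }
    if (row$kind == "ordinal" && any(diff(thresholds[[i]]) <= 0)) {
      lp_abort(paste0("thresholds for '", y, "' must be increasing"),
               class = "lp_error_threshold")
    }
  }
  corr <- diag(K)
  if (K > 1) {
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        r <- theta[[paste0("rho.", outcomes$name[i], ".", outcomes$name[j])]]
        if (abs(r) >= 1) {
          lp_abort("correlations must lie in (-1, 1)", class = "lp_error_corr")
        }
        corr[i, j] <- corr[j, i] <- r
      }
    }
  }
  list(mu_T = mu_T, mu_C = mu_C, sd = sds, thresholds = thresholds,
       corr = corr)
}

fit_arm_params <- function(fit) {
  arm_params_from_theta(fit$theta, fit$outcomes)
}
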